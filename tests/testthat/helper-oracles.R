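# Independent oracles and toy-data builders used across the suite.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Brute-force optimal global alignment score by exhaustive enumeration of all
# alignment paths, with affine gaps (a gap run costs gap_open + len * extend).
# Exponential; use only on short strings.
brute_force_align_score <- function(a, b, sc = alignment_scoring()) {
  na <- nchar(a); nb <- nchar(b)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i == na && j == nb) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i < na && j < nb) {
      s <- if (substr(a, i + 1, i + 1) == substr(b, j + 1, j + 1))
        sc$match else sc$mismatch
      rec(i + 1, j + 1, score + s, "M")
    }
    if (i < na)
      rec(i + 1, j, score - sc$gap_extend -
            (if (prev == "I") 0 else sc$gap_open), "I")
    if (j < nb)
      rec(i, j + 1, score - sc$gap_extend -
            (if (prev == "D") 0 else sc$gap_open), "D")
  }
  rec(0L, 0L, 0, "start")
  best
}

# Brute-force left-normalization oracle: the smallest 0-based position at
# which deleting `len` bases from `sequence` yields `result`.
leftmost_equivalent_deletion <- function(sequence, len, result) {
  hits <- integer()
  for (p in 0:(nchar(sequence) - len)) {
    cand <- paste0(substr(sequence, 1, p),
                   substr(sequence, p + len + 1, nchar(sequence)))
    if (cand == result) hits <- c(hits, p)
  }
  min(hits)
}

# Exact multinomial enumeration of P(frameshift count <= x) over the three
# frame classes (in-frame 1-f, 3n+1 f/2, 3n+2 f/2) for k independent events.
enumerate_deficit_pvalue <- function(k, x, f_exp = 2 / 3) {
  probs <- c(1 - f_exp, f_exp / 2, f_exp / 2)
  grid <- do.call(expand.grid, rep(list(1:3), k))
  p_tot <- 0
  for (r in seq_len(nrow(grid))) {
    classes <- as.integer(grid[r, ])
    if (sum(classes != 1L) <= x) p_tot <- p_tot + prod(probs[classes])
  }
  p_tot
}

# Deterministic toy reference with the guide planted at `offset` (plus
# strand, AGG PAM); flanks drawn from the current RNG stream.
toy_guide <- "GGTACCTGAACGATTGCAAT"

make_toy_target <- function(offset = 10L, total = 90L, guide = toy_guide,
                            window_halfwidth = 30L) {
  repeat {
    seq <- paste0(random_dna(offset), guide, "AGG",
                  random_dna(total - offset - 23L))
    if (length(gregexpr(guide, seq, fixed = TRUE)[[1]]) == 1L &&
        !grepl(guide, reverse_complement(seq), fixed = TRUE))
      break
  }
  ref <- reference_target("toy", seq, 0L, 3L * (nchar(seq) %/% 3L))
  list(ref = ref,
       site = find_target_site(ref, guide, window_halfwidth = window_halfwidth))
}

example_calls <- function(name) crispr_e_example_calls(name)
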