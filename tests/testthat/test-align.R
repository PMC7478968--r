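test_that("a 3-nt deletion is recovered as a single left-normalized gap", {
  ref <- reference_target("toy", "ATGGCAGCTTAA", 0, 12)
  aln <- align_clone(ref, c(cl = "ATGGCTTAA"))
  # optimality against exhaustive enumeration of all global alignments
  expect_equal(aln$score,
               brute_force_align_score("ATGGCTTAA", "ATGGCAGCTTAA"))
  edits <- extract_edits(aln)
  expect_equal(nrow(edits), 1L)
  expect_equal(edits$kind, "deletion")
  expect_equal(nchar(edits$ref_allele), 3L)
  # left-normalization against brute-force enumeration of equivalent gaps
  expect_equal(edits$position,
               leftmost_equivalent_deletion("ATGGCAGCTTAA", 3, "ATGGCTTAA"))
})

test_that("an identical clone aligns gap-free with 100% identity and no edits", {
  set.seed(21)
  tt <- make_toy_target()
  aln <- align_clone(tt$ref, c(cl = tt$ref$sequence))
  expect_equal(aln$identity, 1)
  expect_equal(aln$score, 2 * nchar(tt$ref$sequence))
  expect_equal(nrow(extract_edits(aln)), 0L)
})

test_that("an unrelated sequence of equal length is rejected as unalignable", {
  set.seed(22)
  tt <- make_toy_target()
  polyA <- paste(rep("A", nchar(tt$ref$sequence)), collapse = "")
  expect_error(align_clone(tt$ref, c(bad = polyA)),
               class = "unalignable_clone")
})

test_that("alignment scores equal brute-force enumeration on short strings", {
  set.seed(23)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- random_dna(n1); b <- random_dna(n2)
    ref <- reference_target("t", b, 0, 3 * (nchar(b) %/% 3))
    aln <- align_clone(ref, c(x = a), min_identity = 0)
    expect_equal(aln$score, brute_force_align_score(a, b),
                 info = paste(a, "vs", b))
  }
  # a couple of longer cases
  for (i in 1:2) {
    a <- random_dna(8); b <- random_dna(8)
    ref <- reference_target("t", b, 0, 6)
    aln <- align_clone(ref, c(x = a), min_identity = 0)
    expect_equal(aln$score, brute_force_align_score(a, b))
  }
})

test_that("applying extracted edits to the reference reconstructs the clone", {
  set.seed(24)
  tt <- make_toy_target(total = 120L)
  for (i in 1:10) {
    # random mutant: one indel near the cut plus a possible substitution
    cfg <- sim_config(n_clones = 1L, p_edit = 1, p_fail = 0,
                      p_duplicate = 0, seed = 100 + i)
    sim <- simulate_experiment(tt$ref, tt$site, cfg)
    clone <- unname(sim$clones[1])
    aln <- align_clone(tt$ref, c(m = clone))
    edits <- extract_edits(aln, tt$site)
    expect_equal(apply_edits(tt$ref$sequence, edits), clone)
  }
})

test_that("substitutions and insertions are reported as separate edits", {
  set.seed(25)
  tt <- make_toy_target(total = 120L)
  cut <- tt$site$cut_index
  seq <- tt$ref$sequence
  ins7 <- "GATCCAT"
  mut <- apply_edits(seq, data.frame(
    kind = c("insertion", "substitution"),
    position = c(cut, cut + 6L),
    ref_allele = c("", substr(seq, cut + 7L, cut + 7L)),
    alt_allele = c(ins7, setdiff(BASES, substr(seq, cut + 7L, cut + 7L))[1]),
    stringsAsFactors = FALSE))
  edits <- extract_edits(align_clone(tt$ref, c(m = mut)), tt$site)
  expect_setequal(edits$kind, c("insertion", "substitution"))
  ins <- edits[edits$kind == "insertion", ]
  expect_equal(nchar(ins$alt_allele), 7L)
  expect_equal(net_frame_shift(edits), 7L)
  expect_equal(sum(nchar(edits$ref_allele[edits$kind == "substitution"])), 1L)
})

test_that("edits are flagged against the analysis window", {
  set.seed(26)
  tt <- make_toy_target(offset = 40L, total = 160L,
                        window_halfwidth = 10L)
  cut <- tt$site$cut_index
  seq <- tt$ref$sequence
  far_pos <- cut + 40L
  mut <- apply_edits(seq, data.frame(
    kind = "substitution", position = far_pos,
    ref_allele = substr(seq, far_pos + 1L, far_pos + 1L),
    alt_allele = setdiff(BASES, substr(seq, far_pos + 1L, far_pos + 1L))[1],
    stringsAsFactors = FALSE))
  edits <- extract_edits(align_clone(tt$ref, c(m = mut)), tt$site)
  expect_false(any(edits$in_window))
  # a deletion straddling the window end counts in-window in full
  del <- data.frame(kind = "deletion", position = cut + 8L,
                    ref_allele = substr(seq, cut + 9L, cut + 13L),
                    alt_allele = "", stringsAsFactors = FALSE)
  edits2 <- extract_edits(align_clone(tt$ref,
                                      c(m = apply_edits(seq, del))),
                          tt$site)
  expect_true(any(edits2$in_window & edits2$kind == "deletion"))
})
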