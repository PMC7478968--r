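#' Locate the sgRNA protospacer and Cas9 cut site on a reference
#'
#' Searches both strands of the reference for an exact, unique match of the
#' 20-nt protospacer immediately adjacent to an NGG protospacer-adjacent motif
#' (PAM), and derives the expected SpCas9 blunt-cut position: 3 bp 5' of the
#' PAM, i.e. between protospacer bases 17 and 18. A symmetric analysis window
#' around the cut is attached; edits outside it are reported but excluded from
#' frame classification, since NHEJ errors cluster at the double-strand break.
#'
#' Minus-strand hits are reported in plus-strand coordinates: `cut_index` is
#' the 0-based plus-strand position such that the blunt cut lies between
#' `cut_index - 1` and `cut_index`.
#'
#' @param ref A [reference_target()].
#' @param guide 20-nt protospacer sequence (A/C/G/T).
#' @param window_halfwidth Half-width of the analysis window in nt
#'   (default 30; the window is `[cut_index - w, cut_index + w)` clipped to
#'   the reference).
#' @param pam_pattern PAM as an IUPAC pattern, default `"NGG"` (SpCas9).
#' @return An object of class `"target_site"` with fields `protospacer`,
#'   `pam` (the observed PAM trinucleotide), `strand` (`"plus"`/`"minus"`),
#'   `cut_index`, `window_start`, `window_end`.
#' @examples
#' guide <- "GGTACCTGAACGATTGCAAT"
#' ref <- reference_target(
#'   "toy", paste0("ATGACCGTAC", guide, "AGGTTTGCAGCTAAACCGGTAGCATCA"), 0, 57)
#' find_target_site(ref, guide)
#' @export
find_target_site <- function(ref, guide, window_halfwidth = 30L,
                             pam_pattern = "NGG") {
  stopifnot(inherits(ref, "reference_target"))
  guide <- toupper(as.character(guide))
  if (nchar(guide) != 20L || grepl("[^ACGT]", guide))
    stop("'guide' must be a 20-nt A/C/G/T protospacer sequence")
  window_halfwidth <- as.integer(window_halfwidth)
  if (is.na(window_halfwidth) || window_halfwidth <= 0L)
    stop("'window_halfwidth' must be a positive integer")

  seq <- ref$sequence
  L <- nchar(seq)
  pam_re <- iupac_to_regex(pam_pattern)
  pam_len <- nchar(pam_pattern)

  hits <- list()   # raw protospacer matches, strand-annotated
  scan_strand <- function(s, strand) {
    starts <- BiocGenerics::start(
      Biostrings::matchPattern(guide, Biostrings::DNAString(s)))
    for (o in starts - 1L) {  # 0-based offset on the scanned strand
      pam <- substr(s, o + 21L, o + 20L + pam_len)
      hits[[length(hits) + 1L]] <<- list(
        offset = o, strand = strand,
        pam = pam, has_pam = nchar(pam) == pam_len && grepl(pam_re, pam)
      )
    }
  }
  scan_strand(seq, "plus")
  scan_strand(reverse_complement(seq), "minus")

  if (length(hits) == 0L)
    stop("guide not found: no exact protospacer match on either strand")
  good <- Filter(function(h) h$has_pam, hits)
  if (length(good) == 0L)
    stop("missing PAM: protospacer match present but not adjacent to ",
         pam_pattern)
  if (length(good) > 1L)
    stop("ambiguous target: ", length(good),
         " protospacer+PAM matches; the guide must be unique")
  h <- good[[1L]]

  # blunt cut between protospacer bases 17 and 18 (1-based), i.e. cut
  # boundary at local offset 17; minus-strand boundaries reflect as L - b.
  cut_index <- if (h$strand == "plus") h$offset + 17L else L - h$offset - 17L
  structure(
    list(protospacer = guide, pam = h$pam, strand = h$strand,
         cut_index = cut_index,
         window_start = max(0L, cut_index - window_halfwidth),
         window_end = min(L, cut_index + window_halfwidth),
         window_halfwidth = window_halfwidth),
    class = "target_site"
  )
}

#' @export
print.target_site <- function(x, ...) {
  cat("Target site: ", x$protospacer, " + PAM ", x$pam,
      " (", x$strand, " strand)\n", sep = "")
  cat("  cut between positions ", x$cut_index - 1L, " and ", x$cut_index,
      "; window [", x$window_start, ", ", x$window_end, ")\n", sep = "")
  invisible(x)
}

# IUPAC nucleotide pattern -> anchored regular expression
iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1L]]
  if (any(!chars %in% names(map)))
    stop("invalid IUPAC character in PAM pattern: ", pattern)
  paste0("^", paste(map[chars], collapse = ""), "$")
}
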