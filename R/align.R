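#' Alignment scoring parameters
#'
#' Scoring used for global (Needleman-Wunsch) alignment of a clone sequence
#' against the reference amplicon, with affine gap penalties: a gap of length
#' L costs `gap_open + L * gap_extend`. The defaults (match +2, mismatch -3,
#' gap open 6, gap extend 1) are chosen so that a single long deletion -- the
#' largest observed clonal deletions are tens of bases -- is recovered as one
#' gap rather than scattered mismatches.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening cost (positive; subtracted once per gap run).
#' @param gap_extend Gap extension cost (positive; subtracted per gap column).
#' @return An object of class `"alignment_scoring"`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3,
                              gap_open = 6, gap_extend = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

# Vectorized global alignment of many clone sequences against one reference.
# Returns a list of clone_alignment objects (see align_clone).
align_many <- function(ref, sequences, scoring = alignment_scoring()) {
  stopifnot(inherits(ref, "reference_target"))
  if (length(sequences) == 0L) return(list())
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(sequences),
    subject = Biostrings::DNAString(ref$sequence),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  scores <- Biostrings::score(aln)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("clone", seq_along(sequences))
  lapply(seq_along(sequences), function(i) {
    p <- pat[i]; s <- sub[i]
    ncol <- nchar(p)
    pm <- strsplit(p, "")[[1L]] == strsplit(s, "")[[1L]]
    structure(
      list(clone_id = ids[i], clone_aln = p, ref_aln = s,
           score = scores[i], identity = sum(pm) / ncol,
           scoring = scoring),
      class = "clone_alignment")
  })
}

#' Globally align one clone sequence to the reference
#'
#' Optimal global alignment of a clone's amplicon sequence against the
#' reference under affine gap scoring (see [alignment_scoring()]). Clones
#' whose alignment identity (matching columns / alignment columns) falls below
#' `min_identity` are rejected as unalignable -- in the full pipeline such
#' clones are demoted to sequencing failures, since a read that does not
#' resemble the amplicon carries no usable genotype.
#'
#' @param ref A [reference_target()].
#' @param clone A single DNA string, optionally named with the clone id.
#' @param scoring An [alignment_scoring()] object.
#' @param min_identity Identity floor in `[0, 1]`; default 0.6.
#' @return An object of class `"clone_alignment"` with the gapped clone and
#'   reference rows, the alignment `score` and `identity`.
#' @examples
#' ref <- reference_target("toy", "ATGGCAGCTTAA", 0, 12)
#' align_clone(ref, c(cl1 = "ATGGCTTAA"))
#' @export
align_clone <- function(ref, clone, scoring = alignment_scoring(),
                        min_identity = 0.6) {
  stopifnot(is.character(clone), length(clone) == 1L)
  clone <- stats::setNames(toupper(clone),
                           if (is.null(names(clone))) "clone" else names(clone))
  if (grepl("[^ACGT]", clone))
    stop("clone sequence contains characters other than A/C/G/T")
  a <- align_many(ref, clone, scoring)[[1L]]
  if (a$identity < min_identity)
    stop(errorCondition(
      paste0("unalignable clone '", a$clone_id, "': identity ",
             sprintf("%.1f%%", 100 * a$identity), " below floor ",
             sprintf("%.0f%%", 100 * min_identity)),
      class = "unalignable_clone"))
  a
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat("Global alignment of clone '", x$clone_id, "' (score ", x$score,
      ", identity ", sprintf("%.1f%%", 100 * x$identity), ")\n", sep = "")
  cat("  clone: ", x$clone_aln, "\n  ref:   ", x$ref_aln, "\n", sep = "")
  invisible(x)
}

#' Extract normalized edits from a clone alignment
#'
#' Walks the aligned columns and converts them to discrete edits: each
#' contiguous gap run in the reference row becomes one insertion, each gap run
#' in the clone row one deletion, and each maximal run of mismatch columns one
#' substitution. Indels are then left-normalized (shifted to their 5'-most
#' equivalent placement, as in VCF), so that sibling clones from a single
#' editing event produce byte-identical edit signatures regardless of how the
#' aligner happened to place a gap inside a repeat.
#'
#' Positions are 0-based reference coordinates; an insertion at position `p`
#' sits between reference bases `p - 1` and `p`. When a [find_target_site()]
#' window is supplied, each edit is flagged `in_window`; an edit overlapping
#' the window at all is counted in-window in full, since a deletion starting
#' at the cut may extend past any fixed window.
#'
#' @param alignment A `"clone_alignment"` from [align_clone()].
#' @param site Optional `"target_site"`; without it all edits are flagged
#'   in-window.
#' @return A data frame with columns `kind`, `position`, `ref_allele`,
#'   `alt_allele`, `in_window` (zero rows for a perfect alignment).
#' @export
extract_edits <- function(alignment, site = NULL) {
  stopifnot(inherits(alignment, "clone_alignment"))
  p <- strsplit(alignment$clone_aln, "")[[1L]]
  s <- strsplit(alignment$ref_aln, "")[[1L]]
  n <- length(p)
  kind <- character(); position <- integer()
  ref_allele <- character(); alt_allele <- character()
  i <- 1L; r <- 0L   # r = reference bases consumed so far (0-based coordinate)
  while (i <= n) {
    if (s[i] == "-") {
      j <- i; while (j <= n && s[j] == "-") j <- j + 1L
      kind <- c(kind, "insertion"); position <- c(position, r)
      ref_allele <- c(ref_allele, "")
      alt_allele <- c(alt_allele, paste(p[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (p[i] == "-") {
      j <- i; while (j <= n && p[j] == "-") j <- j + 1L
      kind <- c(kind, "deletion"); position <- c(position, r)
      ref_allele <- c(ref_allele, paste(s[i:(j - 1L)], collapse = ""))
      alt_allele <- c(alt_allele, "")
      r <- r + (j - i); i <- j
    } else if (p[i] != s[i]) {
      j <- i
      while (j <= n && s[j] != "-" && p[j] != "-" && p[j] != s[j]) j <- j + 1L
      kind <- c(kind, "substitution"); position <- c(position, r)
      ref_allele <- c(ref_allele, paste(s[i:(j - 1L)], collapse = ""))
      alt_allele <- c(alt_allele, paste(p[i:(j - 1L)], collapse = ""))
      r <- r + (j - i); i <- j
    } else {
      r <- r + 1L; i <- i + 1L
    }
  }
  edits <- data.frame(kind = kind, position = position,
                      ref_allele = ref_allele, alt_allele = alt_allele,
                      stringsAsFactors = FALSE)
  edits <- left_normalize(edits, refseq_of(alignment))
  flag_window(edits, site)
}

# Recover the ungapped reference row
refseq_of <- function(alignment) gsub("-", "", alignment$ref_aln, fixed = TRUE)

#' Left-normalize indel edits
#'
#' Shifts each insertion/deletion to its 5'-most equivalent reference
#' position (the placement producing the same mutant sequence), rotating the
#' allele accordingly -- the VCF normalization convention. Substitutions are
#' untouched.
#'
#' @param edits Edit data frame (see [extract_edits()]).
#' @param sequence The (ungapped) reference sequence the positions refer to.
#' @return The normalized edit data frame, ordered by position.
#' @export
left_normalize <- function(edits, sequence) {
  if (nrow(edits) == 0L) return(edits)
  for (i in seq_len(nrow(edits))) {
    kind <- edits$kind[i]
    if (kind == "substitution") next
    pos <- edits$position[i]
    allele <- if (kind == "deletion") edits$ref_allele[i] else edits$alt_allele[i]
    len <- nchar(allele)
    # shifting one left is valid iff the base entering the allele from the
    # left equals the base leaving it on the right
    while (pos > 0L &&
           substr(sequence, pos, pos) == substr(allele, len, len)) {
      allele <- paste0(substr(sequence, pos, pos),
                       substr(allele, 1L, len - 1L))
      pos <- pos - 1L
    }
    edits$position[i] <- pos
    if (kind == "deletion") edits$ref_allele[i] <- allele
    else edits$alt_allele[i] <- allele
  }
  edits[order(edits$position, edits$kind), , drop = FALSE]
}

# Attach the in_window flag; an edit counts in-window if its reference
# footprint intersects [window_start, window_end) (insertions: the insertion
# point lies within the closed window).
flag_window <- function(edits, site) {
  if (nrow(edits) == 0L) {
    edits$in_window <- logical(0)
    return(edits)
  }
  if (is.null(site)) {
    edits$in_window <- rep(TRUE, nrow(edits))
    return(edits)
  }
  stopifnot(inherits(site, "target_site"))
  ws <- site$window_start; we <- site$window_end
  len <- ifelse(edits$kind == "insertion", 0L, nchar(edits$ref_allele))
  edits$in_window <- ifelse(
    edits$kind == "insertion",
    edits$position >= ws & edits$position <= we,
    edits$position < we & (edits$position + len) > ws)
  edits
}
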