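#' Reference amplicon with ORF annotation
#'
#' Constructs the reference target object: the amplified reference sequence
#' (the region PCR-amplified and Sanger-sequenced in each clone) together with
#' the coordinates of the open reading frame it covers. Coordinates are
#' 0-based, half-open throughout the package: `orf_start` is the offset of the
#' first base of a codon, `orf_end` the exclusive end of the ORF region
#' covered by the amplicon.
#'
#' @param name Identifier for the target (typically the gene name).
#' @param sequence DNA string. Uppercased on input; only A/C/G/T are accepted
#'   (ambiguity codes are rejected, since clonal Sanger calls of a haploid
#'   target should be unambiguous).
#' @param orf_start 0-based offset of the first codon base within `sequence`.
#' @param orf_end 0-based exclusive end of the ORF region
#'   (`orf_start < orf_end <= nchar(sequence)`).
#' @return An object of class `"reference_target"`.
#' @seealso [read_reference()], [find_target_site()]
#' @examples
#' ref <- reference_target("toy", "ATGGCAGCTGGTTAA", 0, 15)
#' ref
#' @export
reference_target <- function(name, sequence, orf_start, orf_end) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty DNA string")
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence contains characters other than A/C/G/T ",
         "(ambiguity codes are not supported)")
  orf_start <- as.integer(orf_start)
  orf_end <- as.integer(orf_end)
  if (is.na(orf_start) || is.na(orf_end) ||
      orf_start < 0L || orf_start >= orf_end || orf_end > nchar(sequence))
    stop("invalid ORF annotation: need 0 <= orf_start < orf_end <= length(sequence)")
  structure(
    list(name = name, sequence = sequence,
         orf_start = orf_start, orf_end = orf_end),
    class = "reference_target"
  )
}

#' @export
print.reference_target <- function(x, ...) {
  cat("Reference target '", x$name, "': ", nchar(x$sequence), " nt, ORF [",
      x$orf_start, ", ", x$orf_end, ")\n", sep = "")
  invisible(x)
}

#' Read a reference target from a FASTA file
#'
#' Reads a single-record FASTA file and annotates the ORF interval.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param orf_start,orf_end 0-based half-open ORF interval (see
#'   [reference_target()]). Default: the whole sequence trimmed to a codon
#'   boundary.
#' @param name Optional name override; defaults to the FASTA record id.
#' @return A `"reference_target"` object.
#' @export
read_reference <- function(path, orf_start = 0L, orf_end = NULL, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(seqs))
  seq <- as.character(seqs[[1L]])
  if (is.null(name)) name <- sub("\\s.*$", "", names(seqs)[1L])
  if (is.null(orf_end))
    orf_end <- orf_start + 3L * ((nchar(seq) - orf_start) %/% 3L)
  reference_target(name, seq, orf_start, orf_end)
}

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string (A/C/G/T).
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Apply edits to a reference sequence
#'
#' Reconstructs a mutant sequence by applying a set of edits (as produced by
#' [extract_edits()] or read from a variant table) to the reference. Edits
#' must be non-overlapping; they are applied right-to-left so positions refer
#' to the unedited reference.
#'
#' @param sequence Reference DNA string.
#' @param edits A data frame with columns `kind`
#'   (`"insertion"`/`"deletion"`/`"substitution"`), `position` (0-based
#'   reference coordinate), `ref_allele`, `alt_allele`. Insertions have an
#'   empty `ref_allele` and are placed before `position`; deletions remove
#'   `nchar(ref_allele)` bases starting at `position`.
#' @return The mutant sequence as a character string.
#' @export
apply_edits <- function(sequence, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(sequence)
  edits <- edits[order(edits$position, decreasing = TRUE), , drop = FALSE]
  n <- nchar(sequence)
  for (i in seq_len(nrow(edits))) {
    pos <- edits$position[i]
    kind <- edits$kind[i]
    ref <- edits$ref_allele[i]
    alt <- edits$alt_allele[i]
    left <- if (pos > 0L) substr(sequence, 1L, pos) else ""
    if (kind == "insertion") {
      right <- substr(sequence, pos + 1L, nchar(sequence))
      sequence <- paste0(left, alt, right)
    } else if (kind == "deletion") {
      if (substr(sequence, pos + 1L, pos + nchar(ref)) != ref)
        stop("deletion ref_allele does not match reference at position ", pos)
      right <- substr(sequence, pos + nchar(ref) + 1L, nchar(sequence))
      sequence <- paste0(left, right)
    } else if (kind == "substitution") {
      if (substr(sequence, pos + 1L, pos + nchar(ref)) != ref)
        stop("substitution ref_allele does not match reference at position ", pos)
      right <- substr(sequence, pos + nchar(ref) + 1L, nchar(sequence))
      sequence <- paste0(left, alt, right)
    } else stop("unknown edit kind: ", kind)
  }
  sequence
}

# Standard genetic code as a plain lookup, fixed once at install time.
CODON_TABLE <- Biostrings::GENETIC_CODE

# Translate a strict A/C/G/T DNA string, trimming to a codon boundary.
# Plain table lookup: orders of magnitude cheaper than constructing XString
# objects per clone, and the inputs are already validated.
translate_dna <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0L) return("")
  codons <- substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  paste(unname(CODON_TABLE[codons]), collapse = "")
}
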