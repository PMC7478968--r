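#' Read clone sequences and statuses
#'
#' Reads a multi-FASTA of per-clone amplicon sequences (record ids are clone
#' ids) plus an optional sidecar status table marking clones whose sequencing
#' failed; failed clones listed only in the status table (no usable sequence)
#' are carried as failures.
#'
#' @param fasta Path to a multi-FASTA file.
#' @param status_tsv Optional path to a TSV with columns `clone_id`, `status`
#'   (`ok` / `failed_sequencing`).
#' @return A list with `sequences` (named character vector) and `status`
#'   (data frame, `NULL` when no sidecar is given).
#' @export
read_clones <- function(fasta, status_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no clones: FASTA file contains no records")
  sequences <- stats::setNames(as.character(seqs),
                               sub("\\s.*$", "", names(seqs)))
  status <- NULL
  if (!is.null(status_tsv)) {
    status <- utils::read.delim(status_tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("clone_id", "status") %in% names(status)))
  }
  list(sequences = sequences, status = status)
}

#' Read a pre-called variant table
#'
#' Reads the TSV format used for pre-called per-clone variants (and for the
#' published clone compositions shipped with the package): columns
#' `clone_id`, `kind` (`insertion`/`deletion`/`substitution`/`none`),
#' `position` (0-based), `ref_allele`, `alt_allele`, optional `status`.
#'
#' @param path Path to the TSV.
#' @return A data frame suitable for [calls_from_variants()].
#' @export
read_variant_table <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = character())
  need <- c("clone_id", "kind", "position", "ref_allele", "alt_allele")
  if (!all(need %in% names(v)))
    stop("variant table must have columns ", paste(need, collapse = ", "))
  v$position <- suppressWarnings(as.integer(v$position))
  v
}

# serialize one clone's edits for the per-clone TSV
edits_field <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  paste(sprintf("%s:%d:%s>%s", substr(edits$kind, 1, 3), edits$position,
                edits$ref_allele, edits$alt_allele), collapse = ";")
}

#' Write per-clone and per-event call tables
#'
#' @param calls An `"allele_calls"` table.
#' @param events Event table from [collapse_events()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_call_tables <- function(calls, events, dir, prefix = "crisprE") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_clone <- calls[, setdiff(names(calls), "edits")]
  per_clone$edits <- vapply(calls$edits, edits_field, "")
  paths <- c(clones = file.path(dir, paste0(prefix, "_clones.tsv")),
             events = file.path(dir, paste0(prefix, "_events.tsv")))
  utils::write.table(per_clone, paths[["clones"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(events, paths[["events"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Paths to the bundled example datasets
#'
#' The package ships the clone compositions of five published clonal editing
#' experiments in the model amoeba Dictyostelium discoideum as pre-called
#' variant tables: `grlB` (6 edited + 6 failed clones), `grlC` (12 edited
#' clones containing two identical sibling pairs), `KIF1A` (19 clones),
#' `fAR1` (5 clones) and three `Dync1li1` experiments (two single-guide
#' experiments and a two-guide combined experiment in which every surviving
#' edited allele is in-frame). Net indel sizes, substitution counts, failure
#' and sibling structure follow the published per-clone compositions; the
#' nucleotide-level sequences and coordinates are synthetic stand-ins (the
#' source experiments deposited none), so files carrying sequence are named
#' `*synthetic*`. For `grlB` a synthetic reference/guide/clone-FASTA trio
#' exercises the full alignment path.
#'
#' @param name One of `"grlB"`, `"grlC"`, `"KIF1A"`, `"fAR1"`,
#'   `"Dync1li1_sg1"`, `"Dync1li1_sg2"`, `"Dync1li1_combined"`.
#' @return For `crispr_e_example()`, a list with `variants` (data frame) and,
#'   for `grlB`, paths `reference`, `clones`, `status` and the `guide`
#'   string. `crispr_e_example_calls()` returns the `"allele_calls"` table
#'   directly.
#' @examples
#' ex <- crispr_e_example("grlC")
#' head(ex$variants)
#' @export
crispr_e_example <- function(name = c("grlB", "grlC", "KIF1A", "fAR1",
                                      "Dync1li1_sg1", "Dync1li1_sg2",
                                      "Dync1li1_combined")) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "crisprE",
                                 mustWork = TRUE)
  out <- list(name = name,
              variants = read_variant_table(
                ext(paste0(name, "_variants.tsv"))))
  if (name == "grlB") {
    out$reference <- ext("grlB_synthetic_ref.fasta")
    out$clones <- ext("grlB_synthetic_clones.fasta")
    out$status <- ext("grlB_clone_status.tsv")
    out$guide <- readLines(ext("grlB_guide.txt"))[1L]
    out$orf_start <- 0L
  }
  out
}

#' @rdname crispr_e_example
#' @export
crispr_e_example_calls <- function(name) {
  calls_from_variants(crispr_e_example(name)$variants)
}
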