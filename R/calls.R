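FRAME_CLASSES <- c("WT", "in_frame", "frameshift_plus1", "frameshift_plus2")

#' Net reading-frame shift of a set of edits
#'
#' Sums insertion lengths (positive) and deletion lengths (negative);
#' substitutions preserve length and contribute 0. The residue of this net
#' length mod 3 decides the frame class: 3n edits leave the downstream frame
#' intact, 3n+1 and 3n+2 scramble it.
#'
#' @param edits Edit data frame (see [extract_edits()]); callers should pass
#'   in-window edits only.
#' @return Integer net indel length in nt.
#' @export
net_frame_shift <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(0L)
  as.integer(sum(ifelse(edits$kind == "insertion", nchar(edits$alt_allele),
                 ifelse(edits$kind == "deletion", -nchar(edits$ref_allele),
                        0L))))
}

#' Classify an allele by its reading-frame consequence
#'
#' Maps the in-window edits of one clone to a frame class: no edits is `WT`;
#' otherwise the non-negative residue of the net indel length mod 3 gives
#' `in_frame` (0), `frameshift_plus1` (1) or `frameshift_plus2` (2).
#' Substitution-only alleles are edited and in-frame. For in-frame alleles a
#' `stop_gain` flag records whether the re-translated ORF segment gains a stop
#' codon absent from the reference segment -- an in-frame edit that may still
#' knock the gene out. A frameshift's downstream stop is implied, never
#' flagged.
#'
#' @param edits In-window edit data frame for one clone.
#' @param ref Optional [reference_target()]; required for stop-gain detection.
#' @param site Optional `"target_site"` bounding the re-translated segment.
#' @return A list with `frame_class`, `net_indel`, `n_substitutions`,
#'   `stop_gain` (NA when no reference is available) and
#'   `protein_consequence` (NA without a reference).
#' @examples
#' del4 <- data.frame(kind = "deletion", position = 10, ref_allele = "ACGT",
#'                    alt_allele = "")
#' classify_allele(del4)$frame_class   # -4 = 3n+2
#' @export
classify_allele <- function(edits, ref = NULL, site = NULL) {
  net <- net_frame_shift(edits)
  nsub <- if (is.null(edits) || nrow(edits) == 0L) 0L else
    as.integer(sum(nchar(edits$ref_allele[edits$kind == "substitution"])))
  if (is.null(edits) || nrow(edits) == 0L) {
    return(list(frame_class = "WT", net_indel = 0L, n_substitutions = 0L,
                stop_gain = FALSE, protein_consequence = NA_character_))
  }
  frame_class <- switch(as.character(net %% 3L),
                        "0" = "in_frame",
                        "1" = "frameshift_plus1",
                        "2" = "frameshift_plus2")
  stop_gain <- NA
  consequence <- NA_character_
  if (!is.null(ref) && all(edits$position >= ref$orf_start)) {
    tr <- translate_allele(ref, edits, site)
    consequence <- tr$protein
    stop_gain <- if (frame_class == "in_frame") tr$stop_gain else FALSE
  } else if (frame_class != "in_frame") {
    stop_gain <- FALSE
  }
  list(frame_class = frame_class, net_indel = net, n_substitutions = nsub,
       stop_gain = stop_gain, protein_consequence = consequence)
}

#' Translate the mutant ORF segment of an allele
#'
#' Applies the edits to the reference, then translates the mutant ORF from
#' `orf_start` with the standard codon table. For in-frame alleles the
#' translated segment spans the edited region plus one codon (so a stop
#' created at the cut is seen); for frameshift alleles translation continues
#' downstream to the first stop codon or the end of the annotated ORF.
#'
#' @param ref A [reference_target()].
#' @param edits In-window edit data frame.
#' @param site Optional `"target_site"`; bounds the in-frame segment at
#'   `window_end` plus one codon. Without it the whole ORF is used.
#' @return A list with `protein` (mutant amino-acid string), `ref_protein`
#'   (reference segment) and `stop_gain`.
#' @export
translate_allele <- function(ref, edits, site = NULL) {
  stopifnot(inherits(ref, "reference_target"))
  if (ref$orf_start >= ref$orf_end)
    stop("frame annotation error: empty ORF interval")
  net <- net_frame_shift(edits)
  seg_end_lim <- if (is.null(site)) ref$orf_end else
    min(ref$orf_end, site$window_end + 3L)
  if (!is.null(edits) && nrow(edits) > 0L) {
    last <- max(edits$position + ifelse(edits$kind == "insertion", 0L,
                                        nchar(edits$ref_allele)))
    seg_end_lim <- max(seg_end_lim, min(ref$orf_end, last + 3L))
    if (any(edits$position < ref$orf_start))
      stop("frame annotation error: edit upstream of orf_start")
  }
  seg_len <- 3L * ((seg_end_lim - ref$orf_start) %/% 3L)
  seg_end <- ref$orf_start + seg_len
  ref_seg <- substr(ref$sequence, ref$orf_start + 1L, seg_end)
  ref_prot <- translate_dna(ref_seg)
  mut <- apply_edits(ref$sequence, edits)
  if (net %% 3L == 0L) {
    mut_seg <- substr(mut, ref$orf_start + 1L, seg_end + net)
    prot <- translate_dna(mut_seg)
    stop_gain <- grepl("*", prot, fixed = TRUE) &&
      !grepl("*", ref_prot, fixed = TRUE)
  } else {
    # frameshift: read through to the first downstream stop or ORF end
    mut_orf_end <- min(nchar(mut), ref$orf_end + net)
    prot <- translate_dna(substr(mut, ref$orf_start + 1L, mut_orf_end))
    prot <- sub("(\\*).*$", "\\1", prot)   # truncate after first stop
    stop_gain <- FALSE
  }
  list(protein = prot, ref_protein = ref_prot, stop_gain = stop_gain)
}

# Canonical signature of a clone's in-window edits, for sibling detection.
edit_signature <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  e <- edits[order(edits$position, edits$kind, edits$alt_allele), , drop = FALSE]
  paste(sprintf("%s:%d:%s:%s", e$kind, e$position, e$ref_allele, e$alt_allele),
        collapse = ";")
}

new_allele_calls <- function(df) {
  class(df) <- c("allele_calls", "data.frame")
  df
}

#' Call alleles for a set of clone sequences
#'
#' The per-clone workhorse: aligns every successfully sequenced clone to the
#' reference ([align_clone()]), extracts and normalizes its edits
#' ([extract_edits()]), computes the net frame shift over in-window edits,
#' classifies the allele ([classify_allele()]) and translates its protein
#' consequence. Clones listed as failed, or whose alignment identity falls
#' below the floor, are carried through with status `failed_sequencing` and
#' excluded from all denominators downstream.
#'
#' @param ref A [reference_target()].
#' @param clones Named character vector of clone sequences (names are clone
#'   ids), or a `Biostrings::DNAStringSet`.
#' @param site A `"target_site"` from [find_target_site()]; may be `NULL`, in
#'   which case every edit is in-window.
#' @param status Optional data frame (`clone_id`, `status`) marking
#'   `failed_sequencing` clones; clones present here but absent from `clones`
#'   are included as failed.
#' @param scoring An [alignment_scoring()].
#' @param min_identity Alignment identity floor (see [align_clone()]).
#' @return An `"allele_calls"` data frame with one row per clone: `clone_id`,
#'   `status`, `edited` (has in-window edits), `n_edits`, `net_indel`,
#'   `n_substitutions`, `frame_class`, `stop_gain`, `protein_consequence`,
#'   `signature`, `outside_window`, and a list column `edits`.
#' @export
call_alleles <- function(ref, clones, site = NULL, status = NULL,
                         scoring = alignment_scoring(), min_identity = 0.6) {
  stopifnot(inherits(ref, "reference_target"))
  if (methods::is(clones, "DNAStringSet"))
    clones <- stats::setNames(as.character(clones), names(clones))
  if (length(clones) > 0 && is.null(names(clones)))
    names(clones) <- paste0("clone", seq_along(clones))
  failed_ids <- character()
  if (!is.null(status)) {
    stopifnot(all(c("clone_id", "status") %in% names(status)))
    failed_ids <- status$clone_id[status$status == "failed_sequencing"]
  }
  ok_ids <- setdiff(names(clones), failed_ids)
  all_ids <- union(names(clones), if (!is.null(status)) status$clone_id else character())

  alns <- align_many(ref, clones[ok_ids], scoring)
  rows <- lapply(all_ids, function(id) {
    if (!(id %in% ok_ids))
      return(call_row(id, "failed_sequencing"))
    a <- alns[[match(id, ok_ids)]]
    if (a$identity < min_identity)
      return(call_row(id, "failed_sequencing"))
    edits <- extract_edits(a, site)
    inw <- edits[edits$in_window, , drop = FALSE]
    cls <- classify_allele(inw, ref, site)
    call_row(id, "ok", edits = edits, cls = cls,
             outside_window = any(!edits$in_window))
  })
  out <- do.call(rbind, rows)
  out$edits <- I(lapply(rows, attr, "edits"))
  new_allele_calls(out)
}

call_row <- function(id, status, edits = NULL, cls = NULL,
                     outside_window = FALSE) {
  if (is.null(cls))
    cls <- list(frame_class = NA_character_, net_indel = NA_integer_,
                n_substitutions = NA_integer_, stop_gain = NA,
                protein_consequence = NA_character_)
  inw <- if (is.null(edits)) NULL else edits[edits$in_window, , drop = FALSE]
  df <- data.frame(
    clone_id = id, status = status,
    edited = !is.null(inw) && nrow(inw) > 0L,
    n_edits = if (is.null(edits)) NA_integer_ else nrow(edits),
    net_indel = cls$net_indel, n_substitutions = cls$n_substitutions,
    frame_class = cls$frame_class, stop_gain = cls$stop_gain,
    protein_consequence = cls$protein_consequence,
    signature = if (is.null(inw)) NA_character_ else edit_signature(inw),
    outside_window = outside_window,
    stringsAsFactors = FALSE)
  attr(df, "edits") <- edits
  df
}

#' Build allele calls from a pre-called variant table
#'
#' Bypasses alignment: takes per-clone edits already expressed as variants
#' (the format in which published clone compositions are distributed with
#' this package) and produces the same `"allele_calls"` table as
#' [call_alleles()]. Rows with `kind = "none"` denote unedited (WT) clones; a
#' `status` column may mark `failed_sequencing` clones.
#'
#' @param variants Data frame with columns `clone_id`, `kind`
#'   (`insertion`/`deletion`/`substitution`/`none`), `position`, `ref_allele`,
#'   `alt_allele`, and optionally `status`. Multiple rows per clone are
#'   multiple edits of that clone.
#' @param ref Optional [reference_target()] enabling translation and
#'   stop-gain calls (positions must then refer to this reference).
#' @param site Optional `"target_site"` for window flagging.
#' @return An `"allele_calls"` data frame (see [call_alleles()]).
#' @export
calls_from_variants <- function(variants, ref = NULL, site = NULL) {
  need <- c("clone_id", "kind", "position", "ref_allele", "alt_allele")
  stopifnot(all(need %in% names(variants)))
  variants$ref_allele[is.na(variants$ref_allele)] <- ""
  variants$alt_allele[is.na(variants$alt_allele)] <- ""
  ids <- unique(variants$clone_id)
  rows <- lapply(ids, function(id) {
    v <- variants[variants$clone_id == id, , drop = FALSE]
    if ("status" %in% names(v) && any(v$status == "failed_sequencing"))
      return(call_row(id, "failed_sequencing"))
    v <- v[v$kind != "none", , drop = FALSE]
    edits <- data.frame(kind = v$kind, position = as.integer(v$position),
                        ref_allele = v$ref_allele, alt_allele = v$alt_allele,
                        stringsAsFactors = FALSE)
    if (!is.null(ref)) edits <- left_normalize(edits, ref$sequence)
    edits <- flag_window(edits, site)
    inw <- edits[edits$in_window, , drop = FALSE]
    cls <- classify_allele(inw, ref, site)
    call_row(id, "ok", edits = edits, cls = cls,
             outside_window = any(!edits$in_window))
  })
  out <- do.call(rbind, rows)
  out$edits <- I(lapply(rows, attr, "edits"))
  new_allele_calls(out)
}

#' @export
print.allele_calls <- function(x, ...) {
  cat("Allele calls for ", nrow(x), " clones (",
      sum(x$status == "ok"), " sequenced, ",
      sum(x$status != "ok"), " failed)\n", sep = "")
  print.data.frame(x[, setdiff(names(x), "edits")], row.names = FALSE, ...)
  invisible(x)
}

#' Collapse identical clones into independent editing events
#'
#' Clones with byte-identical in-window edit signatures are progeny of a
#' single Cas9 cut-and-repair event that divided before cloning; they are
#' merged into one independent event so downstream statistics are not
#' pseudo-replicated. WT clones are never events and never merged with edited
#' clones.
#'
#' @param calls An `"allele_calls"` data frame.
#' @return A list with `events` (one row per independent event: `event_id`,
#'   `signature`, `n_clones`, `clone_ids`, `net_indel`, `frame_class`,
#'   `stop_gain`) and `summary`, an [editing_summary()] object.
#' @export
collapse_events <- function(calls) {
  stopifnot(inherits(calls, "allele_calls"))
  ok <- calls[calls$status == "ok", , drop = FALSE]
  ed <- ok[ok$edited, , drop = FALSE]
  sigs <- unique(ed$signature)
  events <- do.call(rbind, lapply(seq_along(sigs), function(i) {
    g <- ed[ed$signature == sigs[i], , drop = FALSE]
    data.frame(event_id = sprintf("event%02d", i), signature = sigs[i],
               n_clones = nrow(g),
               clone_ids = paste(g$clone_id, collapse = ","),
               net_indel = g$net_indel[1L],
               n_substitutions = g$n_substitutions[1L],
               frame_class = g$frame_class[1L], stop_gain = g$stop_gain[1L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(event_id = character(), signature = character(),
                         n_clones = integer(), clone_ids = character(),
                         net_indel = integer(), n_substitutions = integer(),
                         frame_class = character(), stop_gain = logical(),
                         stringsAsFactors = FALSE)
  list(events = events, summary = editing_summary(calls, events))
}

#' Per-experiment editing summary
#'
#' Tallies clones and independent events: total clones, sequencing failures,
#' successfully sequenced clones, WT vs edited clones, independent events,
#' and frame-class counts over both clones and events. Invariants
#' `n_clones = n_failed + n_sequenced`, `n_sequenced = n_wt + n_edited` and
#' `n_events <= n_edited` hold by construction.
#'
#' @param calls An `"allele_calls"` data frame.
#' @param events Event table from [collapse_events()]; computed if missing.
#' @return An object of class `"editing_summary"`.
#' @export
editing_summary <- function(calls, events = NULL) {
  stopifnot(inherits(calls, "allele_calls"))
  if (is.null(events)) return(collapse_events(calls)$summary)
  ok <- calls[calls$status == "ok", , drop = FALSE]
  tally <- function(fc) {
    out <- stats::setNames(integer(length(FRAME_CLASSES)), FRAME_CLASSES)
    t <- table(factor(fc, levels = FRAME_CLASSES))
    out[names(t)] <- as.integer(t)
    out
  }
  clone_counts <- tally(ok$frame_class)
  event_counts <- tally(events$frame_class)
  structure(list(
    n_clones = nrow(calls),
    n_failed = sum(calls$status != "ok"),
    n_sequenced = nrow(ok),
    n_wt = sum(!ok$edited),
    n_edited = sum(ok$edited),
    n_events = nrow(events),
    clone_class_counts = clone_counts,
    event_class_counts = event_counts,
    n_stop_gain = sum(events$stop_gain %in% TRUE),
    failed_ids = calls$clone_id[calls$status != "ok"]
  ), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("Editing summary: ", x$n_clones, " clones (",
      x$n_sequenced, " sequenced, ", x$n_failed, " failed)\n", sep = "")
  cat("  WT ", x$n_wt, " | edited ", x$n_edited,
      " | independent events ", x$n_events, "\n", sep = "")
  ev <- x$event_class_counts
  cat("  events by frame class: in-frame ", ev[["in_frame"]],
      ", 3n+1 ", ev[["frameshift_plus1"]],
      ", 3n+2 ", ev[["frameshift_plus2"]], "\n", sep = "")
  if (x$n_stop_gain > 0)
    cat("  note: ", x$n_stop_gain,
        " in-frame event(s) create a premature stop codon\n", sep = "")
  invisible(x)
}
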