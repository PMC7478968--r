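#' Run the allele-calling stage of the workflow
#'
#' File-level entry point tying the calling modules together: reads the
#' reference and clones (FASTA plus optional status sidecar) or a pre-called
#' variant table, locates the target site when a guide is given, calls
#' alleles, collapses siblings into events, and optionally writes the
#' per-clone and per-event TSVs. Exactly one of `clones` or `variants` must
#' be supplied.
#'
#' @param reference Path to a single-record reference FASTA, or a
#'   [reference_target()] (optional for the variant-table path).
#' @param clones Path to a clones multi-FASTA.
#' @param variants Path to a variant table TSV (see [read_variant_table()]).
#' @param status Optional path to a clone-status TSV.
#' @param guide Optional 20-nt protospacer; enables window flagging.
#' @param orf_start,orf_end ORF annotation when `reference` is a path.
#' @param window_halfwidth Analysis window half-width (default 30 nt).
#' @param scoring An [alignment_scoring()].
#' @param min_identity Alignment identity floor (default 0.6).
#' @param out_dir Optional output directory for TSVs.
#' @return A list with `calls`, `events`, `summary`, `ref`, `site`.
#' @export
run_call <- function(reference = NULL, clones = NULL, variants = NULL,
                     status = NULL, guide = NULL,
                     orf_start = 0L, orf_end = NULL, window_halfwidth = 30L,
                     scoring = alignment_scoring(), min_identity = 0.6,
                     out_dir = NULL) {
  if (is.null(clones) == is.null(variants))
    stop("provide exactly one of 'clones' (FASTA) or 'variants' (TSV)")
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "reference_target")) reference
           else read_reference(reference, orf_start, orf_end)
  }
  site <- NULL
  if (!is.null(guide)) {
    if (is.null(ref)) stop("a reference is required to locate the guide")
    site <- find_target_site(ref, guide, window_halfwidth)
  }
  status_df <- if (is.null(status)) NULL
               else if (is.data.frame(status)) status
               else utils::read.delim(status, stringsAsFactors = FALSE)
  calls <- if (!is.null(clones)) {
    if (is.null(ref)) stop("a reference is required to align clones")
    cl <- read_clones(clones, NULL)
    call_alleles(ref, cl$sequences, site, status = status_df,
                 scoring = scoring, min_identity = min_identity)
  } else {
    v <- if (is.data.frame(variants)) variants else read_variant_table(variants)
    calls_from_variants(v, ref = ref, site = site)
  }
  ev <- collapse_events(calls)
  for (id in ev$summary$failed_ids)
    message("clone ", id, " excluded: failed sequencing / unalignable")
  if (!is.null(out_dir)) write_call_tables(calls, ev$events, out_dir)
  list(calls = calls, events = ev$events, summary = ev$summary,
       ref = ref, site = site)
}

#' Run the essentiality-statistics stage
#'
#' Fits the CRISPR-E model to an editing summary (or the result of
#' [run_call()]) and renders the report. When no edited events were observed
#' the function warns and reports that essentiality is untestable instead of
#' failing.
#'
#' @param x An [editing_summary()], an `"allele_calls"` table, or the list
#'   returned by [run_call()].
#' @param f_exp Theoretical frameshift frequency (default 2/3).
#' @param confidence Confidence level (default 0.95).
#' @return A list with `fit` (`"crispr_e"` or `NULL`), `summary`, `report`
#'   (character vector of text lines) and `json` (single JSON string).
#' @export
run_stats <- function(x, f_exp = 2 / 3, confidence = 0.95) {
  summary <-
    if (inherits(x, "editing_summary")) x
    else if (inherits(x, "allele_calls")) collapse_events(x)$summary
    else if (is.list(x) && inherits(x$summary, "editing_summary")) x$summary
    else stop("cannot extract an editing summary from 'x'")
  fit <- NULL
  if (summary$n_events > 0L) {
    fit <- crispr_e(summary, f_exp = f_exp, conf.level = confidence)
  } else {
    warning("no evidence of editing; essentiality untestable")
  }
  rep <- render_report(fit, summary)
  list(fit = fit, summary = summary, report = rep$text, json = rep$json)
}

#' Render the CRISPR-E report
#'
#' Produces the human-readable report block and the machine-readable JSON for
#' a fit and its editing summary. Every number in the text also appears in
#' the JSON; field order is fixed and the schema is versioned, so re-running
#' on identical inputs yields byte-identical JSON.
#'
#' @param fit A `"crispr_e"` fit, or `NULL` when no editing was observed.
#' @param summary The [editing_summary()] the fit was made from (optional
#'   when `fit` carries one).
#' @return A list with `text` (character lines) and `json` (string).
#' @export
render_report <- function(fit, summary = NULL) {
  if (is.null(summary) && !is.null(fit)) summary <- fit$summary
  payload <- list(schema = "crisprE-report/1")
  text <- character()
  push <- function(...) text <<- c(text, sprintf(...))

  if (!is.null(summary)) {
    ev <- summary$event_class_counts
    payload$counts <- list(
      n_clones = summary$n_clones, n_failed = summary$n_failed,
      n_sequenced = summary$n_sequenced, n_wt = summary$n_wt,
      n_edited = summary$n_edited, n_events = summary$n_events,
      events_in_frame = unname(ev[["in_frame"]]),
      events_frameshift_plus1 = unname(ev[["frameshift_plus1"]]),
      events_frameshift_plus2 = unname(ev[["frameshift_plus2"]]),
      n_stop_gain_in_frame = summary$n_stop_gain)
    payload$failed_clones <- as.list(summary$failed_ids)
    push("Clones: %d total, %d sequenced, %d failed (%s)",
         summary$n_clones, summary$n_sequenced, summary$n_failed,
         if (summary$n_failed > 0)
           paste(summary$failed_ids, collapse = ", ") else "none")
    push("Sequenced clones: %d WT, %d edited; %d independent events",
         summary$n_wt, summary$n_edited, summary$n_events)
    push("Events by frame class: in-frame %d, 3n+1 %d, 3n+2 %d (stop-gain in-frame: %d)",
         ev[["in_frame"]], ev[["frameshift_plus1"]], ev[["frameshift_plus2"]],
         summary$n_stop_gain)
    if (summary$n_sequenced > 0) {
      ee <- editing_efficiency(summary)
      ie <- inactivation_efficiency(summary)
      payload$clone_level <- list(
        editing_efficiency = as.numeric(ee),
        editing_numerator = attr(ee, "numerator"),
        editing_denominator = attr(ee, "denominator"),
        inactivation_efficiency = as.numeric(ie),
        inactivation_numerator = attr(ie, "numerator"),
        inactivation_denominator = attr(ie, "denominator"))
      push("Editing efficiency (per sequenced clone): %d/%d = %.1f%%",
           attr(ee, "numerator"), attr(ee, "denominator"), 100 * as.numeric(ee))
      push("Inactivation efficiency (per sequenced clone): %d/%d = %.1f%%",
           attr(ie, "numerator"), attr(ie, "denominator"), 100 * as.numeric(ie))
    }
  }
  if (!is.null(fit)) {
    payload$essentiality <- list(
      k = fit$k, x = fit$x, f_obs = fit$f_obs, f_exp = fit$f_exp,
      E = fit$E, E_ci_lower = fit$E_ci[1], E_ci_upper = fit$E_ci[2],
      conf_level = fit$conf.level,
      p_all_in_frame = fit$p_all_in_frame, p_deficit = fit$p_deficit,
      verdict = fit$verdict)
    push("Essentiality (per independent event): x = %d of k = %d frameshift, f_obs = %.4g, f_exp = %.4g",
         fit$x, fit$k, fit$f_obs, fit$f_exp)
    push("E = %.4g, %g%% exact CI [%.4g, %.4g]",
         fit$E, 100 * fit$conf.level, fit$E_ci[1], fit$E_ci[2])
    push("P(all in-frame | no selection) = %.4g; one-sided deficit p = %.4g",
         fit$p_all_in_frame, fit$p_deficit)
    push("Verdict: %s -- %s", fit$verdict, verdict_text[[fit$verdict]])
  } else {
    payload$essentiality <- list(verdict = "untestable")
    push("No evidence of editing; essentiality untestable")
  }
  list(text = text,
       json = as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                            digits = NA)))
}
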