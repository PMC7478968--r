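#' Configuration for the clonal NHEJ outcome simulator
#'
#' Describes the generative model for a clonal editing experiment: each
#' picked clone either failed sequencing, is a sibling of an earlier editing
#' event, is unedited (WT), or carries a fresh NHEJ repair product drawn from
#' a mixture of deletions, insertions and substitution-only outcomes centred
#' at the Cas9 cut. Viability selection then removes frameshift lineages with
#' probability `1 - s`; removed lineages are resampled as surviving
#' genotypes, keeping the number of picked clones fixed (a picked-N-clones
#' design).
#'
#' Indel sizes default to capped geometric distributions (most NHEJ indels
#' are a few bases, with a tail out to tens of bases -- caps 30 nt for
#' deletions, 12 nt for insertions cover the sizes seen in clonal data);
#' `size_dist = "uniform"` draws sizes uniformly on `1..cap`, which with
#' `cap = 6` gives the frame-uniform spectrum (frameshift probability exactly
#' 2/3) used in calibration studies.
#'
#' @param n_clones Number of clones picked (default 24).
#' @param p_edit Probability a clone's target was cut and repaired with an
#'   error (default 0.7).
#' @param deletion_weight,insertion_weight,substitution_only_weight Mixture
#'   weights of the three edit kinds (default 0.55/0.30/0.15, deletions
#'   dominating as in clonal NHEJ spectra); must sum to 1.
#' @param del_geom_p,del_cap Deletion-size geometric parameter and cap
#'   (defaults 0.25, 30 nt).
#' @param ins_geom_p,ins_cap Insertion-size geometric parameter and cap
#'   (defaults 0.40, 12 nt).
#' @param size_dist `"geometric"` (default) or `"uniform"` sizes on `1..cap`.
#' @param p_duplicate Probability a clone is a sibling of a previous event
#'   (default 0.1).
#' @param p_fail Sequencing-failure probability (default 0.1).
#' @param s Frameshift survival probability in `[0, 1]`: 0 models an
#'   essential gene, 1 a neutral one.
#' @param seed RNG seed; the same seed reproduces the experiment exactly.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_clones = 24L, p_edit = 0.7,
                       deletion_weight = 0.55, insertion_weight = 0.30,
                       substitution_only_weight = 0.15,
                       del_geom_p = 0.25, del_cap = 30L,
                       ins_geom_p = 0.40, ins_cap = 12L,
                       size_dist = c("geometric", "uniform"),
                       p_duplicate = 0.1, p_fail = 0.1,
                       s = 1, seed = 1L) {
  size_dist <- match.arg(size_dist)
  w <- c(deletion = deletion_weight, insertion = insertion_weight,
         substitution_only = substitution_only_weight)
  probs <- c(p_edit = p_edit, p_duplicate = p_duplicate, p_fail = p_fail,
             s = s, w)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities and weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("edit-kind mixture weights must sum to 1")
  if (del_cap < 1L || ins_cap < 1L)
    stop("size caps must be >= 1")
  if (p_edit == 0 && s < 1)
    warning("p_edit = 0: selection parameter s has no effect")
  structure(list(
    n_clones = as.integer(n_clones), p_edit = p_edit,
    weights = w, del_geom_p = del_geom_p, del_cap = as.integer(del_cap),
    ins_geom_p = ins_geom_p, ins_cap = as.integer(ins_cap),
    size_dist = size_dist, p_duplicate = p_duplicate, p_fail = p_fail,
    s = s, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("NHEJ simulation config: ", x$n_clones, " clones, p_edit = ", x$p_edit,
      ", s = ", x$s, ", p_dup = ", x$p_duplicate, ", p_fail = ", x$p_fail,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  kinds del/ins/sub = ", paste(x$weights, collapse = "/"),
      "; sizes ", x$size_dist, " (caps ", x$del_cap, "/", x$ins_cap, ")\n",
      sep = "")
  invisible(x)
}

# size distribution over 1..cap as a probability vector
size_pmf <- function(config, kind) {
  cap <- if (kind == "deletion") config$del_cap else config$ins_cap
  if (config$size_dist == "uniform") return(rep(1 / cap, cap))
  p <- if (kind == "deletion") config$del_geom_p else config$ins_geom_p
  w <- p * (1 - p)^(0:(cap - 1L))
  w / sum(w)
}

#' Frameshift probability implied by a simulation config
#'
#' Exact frameshift probability of one fresh edit under the configured
#' mixture and size distributions: the kind-weighted mass of indel sizes not
#' divisible by 3 (substitution-only outcomes are always in-frame). Useful as
#' the analytic benchmark for convergence and recovery studies.
#'
#' @param config A [sim_config()].
#' @return Probability in `[0, 1]`.
#' @export
spectrum_frameshift_prob <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs_mass <- function(kind) {
    pmf <- size_pmf(config, kind)
    sum(pmf[seq_along(pmf) %% 3L != 0L])
  }
  unname(config$weights[["deletion"]] * fs_mass("deletion") +
         config$weights[["insertion"]] * fs_mass("insertion"))
}

#' Expected essentiality score under clone-level selection
#'
#' Closed-form expectation of the observed frameshift frequency among
#' surviving edited events when a fresh edit is frameshift with probability
#' `f_fs` and frameshift lineages survive with probability `s`, rescaled to
#' the E scale:
#' \deqn{E_{true} = \frac{f_{fs} s / (f_{fs} s + 1 - f_{fs})}{f_{exp}}.}
#'
#' @param s Frameshift survival probability.
#' @param f_fs Frameshift probability of a fresh edit (default 2/3).
#' @param f_exp Theoretical frequency used in the score (default 2/3).
#' @return The expected E.
#' @export
expected_E <- function(s, f_fs = 2 / 3, f_exp = 2 / 3) {
  (f_fs * s / (f_fs * s + (1 - f_fs))) / f_exp
}

#' Simulate a clonal CRISPR editing experiment
#'
#' Generates clone sequences and a ground-truth table under the model in
#' [sim_config()]: per clone, a sequencing-failure coin, then a genotype
#' (sibling of an earlier event, fresh edit, or WT), then frameshift
#' survival -- rejected frameshift lineages are resampled until a surviving
#' genotype is drawn, so `n_clones` is preserved. Fresh edits are placed at
#' the cut site: deletions straddle the cut, insertions and substitution runs
#' start at it. Fully reproducible for a fixed `config$seed`.
#'
#' @param ref A [reference_target()].
#' @param site A `"target_site"` from [find_target_site()].
#' @param config A [sim_config()].
#' @return An object of class `"sim_experiment"`: `clones` (named character
#'   vector of sequenced clones), `status` (clone_id/status table including
#'   failures), `truth` (clone_id, status, edited, kind, net_indel,
#'   frame_class, event_id, duplicate_of), and the echoed `config`.
#' @export
simulate_experiment <- function(ref, site, config) {
  stopifnot(inherits(ref, "reference_target"),
            inherits(site, "target_site"),
            inherits(config, "sim_config"))
  set.seed(config$seed)
  cut <- site$cut_index
  L <- nchar(ref$sequence)
  events <- list()       # distinct surviving fresh edits, by event index
  clones <- character()
  truth <- vector("list", config$n_clones)
  status <- character(config$n_clones)
  ids <- sprintf("sim%04d", seq_len(config$n_clones))

  draw_fresh_edit <- function() {
    kind <- sample(names(config$weights), 1L, prob = config$weights)
    if (kind == "substitution_only") {
      m <- sample(1:3, 1L)
      pos <- min(cut, L - m)
      refa <- substr(ref$sequence, pos + 1L, pos + m)
      alt <- vapply(strsplit(refa, "")[[1L]], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      data.frame(kind = "substitution", position = pos,
                 ref_allele = refa, alt_allele = paste(alt, collapse = ""),
                 stringsAsFactors = FALSE)
    } else if (kind == "deletion") {
      size <- sample(seq_along(size_pmf(config, "deletion")), 1L,
                     prob = size_pmf(config, "deletion"))
      # start anywhere such that the deleted run touches the cut
      lo <- max(1L, cut - size)
      hi <- min(cut, L - size - 1L)
      pos <- if (hi > lo) sample(lo:hi, 1L) else lo
      data.frame(kind = "deletion", position = pos,
                 ref_allele = substr(ref$sequence, pos + 1L, pos + size),
                 alt_allele = "", stringsAsFactors = FALSE)
    } else {
      size <- sample(seq_along(size_pmf(config, "insertion")), 1L,
                     prob = size_pmf(config, "insertion"))
      data.frame(kind = "insertion", position = cut, ref_allele = "",
                 alt_allele = paste(sample(c("A", "C", "G", "T"), size,
                                           replace = TRUE), collapse = ""),
                 stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(config$n_clones)) {
    id <- ids[i]
    if (stats::runif(1) < config$p_fail) {
      status[i] <- "failed_sequencing"
      truth[[i]] <- data.frame(clone_id = id, status = "failed_sequencing",
                               edited = NA, kind = NA_character_,
                               net_indel = NA_integer_,
                               frame_class = NA_character_,
                               event_id = NA_integer_,
                               duplicate_of = NA_integer_,
                               stringsAsFactors = FALSE)
      next
    }
    status[i] <- "ok"
    repeat {
      dup_of <- NA_integer_
      if (length(events) > 0L && stats::runif(1) < config$p_duplicate) {
        dup_of <- sample(length(events), 1L)
        edits <- events[[dup_of]]
      } else if (stats::runif(1) < config$p_edit) {
        edits <- draw_fresh_edit()
      } else {
        edits <- NULL
      }
      net <- net_frame_shift(edits)
      frameshift <- !is.null(edits) && net %% 3L != 0L
      # siblings of surviving events already passed selection
      if (!frameshift || !is.na(dup_of) || stats::runif(1) < config$s) break
    }
    if (is.null(edits)) {
      clones[id] <- ref$sequence
      truth[[i]] <- data.frame(clone_id = id, status = "ok", edited = FALSE,
                               kind = NA_character_, net_indel = 0L,
                               frame_class = "WT", event_id = NA_integer_,
                               duplicate_of = NA_integer_,
                               stringsAsFactors = FALSE)
    } else {
      if (is.na(dup_of)) {
        # identical independent events are possible but recorded separately
        events[[length(events) + 1L]] <- edits
        ev <- length(events)
      } else ev <- dup_of
      clones[id] <- apply_edits(ref$sequence, edits)
      fc <- switch(as.character(net_frame_shift(edits) %% 3L),
                   "0" = "in_frame", "1" = "frameshift_plus1",
                   "2" = "frameshift_plus2")
      truth[[i]] <- data.frame(clone_id = id, status = "ok", edited = TRUE,
                               kind = edits$kind[1L],
                               net_indel = net_frame_shift(edits),
                               frame_class = fc, event_id = ev,
                               duplicate_of = dup_of,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(
    clones = clones,
    status = data.frame(clone_id = ids, status = status,
                        stringsAsFactors = FALSE),
    truth = do.call(rbind, truth),
    config = config
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  tr <- x$truth
  cat("Simulated experiment: ", nrow(tr), " clones (",
      sum(tr$status == "ok"), " sequenced), ",
      sum(tr$edited %in% TRUE), " edited, ",
      length(unique(stats::na.omit(tr$event_id))), " events, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the sequenced clones as multi-FASTA, the truth table and status
#' table as TSV, and the configuration (seed included) as JSON, so a
#' simulated dataset can round-trip through the file-based workflow.
#'
#' @param sim A `"sim_experiment"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    clones = file.path(dir, paste0(prefix, "_clones.fasta")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    status = file.path(dir, paste0(prefix, "_status.tsv")),
    config = file.path(dir, paste0(prefix, "_config.json")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$clones),
                              paths[["clones"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$status, paths[["status"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Recover the essentiality score from a simulated experiment
#'
#' Validation harness: runs the full analysis pipeline (alignment, edit
#' extraction, classification, sibling collapsing, CRISPR-E fit) on the
#' simulated clone sequences and compares the estimated E with the
#' closed-form expectation [expected_E()] for the simulated survival `s`.
#'
#' @param sim A `"sim_experiment"`.
#' @param ref,site The reference and target site used to simulate.
#' @param f_exp Theoretical frameshift frequency for the fit (default 2/3).
#' @param conf.level Confidence level (default 0.95).
#' @return A list with the `fit` (`"crispr_e"`, or `NULL` when no edited
#'   events were recovered), `E_hat`, `E_true`, `covered` (is `E_true` inside
#'   the fitted CI) and the `calls` table.
#' @export
recover_parameters <- function(sim, ref, site, f_exp = 2 / 3,
                               conf.level = 0.95) {
  stopifnot(inherits(sim, "sim_experiment"))
  calls <- call_alleles(ref, sim$clones, site, status = sim$status)
  ev <- collapse_events(calls)
  E_true <- expected_E(sim$config$s,
                       f_fs = spectrum_frameshift_prob(sim$config),
                       f_exp = f_exp)
  if (ev$summary$n_events == 0L)
    return(list(fit = NULL, E_hat = NA_real_, E_true = E_true,
                covered = NA, calls = calls))
  fit <- crispr_e(ev$summary, f_exp = f_exp, conf.level = conf.level)
  list(fit = fit, E_hat = fit$E, E_true = E_true,
       covered = E_true >= fit$E_ci[1] && E_true <= fit$E_ci[2],
       calls = calls)
}
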