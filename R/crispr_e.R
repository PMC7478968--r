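#' Fit the CRISPR essentiality (CRISPR-E) model
#'
#' The central estimator of the package. Among `k` independent CRISPR/Cas9
#' editing events recovered from surviving clones, `x` carry frameshift
#' alleles. Absent selection, frameshifts arise with probability `f_exp`
#' (default 2/3, the frame-uniform NHEJ assumption), so the essentiality
#' score is
#' \deqn{E = \frac{x/k}{f_{exp}},}
#' the observed frequency of gene-inactivating mutations divided by its
#' theoretical frequency. `E = 0` (no surviving frameshift allele) diagnoses
#' an essential gene; `0 < E < 1` a fitness cost of losing the gene; `E = 1`
#' neutrality; `E > 1` a benefit. The fit also carries the exact all-in-frame
#' null probability `(1 - f_exp)^k`, the one-sided exact frameshift-deficit
#' p-value `P(Binom(k, f_exp) <= x)`, and a Clopper-Pearson confidence
#' interval for `x/k` rescaled to the E scale.
#'
#' Methods: [print.crispr_e()], [summary.crispr_e()], `coef()` (the E score),
#' `confint()`, `plot()` (observed vs expected class fractions),
#' `simulate()` (parametric draws of the frameshift count at the fitted E).
#'
#' @param x Frameshift event count, an [editing_summary()], or an
#'   `"allele_calls"` table (collapsed internally).
#' @param ... Passed to methods.
#' @return An object of class `"crispr_e"`.
#' @examples
#' fit <- crispr_e(x = 0, k = 18)
#' fit
#' coef(fit)
#' confint(fit)
#' @importFrom stats coef confint simulate
#' @importFrom graphics plot
#' @export
crispr_e <- function(x, ...) UseMethod("crispr_e")

#' @rdname crispr_e
#' @param k Number of independent edited events (`k > 0`).
#' @param f_exp Theoretical frameshift frequency among edits (default 2/3).
#' @param conf.level Confidence level for the exact interval (default 0.95).
#' @export
crispr_e.default <- function(x, k, f_exp = 2 / 3, conf.level = 0.95, ...) {
  check_f_exp(f_exp)
  if (length(x) != 1L || length(k) != 1L || is.na(x) || is.na(k) ||
      x != floor(x) || k != floor(k) || x < 0)
    stop("'x' and 'k' must be single non-negative integers")
  if (k <= 0L) stop("no edited events; E undefined (k must be positive)")
  if (x > k) stop("invalid counts: x cannot exceed k")
  x <- as.integer(x); k <- as.integer(k)
  f_obs <- x / k
  E <- f_obs / f_exp
  ci_prop <- clopper_pearson(x, k, conf.level)
  verdict <-
    if (x == 0L) "essential"
    else if (abs(f_obs - f_exp) < 1e-12) "neutral"
    else if (f_obs < f_exp) "deleterious"
    else "beneficial_to_lose"
  structure(list(
    k = k, x = x, f_obs = f_obs, f_exp = f_exp,
    E = E, E_ci = as.numeric(ci_prop) / f_exp,
    prop_ci = as.numeric(ci_prop), conf.level = conf.level,
    p_all_in_frame = all_in_frame_pvalue(k, f_exp),
    p_deficit = stats::pbinom(x, k, f_exp),
    verdict = verdict,
    class_counts = NULL,
    call = match.call()
  ), class = "crispr_e")
}

#' @rdname crispr_e
#' @export
crispr_e.editing_summary <- function(x, f_exp = 2 / 3, conf.level = 0.95, ...) {
  summary <- x
  if (summary$n_events == 0L)
    stop("no edited events; E undefined ",
         "(no evidence of editing; essentiality untestable)")
  xs <- sum(summary$event_class_counts[c("frameshift_plus1",
                                         "frameshift_plus2")])
  fit <- crispr_e.default(xs, summary$n_events, f_exp = f_exp,
                          conf.level = conf.level)
  fit$class_counts <- summary$event_class_counts
  fit$summary <- summary
  fit$call <- match.call()
  fit
}

#' @rdname crispr_e
#' @export
crispr_e.allele_calls <- function(x, f_exp = 2 / 3, conf.level = 0.95, ...) {
  crispr_e(collapse_events(x)$summary, f_exp = f_exp, conf.level = conf.level)
}

#' Essentiality score from event counts
#'
#' Count-first wrapper around [crispr_e()]: computes the essentiality score E
#' and its exact confidence interval from bare counts.
#'
#' @param k Independent edited events (`k > 0`).
#' @param x Frameshift events among them.
#' @param f_exp Theoretical frameshift frequency (default 2/3).
#' @param confidence Confidence level (default 0.95).
#' @return A `"crispr_e"` object.
#' @export
essentiality_score <- function(k, x, f_exp = 2 / 3, confidence = 0.95) {
  crispr_e.default(x, k, f_exp = f_exp, conf.level = confidence)
}

verdict_text <- c(
  essential = "essential (no surviving frameshift allele)",
  deleterious = "loss is deleterious (frameshift deficit)",
  neutral = "loss is neutral",
  beneficial_to_lose = "loss is beneficial (frameshift excess)")

#' @export
print.crispr_e <- function(x, digits = 4, ...) {
  cat("CRISPR-E essentiality fit\n")
  cat("  events: k = ", x$k, ", frameshift x = ", x$x,
      " (f_obs = ", signif(x$f_obs, digits),
      ", f_exp = ", signif(x$f_exp, digits), ")\n", sep = "")
  cat("  E = ", signif(x$E, digits), "  [",
      signif(x$E_ci[1], digits), ", ", signif(x$E_ci[2], digits), "] (",
      100 * x$conf.level, "% exact CI)\n", sep = "")
  cat("  P(all in-frame | no selection) = ",
      signif(x$p_all_in_frame, digits),
      ";  one-sided deficit p = ", signif(x$p_deficit, digits), "\n",
      sep = "")
  cat("  verdict: ", verdict_text[[x$verdict]], "\n", sep = "")
  invisible(x)
}

#' @export
coef.crispr_e <- function(object, ...) c(E = object$E)

#' @export
confint.crispr_e <- function(object, parm = "E", level = NULL, ...) {
  if (!is.null(level) && level != object$conf.level) {
    ci <- clopper_pearson(object$x, object$k, level)
    out <- matrix(as.numeric(ci) / object$f_exp, nrow = 1)
  } else {
    level <- object$conf.level
    out <- matrix(object$E_ci, nrow = 1)
  }
  a <- (1 - level) / 2
  dimnames(out) <- list("E", sprintf("%.1f %%", 100 * c(a, 1 - a)))
  out
}

#' Summarize a CRISPR-E fit
#'
#' @param object A `"crispr_e"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.crispr_e"`: the fit plus, when the
#'   fit was made from an [editing_summary()], both denominator conventions
#'   (per sequenced clone and per independent event) spelled out.
#' @export
summary.crispr_e <- function(object, ...) {
  out <- unclass(object)
  if (!is.null(object$summary)) {
    out$editing_efficiency <- editing_efficiency(object$summary)
    out$inactivation_efficiency <- inactivation_efficiency(object$summary)
    out$fractions <- class_fractions(object$summary)
  }
  structure(out, class = "summary.crispr_e")
}

#' @export
print.summary.crispr_e <- function(x, digits = 4, ...) {
  print.crispr_e(structure(x, class = "crispr_e"), digits = digits)
  if (!is.null(x$summary)) {
    s <- x$summary
    cat("Clone-level denominators (", s$n_sequenced,
        " sequenced clones):\n  ", sep = "")
    print(x$editing_efficiency)
    cat("  "); print(x$inactivation_efficiency)
    cat("Event-level class fractions (", s$n_events,
        " independent events):\n", sep = "")
    f <- x$fractions
    cat(sprintf("  in-frame %.0f%% | 3n+1 %.0f%% | 3n+2 %.0f%%\n",
                100 * f[["in_frame"]], 100 * f[["frameshift_plus1"]],
                100 * f[["frameshift_plus2"]]))
    if (s$n_stop_gain > 0)
      cat("  ", s$n_stop_gain, " in-frame event(s) carry a premature stop",
          " (possible knockout despite frame)\n", sep = "")
  }
  invisible(x)
}

#' Plot observed versus expected frame-class composition
#'
#' Bar chart of the observed event fractions (in-frame, 3n+1, 3n+2, pooled
#' frameshift) against the no-selection expectation implied by `f_exp`.
#'
#' @param x A `"crispr_e"` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.crispr_e <- function(x, ...) {
  if (!is.null(x$class_counts)) {
    n <- sum(x$class_counts[c("in_frame", "frameshift_plus1",
                              "frameshift_plus2")])
    obs <- x$class_counts[c("in_frame", "frameshift_plus1",
                            "frameshift_plus2")] / n
    exp <- c(1 - x$f_exp, x$f_exp / 2, x$f_exp / 2)
    m <- rbind(observed = obs, expected = exp)
    colnames(m) <- c("in-frame", "3n+1", "3n+2")
  } else {
    m <- rbind(observed = c(1 - x$f_obs, x$f_obs),
               expected = c(1 - x$f_exp, x$f_exp))
    colnames(m) <- c("in-frame", "frameshift")
  }
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    legend.text = rownames(m),
                    ylab = "fraction of edited events",
                    main = sprintf("CRISPR-E: E = %.2f (%s)", x$E, x$verdict),
                    ...)
  invisible(m)
}

#' Simulate frameshift counts from a fitted CRISPR-E model
#'
#' Parametric draws of the frameshift event count `x* ~ Binomial(k, f_obs)`
#' at the fitted frameshift frequency, with the corresponding simulated E
#' scores.
#'
#' @param object A `"crispr_e"` fit.
#' @param nsim Number of simulated experiments.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with columns `x` and `E`.
#' @export
simulate.crispr_e <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  xs <- stats::rbinom(nsim, object$k, object$f_obs)
  data.frame(x = xs, E = (xs / object$k) / object$f_exp)
}
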