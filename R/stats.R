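#' Editing and inactivation efficiency
#'
#' `editing_efficiency()` is the fraction of successfully sequenced clones
#' carrying any in-window edit (on-target cutting/editing efficiency);
#' `inactivation_efficiency()` is the fraction carrying a frameshift allele
#' (the alleles expected to inactivate the gene). Both use sequenced clones
#' as the denominator -- failures carry no genotype and are excluded.
#'
#' @param summary An [editing_summary()].
#' @return A `"crispr_fraction"`: the estimate with `numerator` and
#'   `denominator` attributes, printed as "x/n = p%".
#' @examples
#' # 17 edited of 19 sequenced clones
#' @export
editing_efficiency <- function(summary) {
  stopifnot(inherits(summary, "editing_summary"))
  if (summary$n_sequenced == 0L)
    stop("no data: zero successfully sequenced clones")
  crispr_fraction(summary$n_edited, summary$n_sequenced,
                  "editing efficiency")
}

#' @rdname editing_efficiency
#' @export
inactivation_efficiency <- function(summary) {
  stopifnot(inherits(summary, "editing_summary"))
  if (summary$n_sequenced == 0L)
    stop("no data: zero successfully sequenced clones")
  x <- sum(summary$clone_class_counts[c("frameshift_plus1",
                                        "frameshift_plus2")])
  crispr_fraction(x, summary$n_sequenced, "inactivation efficiency")
}

crispr_fraction <- function(x, n, what) {
  structure(x / n, numerator = as.integer(x), denominator = as.integer(n),
            what = what, class = "crispr_fraction")
}

#' @export
print.crispr_fraction <- function(x, ...) {
  cat(attr(x, "what"), ": ", attr(x, "numerator"), "/",
      attr(x, "denominator"), " = ", sprintf("%.1f%%", 100 * as.numeric(x)),
      "\n", sep = "")
  invisible(x)
}

#' Frame-class fractions among independent edited events
#'
#' Fractions of in-frame (3n), 3n+1 and 3n+2 alleles among independent edited
#' events (WT excluded, siblings collapsed). These are the observable the
#' essentiality test interprets: under unbiased NHEJ roughly 2/3 of events
#' should be frameshifts, and their selective absence signals essentiality.
#'
#' @param x An [editing_summary()], or the `events` data frame from
#'   [collapse_events()].
#' @return Named numeric vector `(in_frame, frameshift_plus1,
#'   frameshift_plus2)` summing to 1.
#' @export
class_fractions <- function(x) {
  counts <- if (inherits(x, "editing_summary")) {
    x$event_class_counts[c("in_frame", "frameshift_plus1", "frameshift_plus2")]
  } else {
    stopifnot(is.data.frame(x), "frame_class" %in% names(x))
    t <- table(factor(x$frame_class,
                      levels = c("in_frame", "frameshift_plus1",
                                 "frameshift_plus2")))
    stats::setNames(as.integer(t), names(t))
  }
  n <- sum(counts)
  if (n == 0L) stop("no editing observed: zero edited events")
  counts / n
}

#' Probability that all edited events are in-frame under no selection
#'
#' Under the null model that NHEJ products fall in the three residue classes
#' with frameshift probability `f_exp` (default 2/3, the frame-uniform
#' assumption) and no viability selection, the chance that all `k`
#' independent events are in-frame is `(1 - f_exp)^k` -- `(1/3)^k` at the
#' default. A small value means the observed all-in-frame outcome is very
#' unlikely without selection against frameshifts.
#'
#' @param k Number of independent edited events.
#' @param f_exp Theoretical frameshift frequency among edits (default 2/3).
#' @return Probability in `[0, 1]`.
#' @examples
#' all_in_frame_pvalue(4)   # (1/3)^4 = 1/81
#' all_in_frame_pvalue(7)   # (1/3)^7 = 1/2187
#' @export
all_in_frame_pvalue <- function(k, f_exp = 2 / 3) {
  check_f_exp(f_exp)
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k)))
    stop("invalid count: k must be a non-negative integer")
  (1 - f_exp)^k
}

#' Exact one-sided test for a deficit of frameshift events
#'
#' Generalizes the all-in-frame probability to any observed frameshift count:
#' with `X ~ Binomial(k, f_exp)` under no selection, reports the exact lower
#' tail `P(X <= x)`. At `x = 0` this equals [all_in_frame_pvalue()]. The test
#' is one-sided by default because the essentiality argument is directional
#' (selection can only remove frameshift clones); a two-sided alternative is
#' available.
#'
#' @param k Independent edited events.
#' @param x Observed frameshift events, `0 <= x <= k`.
#' @param f_exp Theoretical frameshift frequency (default 2/3).
#' @param alternative `"less"` (deficit, default) or `"two.sided"`.
#' @return An object of class `"htest"`.
#' @export
frameshift_deficit_test <- function(k, x, f_exp = 2 / 3,
                                    alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  check_f_exp(f_exp)
  if (any(is.na(c(k, x))) || k < 0 || x < 0 || x > k ||
      k != floor(k) || x != floor(x))
    stop("invalid counts: need integer 0 <= x <= k")
  p <- if (alternative == "less") stats::pbinom(x, k, f_exp)
       else stats::binom.test(x, k, p = f_exp,
                              alternative = "two.sided")$p.value
  structure(list(
    statistic = c("frameshift events" = x),
    parameter = c("edited events" = k, "f_exp" = f_exp),
    p.value = p, alternative = alternative,
    method = "Exact binomial test for frameshift deficit",
    data.name = sprintf("%d frameshift among %d edited events", x, k)
  ), class = "htest")
}

#' Minimum number of edited events for a conclusive test
#'
#' Planning aid: the smallest number of independent edited events `k` such
#' that an all-in-frame outcome would be significant at level `alpha`, i.e.
#' `(1 - f_exp)^k <= alpha`. With the default spectrum, 3 events suffice at
#' alpha = 0.05 and 5 at alpha = 0.01.
#'
#' @param alpha Significance level in (0, 1).
#' @param f_exp Theoretical frameshift frequency (default 2/3).
#' @return Integer minimal `k`.
#' @export
min_edited_clones <- function(alpha, f_exp = 2 / 3) {
  check_f_exp(f_exp)
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha out of range: need 0 < alpha < 1")
  k <- max(0L, as.integer(ceiling(log(alpha) / log(1 - f_exp))))
  # guard against floating error at the boundary
  while ((1 - f_exp)^k > alpha) k <- k + 1L
  while (k > 1L && (1 - f_exp)^(k - 1L) <= alpha) k <- k - 1L
  k
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact tail-inversion interval for a binomial proportion, appropriate for
#' the small clone counts typical of clonal editing experiments. Implemented
#' through the beta quantile form so it vectorizes over `x`.
#'
#' @param x Successes (vectorized).
#' @param n Trials.
#' @param conf.level Confidence level (default 0.95).
#' @return A matrix with columns `lower`, `upper`.
#' @export
clopper_pearson <- function(x, n, conf.level = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), n > 0,
            conf.level > 0, conf.level < 1)
  a <- (1 - conf.level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

check_f_exp <- function(f_exp) {
  if (!is.numeric(f_exp) || is.na(f_exp) || f_exp <= 0 || f_exp >= 1)
    stop("'f_exp' must be a frameshift frequency strictly between 0 and 1")
  invisible(f_exp)
}
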