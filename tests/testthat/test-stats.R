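summary_from_counts <- function(wt = 0, in_frame = 0, fs1 = 0, fs2 = 0,
                                failed = 0) {
  mk <- function(id, kind, net, pos = 50) {
    if (kind == "none")
      data.frame(clone_id = id, kind = "none", position = NA,
                 ref_allele = "", alt_allele = "", status = "ok")
    else if (kind == "failed")
      data.frame(clone_id = id, kind = "none", position = NA,
                 ref_allele = "", alt_allele = "",
                 status = "failed_sequencing")
    else
      data.frame(clone_id = id, kind = if (net > 0) "insertion" else "deletion",
                 position = pos, ref_allele = if (net < 0) random_dna(-net) else "",
                 alt_allele = if (net > 0) random_dna(net) else "",
                 status = "ok")
  }
  nets <- c(rep(3, in_frame), rep(1, fs1), rep(2, fs2))
  rows <- list()
  for (i in seq_len(wt)) rows[[length(rows) + 1]] <- mk(paste0("w", i), "none", 0)
  for (i in seq_len(failed)) rows[[length(rows) + 1]] <- mk(paste0("f", i), "failed", 0)
  for (i in seq_along(nets))
    rows[[length(rows) + 1]] <- mk(paste0("e", i), "edit", nets[i],
                                   pos = 20 + i)
  calls <- calls_from_variants(do.call(rbind, rows))
  collapse_events(calls)$summary
}

test_that("editing and inactivation efficiencies use sequenced clones as denominator", {
  set.seed(41)
  s <- summary_from_counts(wt = 2, in_frame = 9, fs1 = 7, fs2 = 1)
  ee <- editing_efficiency(s)
  expect_equal(as.numeric(ee), 17 / 19)
  expect_equal(attr(ee, "numerator"), 17L)
  expect_equal(attr(ee, "denominator"), 19L)
  ie <- inactivation_efficiency(s)
  expect_equal(as.numeric(ie), 8 / 19)
  # failures are excluded from the denominator
  s2 <- summary_from_counts(wt = 0, in_frame = 2, fs1 = 2, fs2 = 2, failed = 6)
  expect_equal(as.numeric(editing_efficiency(s2)), 1)
  expect_equal(as.numeric(inactivation_efficiency(s2)), 4 / 6)
  # all WT
  s3 <- summary_from_counts(wt = 5)
  expect_equal(as.numeric(editing_efficiency(s3)), 0)
  s4 <- summary_from_counts(failed = 3)
  expect_error(editing_efficiency(s4), "no data")
})

test_that("class fractions sum to one over edited events and fail without editing", {
  set.seed(42)
  s <- summary_from_counts(in_frame = 3, fs1 = 2, fs2 = 5)
  f <- class_fractions(s)
  expect_equal(unname(f), c(0.3, 0.2, 0.5))
  expect_equal(sum(f), 1)
  expect_equal(unname(class_fractions(summary_from_counts(in_frame = 1))),
               c(1, 0, 0))
  expect_error(class_fractions(summary_from_counts(wt = 4)), "no editing")
})

test_that("all-in-frame probability is (1 - f_exp)^k and decreasing in k", {
  expect_equal(all_in_frame_pvalue(0), 1)
  expect_equal(all_in_frame_pvalue(4), (1 / 3)^4)
  expect_equal(all_in_frame_pvalue(4), 1 / 81)
  expect_equal(all_in_frame_pvalue(7), 1 / 2187)
  ks <- 0:20
  ps <- all_in_frame_pvalue(ks)
  expect_true(all(diff(ps) < 0))
  expect_error(all_in_frame_pvalue(-1), "invalid count")
  expect_error(all_in_frame_pvalue(3, f_exp = 1.2), "f_exp")
})

test_that("the frameshift-deficit tail matches exact values and the boundary identity", {
  # x = 0 reduces to the all-in-frame probability
  for (k in c(1, 4, 7, 18))
    expect_equal(frameshift_deficit_test(k, 0)$p.value,
                 all_in_frame_pvalue(k))
  expect_equal(frameshift_deficit_test(5, 4)$p.value, 211 / 243)
  expect_equal(frameshift_deficit_test(18, 0)$p.value, (1 / 3)^18)
  # P(X <= k) is always 1
  for (k in c(1, 3, 9))
    expect_equal(frameshift_deficit_test(k, k)$p.value, 1)
  expect_error(frameshift_deficit_test(3, 4), "invalid counts")
})

test_that("deficit tail agrees with brute-force multinomial enumeration for small k", {
  for (k in c(2, 4, 6, 8)) {
    for (x in c(0, 1, k %/% 2, k)) {
      expect_equal(frameshift_deficit_test(k, x)$p.value,
                   enumerate_deficit_pvalue(k, x),
                   tolerance = 1e-12, info = sprintf("k=%d x=%d", k, x))
    }
  }
  # and for a biased spectrum
  expect_equal(frameshift_deficit_test(5, 2, f_exp = 0.5)$p.value,
               enumerate_deficit_pvalue(5, 2, f_exp = 0.5),
               tolerance = 1e-12)
})

test_that("minimum clone numbers invert the all-in-frame probability", {
  expect_equal(min_edited_clones(0.05), 3L)
  expect_equal(min_edited_clones(0.01), 5L)
  expect_equal(min_edited_clones(0.5), 1L)
  for (alpha in c(0.2, 0.07, 0.003)) {
    k <- min_edited_clones(alpha)
    expect_lte(all_in_frame_pvalue(k), alpha)
    if (k > 1) expect_gt(all_in_frame_pvalue(k - 1), alpha)
  }
  expect_error(min_edited_clones(0), "alpha")
  expect_error(min_edited_clones(1), "alpha")
})

test_that("Clopper-Pearson intervals match binom.test exactly", {
  set.seed(43)
  for (i in 1:12) {
    n <- sample(1:25, 1)
    x <- sample(0:n, 1)
    lvl <- sample(c(0.9, 0.95, 0.99), 1)
    ci <- clopper_pearson(x, n, lvl)
    bt <- stats::binom.test(x, n, conf.level = lvl)$conf.int
    expect_equal(unname(ci[1, ]), as.numeric(bt), tolerance = 1e-10,
                 info = sprintf("x=%d n=%d", x, n))
  }
})
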