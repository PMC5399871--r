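test_that("electivity index matches worked values and boundary limits", {
  expect_equal(electivity_index(0.3, 0.3), 0)              # proportional use
  expect_equal(electivity_index(0, 0.2), -1)               # total avoidance
  expect_equal(electivity_index(0.2, 0), 1)                # exclusive use
  expect_true(is.na(electivity_index(0, 0)))               # undefined
  expect_equal(electivity_index(1, 1), 0)
  # rare-prey and dominant-prey worked examples
  expect_equal(round_half_up(electivity_index(0.0196, 0.0031)), 0.73)
  expect_equal(round_half_up(electivity_index(0.5779, 0.0602)), 0.91)
  expect_error(electivity_index(1.2, 0.1), "proportions")
})

test_that("electivity index obeys bounds, sign, symmetry and monotonicity", {
  set.seed(21)
  r <- runif(500); p <- runif(500)
  e <- electivity_index(r, p)
  expect_true(all(e >= -1 & e <= 1))
  expect_true(all(sign(e) == sign(r - p)))
  expect_equal(electivity_index(p, r), -e)
  # strictly increasing in r for fixed p in (0, 1)
  for (pp in c(0.1, 0.5, 0.9)) {
    rs <- seq(0, 1, by = 0.05)
    es <- electivity_index(rs, rep(pp, length(rs)))
    expect_true(all(diff(es) > 0))
  }
})

test_that("the pooled dietary-frequency rule includes and excludes the right taxa", {
  km <- xenopus_counts("Kleinmond")
  mask <- inclusion_mask(km, c("X_laevis", "X_gilli"))
  expect_false(mask[["Trichoptera"]])   # 3 + 6 = 9 < 10
  expect_true(mask[["Daphnia"]])        # 440 + 235
  cogh <- xenopus_counts("CoGH")
  mask2 <- inclusion_mask(cogh, c("X_laevis", "X_gilli"))
  expect_true(mask2[["Coleoptera"]])    # 20 + 30 = 50
  expect_true(mask2[["Heteroptera"]])   # 15 + 1 = 16 (count, not Freq, basis)
  mask0 <- inclusion_mask(cogh, c("X_laevis", "X_gilli"), min_total = 0)
  expect_true(all(mask0))
})

test_that("chi-square selection test matches the textbook formula and chisq.test", {
  # proportional observed: statistic 0
  prop <- chisq_selection_test(c(a = 50, b = 30, c = 20), c(0.5, 0.3, 0.2))
  expect_equal(prop$statistic, 0)
  expect_true(all(prop$residuals == 0))

  # closed form: (10, 0) vs (0.5, 0.5)
  z <- chisq_selection_test(c(a = 10, b = 0), c(0.5, 0.5))
  expect_equal(z$statistic, 10)
  expect_equal(unname(z$residuals), c(sqrt(5), -sqrt(5)))
  expect_equal(z$df, 1)

  set.seed(22)
  for (i in 1:5) {
    p <- runif(5); p <- p / sum(p)
    o <- rmultinom(1, 300, p)[, 1]
    names(o) <- letters[1:5]
    got <- chisq_selection_test(o, p)
    # direct-formula oracle
    expected <- 300 * p
    stat <- sum((o - expected)^2 / expected)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$statistic, sum(got$residuals^2), tolerance = 1e-10)
    # independent implementation
    ct <- suppressWarnings(chisq.test(o, p = p))
    expect_equal(got$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
    # invariant to taxon order
    perm <- sample(5)
    expect_equal(chisq_selection_test(o[perm], p[perm])$statistic,
                 got$statistic)
  }
})

test_that("zero-availability taxa are dropped from the chi-square with a warning", {
  expect_warning(
    res <- chisq_selection_test(c(a = 5, b = 5, c = 10), c(0.5, 0.5, 0)),
    "zero expected")
  expect_equal(res$dropped, "c")
  expect_equal(res$df, 1)
  expect_true(is.na(res$residuals[["c"]]))
})

test_that("Bonferroni intervals match the normal-quantile formula and verdicts follow", {
  ci <- bonferroni_intervals(c(a = 50, b = 50), alpha = 0.05)
  z <- qnorm(1 - 0.05 / 4)
  expect_equal(round(z, 4), 2.2414)
  half <- z * sqrt(0.5 * 0.5 / 100)
  expect_equal(ci$lower, rep(0.5 - half, 2))
  expect_equal(ci$upper, rep(0.5 + half, 2))

  # a zero count yields the degenerate interval [0, 0]
  ci0 <- bonferroni_intervals(c(a = 0, b = 10))
  expect_equal(ci0$lower[1], 0)
  expect_equal(ci0$upper[1], 0)
  expect_equal(selection_verdict(c(0.2, 0), ci0$lower, ci0$upper)[1], "avoided")

  # availability inside every interval: all proportional
  v <- selection_verdict(c(0.5, 0.5), ci$lower, ci$upper)
  expect_equal(v, c("proportional", "proportional"))
  expect_error(bonferroni_intervals(numeric(0)), "no taxa")
})

test_that("site-level electivity analysis is coherent end to end", {
  cogh <- xenopus_counts("CoGH")
  ea <- electivity_analysis(cogh, c("CoGH.X_laevis", "CoGH.X_gilli"),
                            "CoGH.environment")
  lae <- ea$taxa[["CoGH.X_laevis"]]
  # E* only present for included taxa
  expect_true(all(is.na(lae$estar[!lae$included])))
  expect_true(all(!is.na(lae$estar[lae$included & (lae$r + lae$p) > 0])))
  # verdicts match interval position wherever tested
  tested <- !is.na(lae$ci_lower)
  expect_equal(lae$verdict[tested],
               selection_verdict(lae$p[tested], lae$ci_lower[tested],
                                 lae$ci_upper[tested]))
  # strong preference for ostracods, strong avoidance of zygopterans
  expect_equal(lae$verdict[lae$taxon == "Ostracoda"], "preferred")
  expect_equal(lae$verdict[lae$taxon == "Zygoptera"], "avoided")
  # overall chi-square strongly rejects proportional feeding
  expect_true(all(ea$tests$p_value < 1e-10))
  expect_equal(as.data.frame(ea)$group[1], "CoGH.X_laevis")
})
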