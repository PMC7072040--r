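test_that("confusion counts partition the sample", {
  t1 <- confusion(c(1, 1, 0, 0, 1, 0), c(1, 0, 0, 1, 1, 0))
  expect_equal(unclass(t1)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 2L))
  all_pos <- confusion(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_pos$tp, 5L)
  expect_equal(all_pos$fp + all_pos$tn + all_pos$fn, 0L)
  comp <- confusion(c(1, 0, 1), c(0, 1, 0))
  expect_equal(comp$tp + comp$tn, 0L)
  expect_error(confusion(1:3, 1:2), class = "dxascol_invalid_input")
})

test_that("sensitivity and specificity come from the table margins", {
  expect_equal(sens_spec(diagnostic_table(tp = 2, fp = 1, tn = 2, fn = 1)),
               c(sensitivity = 2 / 3, specificity = 2 / 3))
  expect_equal(unname(sens_spec(diagnostic_table(tp = 510, fp = 292,
                                                 tn = 9118, fn = 80))),
               c(510 / 590, 9118 / 9410))
  expect_equal(pct1(sens_spec(diagnostic_table(tp = 510, fp = 292,
                                               tn = 9118, fn = 80))),
               c(sensitivity = 86.4, specificity = 96.9))
  expect_error(sens_spec(diagnostic_table(tp = 0, fp = 2, tn = 3, fn = 0)),
               class = "dxascol_undefined_margin")
})

test_that("AUC equals the Mann-Whitney statistic with tie handling", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 0)$auc,
               0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5), n_boot = 0)$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1), n_boot = 0)$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "dxascol_degenerate_input")
})

test_that("AUC matches the exhaustive pairwise oracle on random inputs", {
  brute_auc <- function(s, t) {
    pos <- s[t == 1]; neg <- s[t == 0]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  withr::with_seed(123, {
    for (i in 1:40) {
      n <- sample(4:50, 1)
      t <- c(0, 1, rbinom(n - 2, 1, 0.4))
      s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      expect_equal(roc_auc(s, t, n_boot = 0)$auc, brute_auc(s, t),
                   tolerance = 1e-12)
    }
  })
})

test_that("bootstrap AUC confidence interval brackets the point estimate", {
  withr::with_seed(5, {
    s <- c(rnorm(40, 1), rnorm(60))
    t <- rep(c(1, 0), c(40, 60))
  })
  a <- roc_auc(s, t, n_boot = 500, seed = 9)
  expect_lte(a$ci_low, a$auc)
  expect_gte(a$ci_high, a$auc)
  a2 <- roc_auc(s, t, n_boot = 500, seed = 9)
  expect_identical(a, a2)  # seeded bootstrap is reproducible
})

test_that("population projection reproduces the published worked example", {
  pr <- project_population(0.865, 0.969, 0.059, 10000)
  expect_equal(unclass(pr$table)[c("tp", "fn", "tn", "fp")],
               list(tp = 510, fn = 80, tn = 9118, fp = 292))
  expect_equal(pct1(pr$ppv), 63.6)
  expect_equal(pct1(pr$npv), 99.1)
  expect_equal(pct1(pr$predicted_prevalence), 8.0)
  pr95 <- project_population(0.946, 0.939, 0.059, 10000)
  expect_equal(pct1(pr95$ppv), 49.3)
  expect_equal(pct1(pr95$npv), 99.6)
  expect_equal(pct1(pr95$predicted_prevalence), 11.3)
  perfect <- project_population(1, 1, 0.2, 500)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$predicted_prevalence, 0.2)
  expect_error(project_population(0, 1, 0.5, 10),
               class = "dxascol_undefined_ppv")
})

test_that("projections conserve n and invert to their inputs", {
  withr::with_seed(77, {
    for (i in 1:60) {
      se <- runif(1, 0.3, 1); sp <- runif(1, 0.3, 1)
      prev <- runif(1, 0.01, 0.5); n <- sample(200:20000, 1)
      pr <- project_population(se, sp, prev, n)
      tab <- pr$table
      expect_equal(tab$tp + tab$fp + tab$tn + tab$fn, n)
      expect_equal(tab$tp + tab$fn, round(n * prev))
      back <- sens_spec(tab)
      pos <- round(n * prev)
      expect_lt(abs(back["sensitivity"] - se), 1 / pos + 1e-12)
      expect_lt(abs(back["specificity"] - sp), 1 / (n - pos) + 1e-12)
    }
  })
})

test_that("cut-off sweep rows are monotone and reproducible", {
  withr::with_seed(8, {
    truth <- rbinom(500, 1, 0.059)
    scores <- plogis(rnorm(500, ifelse(truth == 1, 3, -3), 2))
  })
  sw <- sweep_cutoffs(scores, truth, n_boot = 100, seed = 2)
  expect_equal(sw$cutoff, c(0.95, 0.98, 0.99, 0.995, 0.999, 0.9995))
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
  sw2 <- sweep_cutoffs(scores, truth, n_boot = 100, seed = 2)
  expect_identical(sw, sw2)
  expect_error(sweep_cutoffs(scores, truth, cutoffs = c(0.9, 0.5)),
               class = "dxascol_invalid_input")
})

test_that("kappa matches the hand formula, including the worked 2x2 table", {
  a <- rep(c("yes", "no"), c(25, 75))
  b <- rep(c("yes", "no", "yes", "no"), c(20, 5, 5, 70))
  k <- cohen_kappa(a, b)
  expect_equal(k$percent_agreement, 0.9)
  expect_equal(k$kappa, (0.9 - 0.625) / (1 - 0.625), tolerance = 1e-12)
  expect_equal(round(k$kappa, 4), 0.7333)
  ident <- cohen_kappa(c(1, 0, 1, 1), c(1, 0, 1, 1))
  expect_equal(ident$kappa, 1)
  expect_equal(ident$band, "almost perfect")
  const <- cohen_kappa(rep("x", 5), rep("x", 5))
  expect_true(is.na(const$kappa))
  expect_equal(const$percent_agreement, 1)
})

test_that("kappa agrees with the formula over an exhaustive small-table sweep", {
  kappa_hand <- function(a, b, c, d) {
    n <- a + b + c + d
    po <- (a + d) / n
    pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
    (po - pe) / (1 - pe)
  }
  grid <- 0:6  # all 2x2 tables with cell counts <= 6 and margins <= 100
  for (a in grid) for (b in grid) for (cc in grid) for (d in grid) {
    n <- a + b + cc + d
    if (n < 2) next
    pe1 <- ((a + b) * (a + cc) + (cc + d) * (b + d)) == n^2
    if (pe1) next
    ra <- rep(c(1, 1, 0, 0), c(a, b, cc, d))
    rb <- rep(c(1, 0, 1, 0), c(a, b, cc, d))
    expect_equal(cohen_kappa(ra, rb)$kappa, kappa_hand(a, b, cc, d),
                 tolerance = 1e-12)
  }
})

test_that("kappa CI has the large-sample width and covers the estimate", {
  k <- cohen_kappa(rep(c(1, 1, 0, 0), c(20, 5, 5, 70)),
                   rep(c(1, 0, 1, 0), c(20, 5, 5, 70)))
  se <- sqrt(0.9 * 0.1 / (100 * (1 - 0.625)^2))
  expect_equal(k$ci_low, k$kappa - qnorm(0.975) * se, tolerance = 1e-10)
  expect_equal(k$ci_high, k$kappa + qnorm(0.975) * se, tolerance = 1e-10)
  expect_lte(k$ci_low, k$kappa)
  expect_gte(k$ci_high, k$kappa)
})

test_that("chi-squared association matches hand arithmetic and the gender table", {
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(unname(chi2_association(even)$statistic), 0)
  hand <- chi2_association(matrix(c(10, 20, 20, 10), 2))
  expect_equal(unname(hand$statistic), 20 / 3, tolerance = 1e-12)
  gender <- matrix(c(1526, 1709, 136, 313), 2,
                   dimnames = list(c("male", "female"), c("no", "yes")))
  expect_lt(chi2_association(gender)$p.value, 0.001)
  expect_error(chi2_association(matrix(c(0, 0, 1, 2), 2)),
               class = "dxascol_invalid_table")
})

test_that("row percentages reproduce the cohort gender rows", {
  tab <- matrix(c(1709, 1526, 313, 136), 2,
                dimnames = list(c("female", "male"), c("no", "yes")))
  rp <- row_percentages(tab)
  expect_equal(unname(rp["female", ]), c(84.5, 15.5))
  expect_equal(unname(rp["male", ]), c(91.8, 8.2))
  expect_equal(unname(row_percentages(matrix(c(1, 1), 1))[1, ]), c(50, 50))
  expect_error(row_percentages(matrix(c(0, 1, 0, 2), 2)),
               class = "dxascol_invalid_row")
})

test_that("unpaired t test uses the Welch form and is swap-antisymmetric", {
  tt <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(tt$statistic, 3), -3.674)
  swap <- unpaired_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -tt$statistic)
  expect_equal(swap$p_value, tt$p_value)
  same <- unpaired_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_error(unpaired_t_test(c(1, 1), c(1, 1)),
               class = "dxascol_undefined_test")
})

test_that("percent agreement counts equal positions", {
  expect_equal(percent_agreement(c(1, 0, 1, 1, 0), c(1, 1, 1, 0, 0)), 0.6)
  expect_equal(percent_agreement(1:4, 1:4), 1)
  expect_equal(percent_agreement(c(1, 1), c(0, 0)), 0)
  expect_error(percent_agreement(1:3, 1:4), class = "dxascol_invalid_input")
})

test_that("AUC implementation agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    t <- rbinom(80, 1, 0.4)
    t[1:2] <- c(0, 1)
    s <- rnorm(80, t)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(s, t, n_boot = 0)$auc, ref, tolerance = 1e-12)
})
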