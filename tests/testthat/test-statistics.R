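test_that("motion exclusion applies a strict threshold and preserves order", {
  ph <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    mean_fd_mm = c(0.25, 0.086, 0.200, 0.19)
  )
  mx <- motion_exclude(ph)
  expect_equal(mx$excluded, "a")
  expect_equal(mx$kept$subject_id, c("b", "c", "d"))  # 0.200 is kept
  ph$mean_fd_mm[2] <- NA
  expect_error(motion_exclude(ph), "b")
})

test_that("two-sample t reproduces the published demographic rows", {
  edu <- two_sample_t(mean1 = 12.115, sd1 = 3.191, n1 = 52,
                      mean2 = 14.952, sd2 = 2.747, n2 = 21,
                      variant = "pooled")
  expect_equal(edu$statistic_value, -3.571, tolerance = 0.005 / 3.571)
  age <- two_sample_t(mean1 = 30.615, sd1 = 9.306, n1 = 52,
                      mean2 = 27.000, sd2 = 5.908, n2 = 21,
                      variant = "welch")
  expect_equal(age$statistic_value, 1.982, tolerance = 0.005 / 1.982)
})

test_that("two-sample t degenerate and equivalence cases hold", {
  same <- two_sample_t(mean1 = 5, sd1 = 2, n1 = 10, mean2 = 5, sd2 = 2,
                       n2 = 12, variant = "pooled")
  expect_equal(same$statistic_value, 0)
  expect_equal(same$p_raw, 1)
  # pooled equals Welch for equal n and sd
  p <- two_sample_t(mean1 = 3, sd1 = 1.5, n1 = 14, mean2 = 2.2, sd2 = 1.5,
                    n2 = 14, variant = "pooled")
  w <- two_sample_t(mean1 = 3, sd1 = 1.5, n1 = 14, mean2 = 2.2, sd2 = 1.5,
                    n2 = 14, variant = "welch")
  expect_equal(p$statistic_value, w$statistic_value, tolerance = 1e-12)
  expect_equal(p$p_raw, w$p_raw, tolerance = 1e-12)
  # raw-sample interface agrees with stats::t.test
  withr::with_seed(1, {
    x <- rnorm(20, 1)
    y <- rnorm(15)
    got <- two_sample_t(x, y, variant = "welch")
    ref <- t.test(x, y)
    expect_equal(got$statistic_value, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
  })
  expect_error(two_sample_t(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 2, sd2 = 1,
                            n2 = 5), "positive")
})

test_that("the 2x2 chi-square matches the published sex comparison and anchors", {
  sex <- chi_square_2x2(28, 24, 10, 11)
  expect_equal(sex$statistic_value, 0.232, tolerance = 0.005 / 0.232)
  expect_equal(chi_square_2x2(20, 10, 10, 5)$statistic_value, 0,
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(10, 0, 0, 10)$statistic_value, 20)
  expect_error(chi_square_2x2(5, 0, 3, 0), "margins")
})

test_that("the group ANCOVA is the partial F of the group coefficient", {
  withr::with_seed(21, {
    # outcome driven by the covariates alone: no genuine group signal, so
    # the partial F stays at null-distribution scale even at tiny noise
    # (a real effect of comparable size would push it past 1e6)
    n <- 30
    age <- rnorm(n, 30, 8)
    sex <- rbinom(n, 1, 0.5)
    edu <- rnorm(n, 13, 3)
    grp <- rep(c("patient", "control"), c(18, 12))
    y0 <- 2 + 0.3 * age - 0.5 * sex + 0.1 * edu + rnorm(n, sd = 1e-6)
    r0 <- ancova_group(y0, grp, list(age = age, sex = sex, education = edu))
    expect_lt(r0$statistic_value, 25)

    # against an explicit normal-equations oracle on a 12-row fixture
    covars <- cbind(age = c(25, 30, 35, 40, 28, 33, 27, 38, 31, 26, 36, 29),
                    edu = c(12, 16, 10, 14, 13, 11, 15, 12, 13, 14, 10, 16))
    g <- rep(c(1, 0), 6)
    y <- 1 + 0.2 * covars[, 1] - 0.1 * covars[, 2] + 0.8 * g +
      c(0.05, -0.02, 0.04, -0.06, 0.01, 0.03, -0.04, 0.02, -0.01, 0.06,
        -0.03, -0.05)
    got <- ancova_group(y, ifelse(g == 1, "patient", "control"),
                        as.data.frame(covars))
    want <- ols_partial_f(y, g, covars)
    expect_equal(got$statistic_value, want, tolerance = 1e-10)

    # permutation invariance
    perm <- sample(12)
    got_p <- ancova_group(y[perm], ifelse(g[perm] == 1, "patient", "control"),
                          as.data.frame(covars[perm, ]))
    expect_equal(got_p$statistic_value, got$statistic_value, tolerance = 1e-10)

    # with no covariates the F is the squared pooled t
    x1 <- rnorm(12, 1)
    x2 <- rnorm(9)
    f <- ancova_group(c(x1, x2), rep(c("patient", "control"), c(12, 9)))
    tt <- two_sample_t(x1, x2, variant = "pooled")
    expect_equal(f$statistic_value, tt$statistic_value^2, tolerance = 1e-10)
    expect_equal(f$p_raw, tt$p_raw, tolerance = 1e-10)

    # collinear covariates are reported, not silently dropped
    expect_error(
      ancova_group(y, ifelse(g == 1, "patient", "control"),
                   list(a = covars[, 1], b = 2 * covars[, 1])),
      "collinear"
    )
  })
})

test_that("Spearman correlations match hand values and reduce correctly", {
  up <- spearman_cor(1:6, c(2, 4, 5, 7, 8, 11))
  expect_equal(up$statistic_value, 1)
  down <- spearman_cor(1:6, -(1:6))
  expect_equal(down$statistic_value, -1)
  hand <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(hand$statistic_value, 0.8)  # 1 - 6*4/(5*24)
  ref <- suppressWarnings(cor.test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                                   method = "spearman", exact = FALSE))
  expect_equal(hand$p_raw, ref$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  # a constant covariate changes nothing about the coefficient
  withr::with_seed(31, {
    x <- rnorm(25)
    y <- 0.5 * x + rnorm(25)
    plain <- spearman_cor(x, y)
    part <- spearman_cor(x, y, covariate = rep(2, 25))
    expect_equal(part$statistic_value, plain$statistic_value,
                 tolerance = 1e-10)
    # partialling out a genuine confounder moves rho towards zero
    z <- rnorm(25)
    x2 <- z + rnorm(25, sd = 0.3)
    y2 <- z + rnorm(25, sd = 0.3)
    expect_lt(abs(spearman_cor(x2, y2, covariate = z)$statistic_value),
              abs(spearman_cor(x2, y2)$statistic_value))
  })
})

test_that("Benjamini-Hochberg adjustment matches the worked example and is stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  withr::with_seed(41, {
    p <- runif(20)
    perm <- sample(20)
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
    expect_true(all(bh_fdr(p) >= p))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the proportional-odds slope agrees with a grid-search likelihood oracle", {
  y <- c(0, 1, 0, 2, 1, 0, 2, 1, 2, 0, 1, 2)
  x <- c(0.2, 0.5, 0.6, 1.4, 0.3, 0.8, 1.0, 1.2, 0.9, 0.4, 0.7, 1.6)
  slope <- dynstab:::ordinal_logistic_slope(y, x)
  coarse <- polr_grid_slope(y, x, seq(-1, 6, by = 0.05))
  fine <- polr_grid_slope(y, x, seq(coarse - 0.06, coarse + 0.06, by = 5e-4))
  expect_equal(slope, fine, tolerance = 2e-3)
})

test_that("the proportional-odds Wald test has nominal size under the null", {
  withr::with_seed(51, {
    hits <- vapply(1:100, function(r) {
      y <- sample(0:4, 200, replace = TRUE,
                  prob = c(0.2, 0.25, 0.25, 0.18, 0.12))
      x <- rnorm(200)
      abs(ordinal_logistic(y, x)$statistic_value) < 1.96
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  })
})

test_that("proportional-odds degenerate inputs raise explicit errors", {
  expect_error(ordinal_logistic(rep(c(0, 1, 2), 5), rep(1, 15)), "constant")
  expect_error(ordinal_logistic(c(0, 1, 2), c(1, 2, 3)), "at least 10")
  # complete separation: low x always scores 0, high x always 2
  y <- rep(c(0, 2), each = 10)
  x <- c(seq(0, 0.9, length.out = 10), seq(5, 6, length.out = 10))
  expect_error(ordinal_logistic(y, x), "converge")
})

test_that("the study harness joins, drops and corrects as designed", {
  withr::with_seed(61, {
    tab <- synthetic_node_table(12)
    cfg <- cohort_config(n_patients = 12, n_controls = 8, n_nodes = 12,
                         n_timepoints = 120, node_table = tab, seed = 3)
    coh <- generate_cohort(cfg)
    profs <- cohort_stability(coh$time_series, tab,
                              densities = density_grid(0.1, 0.5, 0.1))
    # a phenotype row without a profile is dropped with a warning
    extra <- coh$phenotype[1, ]
    extra$subject_id <- "ghost"
    ph <- dplyr::bind_rows(coh$phenotype, extra)
    expect_warning(
      res <- run_study_statistics(profs, ph),
      "ghost"
    )
    expect_true(all(res$n_used <= length(profs)))
    nets <- res[res$analysis == "ancova:network", ]
    expect_equal(nrow(nets), 9)
    expect_equal(nets$p_adjusted, bh_fdr(nets$p_raw))
    expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))
    demo <- res[grepl("^demographic", res$analysis), ]
    expect_setequal(demo$analysis,
                    c("demographic:age_years", "demographic:education_years",
                      "demographic:mean_fd_mm", "demographic:sex"))
  })
})
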