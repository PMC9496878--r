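stat_row <- function(analysis, unit, statistic_name, statistic_value,
                     p_raw, n_used, covariates = character(),
                     p_adjusted = NA_real_) {
  tibble(
    analysis = analysis,
    unit = unit,
    statistic_name = statistic_name,
    statistic_value = as.numeric(statistic_value),
    p_raw = as.numeric(p_raw),
    p_adjusted = as.numeric(p_adjusted),
    n_used = as.integer(n_used),
    covariates = paste(covariates, collapse = ",")
  )
}

#' Exclude high-motion subjects
#'
#' Removes subjects whose mean framewise displacement exceeds the
#' threshold. The rule is a strict inequality: a subject at exactly the
#' threshold is kept.
#'
#' @param pheno Phenotype data frame with a `mean_fd_mm` column.
#' @param threshold_mm Exclusion threshold in millimetres (default 0.2).
#' @return List with `kept` (the filtered table, original order) and
#'   `excluded` (character vector of removed subject IDs).
#' @export
motion_exclude <- function(pheno, threshold_mm = 0.2) {
  if (!"mean_fd_mm" %in% names(pheno)) {
    abort("`pheno` must contain a `mean_fd_mm` column.")
  }
  bad <- is.na(pheno$mean_fd_mm)
  if (any(bad)) {
    abort(paste0(
      "mean framewise displacement missing for subject(s): ",
      paste(pheno$subject_id[bad], collapse = ", ")
    ))
  }
  drop <- pheno$mean_fd_mm > threshold_mm
  list(
    kept = as_tibble(pheno[!drop, , drop = FALSE]),
    excluded = as.character(pheno$subject_id[drop])
  )
}

#' Two-sample t test from raw samples or summary statistics
#'
#' Computes the pooled-variance or Welch t statistic either from two raw
#' sample vectors or from the published summary statistics
#' (mean, SD, n per group), as needed when recomputing a demographic table
#' from a paper's printed rows.
#'
#' @param x,y Optional raw sample vectors. If given, summaries are derived
#'   from them and the `mean1 ... n2` arguments are ignored.
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @param variant `"pooled"` (equal-variance) or `"welch"`.
#' @param analysis Label for the result row.
#' @return A one-row tibble (statistic `t`, two-sided `p_raw`).
#' @export
#' @examples
#' two_sample_t(mean1 = 12.115, sd1 = 3.191, n1 = 52,
#'              mean2 = 14.952, sd2 = 2.747, n2 = 21, variant = "pooled")
two_sample_t <- function(x = NULL, y = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         variant = c("pooled", "welch"),
                         analysis = "two_sample_t") {
  variant <- arg_match(variant)
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) abort("supply both `x` and `y`.")
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2)) {
    abort("supply raw samples or the six summary statistics.")
  }
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  if (sd1 <= 0 || sd2 <= 0) abort("standard deviations must be positive.")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  stat_row(analysis, variant, "t", tval, 2 * pt(-abs(tval), df), n1 + n2)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Pearson's statistic without continuity correction, df = 1. The four
#' counts are given row-wise: `a`, `b` in row one and `c`, `d` in row two.
#'
#' @param a,b,c,d Non-negative integer cell counts; all four margins must
#'   be positive.
#' @param analysis Label for the result row.
#' @return A one-row tibble (statistic `chi2`).
#' @export
#' @examples
#' chi_square_2x2(28, 24, 10, 11)  # ~0.232
chi_square_2x2 <- function(a, b, c, d, analysis = "chi_square_2x2") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers.")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("all margins of the 2x2 table must be positive.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  stat_row(analysis, "2x2", "chi2", unname(res$statistic),
           unname(res$p.value), sum(counts))
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Tests the group effect on a continuous outcome in the linear model
#' `y ~ group + covariates`, reporting the partial F of the group term
#' (for a two-level factor this equals the squared t of its coefficient).
#' With no covariates this reduces to the squared pooled two-sample t.
#'
#' @param y Numeric outcome vector.
#' @param group Two-level factor (or coercible) giving group membership.
#' @param covariates Optional data frame (or named list) of numeric
#'   covariate vectors; a factor/character covariate with two levels is
#'   converted to a 0/1 indicator.
#' @param analysis Label for the result row.
#' @return A one-row tibble (statistic `F`).
#' @export
ancova_group <- function(y, group, covariates = NULL,
                         analysis = "ancova") {
  keep <- !is.na(y) & !is.na(group)
  covnames <- character()
  df_cov <- NULL
  if (!is.null(covariates)) {
    df_cov <- as.data.frame(covariates)
    covnames <- names(df_cov)
    for (nm in covnames) {
      v <- df_cov[[nm]]
      if (is.character(v) || is.factor(v)) {
        lev <- sort(unique(as.character(v[!is.na(v)])))
        if (length(lev) != 2) {
          abort(paste0("covariate `", nm, "` must be numeric or two-level."))
        }
        df_cov[[nm]] <- as.numeric(as.character(v) == lev[2])
      }
      keep <- keep & !is.na(df_cov[[nm]])
    }
  }
  y <- y[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2) {
    abort("`group` must have exactly two levels among the used rows.")
  }
  dat <- data.frame(.y = y, .group = as.numeric(group == levels(group)[2]))
  if (!is.null(df_cov)) dat <- cbind(dat, df_cov[keep, , drop = FALSE])
  fml <- stats::as.formula(paste(
    ".y ~ .group",
    if (length(covnames) > 0) paste("+", paste(covnames, collapse = " + ")) else ""
  ))
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0(
      "rank-deficient design; collinear term(s): ",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ))
  }
  sm <- summary(fit)
  tval <- sm$coefficients[".group", "t value"]
  df2 <- fit$df.residual
  fval <- tval^2
  stat_row(analysis, "group", "F", fval, pf(fval, 1, df2, lower.tail = FALSE),
           length(y), covnames)
}

#' Spearman rank correlation, optionally partial
#'
#' Plain Spearman correlation with midrank tie handling, or — when a
#' covariate is supplied — the partial Spearman correlation: both
#' variables' ranks are residualised on the covariate's ranks and the
#' Pearson correlation of the residuals is tested on `n - 3` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Optional numeric vector to partial out (on ranks).
#' @param analysis Label for the result row.
#' @return A one-row tibble (statistic `rho`, two-sided `p_raw`).
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))  # rho = 0.8
spearman_cor <- function(x, y, covariate = NULL, analysis = "spearman") {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for a constant vector.")
  }
  if (is.null(covariate)) {
    res <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
    return(stat_row(analysis, "plain", "rho", unname(res$estimate),
                    unname(res$p.value), n))
  }
  z <- covariate[keep]
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(lm(rx ~ rz))
  ey <- stats::resid(lm(ry ~ rz))
  if (sd(ex) == 0 || sd(ey) == 0) {
    abort("partial Spearman undefined: ranks fully explained by covariate.")
  }
  r <- cor(ex, ey)
  dfree <- n - 3
  tval <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
  stat_row(analysis, "partial", "rho", r, 2 * pt(-abs(tval), dfree), n,
           covariates = "covariate_ranks")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values, clipped at 1.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) abort("empty p-value vector.")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p values must lie in [0, 1] with no missing entries.")
  }
  p.adjust(p_values, method = "BH")
}

#' Proportional-odds ordinal logistic regression with one predictor
#'
#' Fits the proportional-odds model of an ordinal response (e.g. a 0-4
#' clinical item) on a single continuous predictor by maximum likelihood
#' and reports the Wald z of the slope. Complete or quasi-complete
#' separation is detected (diverging slope or unusable Hessian) and raised
#' as an explicit error rather than returned as a huge coefficient.
#'
#' @param y Integer-valued ordinal response with at least two observed
#'   levels.
#' @param x Numeric predictor.
#' @param analysis Label for the result row.
#' @return A one-row tibble (statistic `z`, plus the slope in an
#'   `estimate` attribute-free extra column is not kept; use the z and p).
#' @export
ordinal_logistic <- function(y, x, analysis = "ordinal_logistic") {
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 10) abort("need at least 10 complete observations.")
  if (length(unique(y)) < 2) abort("response has fewer than 2 observed levels.")
  if (sd(x) == 0) abort("predictor is constant; slope not identifiable.")
  yf <- factor(y, levels = sort(unique(y)), ordered = TRUE)
  xs <- as.numeric(scale(x))  # standardised internally for stable fitting
  fit <- tryCatch(
    suppressWarnings(MASS::polr(yf ~ xs, Hess = TRUE,
                                control = list(reltol = 1e-10))),
    error = function(e) {
      abort(paste0("proportional-odds fit did not converge: ",
                   conditionMessage(e)))
    }
  )
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  beta_std <- unname(coef(fit)["xs"])
  if (is.null(vc) || !is.finite(vc["xs", "xs"]) || vc["xs", "xs"] <= 0 ||
      abs(beta_std) > 15 || sqrt(vc["xs", "xs"]) > 1e3) {
    abort("proportional-odds fit did not converge (separation suspected).")
  }
  se <- sqrt(vc["xs", "xs"])
  z <- beta_std / se
  stat_row(analysis, "slope", "z", z, 2 * pnorm(-abs(z)), length(y))
}

# slope of the proportional-odds model on the original predictor scale;
# used by tests that compare against a brute-force likelihood oracle
ordinal_logistic_slope <- function(y, x) {
  yf <- factor(y, levels = sort(unique(y)), ordered = TRUE)
  fit <- suppressWarnings(MASS::polr(yf ~ x, Hess = TRUE,
                                     control = list(reltol = 1e-10)))
  unname(coef(fit)["x"])
}
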