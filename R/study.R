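#' Run the full statistical layer of a stability study
#'
#' Given per-subject stability profiles and a phenotype table, reproduces
#' the statistical design of a case-control dynamic-connectivity study:
#'
#' 1. high-motion subjects are excluded (mean FD strictly above
#'    `fd_threshold_mm`);
#' 2. demographic comparisons (age, education, mean FD by t test; sex by
#'    Pearson chi-square without continuity correction);
#' 3. ANCOVA of the whole-brain temporal correlation coefficient on group,
#'    adjusting for age, sex and education (reported uncorrected), and of
#'    each functional network, with Benjamini-Hochberg correction across
#'    the network family;
#' 4. in patients, Spearman correlations of every significant level with
#'    the total symptom score and with the ordinal suicidality item,
#'    BH-corrected as one family;
#' 5. post-hoc analyses on the significant levels: Spearman with illness
#'    duration, drug-naive vs medicated ANCOVA, Spearman with daily dose;
#' 6. validation: the clinical correlations repeated as partial Spearman
#'    with dose as covariate, and a proportional-odds model of the
#'    suicidality item on the default-mode stability value.
#'
#' Failures of individual analyses (e.g. too few complete cases) are
#' reported as warnings and skipped, not raised.
#'
#' @param profiles List of [stability_profile][compute_stability] objects.
#' @param pheno Phenotype data frame; required columns `subject_id`,
#'   `group` (`"patient"`/`"control"`), `age_years`, `sex`
#'   (`"male"`/`"female"`), `education_years`, `mean_fd_mm`; optional
#'   clinical columns `hamd_total`, `hamd_item3`,
#'   `illness_duration_months`, `medication_status`
#'   (`"drug_naive"`/`"medicated"`), `dose_mg_per_day`.
#' @param alpha Significance level on adjusted p values (default 0.05).
#' @param fd_threshold_mm Motion-exclusion threshold (default 0.2).
#' @param demographic_variant t-test variant for the demographic rows
#'   (`"welch"` default, or `"pooled"`).
#' @param sex_female_is_one Code sex as female = 1 in the ANCOVA design
#'   (default `TRUE`; `FALSE` codes male = 1).
#' @param apply_motion_filter Apply the mean-FD exclusion (default `TRUE`).
#' @return A tibble of result rows: `analysis`, `unit`, `statistic_name`,
#'   `statistic_value`, `p_raw`, `p_adjusted`, `n_used`, `covariates`.
#' @export
run_study_statistics <- function(profiles, pheno,
                                 alpha = 0.05,
                                 fd_threshold_mm = 0.2,
                                 demographic_variant = c("welch", "pooled"),
                                 sex_female_is_one = TRUE,
                                 apply_motion_filter = TRUE) {
  demographic_variant <- arg_match(demographic_variant)
  pheno <- as_tibble(pheno)
  needed <- c("subject_id", "group", "age_years", "sex", "education_years",
              "mean_fd_mm")
  miss <- setdiff(needed, names(pheno))
  if (length(miss) > 0) {
    abort(paste0("phenotype table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (apply_motion_filter) {
    mx <- motion_exclude(pheno, fd_threshold_mm)
    if (length(mx$excluded) > 0) {
      inform(paste0("excluded ", length(mx$excluded),
                    " high-motion subject(s): ",
                    paste(mx$excluded, collapse = ", ")))
    }
    pheno <- mx$kept
  }

  stab <- tidy_profiles(profiles, level = c("whole_brain", "network"))
  stab <- tidyr::pivot_wider(
    stab[, c("subject_id", "unit", "temporal_correlation")],
    names_from = "unit", values_from = "temporal_correlation"
  )
  only_pheno <- setdiff(pheno$subject_id, stab$subject_id)
  if (length(only_pheno) > 0) {
    warn(paste0("no stability profile for subject(s): ",
                paste(only_pheno, collapse = ", "), "; dropped."))
  }
  dat <- dplyr::inner_join(pheno, stab, by = "subject_id")
  if (!all(c("patient", "control") %in% dat$group)) {
    abort("both groups must be present after filtering and joining.")
  }
  networks <- setdiff(
    names(stab), c("subject_id", "whole_brain")
  )
  sexlev <- if (sex_female_is_one) "female" else "male"
  covs <- function(d) list(
    age = d$age_years,
    sex = as.numeric(d$sex == sexlev),
    education = d$education_years
  )
  pat <- dat[dat$group == "patient", ]
  out <- list()
  addrow <- function(row) out[[length(out) + 1L]] <<- row
  safely_row <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warn(paste0(what, " skipped: ", conditionMessage(e)))
      NULL
    })
  }

  # --- demographics -------------------------------------------------------
  grp <- function(col, g) dat[[col]][dat$group == g]
  for (col in c("age_years", "education_years", "mean_fd_mm")) {
    addrow(safely_row(
      two_sample_t(x = grp(col, "patient"), y = grp(col, "control"),
                   variant = demographic_variant,
                   analysis = paste0("demographic:", col)),
      paste0("demographic test of ", col)
    ))
  }
  sx <- table(factor(dat$group, c("patient", "control")),
              factor(dat$sex, c("male", "female")))
  addrow(safely_row(
    chi_square_2x2(sx[1, 1], sx[1, 2], sx[2, 1], sx[2, 2],
                   analysis = "demographic:sex"),
    "demographic test of sex"
  ))

  # --- group ANCOVAs ------------------------------------------------------
  wb <- safely_row(
    ancova_group(dat$whole_brain, dat$group, covs(dat),
                 analysis = "ancova:whole_brain"),
    "whole-brain ANCOVA"
  )
  if (!is.null(wb)) wb$unit <- "whole_brain"
  addrow(wb)
  net_rows <- list()
  for (nw in networks) {
    r <- safely_row(
      ancova_group(dat[[nw]], dat$group, covs(dat),
                   analysis = "ancova:network"),
      paste0("ANCOVA of ", nw)
    )
    if (!is.null(r)) {
      r$unit <- nw
      net_rows[[nw]] <- r
    }
  }
  if (length(net_rows) > 0) {
    net_tbl <- bind_rows(net_rows)
    net_tbl$p_adjusted <- bh_fdr(net_tbl$p_raw)
    for (i in seq_len(nrow(net_tbl))) addrow(net_tbl[i, ])
    sig_networks <- net_tbl$unit[net_tbl$p_adjusted < alpha]
  } else {
    sig_networks <- character()
  }
  sig_levels <- c(
    if (!is.null(wb) && isTRUE(wb$p_raw < alpha)) "whole_brain",
    sig_networks
  )

  # --- clinical correlations in patients ---------------------------------
  cor_rows <- list()
  for (lev in sig_levels) {
    for (score in c("hamd_total", "hamd_item3")) {
      if (!score %in% names(pat)) next
      r <- safely_row(
        spearman_cor(pat[[lev]], pat[[score]],
                     analysis = paste0("spearman:", score)),
        paste0("correlation of ", lev, " with ", score)
      )
      if (!is.null(r)) {
        r$unit <- lev
        cor_rows[[paste(lev, score)]] <- r
      }
    }
  }
  if (length(cor_rows) > 0) {
    cor_tbl <- bind_rows(cor_rows)
    cor_tbl$p_adjusted <- bh_fdr(cor_tbl$p_raw)
    for (i in seq_len(nrow(cor_tbl))) addrow(cor_tbl[i, ])
  }

  # --- post-hoc clinical analyses ----------------------------------------
  for (lev in sig_levels) {
    if ("illness_duration_months" %in% names(pat)) {
      r <- safely_row(
        spearman_cor(pat[[lev]], pat$illness_duration_months,
                     analysis = "spearman:illness_duration"),
        paste0("illness-duration correlation for ", lev)
      )
      if (!is.null(r)) { r$unit <- lev; addrow(r) }
    }
    if ("medication_status" %in% names(pat)) {
      r <- safely_row(
        ancova_group(pat[[lev]], pat$medication_status, covs(pat),
                     analysis = "ancova:medication_status"),
        paste0("medication-status ANCOVA for ", lev)
      )
      if (!is.null(r)) { r$unit <- lev; addrow(r) }
    }
    if ("dose_mg_per_day" %in% names(pat)) {
      r <- safely_row(
        spearman_cor(pat[[lev]], pat$dose_mg_per_day,
                     analysis = "spearman:dose"),
        paste0("dose correlation for ", lev)
      )
      if (!is.null(r)) { r$unit <- lev; addrow(r) }
    }
  }

  # --- validation ---------------------------------------------------------
  if ("dose_mg_per_day" %in% names(pat)) {
    for (lev in sig_levels) {
      for (score in c("hamd_total", "hamd_item3")) {
        if (!score %in% names(pat)) next
        r <- safely_row(
          spearman_cor(pat[[lev]], pat[[score]],
                       covariate = pat$dose_mg_per_day,
                       analysis = paste0("partial_spearman:", score)),
          paste0("dose-partial correlation of ", lev, " with ", score)
        )
        if (!is.null(r)) { r$unit <- lev; addrow(r) }
      }
    }
  }
  if ("hamd_item3" %in% names(pat) && "default-mode" %in% names(pat)) {
    r <- safely_row(
      ordinal_logistic(pat$hamd_item3, pat[["default-mode"]],
                       analysis = "ordinal_logistic:hamd_item3"),
      "proportional-odds validation model"
    )
    if (!is.null(r)) { r$unit <- "default-mode"; addrow(r) }
  }

  bind_rows(out)
}
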