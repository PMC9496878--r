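#' Configuration for a synthetic stability cohort
#'
#' Bundles every generative parameter of the synthetic-cohort model. The
#' model emulates a two-group resting-state case-control design: each
#' functional network (block of nodes) switches between hidden coherence
#' states with geometrically distributed dwell times, patients switch
#' faster than controls globally and faster still within two targeted
#' networks, and an ordinal 0-4 clinical score is negatively coupled to
#' each patient's true default-mode stability.
#'
#' Within a hidden state every node of a block loads on the block's
#' latent factor with weight `+sqrt(rho)` or `-sqrt(rho)`: state 1 is the
#' fully coherent configuration (all weights positive, within-block
#' correlation `rho`), and each higher state is a "fragmented"
#' configuration with a random sign pattern drawn once per subject, so a
#' state switch re-arranges which node pairs are positively coupled.
#' Off-block correlation is zero and independent Gaussian noise of
#' standard deviation `noise_sd` is added on top. Factors and noise are
#' AR(1) processes with coefficient `ar_phi`, mimicking the temporal
#' smoothness of band-limited haemodynamic signals; fast state switching
#' averages the fragmented patterns away and genuinely destabilises the
#' windowed networks, so longer dwell times mean higher measured temporal
#' stability. Blocks switch independently of one another.
#'
#' @param n_patients,n_controls Group sizes (defaults 52 and 21).
#' @param n_nodes Number of nodes (default 90).
#' @param n_timepoints Series length in volumes (default 240).
#' @param tr_seconds Sampling interval (default 2).
#' @param node_table Node-to-network mapping; defaults to
#'   [synthetic_node_table()]`(n_nodes)`.
#' @param n_states Number of hidden coherence states per block (>= 2).
#' @param within_state_block_correlation Within-block correlation `rho` of
#'   the most coherent state, in (0, 1).
#' @param noise_sd Additive noise SD (default 0.2).
#' @param ar_phi AR(1) coefficient of factors and noise, in \[0, 1)
#'   (default 0.95; about a 40 s autocorrelation time at TR 2 s).
#' @param dwell_mean_control Mean state dwell time, in samples, for every
#'   block of a control subject (default 120, i.e. 4 min at TR 2 s).
#' @param dwell_mean_patient_global Mean dwell time for a patient's
#'   non-targeted blocks; must not exceed `dwell_mean_control`
#'   (default 84).
#' @param targeted_networks Networks with an extra dwell reduction in
#'   patients (default default-mode and subcortical).
#' @param targeted_dwell_factor Multiplier in (0, 1] applied to patients'
#'   dwell time within targeted networks (default 0.15).
#' @param score_coupling Non-positive coefficient linking a patient's
#'   standardised true default-mode stability latent to the ordinal score
#'   (default -2.5; 0 decouples them).
#' @param subject_dwell_sdlog Log-normal SD of the per-subject dwell
#'   multiplier, creating between-subject stability heterogeneity
#'   (default 0.4).
#' @param frac_high_motion Fraction of subjects given mean FD above the
#'   0.2 mm exclusion threshold, to exercise motion filtering (default 0).
#' @param seed Master seed; every subject's stream is derived from it.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 52,
                          n_controls = 21,
                          n_nodes = 90,
                          n_timepoints = 240,
                          tr_seconds = 2,
                          node_table = NULL,
                          n_states = 6,
                          within_state_block_correlation = 0.95,
                          noise_sd = 0.2,
                          ar_phi = 0.95,
                          dwell_mean_control = 120,
                          dwell_mean_patient_global = 84,
                          targeted_networks = c("default-mode", "subcortical"),
                          targeted_dwell_factor = 0.15,
                          score_coupling = -2.5,
                          subject_dwell_sdlog = 0.4,
                          frac_high_motion = 0,
                          seed = 1L) {
  if (n_patients < 2 || n_controls < 2) abort("group sizes must be >= 2.")
  if (is.null(node_table)) node_table <- synthetic_node_table(n_nodes)
  node_table <- validate_node_table(node_table,
                                    networks = node_table_networks(node_table))
  if (nrow(node_table) != n_nodes) {
    abort("`node_table` size does not match `n_nodes`.")
  }
  if (n_states < 2) abort("`n_states` must be at least 2.")
  rho <- within_state_block_correlation
  if (rho <= 0 || rho >= 1) {
    abort("`within_state_block_correlation` must lie in (0, 1).")
  }
  # block-constant correlation matrices have smallest eigenvalue 1 - c;
  # guard against a degenerate (non-positive-definite) coherent state
  min_eig <- 1 - rho
  if (min_eig <= 0) {
    abort(paste0("state correlation matrix is not positive definite ",
                 "(minimum eigenvalue ", format(min_eig), ")."))
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (ar_phi < 0 || ar_phi >= 1) abort("`ar_phi` must lie in [0, 1).")
  if (dwell_mean_control < 1 || dwell_mean_patient_global < 1) {
    abort("dwell means must be at least 1 sample.")
  }
  if (dwell_mean_patient_global > dwell_mean_control) {
    abort("`dwell_mean_patient_global` must not exceed `dwell_mean_control`.")
  }
  if (targeted_dwell_factor <= 0 || targeted_dwell_factor > 1) {
    abort("`targeted_dwell_factor` must lie in (0, 1].")
  }
  bad <- setdiff(targeted_networks, unique(node_table$network_label))
  if (length(bad) > 0) {
    abort(paste0("targeted network(s) absent from node table: ",
                 paste(bad, collapse = ", ")))
  }
  if (score_coupling > 0) abort("`score_coupling` must be <= 0.")
  if (frac_high_motion < 0 || frac_high_motion >= 1) {
    abort("`frac_high_motion` must lie in [0, 1).")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_controls = as.integer(n_controls),
      n_nodes = as.integer(n_nodes),
      n_timepoints = as.integer(n_timepoints),
      tr_seconds = tr_seconds,
      node_table = node_table,
      n_states = as.integer(n_states),
      within_state_block_correlation = rho,
      noise_sd = noise_sd,
      ar_phi = ar_phi,
      dwell_mean_control = dwell_mean_control,
      dwell_mean_patient_global = dwell_mean_patient_global,
      targeted_networks = targeted_networks,
      targeted_dwell_factor = targeted_dwell_factor,
      score_coupling = score_coupling,
      subject_dwell_sdlog = subject_dwell_sdlog,
      frac_high_motion = frac_high_motion,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Piecewise-constant hidden-state sequence
#'
#' Draws a sequence of state labels whose segment lengths are geometric
#' with the requested mean (support starting at 1 sample) and whose
#' successive segments always change state (when more than one state
#' exists).
#'
#' @param n_timepoints Sequence length.
#' @param dwell_mean_samples Mean segment length, >= 1.
#' @param n_states Number of states (1 gives a constant sequence).
#' @param seed Optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return Integer vector of length `n_timepoints` with values in
#'   `1..n_states`.
#' @export
generate_state_sequence <- function(n_timepoints, dwell_mean_samples,
                                    n_states, seed = NULL) {
  if (n_timepoints < 1) abort("`n_timepoints` must be positive.")
  if (dwell_mean_samples < 1) abort("`dwell_mean_samples` must be >= 1.")
  if (n_states < 1) abort("`n_states` must be >= 1.")
  draw <- function() {
    out <- integer(0)
    state <- sample.int(n_states, 1)
    p <- 1 / dwell_mean_samples
    while (length(out) < n_timepoints) {
      len <- 1L + rgeom(1, p)
      out <- c(out, rep(state, len))
      if (n_states > 1) {
        nxt <- sample.int(n_states - 1L, 1)
        state <- if (nxt >= state) nxt + 1L else nxt
      }
    }
    out[seq_len(n_timepoints)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# mean realized segment length of a label sequence
mean_segment_length <- function(seq) {
  r <- rle(seq)
  mean(r$lengths)
}

# one AR(1) series / a matrix of independent AR(1) rows, unit variance
ar1_series <- function(n, phi) {
  if (phi == 0) return(rnorm(n))
  as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive",
                           init = rnorm(1)))
}
ar1_matrix <- function(nr, nc, phi) {
  t(vapply(seq_len(nr), function(i) ar1_series(nc, phi), numeric(nc)))
}

generate_subject_impl <- function(cfg, dwell_global, dwell_targeted,
                                  subject_id) {
  tbl <- cfg$node_table
  n <- cfg$n_nodes
  tt <- cfg$n_timepoints
  rho <- cfg$within_state_block_correlation
  phi <- cfg$ar_phi
  nets <- intersect(unique(tbl$network_label),
                    setdiff(node_table_networks(tbl), "unassigned"))
  x <- ar1_matrix(n, tt, phi)  # baseline: unit-variance residual part
  sequences <- list()
  for (nw in nets) {
    idx <- nodes_of_network(tbl, nw) + 1L
    m <- length(idx)
    dwell <- if (nw %in% cfg$targeted_networks) dwell_targeted else dwell_global
    s <- generate_state_sequence(tt, dwell, cfg$n_states)
    sequences[[nw]] <- s
    # loading signs: state 1 coherent, higher states random fragmentation
    w <- cbind(rep(1, m),
               matrix(sample(c(-1, 1), m * (cfg$n_states - 1), replace = TRUE),
                      m, cfg$n_states - 1))
    g <- ar1_series(tt, phi)  # shared block factor
    x[idx, ] <- sqrt(rho) * w[, s, drop = FALSE] * rep(g, each = m) +
      sqrt(1 - rho) * x[idx, , drop = FALSE]
  }
  x <- x + ar1_matrix(n, tt, phi) * cfg$noise_sd
  ts <- subject_time_series(x, subject_id, cfg$tr_seconds)
  attr(ts, "state_sequences") <- sequences
  ts
}

#' Generate one synthetic subject
#'
#' Draws one subject's node-by-time series under the hidden-state
#' covariance-switching model of [cohort_config()]. Each populated
#' network's block follows its own independent state sequence; targeted
#' networks use `dwell_targeted`, all others `dwell_global`.
#'
#' @param cfg A [cohort_config()].
#' @param dwell_global Mean dwell time (samples) of non-targeted blocks.
#' @param dwell_targeted Mean dwell time of targeted blocks (defaults to
#'   `dwell_global`).
#' @param seed Seed for a reproducible draw.
#' @param subject_id Identifier attached to the series.
#' @return A [subject_time_series()]; the hidden state sequences are kept
#'   in the `"state_sequences"` attribute for truth bookkeeping.
#' @export
generate_subject <- function(cfg, dwell_global,
                             dwell_targeted = dwell_global,
                             seed = NULL, subject_id = "subject") {
  stopifnot(inherits(cfg, "cohort_config"))
  if (dwell_global < 1 || dwell_targeted < 1) {
    abort("dwell means must be at least 1 sample.")
  }
  run <- function() generate_subject_impl(cfg, dwell_global, dwell_targeted,
                                          subject_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * index) %% 2147483629)
}

# hamd item-3 marginal cutpoints: cumulative probabilities chosen to give
# a mean near 1.8 and SD near 1.2 on the 0-4 scale when the latent is null
item3_cutpoints <- function() qlogis(c(0.20, 0.45, 0.70, 0.88))

#' Generate a full synthetic cohort
#'
#' Draws every subject's time series, a matching phenotype table, and a
#' truth table recording each subject's generating parameters and
#' realised default-mode stability latent. Patients receive the reduced
#' global dwell time and the extra targeted-network reduction; a
#' per-subject log-normal multiplier adds between-subject heterogeneity.
#' The ordinal suicidality item is drawn for patients from a
#' proportional-odds model whose linear predictor is
#' `score_coupling x` (standardised true default-mode dwell latent), so
#' recovering the negative score-stability correlation through the
#' pipeline genuinely tests estimation rather than restating the
#' construction.
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return List with `time_series` (list of [subject_time_series()]),
#'   `phenotype` (tibble) and `truth` (tibble of per-subject generating
#'   parameters).
#' @export
generate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  master <- if (is.null(seed)) cfg$seed else as.integer(seed)
  n_tot <- cfg$n_patients + cfg$n_controls
  ids <- sprintf("sub%03d", seq_len(n_tot))
  group <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))

  pheno <- withr::with_seed(master, {
    is_pat <- group == "patient"
    age <- ifelse(is_pat, rnorm(n_tot, 30.6, 9.3), rnorm(n_tot, 27.0, 5.9))
    sex <- ifelse(
      runif(n_tot) < ifelse(is_pat, 28 / 52, 10 / 21), "male", "female"
    )
    edu <- ifelse(is_pat, rnorm(n_tot, 12.1, 3.2), rnorm(n_tot, 15.0, 2.7))
    fd <- runif(n_tot, 0.03, 0.18)
    if (cfg$frac_high_motion > 0) {
      hi <- runif(n_tot) < cfg$frac_high_motion
      fd[hi] <- runif(sum(hi), 0.21, 0.35)
    }
    hamd <- ifelse(is_pat, pmin(pmax(round(rnorm(n_tot, 20.8, 6.4)), 8), 52),
                   NA_real_)
    dur <- ifelse(is_pat, rlnorm(n_tot, 3.19, 1.07), NA_real_)
    med <- ifelse(is_pat,
                  ifelse(runif(n_tot) < 43 / 52, "medicated", "drug_naive"),
                  NA_character_)
    dose <- ifelse(!is.na(med) & med == "medicated",
                   rlnorm(n_tot, 2.99, 0.69), ifelse(is_pat, 0, NA_real_))
    mult <- exp(rnorm(n_tot, 0, cfg$subject_dwell_sdlog))
    tibble(
      subject_id = ids, group = group,
      age_years = pmax(age, 18), sex = sex,
      education_years = pmax(edu, 6),
      mean_fd_mm = fd, hamd_total = hamd, hamd_item3 = NA_integer_,
      illness_duration_months = dur, medication_status = med,
      dose_mg_per_day = dose, .dwell_mult = mult
    )
  })

  dwell_global <- ifelse(
    group == "patient", cfg$dwell_mean_patient_global, cfg$dwell_mean_control
  ) * pheno$.dwell_mult
  dwell_targeted <- dwell_global *
    ifelse(group == "patient", cfg$targeted_dwell_factor, 1)
  dwell_global <- pmax(dwell_global, 1)
  dwell_targeted <- pmax(dwell_targeted, 1)

  series <- vector("list", n_tot)
  dmn_dwell <- numeric(n_tot)
  has_dmn <- "default-mode" %in% cfg$node_table$network_label
  for (i in seq_len(n_tot)) {
    series[[i]] <- generate_subject(
      cfg, dwell_global[i], dwell_targeted[i],
      seed = subject_seed(master, i), subject_id = ids[i]
    )
    seqs <- attr(series[[i]], "state_sequences")
    dmn_dwell[i] <- if (has_dmn) {
      mean_segment_length(seqs[["default-mode"]])
    } else NA_real_
  }

  latent <- log(dmn_dwell)
  is_pat <- group == "patient"
  if (has_dmn && any(is_pat)) {
    z <- (latent[is_pat] - mean(latent[is_pat])) /
      max(sd(latent[is_pat]), .Machine$double.eps)
    eta <- cfg$score_coupling * z
    cuts <- item3_cutpoints()
    item3 <- withr::with_seed(subject_seed(master, n_tot + 1L), {
      u <- runif(sum(is_pat))
      vapply(seq_along(u), function(j) {
        sum(u[j] > plogis(cuts - eta[j]))
      }, numeric(1))
    })
    pheno$hamd_item3[is_pat] <- as.integer(item3)
  }

  truth <- tibble(
    subject_id = ids, group = group,
    dwell_global = dwell_global, dwell_targeted = dwell_targeted,
    dwell_multiplier = pheno$.dwell_mult,
    dmn_realized_dwell = dmn_dwell,
    dmn_latent = latent
  )
  pheno$.dwell_mult <- NULL
  list(time_series = series, phenotype = pheno, truth = truth)
}

#' Compute stability profiles for a whole cohort
#'
#' Convenience wrapper running [compute_stability()] over every subject of
#' a generated or loaded cohort.
#'
#' @param series List of [subject_time_series()].
#' @param table Node table shared by all subjects.
#' @param ... Passed to [compute_stability()].
#' @return List of `stability_profile` objects, named by subject.
#' @export
cohort_stability <- function(series, table, ...) {
  out <- lapply(series, compute_stability, table = table, ...)
  names(out) <- vapply(out, function(p) p$subject_id, character(1))
  out
}
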