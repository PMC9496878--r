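#' Read one subject's time series from a delimited file
#'
#' Expects tab-separated text, nodes in rows and time points in columns,
#' no header.
#'
#' @param path File path.
#' @param subject_id Identifier for the subject.
#' @param tr_seconds Sampling interval in seconds.
#' @return A [subject_time_series()].
#' @export
read_time_series <- function(path, subject_id, tr_seconds) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  subject_time_series(m, subject_id, tr_seconds)
}

#' Read a cohort from a manifest
#'
#' The manifest is tab-separated with columns `subject_id`, `path`
#' (relative to the manifest's directory or absolute), `tr_seconds`.
#'
#' @param manifest_path Path to the manifest file.
#' @return List of [subject_time_series()].
#' @export
read_cohort <- function(manifest_path) {
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  needed <- c("subject_id", "path", "tr_seconds")
  miss <- setdiff(needed, names(man))
  if (length(miss) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_time_series(p, man$subject_id[i], man$tr_seconds[i])
  })
}

#' Read a phenotype table
#'
#' @param path Tab-separated file with at least `subject_id`, `group`,
#'   `age_years`, `sex`, `education_years`, `mean_fd_mm`.
#' @return A tibble.
#' @export
read_phenotype_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "group", "age_years", "sex", "education_years",
              "mean_fd_mm")
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("phenotype table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tbl
}

#' Write a generated cohort to a directory
#'
#' Writes one tab-separated series file per subject, a `manifest.tsv`, the
#' phenotype table and the truth table, so a simulated study can be
#' re-analysed from plain files alone.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$time_series, function(ts) {
    fn <- paste0(ts$subject_id, ".tsv")
    utils::write.table(ts$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    tibble(subject_id = ts$subject_id, path = fn,
           tr_seconds = ts$tr_seconds)
  })
  readr::write_tsv(bind_rows(rows), file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$phenotype, file.path(dir, "phenotype.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Write study results to a delimited file
#'
#' @param results Result tibble from [run_study_statistics()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
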