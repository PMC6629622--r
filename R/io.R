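# CSV dialects: RFC 4180, UTF-8, "." decimal separator throughout.

#' Read / write the long per-second monitoring CSV
#'
#' Columns: `patient_id,t,resp_rate,etco2,rel_amplitude,waveform_present,`
#' `artifact,spo2,pulse_detected,tcco2`.
#'
#' @param path file path.
#' @return `read_monitoring_csv`: monitoring data.frame.
#' @export
read_monitoring_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("waveform_present", "artifact", "pulse_detected")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname read_monitoring_csv
#' @param monitoring monitoring data.frame.
#' @export
write_monitoring_csv <- function(monitoring, path) {
  utils::write.csv(monitoring, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the per-patient covariate CSV
#'
#' @param path file path.
#' @return `read_covariates_csv`: covariate data.frame.
#' @export
read_covariates_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_covariates_csv
#' @param covariates covariate data.frame.
#' @export
write_covariates_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dissimilarity matrix as square CSV plus JSON sidecar
#'
#' The CSV has patient ids as header row and first column; the sidecar
#' records the metric, the pooled marginal state proportions used as
#' chi-squared weights, and the interval count.
#'
#' @param D dissimilarity matrix from [seq_dissimilarity()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_dissimilarity_csv <- function(D, path) {
  df <- data.frame(patient_id = rownames(D), as.data.frame(unclass(D)[, ]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(metric = attr(D, "metric"),
                  marginal = as.list(attr(D, "marginal")),
                  n_intervals = attr(D, "n_intervals"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dissimilarity_csv
#' @return `read_dissimilarity_csv`: the matrix with attributes restored
#'   from the sidecar when present.
#' @export
read_dissimilarity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(D) <- list(df$patient_id, colnames(D))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(D, "metric") <- sc$metric
    attr(D, "marginal") <- unlist(sc$marginal)
    attr(D, "n_intervals") <- sc$n_intervals
  }
  D
}

#' Write an MDMR result as a Table-2-shaped CSV
#'
#' Columns `term, pseudo_F, pseudo_R2, proportion_explained, p_value` with a
#' final `Total` row.
#'
#' @param fit an [mdmr()] object.
#' @param path CSV path.
#' @export
write_mdmr_csv <- function(fit, path) {
  tab <- fit$aov_table[, c("term", "pseudo_F", "pseudo_R2",
                           "proportion_explained", "p_value")]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
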