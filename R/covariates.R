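#' Principal-component scores for sedation doses
#'
#' Midazolam and fentanyl total doses are typically highly correlated, so
#' the two doses enter regression models as principal-component scores
#' rather than raw doses. Each dose is standardized (mean 0, sd 1), the
#' 2x2 correlation matrix is eigen-decomposed (eigenvalues `1 + r` and
#' `1 - r` for correlation `r`), and scores are the standardized data
#' rotated onto the eigenvectors, ordered by descending eigenvalue. Sign
#' convention: the largest-magnitude element of each loading vector (first
#' on ties) is positive.
#'
#' @param midazolam,fentanyl numeric dose vectors (mg / micrograms) over the
#'   same patients; at least 3 patients, each dose with positive variance.
#' @return Numeric matrix with columns `pca_dose_1`, `pca_dose_2` and
#'   attributes `eigenvalues` and `loadings`.
#' @export
#' @examples
#' set.seed(1)
#' m <- rlnorm(20); f <- m * 25 + rlnorm(20)
#' s <- pca_dose_scores(m, f)
#' attr(s, "eigenvalues")
pca_dose_scores <- function(midazolam, fentanyl) {
  if (length(midazolam) != length(fentanyl)) stop("dose vectors differ in length")
  if (length(midazolam) < 3L) stop("need at least 3 patients")
  if (anyNA(midazolam) || anyNA(fentanyl)) stop("doses contain missing values")
  if (any(midazolam < 0) || any(fentanyl < 0)) stop("doses must be non-negative")
  if (stats::sd(midazolam) == 0 || stats::sd(fentanyl) == 0) {
    stop("a dose has zero variance; PCA scores are undefined")
  }
  Z <- cbind(scale(midazolam)[, 1L], scale(fentanyl)[, 1L])
  e <- eigen(stats::cor(Z), symmetric = TRUE)
  V <- e$vectors
  for (j in 1:2) {
    lead <- which.max(abs(V[, j]))
    if (V[lead, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Z %*% V
  colnames(scores) <- c("pca_dose_1", "pca_dose_2")
  attr(scores, "eigenvalues") <- e$values
  attr(scores, "loadings") <- V
  scores
}

#' Hyperoxia and hypoxemia durations with pulse filtering
#'
#' SpO2 readings taken while no pulse was detectable are unreliable and are
#' filtered out before counting. Among pulse-valid seconds, hyperoxia is the
#' time with SpO2 strictly above `high_thresh` (%), hypoxemia the time with
#' SpO2 strictly below `low_thresh` (%).
#'
#' @param spo2 per-second SpO2 track (%).
#' @param pulse_detected per-second logical pulse flag (same length).
#' @param high_thresh,low_thresh hyperoxia / hypoxemia cut-offs (defaults
#'   97 and 90, strict comparisons).
#' @return Named numeric vector `c(hyperoxia_s, hypoxemia_s, valid_s)`.
#' @export
#' @examples
#' oxygen_durations(c(98, 98, 88, 88), c(TRUE, TRUE, TRUE, FALSE))
oxygen_durations <- function(spo2, pulse_detected, high_thresh = 97, low_thresh = 90) {
  if (length(spo2) != length(pulse_detected)) stop("track lengths differ")
  valid <- as.logical(pulse_detected) & !is.na(spo2)
  c(hyperoxia_s = sum(spo2[valid] > high_thresh),
    hypoxemia_s = sum(spo2[valid] < low_thresh),
    valid_s = sum(valid))
}

#' Baseline and peak transcutaneous CO2
#'
#' Baseline is the mean over a stabilized pre-sedation window (default the
#' first 60 seconds of the track); peak is the maximum over the whole
#' procedure. The peak may be below baseline.
#'
#' @param tcco2 per-second TcCO2 track (mmHg).
#' @param baseline_window pre-sedation window length in seconds.
#' @return Named numeric vector `c(baseline, peak)`.
#' @export
tcco2_summary <- function(tcco2, baseline_window = 60L) {
  tcco2 <- tcco2[!is.na(tcco2)]
  if (!length(tcco2)) stop("empty TcCO2 track")
  w <- min(as.integer(baseline_window), length(tcco2))
  c(baseline = mean(tcco2[seq_len(w)]), peak = max(tcco2))
}

#' Derive model covariates from raw monitoring tracks
#'
#' Joins a per-patient covariate table with the covariates constructed from
#' the per-second monitoring stream: sedation-dose principal-component
#' scores, pulse-filtered hyperoxia/hypoxemia durations, and TcCO2 baseline
#' and peak.
#'
#' @param monitoring long per-second monitoring data.frame with
#'   `patient_id`, `spo2`, `pulse_detected` and `tcco2` columns.
#' @param covariates per-patient data.frame with `patient_id`,
#'   `midazolam_dose` and `fentanyl_dose` columns (other columns are passed
#'   through).
#' @param baseline_window TcCO2 baseline window, seconds.
#' @return `covariates` augmented with `pca_dose_1`, `pca_dose_2`,
#'   `hyperoxia_s`, `hypoxemia_s`, `valid_s`, `tcco2_baseline`,
#'   `tcco2_peak`.
#' @export
derive_covariates <- function(monitoring, covariates, baseline_window = 60L) {
  ids <- as.character(covariates$patient_id)
  scores <- pca_dose_scores(covariates$midazolam_dose, covariates$fentanyl_dose)
  covariates$pca_dose_1 <- scores[, 1L]
  covariates$pca_dose_2 <- scores[, 2L]
  mon_split <- split(monitoring, as.character(monitoring$patient_id))
  per_patient <- t(vapply(ids, function(id) {
    trk <- mon_split[[id]]
    if (is.null(trk)) stop("no monitoring records for patient ", id)
    trk <- trk[order(trk$t), ]
    ox <- oxygen_durations(trk$spo2, trk$pulse_detected)
    tc <- tcco2_summary(trk$tcco2, baseline_window = baseline_window)
    c(ox, tcco2_baseline = unname(tc["baseline"]), tcco2_peak = unname(tc["peak"]))
  }, numeric(5)))
  cbind(covariates, as.data.frame(per_patient))
}
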