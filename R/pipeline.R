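#' Configuration for the end-to-end pipeline
#'
#' Bundles inputs (a synthetic-cohort configuration or paths to the
#' monitoring and covariate CSVs), analysis settings and output locations.
#' Classification and oxygenation thresholds default to the standard
#' cut-offs (respiratory rate < 8/min, amplitude deviation > 10%,
#' SpO2 > 97% / < 90%) and are overridable.
#'
#' @param synth optional [cohort_config()]; when supplied the cohort is
#'   simulated, otherwise `monitoring_csv` and `covariates_csv` are read.
#' @param monitoring_csv,covariates_csv input CSV paths (ignored when
#'   `synth` is given).
#' @param out_dir output directory (created if needed).
#' @param metric dissimilarity metric, `"chi2"` (default) or `"euclid"`.
#' @param n_intervals spans per sequence for the state distributions.
#' @param ks candidate cluster counts for the quality report.
#' @param k final typology size (default 4).
#' @param n_perm permutations for the MDMR (default 1000).
#' @param seed seed for the permutation stream.
#' @param rate_cutoff,amp_tol classifier thresholds.
#' @param high_thresh,low_thresh SpO2 hyperoxia / hypoxemia thresholds.
#' @param tcco2_baseline_window TcCO2 baseline window, seconds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, monitoring_csv = NULL,
                            covariates_csv = NULL, out_dir = "capnoseq-out",
                            metric = c("chi2", "euclid"), n_intervals = 1L,
                            ks = 2:6, k = 4L, n_perm = 1000L, seed = 1L,
                            rate_cutoff = 8, amp_tol = 0.10,
                            high_thresh = 97, low_thresh = 90,
                            tcco2_baseline_window = 60L) {
  metric <- match.arg(metric)
  if (is.null(synth) && (is.null(monitoring_csv) || is.null(covariates_csv))) {
    stop("supply either a synth cohort_config or both input CSV paths")
  }
  if (rate_cutoff <= 0 || amp_tol <= 0 || high_thresh <= 0 || low_thresh <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(synth = synth, monitoring_csv = monitoring_csv,
                 covariates_csv = covariates_csv, out_dir = out_dir,
                 metric = metric, n_intervals = as.integer(n_intervals),
                 ks = as.integer(ks), k = as.integer(k),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 rate_cutoff = rate_cutoff, amp_tol = amp_tol,
                 high_thresh = high_thresh, low_thresh = low_thresh,
                 tcco2_baseline_window = as.integer(tcco2_baseline_window)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # the analytic configuration, not where it lands
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full state-sequence analysis pipeline
#'
#' Executes classification, dissimilarity computation, Ward typology with a
#' cluster-quality report, sequence index plots, the multivariable distance
#' matrix regression and the separate bivariate hypoxemia test, writing a
#' deterministic artifact bundle to `config$out_dir`:
#' `sequences.csv`, `distance.csv` (+ `.json` sidecar), `clusters.csv`,
#' `quality.json`, `seqplot.png`, `mdmra.csv`, `hypoxemia.json` and
#' `run.log` (package version and configuration hash).
#'
#' @param config a [pipeline_config()] object.
#' @return (invisibly) list with the in-memory results: `seqs`, `D`,
#'   `typology`, `quality_report`, `covariates`, `mdmr_fit`,
#'   `hypoxemia_fit`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- run_stage("input", {
    if (!is.null(config$synth)) {
      cohort <- simulate_cohort(config$synth)
      list(monitoring = cohort$samples, covariates = cohort$covariates,
           cohort = cohort)
    } else {
      list(monitoring = read_monitoring_csv(config$monitoring_csv),
           covariates = read_covariates_csv(config$covariates_csv),
           cohort = NULL)
    }
  })

  seqs <- run_stage("classify", {
    s <- build_sequences(inputs$monitoring, rate_cutoff = config$rate_cutoff,
                         amp_tol = config$amp_tol)
    long <- data.frame(
      patient_id = rep(names(s), lengths(s)),
      t = unlist(lapply(s, seq_along), use.names = FALSE) - 1L,
      state = unlist(s, use.names = FALSE))
    utils::write.csv(long, out("sequences.csv"), row.names = FALSE, quote = FALSE)
    s
  })

  D <- run_stage("dist", {
    D <- seq_dissimilarity(seqs, metric = config$metric,
                           n_intervals = config$n_intervals)
    write_dissimilarity_csv(D, out("distance.csv"))
    D
  })

  typology <- run_stage("cluster", {
    ty <- seq_cluster(D, k = config$k, seqs = seqs)
    utils::write.csv(data.frame(patient_id = names(ty$labels),
                                cluster = unname(ty$labels)),
                     out("clusters.csv"), row.names = FALSE, quote = FALSE)
    ty
  })
  quality_report <- run_stage("cluster", {
    qr <- cluster_quality_report(D, ks = config$ks)
    jsonlite::write_json(
      list(report = qr, best_k = attr(qr, "best_k"), final_k = config$k),
      out("quality.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    qr
  })

  run_stage("plot", {
    seq_index_plot(seqs, groups = typology$labels, file = out("seqplot.png"))
  })

  covariates <- run_stage("covariates", {
    derive_covariates(inputs$monitoring, inputs$covariates,
                      baseline_window = config$tcco2_baseline_window)
  })

  mdmr_fit <- run_stage("mdmra", {
    model_terms <- c("age", "sex", "pca_dose_1", "pca_dose_2", "osa",
                     "stopbang", "copd", "admission", "bmi", "charlson",
                     "smoker", "tcco2_baseline", "tcco2_peak",
                     "intervention_received", "hyperoxia_s")
    model_terms <- intersect(model_terms, names(covariates))
    dat <- covariates
    dat$..D <- NULL
    f <- stats::as.formula(paste("..D ~", paste(model_terms, collapse = " + ")))
    environment(f) <- list2env(list(..D = D), parent = baseenv())
    fit <- mdmr(f, data = dat, n_perm = config$n_perm, seed = config$seed)
    write_mdmr_csv(fit, out("mdmra.csv"))
    fit
  })

  hypoxemia_fit <- run_stage("hypoxemia", {
    fit <- bivariate_mdmr(D, covariates$hypoxemia_s, n_perm = config$n_perm,
                          seed = config$seed)
    jsonlite::write_json(fit$aov_table, out("hypoxemia.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    fit
  })

  run_stage("log", {
    writeLines(c(
      paste0("capnoseq version: ", as.character(utils::packageVersion("capnoseq"))),
      paste0("config hash: ", config_hash(config)),
      paste0("patients: ", length(seqs)),
      paste0("metric: ", config$metric),
      paste0("final k: ", config$k),
      paste0("permutations: ", config$n_perm),
      paste0("seed: ", config$seed)), out("run.log"))
  })

  invisible(list(seqs = seqs, D = D, typology = typology,
                 quality_report = quality_report, covariates = covariates,
                 mdmr_fit = mdmr_fit, hypoxemia_fit = hypoxemia_fit,
                 cohort = inputs$cohort, out_dir = config$out_dir))
}
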