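#' Read biokinetic records from CSV
#'
#' Reads a flat CSV (comma separator, dot decimal, UTF-8, mandatory header
#' `patient_id,time_h,retention`; lines starting with `#` are ignored) into
#' a validated record table. Duplicate (patient, time) pairs and negative
#' retentions are rejected with the offending line numbers; times are
#' sorted within patient.
#'
#' @param path CSV file path.
#' @return Data frame with `patient_id` (character), `time_h`, `retention`.
#' @export
read_biokinetics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("patient_id", "time_h", "retention")
  if (!all(req %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_num <- !is.finite(df$time_h) | !is.finite(df$retention)
  if (any(bad_num))
    stop("malformed numeric fields at line(s): ",
         paste(line[bad_num], collapse = ", "), call. = FALSE)
  if (any(df$time_h <= 0))
    stop("non-positive time_h at line(s): ",
         paste(line[df$time_h <= 0], collapse = ", "), call. = FALSE)
  if (any(df$retention < 0))
    stop("negative retention at line(s): ",
         paste(line[df$retention < 0], collapse = ", "), call. = FALSE)
  dup <- duplicated(df[, c("patient_id", "time_h")])
  if (any(dup))
    stop("duplicate (patient_id, time_h) at line(s): ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  df <- df[order(df$patient_id, df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write biokinetic records to CSV
#'
#' Inverse of [read_biokinetics()]; a write-then-read round trip is the
#' identity on the validated columns. An optional header comment embeds a
#' provenance hash.
#'
#' @param records Record table.
#' @param path Output CSV path.
#' @param config_hash Optional hash string embedded as a `#` comment line.
#' @return `path`, invisibly.
#' @export
write_biokinetics <- function(records, path, config_hash = NULL) {
  .validate_records(records, min_patients = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# stpdosim config ", config_hash), con)
  utils::write.csv(records[, c("patient_id", "time_h", "retention")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TIA estimate table to CSV
#'
#' @param estimates A [tia_estimates()] table.
#' @param path Output CSV path.
#' @param config_hash Optional hash embedded as a `#` comment line.
#' @return `path`, invisibly.
#' @export
write_tia_estimates <- function(estimates, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# stpdosim config ", config_hash), con)
  utils::write.csv(as.data.frame(estimates), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort source (an input
#' CSV or a simulated population), the fitting configuration, the STP time
#' grid, and the output directory. The seed is mandatory: every stochastic
#' step (cohort generation, start screening) derives from it, and rerunning
#' with the same configuration reproduces the outputs byte for byte.
#'
#' @param seed Integer seed (mandatory).
#' @param output_dir Directory for all outputs (created if absent).
#' @param input_csv Optional path to a records CSV; when `NULL` a cohort is
#'   simulated from `population`.
#' @param population A [population_truth()] used when simulating (default
#'   [default_population()] with the run seed).
#' @param fit A [fit_config()]; its seed is overridden by `seed`.
#' @param stp_time_points Time grid (h) for the STP estimators.
#' @param sop_time_points Time points (h) for the closed-form SOP
#'   estimator.
#' @param models Structural models to run in the STP grid.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed,
                       output_dir = "stpdosim-run",
                       input_csv = NULL,
                       population = NULL,
                       fit = fit_config(),
                       stp_time_points = c(24, 120),
                       sop_time_points = c(24, 48, 96, 120),
                       models = c("a4c", "a3b")) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("run_config requires an explicit integer seed", call. = FALSE)
  if (is.null(population)) population <- default_population(seed = seed)
  fit$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 input_csv = input_csv, population = population, fit = fit,
                 stp_time_points = stp_time_points,
                 sop_time_points = sop_time_points,
                 models = match.arg(models, c("a4c", "a3b"),
                                    several.ok = TRUE)),
            class = "run_config")
}

# Stable short hash of the serialized configuration, embedded in every
# output for provenance.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(.serialize_config(config)), tmp)
  unname(tools::md5sum(tmp))
}

.serialize_config <- function(config) {
  pop <- config$population
  list(seed = config$seed,
       stp_time_points = config$stp_time_points,
       sop_time_points = config$sop_time_points,
       models = config$models,
       input_csv = if (is.null(config$input_csv)) "" else config$input_csv,
       fit = config$fit[c("error_model", "n_starts", "n_refine",
                          "tolerance", "max_iter", "stp_mode")],
       population = list(
         typical = with(pop$typical_params,
                        list(lambda1 = lambda1, lambda2 = lambda2,
                             lambda3 = lambda3, a1 = a1)),
         iiv_cv = as.list(pop$iiv_cv),
         residual = pop$residual_model,
         common_times = pop$common_times,
         late_times = pop$late_times, late_n = pop$late_n,
         n = pop$n, miss_6h_patient = pop$miss_6h_patient))
}

#' Run the full single-time-point dosimetry pipeline
#'
#' Chains the study workflow end to end: obtain a cohort (read or
#' simulate), fit the all-time-point reference model and derive the rTIAs
#' and the nTIA, run the STP grids for the requested structural models,
#' compute the closed-form SOP hTIAs, assemble the accuracy table, and
#' write everything to `output_dir` as CSV files plus a manifest with MD5
#' checksums. Each output embeds the configuration hash; rerunning with
#' the same configuration and seed reproduces the files byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` (data frame of files and
#'   checksums), `accuracy` (the accuracy table), `estimates`, and
#'   `reference` tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  out <- function(f) file.path(config$output_dir, f)
  files <- character(0)

  writeLines(yaml::as.yaml(.serialize_config(config)), out("config.yml"))
  files <- c(files, out("config.yml"))

  if (is.null(config$input_csv)) {
    cohort <- generate_cohort(config$population, seed = config$seed)
    records <- cohort$records
    utils::write.csv(cohort$truth, out("truth.csv"), row.names = FALSE)
    files <- c(files, out("truth.csv"))
  } else {
    records <- read_biokinetics(config$input_csv)
  }
  write_biokinetics(records, out("records.csv"), config_hash = hash)
  files <- c(files, out("records.csv"))

  refs <- compute_reference_tias(records, config = config$fit)
  ref_fit <- attr(refs, "fit")
  write_tia_estimates(refs, out("rtia.csv"), config_hash = hash)
  files <- c(files, out("rtia.csv"))

  ests <- list()
  for (model in config$models) {
    grid <- run_stp_grid(records, model = model,
                         time_points = config$stp_time_points,
                         config = config$fit,
                         ref_fit = if (model == "a4c") ref_fit else NULL)
    fn <- out(sprintf("%s.csv", if (model == "a4c") "s1tia" else "s2tia"))
    write_tia_estimates(grid, fn, config_hash = hash)
    utils::write.csv(attr(grid, "log"), out(sprintf(
      "%s_fitlog.csv", if (model == "a4c") "s1tia" else "s2tia")),
      row.names = FALSE)
    files <- c(files, fn, out(sprintf(
      "%s_fitlog.csv", if (model == "a4c") "s1tia" else "s2tia")))
    ests[[model]] <- grid
  }

  htias <- eanm_tias(records, time_points = config$sop_time_points)
  write_tia_estimates(htias, out("htia.csv"), config_hash = hash)
  files <- c(files, out("htia.csv"))
  ests$htia <- htias

  ntias <- ntp_tia(ref_fit)
  write_tia_estimates(ntias, out("ntia.csv"), config_hash = hash)
  files <- c(files, out("ntia.csv"))
  ests$ntia <- ntias

  all_est <- do.call(rbind, lapply(ests, as.data.frame))
  class(all_est) <- c("tia_estimates", "data.frame")
  tab <- build_accuracy_table(all_est, refs)
  rep_tab <- format_accuracy_table(tab)
  con <- file(out("metrics.csv"), "w")
  writeLines(paste0("# stpdosim config ", hash), con)
  utils::write.csv(rep_tab, con, row.names = FALSE, quote = FALSE)
  close(con)
  files <- c(files, out("metrics.csv"))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         config_hash = hash, stringsAsFactors = FALSE)
  utils::write.csv(manifest, out("manifest.csv"), row.names = FALSE)

  invisible(list(manifest = manifest, accuracy = tab,
                 estimates = all_est, reference = refs))
}
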