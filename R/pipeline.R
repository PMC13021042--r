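#' Assemble a reproducible run configuration
#'
#' A run is fully determined by its configuration and master seed: the
#' design, the simulated population, the analysis options, and the fit
#' options. Defaults are filled in so that a bare configuration expands
#' to a complete, serializable one.
#'
#' @param seed master integer seed.
#' @param design_id `"exp1"`, `"exp2"` or `"exp3"`.
#' @param stimulus_domain `"shape"` or `"color"` (label only).
#' @param n_participants cohort size.
#' @param observer an [observer_spec()] shared by the cohort, or a list
#'   of specs (one per participant). For exp3 a population is drawn with
#'   [generate_population_exp3()] when a single spec is given.
#' @param analysis list of analysis options: `bin_width`, `outlier_sd`,
#'   `high_confidence_only`, `smooth_window`.
#' @param fit list of fit options: `objective`, `error_type`,
#'   `kappa_M_source` (`"baseline-fit"` or `"true"`).
#' @param out_dir output directory for file-writing stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, design_id = "exp1",
                       stimulus_domain = "shape",
                       n_participants = 16,
                       observer = observer_spec(),
                       analysis = list(), fit = list(),
                       out_dir = tempdir()) {
  analysis <- utils::modifyList(
    list(bin_width = 5, outlier_sd = 3, high_confidence_only = TRUE,
         smooth_window = 30), analysis)
  fit <- utils::modifyList(
    list(objective = "analytic", error_type = "signed",
         kappa_M_source = "baseline-fit"), fit)
  structure(list(seed = as.integer(seed), design_id = design_id,
                 stimulus_domain = stimulus_domain,
                 n_participants = as.integer(n_participants),
                 observer = observer, analysis = analysis, fit = fit,
                 out_dir = out_dir),
            class = "run_config")
}

## population implied by a config
config_population <- function(config) {
  if (is.list(config$observer) && !inherits(config$observer, "observer_spec")) {
    stopifnot(length(config$observer) == config$n_participants)
    return(config$observer)
  }
  if (config$design_id == "exp3") {
    generate_population_exp3(config$n_participants, seed = config$seed,
                             base = config$observer)
  } else {
    rep(list(config$observer), config$n_participants)
  }
}

## serialize a config (observer specs flattened) and return its md5
config_digest <- function(config) {
  ser <- jsonlite::toJSON(rapply(unclass(config), identity, how = "list"),
                          auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(ser, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, files, path) {
  manifest <- list(
    config_hash = config_digest(config),
    seed = config$seed,
    design_id = config$design_id,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulation stage: generate and write a trial table
#'
#' @param config a [run_config()].
#' @return path of the written trial CSV, invisibly; a manifest JSON is
#'   written alongside.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- experiment_design(config$design_id, config$stimulus_domain)
  pop <- config_population(config)
  trials <- generate_dataset(design, pop, config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(config$out_dir, "trials.csv")
  write_trials_csv(trials, csv)
  write_manifest(config, list(csv),
                 file.path(config$out_dir, "simulate_manifest.json"))
  message("simulate: ", nrow(trials), " trials, ",
          length(pop), " participants -> ", csv)
  invisible(csv)
}

#' Analysis stage: signed-offset pipeline for one design
#'
#' Runs the stages appropriate to the table's design: bias summaries by
#' judgment (exp1), same-/opposite-side contrast (exp2), or the
#' precision-bias correlation (exp3), plus smoothed offset
#' distributions. With an `out_dir` in the config, writes the
#' participant summary CSV, group statistics JSON, and distribution CSV.
#'
#' @param trials trial table (data.frame or CSV path).
#' @param config a [run_config()].
#' @param write write output files (default TRUE).
#' @return list of analysis results (invisible when writing).
#' @export
run_analyze <- function(trials, config = run_config(), write = TRUE) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  design_id <- unique(trials$design_id)
  stopifnot(length(design_id) == 1)
  hc <- if (config$analysis$high_confidence_only)
    filter_high_confidence(trials) else trials
  res <- switch(design_id,
                exp1 = analyze_exp1(hc, config$analysis$bin_width),
                exp2 = analyze_exp2(hc),
                exp3 = analyze_exp3(hc, config$analysis$outlier_sd),
                stop("invalid-design: unknown design_id '", design_id, "'",
                     call. = FALSE))
  res$retention <- attr(hc, "retention")
  res$distribution <- offset_distribution(res$offsets,
                                          config$analysis$smooth_window)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$bias$participant_means,
                     file.path(config$out_dir, "participant_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$distribution,
                     file.path(config$out_dir, "offset_distribution.csv"),
                     row.names = FALSE, quote = FALSE)
    stats <- list(group = res$bias$group, contrast = res$bias$contrast)
    if (!is.null(res$ambivalent_test)) stats$ambivalent <- res$ambivalent_test
    if (!is.null(res$correlation)) {
      stats$correlation <- res$correlation[c("included", "all")]
    }
    jsonlite::write_json(stats, file.path(config$out_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(res))
  }
  res
}

#' Single-probe design analysis
#'
#' Signed offsets toward the probe, bias by judgment (with the
#' similar-minus-dissimilar paired contrast), and the ambivalent-probe
#' analysis with its group-level t test.
#'
#' @param trials (high-confidence) exp1-style trial table.
#' @param bin_width ambivalent-bin width in degrees.
#' @return list with `offsets`, `bias` (a [bias_magnitude()] summary over
#'   baseline/similar/dissimilar pseudo-conditions), `ambivalent` and
#'   `ambivalent_test`.
#' @export
analyze_exp1 <- function(trials, bin_width = 5) {
  off <- compute_offsets(trials)
  comp <- off$condition == "comparison"
  off$condition[comp] <- off$judgment[comp]
  bias <- bias_magnitude(off, conditions = c("similar", "dissimilar"),
                         contrast = c("similar", "dissimilar"))
  amb <- ambivalent_probe_analysis(off[off$condition %in%
                                         c("similar", "dissimilar"), ],
                                   bin_width = bin_width)
  tt <- stats::t.test(amb$difference)
  list(offsets = off, bias = bias, ambivalent = amb,
       ambivalent_test = data.frame(
         mean_difference = mean(amb$difference),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         d = cohens_d(amb$difference)))
}

#' 2AFC probe-pair design analysis
#'
#' Signed offsets toward the first pair's similar probe, per-condition
#' bias, and the same-side vs. opposite-side absolute-bias contrast.
#'
#' @param trials (high-confidence) exp2-style trial table.
#' @return list with `offsets` and `bias`.
#' @export
analyze_exp2 <- function(trials) {
  off <- compute_offsets(trials)
  bias <- bias_magnitude(off, conditions = c("same_side", "opposite_side"),
                         contrast = c("same_side", "opposite_side"),
                         absolute = TRUE)
  list(offsets = off, bias = bias)
}

#' Individual-differences design analysis
#'
#' Per participant: memory precision (von Mises kappa) from
#' high-confidence baseline offsets, and mean signed bias on
#' high-confidence experimental trials on which the similar probe was
#' correctly identified; then the precision-bias Pearson correlation
#' with and without outliers.
#'
#' @param trials (high-confidence) exp3-style trial table.
#' @param outlier_sd bivariate exclusion threshold in SD units.
#' @return list with `offsets`, `bias`, `participants` (precision and
#'   bias per participant) and `correlation`.
#' @export
analyze_exp3 <- function(trials, outlier_sd = 3) {
  off <- compute_offsets(trials)
  bias <- bias_magnitude(off, conditions = "experimental")
  ids <- sort(unique(trials$participant_id))
  per <- do.call(rbind, lapply(ids, function(p) {
    base <- off$offset[off$participant_id == p & off$condition == "baseline"]
    expi <- off$participant_id == p & off$condition == "experimental" &
      off$judgment %in% "similar"
    data.frame(participant_id = p,
               kappa = estimate_precision(base),
               bias = mean(off$offset[expi]),
               n_baseline = length(base), n_experimental = sum(expi))
  }))
  corr <- precision_bias_correlation(per$kappa, per$bias, per$participant_id,
                                     outlier_sd)
  list(offsets = off, bias = bias, participants = per, correlation = corr)
}

#' Fitting stage: response-model fits and comparison for a cohort
#'
#' For each participant, estimates `kappa_M` from high-confidence
#' baseline offsets with [fit_standard_wm()] (kappa component only),
#' fits the joint and mixture models to the participant's
#' [fitting_trials()], and compares the models at the cohort level.
#'
#' @param trials trial table (data.frame or CSV path).
#' @param config a [run_config()].
#' @param true_kappa_M optional named vector of generating
#'   concentrations, used when `config$fit$kappa_M_source == "true"`.
#' @param write write fits JSON and comparison CSV to `config$out_dir`.
#' @return list with `joint`, `mixture` (per-participant fit lists),
#'   `kappa_M` and `comparison`.
#' @export
run_fit <- function(trials, config = run_config(), true_kappa_M = NULL,
                    write = TRUE) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  hc <- filter_high_confidence(trials)
  ft <- fitting_trials(trials)
  ids <- sort(unique(trials$participant_id))
  counts <- table(factor(ft$participant_id, levels = ids))
  if (any(counts == 0)) {
    stop("insufficient-data: no fittable trials for participant(s) ",
         paste(ids[counts == 0], collapse = ", "), call. = FALSE)
  }
  off <- compute_offsets(hc)
  joint <- list(); mixture <- list(); kms <- numeric(0)
  for (p in ids) {
    if (identical(config$fit$kappa_M_source, "true")) {
      km <- true_kappa_M[[as.character(p)]]
      src <- "true"
    } else {
      base <- off$offset[off$participant_id == p &
                           off$condition %in% c("baseline", "baseline_short",
                                                "baseline_long")]
      km <- fit_standard_wm(base)$kappa
      src <- "baseline-fit"
    }
    tp <- ft[ft$participant_id == p, ]
    joint[[as.character(p)]] <- fit_bias_model(
      tp, km, "joint", kappa_M_source = src,
      objective = config$fit$objective, error_type = config$fit$error_type)
    mixture[[as.character(p)]] <- fit_bias_model(
      tp, km, "mixture", kappa_M_source = src,
      objective = config$fit$objective, error_type = config$fit$error_type)
    kms[as.character(p)] <- km
  }
  comparison <- compare_models(joint, mixture)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fits <- lapply(ids, function(p) {
      f <- joint[[as.character(p)]]; m <- mixture[[as.character(p)]]
      list(participant_id = p, kappa_M = unname(kms[as.character(p)]),
           joint = f[c("params", "objective_value", "sum_log_likelihood",
                       "n_trials", "AIC", "BIC")],
           mixture = m[c("params", "objective_value", "sum_log_likelihood",
                         "n_trials", "AIC", "BIC")])
    })
    jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    write_comparison_csv(comparison,
                         file.path(config$out_dir, "model_comparison.csv"))
  }
  invisible(list(joint = joint, mixture = mixture, kappa_M = kms,
                 comparison = comparison))
}

#' Power stage: required sample sizes
#'
#' @param spec data.frame with columns `test` (`"t"` or `"r"`), `effect`
#'   (Cohen's d or rho), `power`, and optionally `alpha`.
#' @return the spec with an added `required_n` column.
#' @export
run_power <- function(spec) {
  if (is.null(spec$alpha)) spec$alpha <- 0.05
  spec$required_n <- vapply(seq_len(nrow(spec)), function(i) {
    if (spec$test[i] == "t") {
      required_n_one_sample_t(spec$effect[i], spec$power[i], spec$alpha[i])
    } else if (spec$test[i] == "r") {
      required_n_correlation(spec$effect[i], spec$power[i], spec$alpha[i])
    } else {
      stop("invalid-request: unknown test '", spec$test[i], "'", call. = FALSE)
    }
  }, numeric(1))
  spec
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; top-level keys mirror the
#'   [run_config()] arguments, with `observer` given as
#'   [observer_spec()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$design_id)) {
    stop("invalid-config: missing field 'design_id'", call. = FALSE)
  }
  if (!is.null(raw$observer)) raw$observer <- do.call(observer_spec, raw$observer)
  do.call(run_config, raw)
}
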