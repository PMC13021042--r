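#' Experiment design descriptors
#'
#' Encodes the three continuous-report designs whose statistical
#' structure the simulator reproduces:
#' \describe{
#'   \item{exp1}{single-probe similarity judgments: 12 blocks of 12
#'     baseline and 36 perceptual-comparison trials; the probe is sampled
#'     16--105 degrees from the target, equiprobably clockwise or
#'     counterclockwise, and judged similar/dissimilar.}
#'   \item{exp2}{two consecutive 2AFC probe-pair judgments: 4 blocks of
#'     10 trials in each of four conditions (short-delay baseline,
#'     long-delay baseline, same-side, opposite-side). Each pair holds a
#'     similar probe 16--45 degrees from the target and a dissimilar
#'     probe 180 degrees from the similar one; in the same-side condition
#'     both similar probes fall on the same side of the target, in the
#'     opposite-side condition on opposite sides.}
#'   \item{exp3}{individual-differences design: 4 blocks of 15 baseline
#'     and 15 experimental trials, a single 2AFC probe-pair judgment on
#'     experimental trials, probes sampled as in exp2.}
#' }
#'
#' @param design_id one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param stimulus_domain label only (`"shape"` or `"color"`); the
#'   stimulus space is treated as an abstract 360-degree circle.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(design_id = c("exp1", "exp2", "exp3"),
                              stimulus_domain = c("shape", "color")) {
  design_id <- match.arg(design_id)
  stimulus_domain <- match.arg(stimulus_domain)
  d <- switch(design_id,
    exp1 = list(
      blocks = 12L,
      trials_per_block = c(baseline = 12L, comparison = 36L),
      probe_range = c(16, 105),
      conditions = c("baseline", "comparison")
    ),
    exp2 = list(
      blocks = 4L,
      trials_per_block = c(baseline_short = 10L, baseline_long = 10L,
                           same_side = 10L, opposite_side = 10L),
      probe_range = c(16, 45),
      conditions = c("baseline_short", "baseline_long",
                     "same_side", "opposite_side")
    ),
    exp3 = list(
      blocks = 4L,
      trials_per_block = c(baseline = 15L, experimental = 15L),
      probe_range = c(16, 45),
      conditions = c("baseline", "experimental")
    )
  )
  stopifnot(all(d$probe_range > 0), all(d$probe_range < 180))
  structure(c(list(design_id = design_id, stimulus_domain = stimulus_domain), d),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Design", x$design_id, "(", x$stimulus_domain, "):",
      x$blocks, "blocks x (", paste(x$trials_per_block, collapse = " + "),
      ") trials; probe range", paste(x$probe_range, collapse = "-"), "deg\n")
  invisible(x)
}

#' Generative observer specification
#'
#' Parameters of a simulated participant. Memory and probe
#' representations are von Mises with concentrations `kappa_M` and
#' `kappa_P`. `generative_model` selects how judged-similar probes enter
#' the report: `"joint"` integrates them into the memory density by
#' normalized product, `"mixture"` reports the probe instead of the
#' memory with probability `1 - alpha`, `"baseline-only"` ignores probes.
#' Similarity judgments are made on the trial's noisy memory sample with
#' a logistic rule: P(similar) = logistic((criterion - perceived
#' distance) / slope). On a lapse (probability `lapse_rate`) the report
#' is uniform and confidence is 3 (none); otherwise confidence is 1
#' (high) with probability `p_high_conf`, else 2 (low).
#'
#' @param kappa_M memory concentration.
#' @param generative_model `"joint"`, `"mixture"` or `"baseline-only"`.
#' @param kappa_P probe concentration.
#' @param alpha memory-based report proportion for the mixture observer.
#' @param criterion similarity criterion in degrees.
#' @param slope logistic slope of the judgment rule, degrees.
#' @param lapse_rate probability of a uniform-guess lapse.
#' @param p_high_conf probability of a high-confidence rating on
#'   non-lapse trials.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(kappa_M = 12, generative_model = c("joint", "mixture",
                                                             "baseline-only"),
                          kappa_P = 3, alpha = 0.85, criterion = 60, slope = 15,
                          lapse_rate = 0.05, p_high_conf = 0.8) {
  generative_model <- match.arg(generative_model)
  stopifnot(kappa_M >= 0, kappa_P >= 0, alpha >= 0, alpha <= 1,
            criterion > 0, slope > 0,
            lapse_rate >= 0, lapse_rate <= 1,
            p_high_conf >= 0, p_high_conf <= 1)
  structure(list(kappa_M = kappa_M, generative_model = generative_model,
                 kappa_P = kappa_P, alpha = alpha, criterion = criterion,
                 slope = slope, lapse_rate = lapse_rate,
                 p_high_conf = p_high_conf),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("Observer (", x$generative_model, "): kappa_M =", x$kappa_M,
      ", kappa_P =", x$kappa_P,
      if (x$generative_model == "mixture") paste0(", alpha = ", x$alpha) else "",
      "\n", sep = "")
  invisible(x)
}

#' Sample a single-probe offset (exp1 style)
#'
#' Probe distance uniform on the design's range, side equiprobable.
#'
#' @param S_M target angle in degrees.
#' @param range numeric length-2, probe distance range in degrees.
#' @return probe angle in [0, 360).
#' @export
sample_probe_exp1 <- function(S_M, range = c(16, 105)) {
  d <- stats::runif(1, range[1], range[2]) * sample(c(-1, 1), 1)
  wrap_position(S_M + d)
}

#' Sample two 2AFC probe pairs (exp2 style)
#'
#' Each pair has a similar probe 16--45 degrees from the target and a
#' dissimilar probe exactly 180 degrees from the similar probe. The first
#' similar probe's side is equiprobable; the second's side matches it
#' (`"same"`) or opposes it (`"opposite"`).
#'
#' @param S_M target angle in degrees.
#' @param side_condition `"same"` or `"opposite"`.
#' @param range similar-probe distance range.
#' @param n_pairs number of pairs (2 for exp2, 1 for exp3).
#' @return data.frame with one row per pair: `sim`, `dis`, `side`
#'   (+1/-1), `distance` (unsigned similar-probe distance).
#' @export
sample_probe_pairs_exp2 <- function(S_M, side_condition = c("same", "opposite"),
                                    range = c(16, 45), n_pairs = 2L) {
  side_condition <- match.arg(side_condition)
  s1 <- sample(c(-1, 1), 1)
  sides <- if (n_pairs == 1L) s1 else
    c(s1, if (side_condition == "same") s1 else -s1)
  d <- stats::runif(n_pairs, range[1], range[2])
  sim <- wrap_position(S_M + sides * d)
  data.frame(sim = sim, dis = wrap_position(sim + 180),
             side = sides, distance = d)
}

#' Simulate a similarity judgment
#'
#' Logistic rule on the perceived distance between the trial's noisy
#' memory sample and the probe: P(similar) =
#' logistic((criterion - |X_M - S_P|) / slope).
#'
#' @param X_M noisy memory sample (degrees).
#' @param S_P probe angle (degrees).
#' @param criterion,slope judgment parameters in degrees, both > 0.
#' @return `"similar"` or `"dissimilar"`.
#' @export
simulate_similarity_judgment <- function(X_M, S_P, criterion = 60, slope = 15) {
  stopifnot(criterion > 0, slope > 0)
  d <- abs(signed_circ_dist(X_M, S_P))
  p_sim <- stats::plogis((criterion - d) / slope)
  if (stats::runif(1) < p_sim) "similar" else "dissimilar"
}

#' Simulate a 2AFC similarity choice
#'
#' Chooses the probe perceptually closer to the noisy memory sample;
#' exact ties are broken at random.
#'
#' @param X_M noisy memory sample (degrees).
#' @param probes numeric vector of two probe angles.
#' @return index (1 or 2) of the chosen probe.
#' @export
simulate_2afc_choice <- function(X_M, probes) {
  stopifnot(length(probes) == 2)
  d <- abs(signed_circ_dist(X_M, probes))
  if (d[1] == d[2]) sample(1:2, 1) else which.min(d)
}

## Draw one angle from a von Mises on the default grid, rotating a
## precomputed concentration kernel to the requested mean.
draw_vm <- function(mu, kernel, grid) {
  shift <- as.integer(round(mu / grid$resolution)) %% grid$n_points
  idx <- ((seq_len(grid$n_points) - 1 - shift) %% grid$n_points) + 1
  sample(grid$points, 1, prob = kernel[idx])
}

vm_kernel <- function(kappa, grid) {
  exp(kappa * (cos(grid$points * pi / 180) - 1))
}

#' Simulate one trial
#'
#' Draws a target uniformly on the wheel, samples probes per the design,
#' generates similarity judgments from the trial's noisy memory sample,
#' and draws the continuous report from the observer's response density:
#' the memory density on baseline trials and, on comparison trials,
#' the joint (product) density over the judged-similar probe(s) applied
#' sequentially for a `"joint"` observer, or a memory/probe mixture for a
#' `"mixture"` observer. Lapses give a uniform report with confidence 3.
#'
#' @param design an [experiment_design()].
#' @param observer an [observer_spec()].
#' @param condition condition label belonging to the design.
#' @param grid a [circular_grid()].
#' @return one-row data.frame in the trial-table schema (see
#'   [generate_dataset()]).
#' @export
simulate_trial <- function(design, observer, condition, grid = circular_grid()) {
  if (!condition %in% design$conditions) {
    stop("invalid-design: unknown condition '", condition, "' for ",
         design$design_id, call. = FALSE)
  }
  S_M <- sample(grid$points, 1)
  kM <- vm_kernel(observer$kappa_M, grid)
  X_M <- draw_vm(S_M, kM, grid)

  out <- list(condition = condition, S_M = S_M,
              probe1_sim = NA_real_, probe1_dis = NA_real_,
              probe2_sim = NA_real_, probe2_dis = NA_real_,
              judgment1 = NA_character_, judgment2 = NA_character_)

  is_baseline <- condition %in% c("baseline", "baseline_short", "baseline_long")
  integrate_probes <- numeric(0)  # probes judged/chosen similar, in order
  chosen_probes <- numeric(0)     # probes selected by any judgment

  if (!is_baseline) {
    if (design$design_id == "exp1") {
      probe <- sample_probe_exp1(S_M, design$probe_range)
      out$probe1_sim <- probe
      out$judgment1 <- simulate_similarity_judgment(
        X_M, probe, observer$criterion, observer$slope)
      chosen_probes <- probe
      if (out$judgment1 == "similar") integrate_probes <- probe
    } else {
      side_cond <- if (design$design_id == "exp3") "same" else
        if (condition == "same_side") "same" else "opposite"
      n_pairs <- if (design$design_id == "exp3") 1L else 2L
      pairs <- sample_probe_pairs_exp2(S_M, side_cond, design$probe_range,
                                       n_pairs)
      out$probe1_sim <- pairs$sim[1]
      out$probe1_dis <- pairs$dis[1]
      for (j in seq_len(n_pairs)) {
        choice <- simulate_2afc_choice(X_M, c(pairs$sim[j], pairs$dis[j]))
        chosen <- if (choice == 1) pairs$sim[j] else pairs$dis[j]
        lab <- if (choice == 1) "similar" else "dissimilar"
        if (j == 1) out$judgment1 <- lab else {
          out$judgment2 <- lab
          out$probe2_sim <- pairs$sim[2]
          out$probe2_dis <- pairs$dis[2]
        }
        chosen_probes <- c(chosen_probes, chosen)
        integrate_probes <- c(integrate_probes, chosen)
      }
    }
  }

  lapse <- stats::runif(1) < observer$lapse_rate
  if (lapse) {
    response <- sample(grid$points, 1)
    confidence <- 3L
  } else {
    model <- if (is_baseline) "baseline-only" else observer$generative_model
    response <- switch(model,
      "baseline-only" = draw_vm(S_M, kM, grid),
      "joint" = {
        if (length(integrate_probes) == 0) draw_vm(S_M, kM, grid) else {
          dens <- vm_density(S_M, observer$kappa_M, grid)
          for (p in integrate_probes) {
            dens <- new_grid_density(
              dens$mass * vm_density(p, observer$kappa_P, grid)$mass, grid)
          }
          sample_response(dens, 1)
        }
      },
      "mixture" = {
        if (length(integrate_probes) == 0 ||
            stats::runif(1) < observer$alpha) {
          draw_vm(S_M, kM, grid)
        } else {
          p <- integrate_probes[sample.int(length(integrate_probes), 1)]
          draw_vm(p, vm_kernel(observer$kappa_P, grid), grid)
        }
      })
    confidence <- if (stats::runif(1) < observer$p_high_conf) 1L else 2L
  }
  out$response <- response
  out$confidence <- confidence
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a full trial table for a simulated cohort
#'
#' Simulates every participant in `population` through all blocks and
#' conditions of `design`. Each participant uses an RNG substream derived
#' deterministically from the master seed, so tables are reproducible
#' and participant data are invariant to cohort composition order.
#'
#' @param design an [experiment_design()].
#' @param population list of [observer_spec()] objects, one per
#'   participant.
#' @param seed master integer seed.
#' @return data.frame, one row per trial, with columns
#'   `participant_id`, `design_id`, `condition`, `block`, `trial`,
#'   `S_M`, `probe1_sim`, `probe1_dis`, `probe2_sim`, `probe2_dis`,
#'   `judgment1`, `judgment2`, `response`, `confidence`. Angles are in
#'   degrees in [0, 360); inapplicable fields are NA.
#' @export
generate_dataset <- function(design, population, seed) {
  stopifnot(inherits(design, "experiment_design"), length(population) >= 1)
  grid <- circular_grid()
  rows <- vector("list", length(population))
  for (i in seq_along(population)) {
    obs <- population[[i]]
    stopifnot(inherits(obs, "observer_spec"))
    set.seed((as.integer(seed) + 104729L * i) %% 2147483629L)
    trials <- vector("list", design$blocks * sum(design$trials_per_block))
    k <- 0L
    for (b in seq_len(design$blocks)) {
      for (cond in design$conditions) {
        for (t in seq_len(design$trials_per_block[[cond]])) {
          k <- k + 1L
          tr <- simulate_trial(design, obs, cond, grid)
          tr$block <- b
          trials[[k]] <- tr
        }
      }
    }
    df <- do.call(rbind, trials)
    df$participant_id <- i
    df$design_id <- design$design_id
    df$trial <- seq_len(nrow(df))
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  out[, c("participant_id", "design_id", "condition", "block", "trial",
          "S_M", "probe1_sim", "probe1_dis", "probe2_sim", "probe2_dis",
          "judgment1", "judgment2", "response", "confidence")]
}

#' Draw an individual-differences population
#'
#' Observer specs for the individual-differences design: memory
#' concentrations are i.i.d. log-normal across participants (precision
#' varies widely between people and is strictly positive); all other
#' parameters are shared.
#'
#' @param n number of observers (>= 2).
#' @param meanlog,sdlog log-normal parameters of `kappa_M`. Defaults give
#'   a median concentration of 12 with a realistic interquartile spread
#'   (roughly 9--16).
#' @param seed integer seed.
#' @param base an [observer_spec()] providing the shared parameters.
#' @return list of `n` observer specs.
#' @export
generate_population_exp3 <- function(n, meanlog = log(12), sdlog = 0.4, seed = 1,
                                     base = observer_spec()) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed) %% 2147483629L)
  kappas <- stats::rlnorm(n, meanlog, sdlog)
  lapply(kappas, function(k) {
    s <- base
    s$kappa_M <- k
    s
  })
}

#' Write a trial table to CSV
#'
#' @param trials trial-table data.frame from [generate_dataset()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table CSV
#'
#' Accepts the schema written by [write_trials_csv()] (the same schema
#' used for real data). Angles must lie in [0, 360) and confidence in
#' {1, 2, 3}; violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return validated trial-table data.frame.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  required <- c("participant_id", "design_id", "condition", "S_M",
                "response", "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema violation: missing columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("S_M", "probe1_sim", "probe1_dis", "probe2_sim", "probe2_dis",
                "response")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v >= 360))
    if (length(bad)) {
      stop("schema violation: column ", col, " out of [0, 360) at row ",
           bad[1], call. = FALSE)
    }
  }
  bad <- which(!df$confidence %in% c(1L, 2L, 3L))
  if (length(bad)) {
    stop("schema violation: confidence not in {1,2,3} at row ", bad[1],
         call. = FALSE)
  }
  df
}

#' Read an observer or population configuration
#'
#' YAML or JSON file mirroring the [observer_spec()] field names; either
#' a single spec or a list of specs under a `population` key.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return a single `observer_spec` or a list of them.
#' @export
read_observer_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  build <- function(x) do.call(observer_spec, x)
  if (!is.null(raw$population)) lapply(raw$population, build) else build(raw)
}
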