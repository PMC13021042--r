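## log Z(kappa) for the per-bin von Mises mass exp(kappa*(cos(theta)-1)),
## summed over the default grid
log_z_grid <- function(kappa, grid = circular_grid()) {
  th <- grid$points * pi / 180
  vapply(kappa, function(k) log(sum(exp(k * (cos(th) - 1)))), numeric(1))
}

#' Fit the standard working-memory mixture model
#'
#' Maximum-likelihood fit of the classic delayed-estimation response
#' model to signed response offsets: a mean-zero von Mises (precision
#' `kappa`) plus a uniform guessing component (`guess_rate`). Continuous
#' von Mises likelihood in radians; optimization on unconstrained
#' transformed parameters (log kappa, logit guess rate) from several
#' starts.
#'
#' @param offsets signed response offsets in degrees.
#' @return object of class `standard_wm_fit`: list with `kappa`,
#'   `guess_rate`, `logLik`, `n`, and a `boundary` flag for estimates at
#'   the parameter bounds.
#' @export
fit_standard_wm <- function(offsets) {
  if (length(offsets) < 10) {
    stop("insufficient-data: need >= 10 offsets", call. = FALSE)
  }
  x <- offsets * pi / 180
  nll <- function(par) {
    k <- exp(par[1])
    g <- stats::plogis(par[2])
    if (!is.finite(k) || k > 1e6) return(1e10)
    logf_vm <- k * (cos(x) - 1) - log(2 * pi) -
      log(besselI(k, 0, expon.scaled = TRUE))
    -sum(log((1 - g) * exp(logf_vm) + g / (2 * pi)))
  }
  starts <- list(c(log(5), stats::qlogis(0.05)),
                 c(log(20), stats::qlogis(0.2)),
                 c(log(1), stats::qlogis(0.5)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  g <- stats::plogis(best$par[2])
  kappa <- exp(best$par[1])
  res <- list(kappa = kappa, guess_rate = g, logLik = -best$value,
              n = length(offsets),
              boundary = g < 1e-4 || g > 1 - 1e-4 || kappa > 1e4)
  class(res) <- "standard_wm_fit"
  res
}

#' @export
print.standard_wm_fit <- function(x, ...) {
  cat(sprintf("Standard WM model: kappa = %.3f, guess rate = %.4f (logLik %.2f, n = %d)\n",
              x$kappa, x$guess_rate, x$logLik, x$n))
  if (x$boundary) cat("  note: estimate at parameter boundary\n")
  invisible(x)
}

#' Select the trials that enter a model fit
#'
#' High-confidence comparison trials on which the reference probe was
#' judged (or chosen as) similar, reduced to the three columns the
#' response models need.
#'
#' @param trials trial-table data.frame (schema of [generate_dataset()]).
#' @return data.frame with columns `participant_id`, `S_M`, `S_P`,
#'   `response`.
#' @export
fitting_trials <- function(trials) {
  keep <- trials$confidence == 1 &
    !trials$condition %in% c("baseline", "baseline_short", "baseline_long") &
    !is.na(trials$judgment1) & trials$judgment1 == "similar"
  x <- trials[keep, , drop = FALSE]
  data.frame(participant_id = x$participant_id, S_M = x$S_M,
             S_P = x$probe1_sim, response = x$response)
}

## per-trial log mass at the observed response bin, joint (product) model
joint_loglik <- function(trials, kappa_M, kappa_P, grid = circular_grid()) {
  th <- grid$points * pi / 180
  dM <- (trials$response - trials$S_M) * pi / 180
  dP <- (trials$response - trials$S_P) * pi / 180
  delta <- abs(signed_circ_dist(trials$S_P, trials$S_M)) * pi / 180
  # normalizer depends on the trial only through the probe distance
  logz <- vapply(delta, function(d) {
    log(sum(exp(kappa_M * (cos(th) - 1) + kappa_P * (cos(th - d) - 1))))
  }, numeric(1))
  sum(kappa_M * (cos(dM) - 1) + kappa_P * (cos(dP) - 1) - logz)
}

## per-trial log mass at the observed response bin, mixture model
mixture_loglik <- function(trials, kappa_M, kappa_P, alpha,
                           grid = circular_grid()) {
  dM <- (trials$response - trials$S_M) * pi / 180
  dP <- (trials$response - trials$S_P) * pi / 180
  lzM <- log_z_grid(kappa_M, grid)
  lzP <- log_z_grid(kappa_P, grid)
  mM <- exp(kappa_M * (cos(dM) - 1) - lzM)
  mP <- exp(kappa_P * (cos(dP) - 1) - lzP)
  sum(log(alpha * mM + (1 - alpha) * mP))
}

#' Fit a response model to comparison trials
#'
#' Fits the joint-density (representational-integration) or
#' mixture-density (swap) model to a set of comparison trials. The
#' fitting objective follows the mean-matching procedure: find the
#' parameters whose predicted average signed response error (the
#' expected circular-mean displacement toward the probe, averaged over
#' the fitted trials) is closest to the observed average signed error,
#' collapsed across probe distances. Optimization is exhaustive grid
#' search (kappa_P log-spaced on 0.1--100; alpha on 0--1 in steps of
#' 0.01) followed by local refinement of kappa_P.
#'
#' Because the mean-matching objective constrains two mixture parameters
#' with a single statistic, mixture candidates that match the observed
#' mean equally well (within `ridge_tol` degrees of the best objective)
#' are disambiguated by their summed log-likelihood.
#'
#' At the optimum the per-trial log-likelihood of the observed responses
#' under the fitted densities is evaluated on the 1-degree grid
#' (probability mass at the observed response bin), giving the AIC/BIC
#' entries used for model comparison.
#'
#' @param trials data.frame with columns `S_M`, `S_P`, `response`
#'   (e.g. from [fitting_trials()]).
#' @param kappa_M memory concentration for this participant, typically
#'   from [fit_standard_wm()] on baseline offsets.
#' @param model `"joint"` or `"mixture"`.
#' @param kappa_M_source provenance note stored with the fit (e.g.
#'   `"baseline-fit"`, `"true"`).
#' @param objective `"analytic"` computes the model's expected signed
#'   error in closed form; `"simulated"` estimates it from `n_sim`
#'   sampled responses per trial (the literal simulate-and-average
#'   procedure, noisier and slower).
#' @param error_type `"signed"` (default) matches mean signed errors;
#'   `"absolute"` matches mean absolute errors.
#' @param kappa_grid candidate kappa_P grid.
#' @param alpha_grid candidate alpha grid (mixture only).
#' @param ridge_tol objective tolerance (degrees) defining the mixture
#'   likelihood tie-break set.
#' @param n_sim simulated responses per trial for
#'   `objective = "simulated"`.
#' @return object of class `simbias_fit`.
#' @export
fit_bias_model <- function(trials, kappa_M, model = c("joint", "mixture"),
                           kappa_M_source = "user",
                           objective = c("analytic", "simulated"),
                           error_type = c("signed", "absolute"),
                           kappa_grid = exp(seq(log(0.1), log(100),
                                                length.out = 61)),
                           alpha_grid = seq(0, 1, by = 0.01),
                           ridge_tol = 0.25, n_sim = 200) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  error_type <- match.arg(error_type)
  if (nrow(trials) == 0) stop("insufficient-data: no trials", call. = FALSE)
  stopifnot(kappa_M >= 0)

  delta <- abs(signed_circ_dist(trials$S_P, trials$S_M))
  obs <- signed_offset(trials$response, trials$S_M, trials$S_P)
  obs_mean <- if (error_type == "signed") mean(obs) else mean(abs(obs))

  pred_mean <- function(kP, a = NULL) {
    if (objective == "analytic") {
      b <- if (model == "joint") joint_bias(delta, kappa_M, kP)
           else mixture_bias(delta, kappa_M, kP, a)
      if (error_type == "signed") mean(b) else mean(abs(b))
    } else {
      sim_mean_error(trials, kappa_M, kP, model, a, n_sim, error_type)
    }
  }

  if (model == "joint") {
    objs <- vapply(kappa_grid, function(k) abs(pred_mean(k) - obs_mean),
                   numeric(1))
    i <- which.min(objs)
    lo <- kappa_grid[max(1, i - 1)]
    hi <- kappa_grid[min(length(kappa_grid), i + 1)]
    opt <- stats::optimize(function(k) abs(pred_mean(k) - obs_mean),
                           c(lo, hi), tol = 1e-6)
    kP <- if (opt$objective < objs[i]) opt$minimum else kappa_grid[i]
    obj <- min(opt$objective, objs[i])
    params <- c(kappa_P = kP)
    ll <- joint_loglik(trials, kappa_M, kP)
    k_free <- 1L
  } else {
    combos <- expand.grid(alpha = alpha_grid, kappa_P = kappa_grid)
    if (objective == "analytic" && error_type == "signed") {
      # vectorized grid sweep: per kappa_P, all alphas at once
      drad <- delta * pi / 180
      sd_ <- sin(drad); cd_ <- cos(drad)
      dM <- (trials$response - trials$S_M) * pi / 180
      dP <- (trials$response - trials$S_P) * pi / 180
      lzM <- log_z_grid(kappa_M)
      mM <- exp(kappa_M * (cos(dM) - 1) - lzM)
      objs <- numeric(nrow(combos)); lls <- numeric(nrow(combos))
      rmM <- vm_A1(kappa_M)
      for (ki in seq_along(kappa_grid)) {
        kP <- kappa_grid[ki]
        rP <- vm_A1(kP)
        mP <- exp(kP * (cos(dP) - 1) - log_z_grid(kP))
        rows <- (ki - 1) * length(alpha_grid) + seq_along(alpha_grid)
        for (ai in seq_along(alpha_grid)) {
          a <- alpha_grid[ai]
          rm <- a * rmM; rp <- (1 - a) * rP
          b <- atan2(rp * sd_, rm + rp * cd_) * 180 / pi
          objs[rows[ai]] <- abs(mean(b) - obs_mean)
          lls[rows[ai]] <- sum(log(a * mM + (1 - a) * mP))
        }
      }
    } else {
      objs <- mapply(function(a, k) abs(pred_mean(k, a) - obs_mean),
                     combos$alpha, combos$kappa_P)
      lls <- mapply(function(a, k) mixture_loglik(trials, kappa_M, k, a),
                    combos$alpha, combos$kappa_P)
    }
    cand <- which(objs <= min(objs) + ridge_tol)
    sel <- cand[which.max(lls[cand])]
    a <- combos$alpha[sel]
    kidx <- which(kappa_grid == combos$kappa_P[sel])
    lo <- kappa_grid[max(1, kidx - 1)]
    hi <- kappa_grid[min(length(kappa_grid), kidx + 1)]
    opt <- stats::optimize(function(k) abs(pred_mean(k, a) - obs_mean),
                           c(lo, hi), tol = 1e-6)
    kP <- if (opt$objective < objs[sel]) opt$minimum else combos$kappa_P[sel]
    obj <- min(opt$objective, objs[sel])
    params <- c(alpha = a, kappa_P = kP)
    ll <- mixture_loglik(trials, kappa_M, kP, a)
    k_free <- 2L
  }

  n <- nrow(trials)
  res <- list(model_id = model, params = params, kappa_M = kappa_M,
              kappa_M_source = kappa_M_source, objective_value = obj,
              observed_mean_error = obs_mean,
              sum_log_likelihood = ll, n_trials = n, k_free_params = k_free,
              AIC = 2 * k_free - 2 * ll, BIC = k_free * log(n) - 2 * ll,
              trials = trials)
  class(res) <- "simbias_fit"
  res
}

## Monte-Carlo estimate of the model's mean response error (the literal
## simulate-and-average objective variant)
sim_mean_error <- function(trials, kappa_M, kappa_P, model, alpha, n_sim,
                           error_type) {
  grid <- circular_grid()
  errs <- vapply(seq_len(nrow(trials)), function(i) {
    dens <- if (model == "joint") {
      joint_density(trials$S_M[i], kappa_M, trials$S_P[i], kappa_P, grid)
    } else {
      mixture_density(trials$S_M[i], kappa_M, trials$S_P[i], kappa_P, alpha,
                      grid)
    }
    r <- sample_response(dens, n_sim)
    e <- signed_offset(r, trials$S_M[i], trials$S_P[i])
    if (error_type == "signed") mean(e) else mean(abs(e))
  }, numeric(1))
  mean(errs)
}

#' @rdname fit_bias_model
#' @param ... passed on to [fit_bias_model()].
#' @export
fit_joint_model <- function(trials, kappa_M, ...) {
  fit_bias_model(trials, kappa_M, model = "joint", ...)
}

#' @rdname fit_bias_model
#' @export
fit_mixture_model <- function(trials, kappa_M, ...) {
  fit_bias_model(trials, kappa_M, model = "mixture", ...)
}

#' @export
print.simbias_fit <- function(x, ...) {
  cat(sprintf("%s-density model fit (%d trials)\n",
              if (x$model_id == "joint") "Joint" else "Mixture", x$n_trials))
  cat("  parameters:",
      paste(sprintf("%s = %.3f", names(x$params), x$params), collapse = ", "),
      "\n")
  cat(sprintf("  kappa_M = %.3f (%s)\n", x$kappa_M, x$kappa_M_source))
  cat(sprintf("  objective |pred - obs mean error| = %.4f deg\n",
              x$objective_value))
  cat(sprintf("  logLik = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$sum_log_likelihood, x$AIC, x$BIC))
  invisible(x)
}

#' @export
summary.simbias_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  observed mean signed error: %.3f deg\n",
              object$observed_mean_error))
  pb <- predicted_bias_by_distance(object)
  cat("  predicted bias by probe-distance bin (deg):\n")
  print(round(stats::setNames(pb$predicted_bias, round(pb$bin_center)), 2))
  invisible(object)
}

#' @export
coef.simbias_fit <- function(object, ...) object$params

#' @export
logLik.simbias_fit <- function(object, ...) {
  structure(object$sum_log_likelihood, df = object$k_free_params,
            nobs = object$n_trials, class = "logLik")
}

#' Predicted signed bias for fitted trials
#'
#' @param object a `simbias_fit`.
#' @param newdata optional data.frame with `S_M`, `S_P` (defaults to the
#'   fitted trials).
#' @param ... unused.
#' @return numeric vector of expected signed biases (degrees, positive
#'   toward the probe), one per trial.
#' @export
predict.simbias_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$trials else newdata
  delta <- abs(signed_circ_dist(d$S_P, d$S_M))
  if (object$model_id == "joint") {
    joint_bias(delta, object$kappa_M, object$params[["kappa_P"]])
  } else {
    mixture_bias(delta, object$kappa_M, object$params[["kappa_P"]],
                 object$params[["alpha"]])
  }
}

#' @export
residuals.simbias_fit <- function(object, ...) {
  obs <- signed_offset(object$trials$response, object$trials$S_M,
                       object$trials$S_P)
  obs - predict(object)
}

#' Simulate responses from a fitted model
#'
#' Draws responses for the fitted trials from the fitted per-trial
#' densities.
#'
#' @param object a `simbias_fit`.
#' @param nsim number of response sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with one column per simulation, one row per trial.
#' @export
simulate.simbias_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- circular_grid()
  tr <- object$trials
  out <- replicate(nsim, vapply(seq_len(nrow(tr)), function(i) {
    dens <- if (object$model_id == "joint") {
      joint_density(tr$S_M[i], object$kappa_M, tr$S_P[i],
                    object$params[["kappa_P"]], grid)
    } else {
      mixture_density(tr$S_M[i], object$kappa_M, tr$S_P[i],
                      object$params[["kappa_P"]], object$params[["alpha"]],
                      grid)
    }
    sample_response(dens, 1)
  }, numeric(1)))
  as.data.frame(out)
}

#' Predicted and observed bias per probe-distance bin
#'
#' Bins the fitted trials' probe distances and reports, per bin, the
#' model's expected signed bias and the observed mean signed offset,
#' ready for the predicted-vs-observed correlation.
#'
#' @param fit a `simbias_fit`.
#' @param n_bins number of equal-width distance bins.
#' @param range probe-distance range.
#' @return data.frame with columns `bin`, `bin_center`, `n`,
#'   `predicted_bias`, `observed_bias`.
#' @export
predicted_bias_by_distance <- function(fit, n_bins = 18, range = c(16, 105)) {
  tr <- fit$trials
  delta <- abs(signed_circ_dist(tr$S_P, tr$S_M))
  range <- c(min(range[1], floor(min(delta))), max(range[2], ceiling(max(delta))))
  bin <- discretize_probe_distance(delta, n_bins, range)
  pred <- predict(fit)
  obs <- signed_offset(tr$response, tr$S_M, tr$S_P)
  width <- diff(range) / n_bins
  out <- data.frame(bin = seq_len(n_bins),
                    bin_center = range[1] + width * (seq_len(n_bins) - 0.5))
  out$n <- tabulate(bin, n_bins)
  out$predicted_bias <- vapply(seq_len(n_bins), function(b)
    if (out$n[b]) mean(pred[bin == b]) else NA_real_, numeric(1))
  out$observed_bias <- vapply(seq_len(n_bins), function(b)
    if (out$n[b]) mean(obs[bin == b]) else NA_real_, numeric(1))
  out
}

#' @export
plot.simbias_fit <- function(x, ...) {
  pb <- predicted_bias_by_distance(x)
  ok <- !is.na(pb$predicted_bias)
  graphics::plot(pb$bin_center[ok], pb$observed_bias[ok],
                 xlab = "Probe distance (deg)",
                 ylab = "Signed bias toward probe (deg)",
                 pch = 19, ...)
  graphics::lines(pb$bin_center[ok], pb$predicted_bias[ok], col = "red")
  graphics::legend("topleft", legend = c("observed", "predicted"),
                   pch = c(19, NA), lty = c(NA, 1), col = c("black", "red"),
                   bty = "n")
  invisible(x)
}

#' Compare joint and mixture fits across participants
#'
#' Sums per-participant log-likelihoods for each model and computes
#' cohort-level AIC/BIC with k = total number of free parameters across
#' participants and n = total number of fitted trials, flagging the
#' preferred model under each criterion.
#'
#' @param joint_fits,mixture_fits lists of `simbias_fit` objects fitted
#'   to identical trial sets.
#' @return object of class `model_comparison`: data.frame with one row
#'   per model (`sum_loglik`, `k`, `n`, `AIC`, `BIC`) plus a `preferred`
#'   attribute naming the winner under each criterion.
#' @export
compare_models <- function(joint_fits, mixture_fits) {
  if (inherits(joint_fits, "simbias_fit")) joint_fits <- list(joint_fits)
  if (inherits(mixture_fits, "simbias_fit")) mixture_fits <- list(mixture_fits)
  nj <- vapply(joint_fits, `[[`, numeric(1), "n_trials")
  nm <- vapply(mixture_fits, `[[`, numeric(1), "n_trials")
  if (length(nj) != length(nm) || any(nj != nm)) {
    stop("invalid-comparison: fits cover different trial sets", call. = FALSE)
  }
  row <- function(fits) {
    ll <- sum(vapply(fits, `[[`, numeric(1), "sum_log_likelihood"))
    k <- sum(vapply(fits, `[[`, numeric(1), "k_free_params"))
    n <- sum(vapply(fits, `[[`, numeric(1), "n_trials"))
    data.frame(sum_loglik = ll, k = k, n = n,
               AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll)
  }
  tab <- rbind(cbind(model = "joint", row(joint_fits)),
               cbind(model = "mixture", row(mixture_fits)))
  attr(tab, "preferred") <- c(
    loglik = tab$model[which.max(tab$sum_loglik)],
    AIC = tab$model[which.min(tab$AIC)],
    BIC = tab$model[which.min(tab$BIC)])
  class(tab) <- c("model_comparison", class(tab))
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison\n")
  df <- as.data.frame(unclass(x))
  df$sum_loglik <- round(df$sum_loglik, 4)
  df$AIC <- round(df$AIC, 4)
  df$BIC <- round(df$BIC, 4)
  print(df, row.names = FALSE)
  pref <- attr(x, "preferred")
  cat("Preferred:", paste(names(pref), pref, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a model-comparison table to CSV
#'
#' @param comparison a `model_comparison`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(as.data.frame(unclass(comparison)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate comparison trials directly from a response model
#'
#' Recovery harness: produces `n` integrated comparison trials (target
#' uniform on the wheel, probe distance uniform on `range` with random
#' side, response drawn from the generating model's density), bypassing
#' the judgment and confidence stages so that the number of fitted
#' trials is exact.
#'
#' @param n number of trials.
#' @param kappa_M,kappa_P generating concentrations.
#' @param model `"joint"` or `"mixture"`.
#' @param alpha mixture proportion (mixture only).
#' @param range probe-distance range in degrees.
#' @return data.frame with columns `S_M`, `S_P`, `response`.
#' @export
simulate_model_trials <- function(n, kappa_M, kappa_P,
                                  model = c("joint", "mixture"), alpha = 0.85,
                                  range = c(16, 105)) {
  model <- match.arg(model)
  grid <- circular_grid()
  S_M <- sample(grid$points, n, replace = TRUE)
  d <- stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
  S_P <- wrap_position(S_M + d)
  kM <- vm_kernel(kappa_M, grid)
  kP <- vm_kernel(kappa_P, grid)
  response <- vapply(seq_len(n), function(i) {
    if (model == "joint") {
      sample_response(joint_density(S_M[i], kappa_M, S_P[i], kappa_P, grid), 1)
    } else if (stats::runif(1) < alpha) {
      draw_vm(S_M[i], kM, grid)
    } else {
      draw_vm(S_P[i], kP, grid)
    }
  }, numeric(1))
  data.frame(S_M = S_M, S_P = S_P, response = response)
}

#' Model-recovery study
#'
#' Repeatedly simulates a cohort from a known generating model, fits
#' both response models to every participant, compares them at the
#' cohort level, and reports how often each criterion prefers the
#' generating model.
#'
#' @param generator `"joint"` or `"mixture"`.
#' @param n_participants participants per replicate.
#' @param n_trials comparison trials per participant.
#' @param reps number of replicates (>= 20 recommended).
#' @param seed master seed.
#' @param kappa_M,kappa_P,alpha generating parameters.
#' @param range probe-distance range.
#' @return object of class `recovery_result`: list with `preference`
#'   (per-criterion fraction of replicates preferring the generator) and
#'   `detail` (per-replicate winners).
#' @export
model_recovery_study <- function(generator = c("joint", "mixture"),
                                 n_participants = 16, n_trials = 300,
                                 reps = 20, seed = 1,
                                 kappa_M = 10, kappa_P = 5, alpha = 0.85,
                                 range = c(16, 105)) {
  generator <- match.arg(generator)
  winners <- matrix(NA_character_, reps, 3,
                    dimnames = list(NULL, c("loglik", "AIC", "BIC")))
  for (r in seq_len(reps)) {
    set.seed((as.integer(seed) + 7919L * r) %% 2147483629L)
    jf <- vector("list", n_participants)
    mf <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      tr <- simulate_model_trials(n_trials, kappa_M, kappa_P, generator,
                                  alpha, range)
      jf[[p]] <- fit_bias_model(tr, kappa_M, "joint", kappa_M_source = "true")
      mf[[p]] <- fit_bias_model(tr, kappa_M, "mixture", kappa_M_source = "true")
    }
    winners[r, ] <- attr(compare_models(jf, mf), "preferred")
  }
  res <- list(generator = generator,
              preference = colMeans(winners == generator),
              detail = winners)
  class(res) <- "recovery_result"
  res
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Model recovery (generator:", x$generator, ")\n")
  cat("  fraction of replicates preferring the generator:\n")
  print(round(x$preference, 3))
  invisible(x)
}
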