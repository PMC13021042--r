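test_that("standard WM mixture fit recovers kappa and guess rate", {
  g <- circular_grid()
  set.seed(51)
  n <- 5000
  guess <- runif(n) < 0.1
  x <- ifelse(guess, runif(n, -180, 180),
              wrap_signed(sample_response(vm_density(0, 10, g), n)))
  fit <- fit_standard_wm(x)
  expect_equal(fit$kappa, 10, tolerance = 0.15 * 10)
  expect_equal(fit$guess_rate, 0.1, tolerance = 0.03)
  # pure von Mises data
  pure <- wrap_signed(sample_response(vm_density(0, 8, g), 3000))
  expect_lt(fit_standard_wm(pure)$guess_rate, 0.02)
  # pure guessing
  unif <- runif(2000, -180, 180)
  expect_gt(fit_standard_wm(unif)$guess_rate, 0.9)
  expect_error(fit_standard_wm(1:5), "insufficient-data")
})

test_that("per-trial likelihoods equal the density mass at the response bin", {
  set.seed(52)
  tr <- simulate_model_trials(40, 10, 5, "joint")
  g <- circular_grid()
  direct <- sum(vapply(seq_len(nrow(tr)), function(i) {
    d <- joint_density(tr$S_M[i], 10, tr$S_P[i], 5, g)
    log(d$mass[which(g$points == tr$response[i])])
  }, numeric(1)))
  expect_equal(simbias:::joint_loglik(tr, 10, 5), direct, tolerance = 1e-8)
  direct_mix <- sum(vapply(seq_len(nrow(tr)), function(i) {
    d <- mixture_density(tr$S_M[i], 10, tr$S_P[i], 5, 0.8, g)
    log(d$mass[which(g$points == tr$response[i])])
  }, numeric(1)))
  expect_equal(simbias:::mixture_loglik(tr, 10, 5, 0.8), direct_mix,
               tolerance = 1e-8)
})

test_that("joint fit is self-consistent and obeys the grid-search contract", {
  set.seed(53)
  n <- 200
  S_M <- sample(0:359, n, replace = TRUE)
  delta <- runif(n, 16, 105) * sample(c(-1, 1), n, replace = TRUE)
  S_P <- (S_M + delta) %% 360
  # responses placed exactly at each trial's joint-density mean
  resp <- (S_M + sign(delta) * joint_bias(abs(delta), 10, 5)) %% 360
  tr <- data.frame(S_M = S_M, S_P = S_P, response = resp)
  fit <- fit_bias_model(tr, 10, "joint")
  expect_lt(fit$objective_value, 1e-4)
  expect_equal(unname(coef(fit)["kappa_P"]), 5, tolerance = 0.01)
  # refining the grid moves the estimate by less than one coarse step
  coarse <- exp(seq(log(0.1), log(100), length.out = 20))
  fine <- exp(seq(log(0.1), log(100), length.out = 80))
  f1 <- fit_bias_model(tr, 10, "joint", kappa_grid = coarse)
  f2 <- fit_bias_model(tr, 10, "joint", kappa_grid = fine)
  step <- exp(diff(log(coarse))[1])
  expect_lt(abs(log(coef(f1)["kappa_P"]) - log(coef(f2)["kappa_P"])),
            log(step))
})

test_that("mixture fit respects the box constraint and boundary data", {
  set.seed(54)
  tr <- simulate_model_trials(300, 10, 10, "mixture", alpha = 1)
  fit <- fit_bias_model(tr, 10, "mixture")
  expect_gte(coef(fit)["alpha"], 0.95)
  tr2 <- simulate_model_trials(200, 10, 10, "mixture", alpha = 0.6)
  fit2 <- fit_bias_model(tr2, 10, "mixture")
  a <- coef(fit2)["alpha"]
  expect_true(a >= 0 && a <= 1)
  expect_error(fit_bias_model(tr2[0, ], 10, "joint"), "insufficient-data")
})

test_that("fit objects satisfy the information-criterion identities", {
  set.seed(55)
  tr <- simulate_model_trials(150, 10, 5, "joint")
  fits <- list(fit_bias_model(tr, 10, "joint"),
               fit_bias_model(tr, 10, "mixture"))
  for (f in fits) {
    expect_equal(f$AIC, 2 * f$k_free_params - 2 * f$sum_log_likelihood)
    expect_equal(f$BIC,
                 f$k_free_params * log(f$n_trials) - 2 * f$sum_log_likelihood)
    ll <- logLik(f)
    expect_equal(AIC(ll), f$AIC)
    expect_equal(BIC(ll), f$BIC)
  }
  expect_equal(fits[[1]]$k_free_params, 1L)
  expect_equal(fits[[2]]$k_free_params, 2L)
})

test_that("cohort comparison applies the AIC/BIC formulas and flags winners", {
  fake <- function(ll, k, n, model) {
    structure(list(model_id = model, sum_log_likelihood = ll,
                   k_free_params = k, n_trials = n,
                   AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll),
              class = "simbias_fit")
  }
  cmp <- compare_models(fake(-100, 1, 50, "joint"),
                        fake(-120, 2, 50, "mixture"))
  expect_equal(cmp$AIC[cmp$model == "joint"], 202)
  expect_equal(cmp$BIC[cmp$model == "joint"], 1 * log(50) + 200)
  # n = e^2 trials makes AIC and BIC coincide for k = 1
  cmp2 <- compare_models(fake(-100, 1, exp(2), "joint"),
                         fake(-100, 2, exp(2), "mixture"))
  expect_equal(cmp2$BIC[cmp2$model == "joint"], 202)
  expect_equal(unname(attr(cmp, "preferred")["AIC"]), "joint")
  expect_error(compare_models(fake(-1, 1, 50, "joint"),
                              fake(-1, 2, 60, "mixture")),
               "invalid-comparison")
})

test_that("predicted bias by distance tracks the closed form and the data", {
  set.seed(56)
  tr <- simulate_model_trials(600, 10, 2.5, "joint")
  fit <- fit_bias_model(tr, 10, "joint")
  pb <- predicted_bias_by_distance(fit)
  ok <- !is.na(pb$predicted_bias)
  # monotone increasing prediction for a weak probe (ratio <= 0.25)
  expect_true(all(diff(pb$predicted_bias[ok]) > 0))
  expect_gt(cor(pb$predicted_bias[ok], pb$observed_bias[ok]), 0)
  # an uninformative probe predicts no bias anywhere
  fit0 <- fit
  fit0$params["kappa_P"] <- 0
  expect_equal(max(abs(predicted_bias_by_distance(fit0)$predicted_bias),
                   na.rm = TRUE), 0)
})

test_that("fit methods expose coefficients, residuals and simulations", {
  set.seed(57)
  tr <- simulate_model_trials(100, 10, 5, "joint")
  fit <- fit_bias_model(tr, 10, "joint")
  expect_named(coef(fit), "kappa_P")
  expect_length(predict(fit), 100)
  expect_length(residuals(fit), 100)
  s1 <- simulate(fit, nsim = 2, seed = 1)
  s2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) >= 0 & unlist(s1) < 360))
  expect_output(print(fit), "Joint-density")
})

test_that("a small recovery study is deterministic and prefers the generator", {
  res1 <- model_recovery_study("joint", n_participants = 4, n_trials = 150,
                               reps = 3, seed = 58)
  res2 <- model_recovery_study("joint", n_participants = 4, n_trials = 150,
                               reps = 3, seed = 58)
  expect_identical(res1$detail, res2$detail)
  expect_equal(unname(res1$preference["AIC"]), 1)
  resm <- model_recovery_study("mixture", n_participants = 4, n_trials = 150,
                               reps = 3, seed = 59, kappa_P = 10, alpha = 0.6)
  expect_gt(unname(resm$preference["AIC"]), 0.5)
})
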