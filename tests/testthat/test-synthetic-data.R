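test_that("single-probe sampling stays in range with equiprobable sides", {
  set.seed(21)
  S_M <- 200
  probes <- replicate(1e4, sample_probe_exp1(S_M))
  d <- signed_circ_dist(probes, S_M)
  expect_true(all(abs(d) >= 16 & abs(d) <= 105))
  expect_equal(mean(d > 0), 0.5, tolerance = 0.02)
  set.seed(4); p1 <- sample_probe_exp1(10)
  set.seed(4); p2 <- sample_probe_exp1(10)
  expect_identical(p1, p2)
})

test_that("2AFC probe pairs obey the side and antipode rules", {
  set.seed(22)
  for (cond in c("same", "opposite")) {
    sides <- replicate(500, {
      pp <- sample_probe_pairs_exp2(120, cond)
      expect_equal(wrap_position(pp$sim + 180), pp$dis)
      d <- signed_circ_dist(pp$sim, 120)
      expect_true(all(abs(d) >= 16 & abs(d) <= 45))
      sign(d)
    })
    if (cond == "same") expect_true(all(sides[1, ] == sides[2, ]))
    else expect_true(all(sides[1, ] == -sides[2, ]))
  }
  first <- replicate(2000, sample_probe_pairs_exp2(0, "same")$side[1])
  expect_equal(mean(first > 0), 0.5, tolerance = 0.05)
})

test_that("similarity judgments follow the logistic distance rule", {
  set.seed(23)
  # at the criterion the judgment is a coin flip
  at_c <- replicate(4000, simulate_similarity_judgment(60, 0, 60, 15))
  expect_equal(mean(at_c == "similar"), 0.5, tolerance = 0.03)
  # monotone decreasing in distance
  p_at <- sapply(c(10, 40, 70, 100), function(d)
    mean(replicate(2000, simulate_similarity_judgment(d, 0, 60, 15)) == "similar"))
  expect_true(all(diff(p_at) < 0))
  # vanishing slope approaches a hard threshold
  expect_equal(mean(replicate(200,
    simulate_similarity_judgment(30, 0, 60, 1e-6)) == "similar"), 1)
  expect_equal(mean(replicate(200,
    simulate_similarity_judgment(90, 0, 60, 1e-6)) == "similar"), 0)
})

test_that("2AFC choices pick the perceptually closer probe", {
  expect_equal(simulate_2afc_choice(30, c(30, 210)), 1)
  set.seed(24)
  g <- circular_grid()
  kM <- simbias:::vm_kernel(10, g)
  acc <- mean(replicate(1e4, {
    X <- simbias:::draw_vm(0, kM, g)
    simulate_2afc_choice(X, c(30, 150)) == 1
  }))
  expect_gt(acc, 0.85)
  ties <- replicate(2000, simulate_2afc_choice(90, c(0, 180)))
  expect_equal(mean(ties == 1), 0.5, tolerance = 0.04)
})

test_that("simulated trials reproduce design-level response signatures", {
  d1 <- experiment_design("exp1")
  obs <- observer_spec(lapse_rate = 0)
  set.seed(25)
  base <- replicate(4000, {
    tr <- simulate_trial(d1, obs, "baseline")
    signed_circ_dist(tr$response, tr$S_M)
  })
  expect_lt(abs(mean(base)), 1)
  set.seed(26)
  comp <- t(replicate(2000, {
    tr <- simulate_trial(d1, obs, "comparison")
    c(off = signed_offset(tr$response, tr$S_M, tr$probe1_sim),
      sim = tr$judgment1 == "similar")
  }))
  expect_gt(mean(comp[comp[, "sim"] == 1, "off"]), 0)
  expect_error(simulate_trial(d1, obs, "same_side"), "invalid-design")
})

test_that("opposite-side judgments cancel the bias induced by the first probe", {
  d2 <- experiment_design("exp2")
  obs <- observer_spec(lapse_rate = 0)
  run <- function(cond, n) {
    replicate(n, {
      tr <- simulate_trial(d2, obs, cond)
      signed_offset(tr$response, tr$S_M, tr$probe1_sim)
    })
  }
  set.seed(27)
  same <- run("same_side", 1500)
  opp <- run("opposite_side", 1500)
  expect_gt(abs(mean(same)), abs(mean(opp)))
  expect_gt(mean(same), 2)
})

test_that("datasets have the per-design trial counts and are seed-deterministic", {
  pop <- rep(list(observer_spec()), 2)
  t1 <- generate_dataset(experiment_design("exp1"), pop, seed = 5)
  expect_equal(nrow(t1), 2 * 12 * (12 + 36))
  expect_equal(sum(t1$condition == "baseline"), 2 * 144)
  expect_equal(sum(t1$condition == "comparison"), 2 * 432)
  t3 <- generate_dataset(experiment_design("exp3"), pop, seed = 5)
  expect_equal(nrow(t3), 2 * 4 * 30)
  expect_equal(sum(t3$condition == "baseline" & t3$participant_id == 1), 60)
  t1b <- generate_dataset(experiment_design("exp1"), pop, seed = 5)
  expect_identical(t1, t1b)
  # probe-placement invariants on every generated row
  t2 <- generate_dataset(experiment_design("exp2"), pop, seed = 6)
  exp_rows <- t2[t2$condition %in% c("same_side", "opposite_side"), ]
  expect_equal(wrap_position(exp_rows$probe1_sim + 180), exp_rows$probe1_dis)
  expect_equal(wrap_position(exp_rows$probe2_sim + 180), exp_rows$probe2_dis)
  d1 <- signed_circ_dist(exp_rows$probe1_sim, exp_rows$S_M)
  d2 <- signed_circ_dist(exp_rows$probe2_sim, exp_rows$S_M)
  expect_true(all(abs(c(d1, d2)) >= 16 & abs(c(d1, d2)) <= 45))
  same <- exp_rows$condition == "same_side"
  expect_true(all(sign(d1[same]) == sign(d2[same])))
  expect_true(all(sign(d1[!same]) == -sign(d2[!same])))
  expect_true(all(t2$confidence %in% 1:3))
})

test_that("individual-differences populations are log-normal and reproducible", {
  pop <- generate_population_exp3(110, seed = 9)
  expect_length(pop, 110)
  k <- vapply(pop, `[[`, numeric(1), "kappa_M")
  expect_true(all(k > 0))
  pop2 <- generate_population_exp3(110, seed = 9)
  expect_identical(k, vapply(pop2, `[[`, numeric(1), "kappa_M"))
  flat <- generate_population_exp3(5, sdlog = 0, seed = 1)
  kf <- vapply(flat, `[[`, numeric(1), "kappa_M")
  expect_equal(kf, rep(12, 5))
})

test_that("trial tables round-trip through CSV and are validated on read", {
  pop <- rep(list(observer_spec()), 2)
  tr <- generate_dataset(experiment_design("exp3"), pop, seed = 31)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(back$response, tr$response)
  expect_equal(back$judgment1, tr$judgment1)
  bad <- tr; bad$response[3] <- 400
  write_trials_csv(bad, path)
  expect_error(read_trials_csv(path), "row 3")
  bad2 <- tr; bad2$confidence[5] <- 7
  write_trials_csv(bad2, path)
  expect_error(read_trials_csv(path), "confidence")
})

test_that("observer configs load from YAML and JSON", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("kappa_M: 9", "generative_model: mixture", "alpha: 0.7"), y)
  o <- read_observer_config(y)
  expect_s3_class(o, "observer_spec")
  expect_equal(o$kappa_M, 9)
  expect_equal(o$alpha, 0.7)
  j <- tempfile(fileext = ".json")
  writeLines('{"population": [{"kappa_M": 5}, {"kappa_M": 15}]}', j)
  pop <- read_observer_config(j)
  expect_length(pop, 2)
  expect_equal(pop[[2]]$kappa_M, 15)
})
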