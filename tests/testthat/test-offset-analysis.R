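test_that("signed offsets are positive toward the reference probe", {
  expect_equal(signed_offset(10, 0, 40), 10)
  expect_equal(signed_offset(10, 0, -40 %% 360), -10)
  expect_equal(signed_offset(0, 0, 40), 0)
  expect_equal(signed_offset(350, 0, 320), 10)   # wraps across 0
  # reference flip negates the sign
  expect_equal(signed_offset_exp2(10, 0, 40), -signed_offset_exp2(10, 0, 320))
  expect_warning(signed_offset(10, 0, 0), "undefined-direction")
})

test_that("baseline signing preserves magnitudes and centers at zero", {
  set.seed(41)
  x <- runif(5000, 0, 30)
  s <- assign_baseline_signs(x)
  expect_equal(abs(s), x)
  expect_lt(abs(mean(s)), 1)
  set.seed(8); a <- assign_baseline_signs(x)
  set.seed(8); b <- assign_baseline_signs(x)
  expect_identical(a, b)
})

test_that("high-confidence filtering keeps confidence-1 rows and reports retention", {
  tab <- data.frame(participant_id = rep(1:2, each = 4),
                    condition = "comparison",
                    confidence = c(1, 1, 2, 3, 1, 2, 2, 3))
  out <- filter_high_confidence(tab)
  expect_true(all(out$confidence == 1))
  ret <- attr(out, "retention")
  expect_equal(sort(ret$retained), c(0.25, 0.5))
  all_hc <- tab[tab$confidence == 1, ]
  expect_equal(nrow(filter_high_confidence(all_hc)), nrow(all_hc))
  tab$confidence[5] <- 2
  expect_warning(filter_high_confidence(tab), "no high-confidence")
})

test_that("bias summaries reproduce hand-computed statistics", {
  off <- data.frame(
    participant_id = rep(1:4, each = 6),
    condition = rep(rep(c("similar", "dissimilar"), each = 3), 4),
    probe_distance = 50, judgment = NA, confidence = 1,
    offset = c(5, 5, 5, 2, 2, 2,   7, 7, 7, 1, 1, 1,
               6, 6, 6, 3, 3, 3,   4, 4, 4, 2, 2, 2))
  bs <- bias_magnitude(off, contrast = c("similar", "dissimilar"))
  sim_means <- c(5, 7, 6, 4)
  dis_means <- c(2, 1, 3, 2)
  g <- bs$group[bs$group$condition == "similar", ]
  expect_equal(g$mean, mean(sim_means))
  expect_equal(g$df, 3)
  expect_equal(g$d, mean(sim_means) / sd(sim_means))
  tt <- t.test(sim_means)
  expect_equal(g$t, unname(tt$statistic))
  expect_equal(c(g$ci_lo, g$ci_hi), as.numeric(tt$conf.int))
  diffs <- sim_means - dis_means
  expect_equal(bs$contrast$mean, mean(diffs))
  expect_equal(bs$contrast$d, mean(diffs) / sd(diffs))
  # antisymmetric offsets cancel
  off2 <- off; off2$offset <- rep(c(-3, 0, 3), 8)
  expect_equal(bias_magnitude(off2)$group$mean, c(0, 0))
  expect_error(bias_magnitude(off[off$participant_id == 1, ]),
               "insufficient-data")
})

test_that("probe distances discretize into 18 right-open bins", {
  expect_equal(discretize_probe_distance(16), 1L)
  expect_equal(discretize_probe_distance(105), 18L)
  width <- (105 - 16) / 18
  edges <- 16 + width * (0:17)
  expect_equal(discretize_probe_distance(edges), 1:18)
  expect_equal(discretize_probe_distance(edges + width * 0.999), 1:18)
  set.seed(42)
  d <- runif(500, 16, 105)
  b <- discretize_probe_distance(d)
  expect_equal(length(b), 500)
  expect_true(all(b %in% 1:18))
  expect_error(discretize_probe_distance(110), "invalid-distance")
})

test_that("ambivalent-probe analysis keeps only bins with both judgments", {
  # constructed arithmetic: +8 after similar, +2 after dissimilar in shared bins
  mk <- function(p, dists_sim, dists_dis) {
    rbind(data.frame(participant_id = p, condition = "comparison",
                     probe_distance = dists_sim, judgment = "similar",
                     offset = 8, confidence = 1),
          data.frame(participant_id = p, condition = "comparison",
                     probe_distance = dists_dis, judgment = "dissimilar",
                     offset = 2, confidence = 1))
  }
  tab <- rbind(mk(1, c(20, 40, 60), c(20.5, 40.5, 60.5)),
               mk(2, c(30, 50), c(30.5, 104)))
  res <- ambivalent_probe_analysis(tab)
  expect_equal(res$n_bins, c(3, 1))
  expect_equal(res$difference, c(6, 6))
  # participant with no shared bin is excluded with a flag
  tab2 <- rbind(tab, mk(3, 20, 80))
  expect_warning(res2 <- ambivalent_probe_analysis(tab2), "no ambivalent")
  expect_equal(attr(res2, "excluded"), 3)
  # simulated joint observer shows a positive similar-minus-dissimilar gap
  set.seed(43)
  tr <- generate_dataset(experiment_design("exp1"),
                         rep(list(observer_spec()), 4), seed = 43)
  hc <- filter_high_confidence(tr)
  off <- compute_offsets(hc)
  comp <- off$condition == "comparison"
  off$condition[comp] <- off$judgment[comp]
  amb <- ambivalent_probe_analysis(off[comp, ])
  expect_true(all(amb$difference > 0))
})

test_that("von Mises precision is recovered from offsets", {
  set.seed(44)
  g <- circular_grid()
  x <- sample_response(vm_density(0, 12, g), 1e4)
  off <- wrap_signed(x)
  k <- estimate_precision(off)
  expect_equal(k, 12, tolerance = 0.05 * 12)
  expect_equal(estimate_precision(-off), k)   # sign-flip invariance
  # wider spread means smaller kappa
  y <- wrap_signed(sample_response(vm_density(0, 4, g), 1e4))
  expect_lt(estimate_precision(y), k)
  expect_warning(kc <- estimate_precision(rep(0, 30)), "capped")
  expect_equal(as.numeric(kc), 1e4)
  expect_error(estimate_precision(rep(0, 5)), "insufficient-data")
  expect_error(estimate_precision(seq(-179, 180, length.out = 40)),
               "unidentifiable")
})

test_that("precision-bias correlation reports df = n - 2 and both outlier modes", {
  p <- c(1:10)
  b <- 11 - p
  res <- precision_bias_correlation(p, b)
  expect_equal(res$included$r, -1)
  expect_equal(res$included$df, 8)
  set.seed(45)
  p2 <- rnorm(30, 10, 1); b2 <- rnorm(30)
  p2[30] <- 40   # gross outlier
  res2 <- precision_bias_correlation(p2, b2, ids = 1:30)
  expect_equal(res2$excluded_ids, 30)
  expect_equal(res2$included$df, 27)
  expect_equal(res2$all$df, 28)
  expect_error(precision_bias_correlation(1:3, 3:1), "insufficient-data")
})

test_that("offset distributions are proportions with within-subject SEs", {
  set.seed(46)
  off <- data.frame(
    participant_id = rep(1:3, each = 200),
    condition = rep(rep(c("a", "b"), each = 100), 3),
    probe_distance = NA, judgment = NA, confidence = 1,
    offset = round(rnorm(600, rep(c(5, -5), each = 100), 15)))
  dist <- offset_distribution(off)
  expect_equal(nrow(dist), 2 * 360)
  for (cc in c("a", "b")) {
    expect_equal(sum(dist$proportion[dist$condition == cc]), 1,
                 tolerance = 1e-9)
  }
  expect_true(all(dist$sem_ws >= 0))
  # the two conditions peak on opposite sides
  a <- dist[dist$condition == "a", ]
  expect_gt(a$offset[which.max(a$proportion)], 0)
})
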