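test_that("choice probabilities match the closed form and its oracle", {
  # chance point: bias of half the foil distance makes away foils chance
  for (sigma in c(4, 9, 25)) {
    p <- observer_params(bias = 5, noise = sigma)
    expect_equal(p_choose_target(10, "away", p), 0.5)
  }
  # no bias: toward/away symmetric
  p0 <- observer_params(bias = 0, noise = 12)
  expect_equal(p_choose_target(20, "toward", p0),
               p_choose_target(20, "away", p0))
  # frozen closed-form spot values at b = 5, sigma = 8, delta = 10
  p <- observer_params(bias = 5, noise = 8)
  expect_equal(p_choose_target(10, "away", p), 0.5)
  expect_equal(p_choose_target(10, "toward", p), pnorm(10 / 8))
  expect_equal(pnorm(10 / 8), 0.8943502, tolerance = 1e-6)
})

test_that("closed form agrees with the Monte Carlo nearest-option oracle", {
  withr::with_seed(99, {
    grid <- expand.grid(delta = c(10, 20, 60), bias = c(0, 5, 11.5),
                        noise = c(8, 15), direction = c("away", "toward"),
                        stringsAsFactors = FALSE)
    n <- 2e5
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      p_mc <- mc_choose_target(g$delta, g$direction, g$bias, g$noise, n = n)
      p_cf <- p_choose_target(g$delta, g$direction,
                              observer_params(bias = g$bias, noise = g$noise))
      # 3/n guard keeps near-degenerate cells (p ~ 1) from tripping on the
      # Monte Carlo's granularity
      se <- sqrt(p_cf * (1 - p_cf) / n)
      expect_lt(abs(p_mc - p_cf), 3 * se + 3 / n)
    }
  })
})

test_that("circular observer matches the linear one in the design regime", {
  for (delta in c(10, 20, 60)) {
    for (sigma in c(5, 15, 30)) {
      for (b in c(0, 5, 11.5)) {
        for (dir in c("away", "toward")) {
          pp <- observer_params(bias = b, noise = sigma)
          expect_lt(abs(p_choose_target(delta, dir, pp, model = "circular") -
                          p_choose_target(delta, dir, pp)),
                    0.005)
        }
      }
    }
  }
  # exact chance point survives the circular geometry
  expect_equal(p_choose_target(10, "away",
                               observer_params(bias = 5, noise = 8),
                               model = "circular"),
               0.5, tolerance = 1e-8)
})

test_that("choice probability is monotone in foil distance and bias", {
  p <- observer_params(bias = 4, noise = 10)
  deltas <- seq(10, 60, by = 5)  # away regime with delta/2 > b
  expect_true(all(diff(p_choose_target(deltas, "away", p)) > 0))
  probs_away <- vapply(seq(0, 15, 1), function(b) {
    p_choose_target(10, "away", observer_params(bias = b, noise = 10))
  }, numeric(1))
  probs_toward <- vapply(seq(0, 15, 1), function(b) {
    p_choose_target(10, "toward", observer_params(bias = b, noise = 10))
  }, numeric(1))
  expect_true(all(diff(probs_away) < 0))
  expect_true(all(diff(probs_toward) > 0))
})

test_that("p_choose_target validates its inputs", {
  p <- observer_params()
  expect_error(p_choose_target(0, "away", p), "positive")
  expect_error(p_choose_target(-10, "toward", p), "positive")
  expect_error(observer_params(noise = 0), "noise")
  expect_error(observer_params(lapse = 0.7), "lapse")
})

test_that("simulated datasets are reproducible and match the closed form", {
  d <- design_experiment("E1", seed = 3)
  params <- observer_params(bias = 8, noise = 10,
                            search_accuracy = flat_search_accuracy("E1", .9))
  s1 <- simulate_dataset(d, params, seed = 21)
  s2 <- simulate_dataset(d, params, seed = 21)
  expect_identical(s1, s2)
  expect_false(identical(s1$choice,
                         simulate_dataset(d, params, seed = 22)$choice))

  # pooled per-cell proportions within 3 binomial SEs of the closed form,
  # with and without lapses
  for (par in list(observer_params(bias = 0, noise = 10),
                   observer_params(bias = 12, noise = 10, lapse = 0.5))) {
    big <- do.call(rbind, lapply(1:20, function(i) {
      simulate_dataset(d, par, seed = 100 + i, subject_id = sprintf("s%02d", i))
    }))
    cs <- condition_summary(big)
    p_exp <- p_choose_target(cs$foil_distance, cs$foil_direction, par,
                             D = cs$target_distractor_distance)
    se <- sqrt(p_exp * (1 - p_exp) / cs$n_trials)
    expect_true(all(abs(cs$p_target - p_exp) < 3 * se + 1e-12))
  }
})

test_that("E3 responses follow the trial kind and search accuracy feeds exclusions", {
  d <- design_experiment("E3", seed = 4)
  params <- observer_params(bias = 5, noise = 9,
                            search_accuracy = c("30" = 0.8, "180" = 0.95))
  s <- simulate_dataset(d, params, seed = 5)
  expect_true(all(is.na(s$choice[s$trial_kind == "search_report"])))
  expect_true(all(!is.na(s$choice[s$trial_kind == "similarity_report"])))
  expect_true(all(!is.na(s$search_correct[s$trial_kind == "search_report"])))
  expect_true(all(is.na(s$search_correct[s$trial_kind == "similarity_report"])))

  expect_error(
    simulate_dataset(d, observer_params(search_accuracy = c("30" = .9)),
                     seed = 1),
    "search_accuracy")
  expect_error(
    simulate_dataset(d, observer_params(bias_by_D = c("30" = 5), noise = 9),
                     seed = 1),
    "bias_by_D")
})

test_that("cohorts share parameters at zero spread and reproduce exactly", {
  d <- design_experiment("E2", seed = 9)
  dist <- cohort_distribution(bias_mean = 7, bias_sd = 0, noise_mean = 9)
  coh <- simulate_cohort(4, d, dist, seed = 31)
  pars <- attr(coh, "subject_params")
  expect_length(pars, 4)
  expect_true(all(vapply(pars, function(p) p$bias, numeric(1)) == 7))
  expect_true(all(vapply(pars, function(p) p$noise, numeric(1)) == 9))
  expect_equal(sort(unique(coh$subject_id)), sprintf("s%02d", 1:4))
  expect_equal(nrow(coh), 4 * 432)
  coh2 <- simulate_cohort(4, d, dist, seed = 31)
  expect_identical(coh$choice, coh2$choice)

  # nonzero spread: biases truncated at zero and not all equal
  dist2 <- cohort_distribution(bias_mean = 2, bias_sd = 3, noise_mean = 9)
  coh3 <- simulate_cohort(8, d, dist2, seed = 32)
  b <- vapply(attr(coh3, "subject_params"), function(p) p$bias, numeric(1))
  expect_true(all(b >= 0))
  expect_gt(stats::sd(b), 0)
})
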