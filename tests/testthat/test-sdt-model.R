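test_that("2AFC d-prime follows the clamped convention", {
  expect_equal(dprime_2afc(13, 26), 0)
  # frozen from sqrt(2) * qnorm(p)
  expect_equal(dprime_2afc(21, 25), 1.406376, tolerance = 1e-6)
  expect_equal(dprime_2afc(25, 25), 2.904440, tolerance = 1e-6)  # clamped
  expect_equal(dprime_2afc(0, 25), -dprime_2afc(25, 25))
  expect_error(dprime_2afc(1, 0), "n_trials")
  # antisymmetry about chance
  withr::with_seed(2, {
    n <- sample(5:200, 50, replace = TRUE)
    k <- vapply(n, function(m) sample(0:m, 1), integer(1))
    expect_equal(dprime_2afc(n - k, n), -dprime_2afc(k, n))
  })
})

test_that("condition summaries have the design's cells and ignore row order", {
  d <- design_experiment("E1", seed = 8)
  s <- simulate_dataset(d, observer_params(bias = 6, noise = 10), seed = 8)
  cs <- condition_summary(s, by_subject = TRUE)
  expect_equal(nrow(cs), 12)  # 6 distances x 2 foil directions
  expect_true(all(cs$n_trials == 25))
  expect_equal(sum(cs$n_trials), 300)
  expect_s3_class(cs, "condition_summary")

  shuffled <- s[sample(nrow(s)), ]
  expect_equal(condition_summary(shuffled, by_subject = TRUE), cs)

  all_target <- s
  all_target$choice[!is.na(all_target$choice)] <- "target"
  cs2 <- condition_summary(all_target)
  expect_true(all(cs2$dprime == dprime_2afc(cs2$n_trials, cs2$n_trials)))

  expect_error(condition_summary(s[, setdiff(names(s), "choice")]), "missing")
})

test_that("the likelihood is sane around the generating parameters", {
  withr::with_seed(14, {
    theta0 <- observer_params(bias = 8, noise = 10)
    cells <- e2_cells()
    s <- simulate_summaries(cells, theta0, n_per_cell = 2000)
    nll0 <- negative_loglik(theta0, s)
    worse <- replicate(100, {
      pert <- observer_params(bias = 8 + rnorm(1, 0, 3),
                              noise = 10 * exp(rnorm(1, 0, 0.3)))
      negative_loglik(pert, s)
    })
    expect_gt(mean(worse > nll0), 0.9)   # near-minimum in expectation
    # single away cell at chance: NLL over b minimized at delta/2
    chance <- data.frame(target_distractor_distance = 60, foil_distance = 10,
                         foil_direction = "away", n_trials = 1000,
                         n_target_chosen = 500)
    bgrid <- seq(0, 10, by = 0.25)
    nll_b <- vapply(bgrid, function(b) {
      negative_loglik(observer_params(bias = b, noise = 9), chance)
    }, numeric(1))
    expect_equal(bgrid[which.min(nll_b)], 5)
    # degenerate probability with discordant counts is flagged infinite
    degen <- data.frame(target_distractor_distance = 30, foil_distance = 10,
                        foil_direction = "away", n_trials = 10,
                        n_target_chosen = 5)
    nll_inf <- negative_loglik(observer_params(bias = 1e6, noise = 1e-4), degen)
    expect_true(is.infinite(nll_inf))
    expect_true(isTRUE(attr(nll_inf, "degenerate")))
  })
})

test_that("free-bias fits nest the zero-bias model", {
  withr::with_seed(4, {
    s <- simulate_summaries(e2_cells(),
                            observer_params(bias = 10, noise = 9), 2000)
    fit_free <- fit_bias_model(s, bias_per_D = FALSE)
    fit_null <- fit_bias_model(s, b_fixed = 0)
    expect_gte(fit_free$loglik, fit_null$loglik)
    expect_equal(fit_free$n_params, 2)
    expect_equal(fit_null$n_params, 1)
    expect_true(all(fit_free$predicted$p_hat > 0 & fit_free$predicted$p_hat < 1))
  })
})

test_that("parameter recovery holds across a (bias, noise) grid", {
  withr::with_seed(6, {
    grid <- expand.grid(bias = c(0, 5, 11.5), noise = c(5, 9, 15))
    err <- vapply(seq_len(nrow(grid)), function(i) {
      truth <- observer_params(bias = grid$bias[i], noise = grid$noise[i])
      cells <- e2_cells()
      cells <- cells[cells$target_distractor_distance == 30, ]
      s <- simulate_summaries(cells, truth, n_per_cell = 5000)
      fit <- fit_bias_model(s, bias_per_D = FALSE)
      abs(unname(fit$estimates["bias"]) - grid$bias[i])
    }, numeric(1))
    expect_lt(stats::median(err), 1)
  })
})

test_that("fits are invariant to relabeling the distractor rotation direction", {
  d <- design_experiment("E1", seed = 18)
  s <- simulate_dataset(d, observer_params(bias = 9, noise = 10), seed = 18)
  flipped <- s
  flipped$distractor_direction <-
    c(cw = "ccw", ccw = "cw")[s$distractor_direction]
  f1 <- fit_bias_model(s)
  f2 <- fit_bias_model(flipped)
  expect_equal(f1$estimates, f2$estimates)
})

test_that("model fit and chance-point inference agree at the chance point", {
  expect_equal(infer_bias_from_chance(10), 5)
  expect_equal(infer_bias_from_chance(20), 10)
  expect_equal(infer_bias_from_chance(0), 0)
  expect_error(infer_bias_from_chance(-4), ">= 0")
  withr::with_seed(26, {
    cells <- data.frame(target_distractor_distance = 60,
                        foil_distance = c(10, 20, 60),
                        foil_direction = "away")
    truth <- observer_params(bias = infer_bias_from_chance(10), noise = 9)
    s <- simulate_summaries(cells, truth, n_per_cell = 5000)
    fit <- fit_bias_model(s, bias_per_D = FALSE)
    expect_lt(abs(unname(fit$estimates["bias"]) - 5), 1)
  })
})

test_that("the free-vs-zero bias likelihood ratio is chi-square calibrated", {
  withr::with_seed(123, {
    cells <- data.frame(target_distractor_distance = 30,
                        foil_distance = c(10, 20, 60),
                        foil_direction = "away")
    truth <- observer_params(bias = 0, noise = 9)
    lr <- replicate(300, {
      s <- simulate_summaries(cells, truth, n_per_cell = 200)
      f1 <- fit_bias_model(s, bias_per_D = FALSE, grid_sigma = seq(4, 20, 2))
      f0 <- fit_bias_model(s, b_fixed = 0, grid_sigma = seq(4, 20, 2))
      max(0, 2 * (f1$loglik - f0$loglik))
    })
    ks <- suppressWarnings(stats::ks.test(lr, stats::pchisq, df = 1))
    expect_gt(ks$p.value, 0.01)
  })
})
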