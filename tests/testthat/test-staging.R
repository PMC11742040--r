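test_that("generator matrix matches the hand-written bidiagonal form", {
  plan <- stage_plan(c("A", "B"), substates = 1, rate_class = 1)
  expect_equal(build_generator(plan, 2),
               matrix(c(-2, 0, 2, 0), 2, 2))
  # K = 3, Erlang shapes (2, 2, 1), distinct rates
  plan3 <- stage_plan(c("A", "B", "C"), substates = c(2, 2),
                      rate_class = c(1, 2))
  Q <- build_generator(plan3, c(1.5, 3))
  by_hand <- matrix(0, 5, 5)
  r <- c(1.5, 1.5, 3, 3, 0)
  diag(by_hand) <- -r
  by_hand[cbind(1:4, 2:5)] <- r[1:4]
  expect_equal(Q, by_hand)
  expect_equal(rowSums(Q), rep(0, 5))
  expect_error(build_generator(plan3, c(1, -1)), "positive")
})

test_that("occupancy matches closed-form Erlang survival and expm", {
  plan <- stage_plan(c("A", "B"), substates = 3, rate_class = 1)
  tt <- seq(0.1, 2, by = 0.1)
  occ <- stage_occupancy(plan, 4, tt)
  surv <- pgamma(tt, shape = 3, rate = 4, lower.tail = FALSE)
  expect_lt(max(abs(occ[, 1] - surv)), 1e-8)
  # independent dense matrix-exponential oracle
  plan3 <- stage_plan(c("A", "B", "C"), substates = c(2, 3),
                      rate_class = c(1, 2))
  Q <- build_generator(plan3, c(1.2, 0.7))
  for (t in c(0.3, 1, 4)) {
    pexp <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))[1, ]
    stage_p <- as.vector(rowsum(pexp, rep(1:3, c(2, 3, 1))))
    expect_lt(max(abs(stage_occupancy(plan3, c(1.2, 0.7), t) - stage_p)),
              1e-8)
  }
})

test_that("occupancy rows are probability vectors and start at stage 1", {
  plan <- stage_plan(paste0("s", 1:5), substates = c(4, 2, 5, 1))
  rates <- c(2, 0.5, 1, 3)
  expect_equal(as.vector(stage_occupancy(plan, rates, 0)),
               c(1, 0, 0, 0, 0))
  occ <- stage_occupancy(plan, rates, seq(0, 12, length.out = 77))
  expect_true(all(occ >= -1e-12))
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-10)
  # single-substate stages with a common rate follow the Poisson counts
  pp <- stage_plan(paste0("s", 1:4), substates = 1,
                   rate_class = c(1, 1, 1))
  lam <- 1.7
  for (t in c(0.4, 1.3)) {
    o <- stage_occupancy(pp, lam, t)
    pois <- c(dpois(0:2, lam * t), ppois(2, lam * t, lower.tail = FALSE))
    expect_lt(max(abs(o - pois)), 1e-8)
  }
  expect_error(stage_occupancy(plan, rates, -0.5), "start time")
})

test_that("log-likelihood sums per-observation log occupancies", {
  plan <- stage_plan(c("a", "b", "c"), substates = c(2, 2))
  rates <- c(1, 0.6)
  expect_identical(
    staging_loglik(plan, rates, data.frame(t = 0, stage = 1)), 0)
  expect_warning(
    ll0 <- staging_loglik(plan, rates, data.frame(t = 0, stage = 2)),
    "zero stage probability")
  expect_lt(ll0, -1e9)
  sim <- simulate_staging_cohort(plan, rates, 50, c(0, 8), seed = 3)
  per_point <- sum(vapply(seq_len(50), function(i) {
    log(stage_occupancy(plan, rates, sim$obs$t[i])[1, sim$obs$stage[i]])
  }, numeric(1)))
  expect_equal(staging_loglik(plan, rates, sim$obs), per_point,
               tolerance = 1e-10)
  expect_message(
    staging_loglik(plan, rates, data.frame(t = c(-1, 2), stage = c(1, 2))),
    "excluded 1")
})

test_that("likelihood is invariant to relabeling of rate classes", {
  obs <- simulate_staging_cohort(
    stage_plan(c("a", "b", "c", "d"), substates = 2), c(1, 0.5, 2),
    80, c(0, 9), seed = 11)$obs
  pl1 <- stage_plan(c("a", "b", "c", "d"), substates = 2,
                    rate_class = c(1, 2, 2))
  pl2 <- stage_plan(c("a", "b", "c", "d"), substates = 2,
                    rate_class = c(2, 1, 1))
  expect_equal(staging_loglik(pl1, c(0.8, 1.6), obs),
               staging_loglik(pl2, c(1.6, 0.8), obs))
})

test_that("stage durations are recovered from a simulated cohort", {
  tru_d <- c(2, 5, 3)
  plan <- stage_plan(paste0("s", 1:4), substates = 5)
  sim <- simulate_staging_cohort(plan, 5 / tru_d, 400, c(0, 10), seed = 7)
  fit <- fit_stage_model(plan, sim$obs, n_restarts = 2)
  expect_lt(max(abs(fit$relative_durations - tru_d / 10)), 0.05)
  expect_equal(sum(fit$relative_durations), 1, tolerance = 1e-12)
  expect_true(all(fit$rates > 0))
})

test_that("relative durations are invariant to a common time rescaling", {
  tru_d <- c(1.5, 4, 2.5)
  plan <- stage_plan(paste0("s", 1:4), substates = 3)
  s1 <- simulate_staging_cohort(plan, 3 / tru_d, 350, c(0, 10), seed = 5)
  s2 <- simulate_staging_cohort(plan, 2 * 3 / tru_d, 350, c(0, 5), seed = 5)
  f1 <- fit_stage_model(plan, s1$obs, n_restarts = 2)
  f2 <- fit_stage_model(plan, s2$obs, n_restarts = 2)
  expect_lt(max(abs(f1$relative_durations - f2$relative_durations)), 0.06)
})

test_that("unidentifiable cohorts are refused", {
  plan <- stage_plan(c("a", "b", "c"), substates = 2)
  expect_error(
    fit_stage_model(plan, data.frame(t = 1:20, stage = 3)),
    "2 distinct stages")
  expect_error(
    fit_stage_model(plan, data.frame(t = 1:20, stage = 1)),
    "2 distinct stages")
})

test_that("longer simulated stages yield larger estimated durations", {
  plan <- stage_plan(c("a", "b", "c"), substates = 5)
  d2 <- c(1, 2, 3.5, 5, 6.5)
  est <- vapply(seq_along(d2), function(i) {
    dur <- c(2, d2[i])
    sim <- simulate_staging_cohort(plan, 5 / dur, 300, c(0, 10),
                                   seed = 100 + i)
    fit_stage_model(plan, sim$obs, n_restarts = 2)$relative_durations[2]
  }, numeric(1))
  expect_gt(cor(d2, est, method = "spearman"), 0.9)
})

test_that("rate-class comparison rejects malformed nesting chains", {
  p1 <- stage_plan(c("a", "b", "c"), substates = 2, rate_class = c(1, 1))
  p2 <- stage_plan(c("a", "b", "c"), substates = 2, rate_class = c(1, 2))
  p2b <- stage_plan(c("a", "b", "c"), substates = 3, rate_class = c(1, 2))
  obs <- simulate_staging_cohort(p2, c(1, 0.5), 120, c(0, 9), seed = 2)$obs
  expect_error(compare_rate_models(obs, list(p2, p1)), "increasing")
  expect_error(compare_rate_models(obs, list(p1, p2b)), "share")
  cmp <- compare_rate_models(obs, list(p1, p2), n_restarts = 2)
  expect_s3_class(cmp, "rate_model_comparison")
  expect_true(all(cmp$lrt$statistic >= 0))
  expect_equal(cmp$lrt$df, 1)
})
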