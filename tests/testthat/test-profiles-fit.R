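test_that("intercept-only NB fit reproduces the closed-form mean", {
  X <- matrix(1, 4, 1, dimnames = list(NULL, "intercept"))
  f <- fit_nb_glm(c(4L, 4L, 4L, 4L), X, rep(1, 4), alpha = 1e-8)
  expect_equal(unname(f$coefficients), log(4), tolerance = 1e-8)
  expect_equal(unname(f$fitted), rep(4, 4), tolerance = 1e-8)
})

test_that("the Poisson limit of the NB fit matches a Poisson GLM", {
  set.seed(21)
  smp <- expand.grid(relative_time = seq(0, 10, length.out = 8),
                     organ = c("lower", "upper"),
                     species = c("spA", "spB"),
                     stringsAsFactors = FALSE)
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  X <- build_design(smp, "species", basis)
  y <- rpois(nrow(smp), 60)
  sf <- exp(runif(nrow(smp), -0.2, 0.2))
  sf <- sf / exp(mean(log(sf)))
  f <- fit_nb_glm(y, X, sf, alpha = 1e-8)
  g <- glm.fit(X, y, family = poisson(), offset = log(sf))
  expect_lt(max(abs(f$coefficients - g$coefficients)), 1e-6)
})

test_that("a simulated complex-model gene's curve is recovered", {
  # deeply sequenced gene with unit library sizes: the log-mean curve
  # should come back nearly exactly
  sim <- simulate_profiles(n_per_class = c(complex = 5),
                           times = seq(0, 10, length.out = 16),
                           dispersion = 0.001,
                           base_log_mean = log(10000), base_log_sd = 0.2,
                           libsize_range = c(1, 1), seed = 31)
  smp <- sim$dataset$samples
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  X <- build_design(smp, "complex", basis)
  sf <- rep(1, nrow(smp))
  for (g in 1:5) {
    f <- fit_nb_glm(sim$dataset$counts[g, ], X, sf, 0.001)
    eta_hat <- drop(X %*% f$coefficients)
    expect_lt(max(abs(eta_hat - sim$mean_log[g, ])), 0.1)
  }
})

test_that("rank-deficient designs are refused with the offending columns", {
  X <- cbind(a = rep(1, 10), b = rep(1, 10))
  expect_error(fit_nb_glm(rpois(10, 5), X, rep(1, 10), 0.1),
               "rank deficient")
})

test_that("dispersion estimation recovers known truth", {
  smp <- expand.grid(relative_time = seq(0, 10, length.out = 8),
                     organ = c("lower", "upper"),
                     species = c("spA", "spB"),
                     stringsAsFactors = FALSE)
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  X <- build_design(smp, "complex", basis)
  sf <- rep(1, nrow(smp))
  # Poisson data: estimate collapses to the floor
  a_pois <- withr::with_seed(5, vapply(1:30, function(i)
    estimate_dispersion(rpois(32, 100), X, sf), numeric(1)))
  expect_lt(median(a_pois), 0.01)
  # strongly overdispersed data: estimate near the generating value
  a_nb <- withr::with_seed(6, vapply(1:200, function(i)
    estimate_dispersion(rnbinom(32, mu = 100, size = 2), X, sf),
    numeric(1)))
  expect_gt(median(a_nb), 0.3)
  expect_lt(median(a_nb), 0.7)
  expect_error(estimate_dispersion(rep(0L, 32), X, sf), "all-zero")
})

test_that("the dispersion trend tracks the generating dispersion", {
  sim <- simulate_profiles(n_per_class = c(simple = 120),
                           dispersion = 0.08, seed = 13)
  smp <- sim$dataset$samples
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  X <- build_design(smp, "complex", basis)
  tr <- dispersion_trend(sim$dataset$counts, X, smp$size_factor)
  expect_true(all(tr > 0.03 & tr < 0.2))
})

test_that("the likelihood-ratio test follows its definition", {
  f_full <- list(log_likelihood = -10, df = 8, alpha = 0.1)
  f_red <- list(log_likelihood = -10, df = 7, alpha = 0.1)
  r <- lrt(f_full, f_red)
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)
  # a statistic of 3.84 on 1 df sits at the 5% point
  f_full$log_likelihood <- f_red$log_likelihood + 3.84 / 2
  expect_equal(lrt(f_full, f_red)$p_value, 0.05, tolerance = 1e-3)
  expect_error(lrt(f_red, f_full), "more free parameters")
  f_full$alpha <- 0.2
  expect_error(lrt(f_full, f_red), "same dispersion")
})

test_that("model nesting is respected by the fitted likelihoods", {
  sim <- simulate_profiles(n_per_class = c(simple = 10, species = 10,
                                           tooth = 10, complex = 10),
                           seed = 8)
  smp <- sim$dataset$samples
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  lv <- list(species = sort(unique(smp$species)),
             organ = sort(unique(smp$organ)))
  Xs <- lapply(stats::setNames(nm = c("simple", "species", "tooth",
                                      "complex")),
               function(cl) build_design(smp, cl, basis, lv))
  sf <- smp$size_factor
  for (g in seq_len(nrow(sim$dataset$counts))) {
    y <- sim$dataset$counts[g, ]
    ll <- vapply(Xs, function(X) fit_nb_glm(y, X, sf, 0.05)$log_likelihood,
                 numeric(1))
    expect_gte(ll["complex"] + 1e-6, ll["species"])
    expect_gte(ll["complex"] + 1e-6, ll["tooth"])
    expect_gte(ll["species"] + 1e-6, ll["simple"])
    expect_gte(ll["tooth"] + 1e-6, ll["simple"])
  }
})

test_that("curve prediction matches the design and a basis oracle", {
  sim <- simulate_profiles(n_per_class = c(complex = 1), seed = 41)
  smp <- sim$dataset$samples
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  lv <- list(species = sort(unique(smp$species)),
             organ = sort(unique(smp$organ)))
  X <- build_design(smp, "complex", basis, lv)
  f <- fit_nb_glm(sim$dataset$counts[1, ], X, smp$size_factor, 0.05)
  # at the sample times of one group, prediction equals design %*% coef
  sel <- smp$species == lv$species[1] & smp$organ == "lower"
  pred <- predict_curve(f, smp$relative_time[sel], lv$species[1], "lower")
  expect_lt(max(abs(pred - drop(X %*% f$coefficients)[sel])), 1e-12)
  # independent basis re-evaluation at random times
  tt <- withr::with_seed(4, runif(100, 0, 10))
  B <- cbind(1, brute_basis(basis, tt))
  idx <- attr(X, "roles")$group == paste(lv$species[1], "lower", sep = ".")
  oracle <- drop(B %*% f$coefficients[idx])
  expect_lt(max(abs(predict_curve(f, tt, lv$species[1], "lower") - oracle)),
            1e-10)
  expect_error(predict_curve(f, tt, "nosuch", "lower"), "absent")
})

test_that("windowed distances behave like a per-point RMS", {
  sim <- simulate_profiles(n_per_class = c(complex = 1), seed = 42)
  smp <- sim$dataset$samples
  basis <- devodrift:::spline_setup(smp$relative_time, spline_config())
  lv <- list(species = sort(unique(smp$species)),
             organ = sort(unique(smp$organ)))
  X <- build_design(smp, "complex", basis, lv)
  f <- fit_nb_glm(sim$dataset$counts[1, ], X, smp$size_factor, 0.05)
  g1 <- list(species = lv$species[1], organ = "lower")
  g2 <- list(species = lv$species[1], organ = "upper")
  # identical curves: copy one group's coefficients onto the other
  roles <- attr(X, "roles")
  i1 <- roles$group == paste(g1$species, g1$organ, sep = ".")
  i2 <- roles$group == paste(g2$species, g2$organ, sep = ".")
  f0 <- f
  f0$coefficients[i2] <- f0$coefficients[i1]
  expect_equal(windowed_distance(f0, g1, g2), rep(0, 10))
  # constant offset: every window distance equals the offset
  fc <- f
  fc$coefficients[i2] <- fc$coefficients[i1]
  fc$coefficients[which(i2)[1]] <- fc$coefficients[which(i1)[1]] + 0.8
  expect_equal(windowed_distance(fc, g1, g2), rep(0.8, 10),
               tolerance = 1e-10)
  # brute-force oracle on the real fit
  tt <- seq(0, 10, length.out = 100)
  d <- predict_curve(f, tt, g1$species, g1$organ) -
    predict_curve(f, tt, g2$species, g2$organ)
  oracle <- vapply(split(d, rep(1:10, each = 10)),
                   function(v) sqrt(sum(v^2) / 10), numeric(1))
  expect_lt(max(abs(windowed_distance(f, g1, g2) - unname(oracle))), 1e-10)
  # symmetry
  expect_equal(windowed_distance(f, g1, g2), windowed_distance(f, g2, g1))
  # a non-complex fit is refused
  fns <- fit_nb_glm(sim$dataset$counts[1, ],
                    build_design(smp, "species", basis, lv),
                    smp$size_factor, 0.05)
  expect_error(windowed_distance(fns, g1, g2), "complex")
})
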