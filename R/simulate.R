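#' @name simulate
#' @title Seeded synthetic-data generators
#' @description Every analysis stage has a matching generator that draws
#'   data with the statistical structure the stage assumes and returns the
#'   ground truth alongside, so recovery can be scored without any real
#'   data.  All generators are pure functions of their arguments and seed:
#'   the global RNG state is left untouched and identical seeds give
#'   identical output.  A global pipeline seed is fanned out to
#'   per-generator streams with [fanout_seed()] so that, e.g., adding
#'   genes to the profile simulation does not shift the staging draws.
NULL

#' Derive independent per-stream seeds from one global seed
#'
#' Linear-congruential scramble of (seed, stream) onto 1..2^31-2.
#'
#' @param seed global integer seed.
#' @param stream stream index (1, 2, ...).
#' @export
fanout_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2 + stream %% 7)) x <- (x * 48271) %% m
  as.integer(1 + (x + 104729 * stream) %% (m - 1))
}

#' Simulate a cross-sectional staged-embryo cohort
#'
#' Draws embryo ages uniformly over a sampling window and, for each, the
#' observed stage from the exact occupancy distribution of the stage
#' model.
#'
#' @param plan a [stage_plan()].
#' @param rates true rates per rate class.
#' @param n number of embryos.
#' @param window sampling window `c(lo, hi)` of relative time.
#' @param seed integer seed.
#' @return list with `obs` (data.frame `t`, `stage`), `truth` (rates,
#'   durations, relative durations).
#' @export
simulate_staging_cohort <- function(plan, rates, n, window, seed = 1L) {
  stopifnot(inherits(plan, "stage_plan"), length(window) == 2)
  if (window[2] <= window[1]) stop("simulate_staging_cohort: empty window")
  if (window[1] < plan$start_time)
    stop("simulate_staging_cohort: window starts before the process origin")
  obs <- withr::with_seed(seed, {
    t <- stats::runif(n, window[1], window[2])
    occ <- stage_occupancy(plan, rates, t)
    cum <- occ %*% upper.tri(diag(plan$K), diag = TRUE)
    u <- stats::runif(n)
    stage <- rowSums(u > cum) + 1L
    data.frame(t = t, stage = pmin(stage, plan$K))
  })
  dur <- plan$substates[-plan$K] / rates[plan$rate_class]
  list(obs = obs,
       truth = list(rates = rates, durations = dur,
                    relative_durations = dur / sum(dur)))
}

#' Simulate an orthologue-paired expression time course
#'
#' Generates NB count series for 2 species x 2 organs under the four
#' profile model classes.  Each gene draws a baseline log-level and a
#' cubic B-spline curve; class-specific coefficient deviations (scaled by
#' `effect_sd`) are added per species, per organ, or per species x organ
#' according to the gene's true class, a per-species baseline offset is
#' applied, and counts are drawn NB with the configured dispersion after
#' scaling by per-sample library sizes.
#'
#' @param n_per_class named integer vector: genes per true class among
#'   `simple`, `species`, `tooth`, `complex`.
#' @param times relative timepoints sampled per species x organ series
#'   (default 8 points spanning the 0-10 window).
#' @param species,organs group labels (2 each).
#' @param effect_size root-mean-square amplitude (natural-log scale,
#'   over the time grid) of each class-specific deviation curve; the
#'   deviation's shape is a random spline but its magnitude is fixed, so
#'   every gene labelled with a class genuinely carries that class's
#'   structure.  0 removes all profile structure.
#' @param base_log_mean,base_log_sd distribution of baseline log
#'   expression.
#' @param species_offset_sd SD of the per-gene species baseline shift.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param libsize_range multiplicative library-size range (log-uniform).
#' @param seed integer seed.
#' @param config a [spline_config()] defining the generating basis.
#' @return list with `dataset` (an [expression_dataset()]), `truth`
#'   (gene, class), `mean_log` (the noiseless log-mean matrix before
#'   library scaling).
#' @export
simulate_profiles <- function(n_per_class = c(simple = 100, species = 100,
                                              tooth = 100, complex = 100),
                              times = seq(0, 10, length.out = 8),
                              species = c("speciesA", "speciesB"),
                              organs = c("lower", "upper"),
                              effect_size = 1, base_log_mean = log(200),
                              base_log_sd = 1, species_offset_sd = 0.5,
                              dispersion = 0.05,
                              libsize_range = c(0.7, 1.4), seed = 1L,
                              config = spline_config()) {
  stopifnot(length(species) == 2, length(organs) == 2)
  if (dispersion < 0) stop("simulate_profiles: negative dispersion")
  classes <- c("simple", "species", "tooth", "complex")
  stopifnot(all(names(n_per_class) %in% classes))
  smp <- expand.grid(relative_time = times, organ = organs,
                     species = species, stringsAsFactors = FALSE)
  smp$sample <- sprintf("s%02d_%s_%s_t%04.1f", seq_len(nrow(smp)),
                        smp$species, smp$organ, smp$relative_time)
  basis <- spline_setup(smp$relative_time, config)
  B <- curve_basis(basis, smp$relative_time)
  nb <- ncol(B)
  cls <- rep(names(n_per_class), n_per_class)
  G <- length(cls)
  is_sp2 <- smp$species == species[2]
  is_og2 <- smp$organ == organs[2]
  sim <- withr::with_seed(seed, {
    lib <- exp(stats::runif(nrow(smp), log(libsize_range[1]),
                            log(libsize_range[2])))
    eta <- matrix(0, G, nrow(smp))
    for (g in seq_len(G)) {
      b0 <- stats::rnorm(nb, 0, 1)
      icpt <- stats::rnorm(1, base_log_mean, base_log_sd)
      off <- stats::rnorm(1, 0, species_offset_sd)
      curve <- icpt + drop(B %*% b0) + off * is_sp2
      dev <- function() {
        d <- drop(B %*% stats::rnorm(nb, 0, 1))
        if (effect_size == 0 || all(d == 0)) return(d * 0)
        d * effect_size / sqrt(mean(d^2))
      }
      curve <- curve + switch(cls[g],
        simple = 0,
        species = dev() * is_sp2,
        tooth = dev() * is_og2,
        complex = dev() * is_sp2 + dev() * is_og2 +
          dev() * (is_sp2 & is_og2))
      eta[g, ] <- curve
    }
    mu <- sweep(exp(eta), 2, lib, "*")
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu,
                     size = if (dispersion == 0) Inf else 1 / dispersion),
      nrow = G)
    list(eta = eta, counts = counts)
  })
  rownames(sim$counts) <- sprintf("g%05d", seq_len(G))
  colnames(sim$counts) <- smp$sample
  list(dataset = expression_dataset(sim$counts, smp),
       truth = data.frame(gene = rownames(sim$counts), class = cls),
       mean_log = sim$eta)
}

#' Simulate two-tissue pure transcriptomes for marker selection
#'
#' NB count tables for two pure tissue compartments: a configurable slice
#' of genes is up-regulated in each tissue at a given log2 fold change,
#' the rest share means.
#'
#' @param n_genes total genes.
#' @param n_marker_each true markers per tissue.
#' @param l2fc true log2 fold change of the markers.
#' @param n_per_tissue samples per tissue.
#' @param base_log_mean,base_log_sd baseline log-mean distribution.
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @return list with `counts_a`, `counts_b` (gene x sample), `truth`
#'   (gene, marker_of).
#' @export
simulate_tissue_counts <- function(n_genes = 2000, n_marker_each = 100,
                                   l2fc = 5, n_per_tissue = 5,
                                   base_log_mean = log(100),
                                   base_log_sd = 1, dispersion = 0.05,
                                   seed = 1L) {
  stopifnot(2 * n_marker_each <= n_genes)
  withr::with_seed(seed, {
    base <- stats::rnorm(n_genes, base_log_mean, base_log_sd)
    marker_of <- rep(c("A", "B", NA), c(n_marker_each, n_marker_each,
                                        n_genes - 2 * n_marker_each))
    shift <- l2fc * log(2)
    mu_a <- exp(base + ifelse(!is.na(marker_of) & marker_of == "A",
                              shift, 0))
    mu_b <- exp(base + ifelse(!is.na(marker_of) & marker_of == "B",
                              shift, 0))
    draw <- function(mu) matrix(
      stats::rnbinom(n_genes * n_per_tissue, mu = rep(mu, n_per_tissue),
                     size = if (dispersion == 0) Inf else 1 / dispersion),
      nrow = n_genes,
      dimnames = list(sprintf("g%05d", seq_len(n_genes)), NULL))
    list(counts_a = draw(mu_a), counts_b = draw(mu_b),
         truth = data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
                            marker_of = marker_of))
  })
}

#' Simulate a bulk mixture of pure-tissue signatures
#'
#' `b = S p` perturbed by multiplicative gamma noise with unit mean and
#' the given coefficient of variation.
#'
#' @param signature marker x tissue signature matrix.
#' @param proportions mixing proportions on the simplex.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed integer seed.
#' @return list with `bulk` (named vector) and `truth` (proportions).
#' @export
simulate_mixture <- function(signature, proportions, noise_cv = 0,
                             seed = 1L) {
  signature <- as.matrix(signature)
  stopifnot(length(proportions) == ncol(signature), noise_cv >= 0)
  if (any(proportions < -1e-12) || abs(sum(proportions) - 1) > 1e-8)
    stop("simulate_mixture: proportions must lie on the simplex")
  b <- drop(signature %*% proportions)
  if (noise_cv > 0) {
    shape <- 1 / noise_cv^2
    b <- withr::with_seed(seed,
      b * stats::rgamma(length(b), shape = shape, rate = shape))
  }
  list(bulk = stats::setNames(b, rownames(signature)),
       truth = proportions)
}

#' Simulate weight-age calibration pairs
#'
#' Weights drawn log-uniformly over a range; ages are a monotone curve of
#' weight plus Gaussian noise.
#'
#' @param curve monotone non-decreasing function weight (mg) -> age (d).
#' @param sigma Gaussian age noise SD in days.
#' @param n number of embryos.
#' @param weight_range range of weights in mg.
#' @param seed integer seed.
#' @return list with `pairs` (data.frame weight, age) and `truth`
#'   (the curve).
#' @export
simulate_weight_age <- function(curve, sigma = 0.1, n = 500,
                                weight_range = c(30, 1000), seed = 1L) {
  stopifnot(is.function(curve), sigma >= 0)
  grid <- seq(weight_range[1], weight_range[2], length.out = 200)
  if (any(diff(curve(grid)) < -1e-10))
    stop("simulate_weight_age: curve is not monotone non-decreasing")
  pairs <- withr::with_seed(seed, {
    w <- exp(stats::runif(n, log(weight_range[1]), log(weight_range[2])))
    data.frame(weight = w, age = curve(w) + stats::rnorm(n, 0, sigma))
  })
  list(pairs = pairs, truth = curve)
}
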