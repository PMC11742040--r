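#' Default synthetic pipeline configuration
#'
#' The preset emulates the rodent study design: a mouse-like staged
#' embryo cohort (9 cusp-patterning stages, 400 embryos sampled uniformly
#' over the 0-10 window), expression time courses of 2 species x 2 organs
#' at 8 timepoints, a weight-to-age calibration set, and a two-tissue
#' bulk mixture.  All sizes are desk-scale and can be overridden by the
#' caller's config.
#'
#' @param seed global seed fanned out to the per-stage generators.
#' @param out_dir output directory.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "devodrift_out") {
  list(
    seed = seed,
    out_dir = out_dir,
    chronology = list(
      n = 500, sigma = 0.1,
      weight_range = c(30, 1000),
      milestones = list(speciesA = c(14.6, 18.0),
                        speciesB = c(12.3, 14.6))),
    staging = list(
      n_stages = 9, substates = 5, n = 400, window = c(0, 10),
      relative_durations = c(0.08, 0.15, 0.12, 0.10, 0.16,
                             0.09, 0.13, 0.17)),
    profiles = list(
      n_per_class = c(simple = 100, species = 100, tooth = 100,
                      complex = 100),
      effect_size = 1, dispersion = 0.05, alpha = 0.05),
    deconvolution = list(
      n_genes = 1200, n_marker_each = 80, l2fc = 5, n_per_tissue = 5,
      proportions = c(0.7, 0.3), noise_cv = 0.2, B = 1000))
}

pipeline_keys <- c("seed", "out_dir", "chronology", "staging", "profiles",
                   "deconvolution", "inputs")

#' Run the full synthetic-data pipeline
#'
#' Executes chronology calibration, stage-duration inference, profile
#' model selection (with coevolution index, per-organ divergence and
#' windowed distances) and tissue deconvolution on seeded synthetic data,
#' writing TSV/JSON results plus a manifest with input checksums to
#' `config$out_dir`.  Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file of the same structure.  Unknown top-level keys
#'   are rejected.
#' @return (invisibly) list of in-memory results; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0)
    stop("run_pipeline: unknown config keys: ",
         paste(unknown, collapse = ", "))
  base <- default_pipeline_config(seed = config$seed %||% 1L)
  cfg <- utils::modifyList(base, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  message("[chronology] calibrating weight-age model")
  res$chronology <- pipeline_chronology(cfg)
  message("[staging] fitting stage durations")
  res$staging <- pipeline_staging(cfg)
  message("[profiles] selecting temporal models")
  res$profiles <- pipeline_profiles(cfg)
  message("[deconvolution] estimating tissue proportions")
  res$deconvolution <- pipeline_deconvolution(cfg)

  write_pipeline_outputs(res, cfg)
  invisible(res)
}

pipeline_chronology <- function(cfg) {
  cc <- cfg$chronology
  curve <- function(w) 8 + 0.35 * w^0.4
  sim <- simulate_weight_age(curve, sigma = cc$sigma, n = cc$n,
                             weight_range = cc$weight_range,
                             seed = fanout_seed(cfg$seed, 1))
  model <- fit_weight_age(sim$pairs, "speciesA")
  pred <- predict_age(model, sim$pairs$weight)
  ms <- cc$milestones[[1]]
  list(model = model,
       mae_vs_truth = stats::median(abs(pred - curve(sim$pairs$weight))),
       relative_times = suppressWarnings(
         to_relative_time(pred, milestones("speciesA", ms[1], ms[2]))))
}

pipeline_staging <- function(cfg) {
  sc <- cfg$staging
  K <- sc$n_stages
  plan <- stage_plan(paste0("stage", seq_len(K)), substates = sc$substates)
  dur <- sc$relative_durations * diff(sc$window)
  rates <- plan$substates[-K] / dur
  sim <- simulate_staging_cohort(plan, rates, sc$n, sc$window,
                                 seed = fanout_seed(cfg$seed, 2))
  fit <- fit_stage_model(plan, sim$obs)
  list(fit = fit, truth = sim$truth,
       max_abs_error = max(abs(fit$relative_durations -
                                 sim$truth$relative_durations)))
}

pipeline_profiles <- function(cfg) {
  pc <- cfg$profiles
  sim <- simulate_profiles(n_per_class = unlist(pc$n_per_class),
                           effect_size = pc$effect_size,
                           dispersion = pc$dispersion,
                           seed = fanout_seed(cfg$seed, 3))
  sel <- select_profile_model(sim$dataset, alpha = pc$alpha)
  coev <- coevolution_index(sel)
  div <- divergence_per_organ(sim$dataset, "lower", alpha = pc$alpha)
  # windowed distances of the upper-vs-lower contrast within species A,
  # over genes truly of class complex
  cxg <- utils::head(which(sim$truth$class == "complex"), 25)
  smp <- sim$dataset$samples
  basis <- spline_setup(smp$relative_time, spline_config())
  lv <- list(species = sort(unique(smp$species)),
             organ = sort(unique(smp$organ)))
  X <- build_design(smp, "complex", basis, lv)
  dists <- t(vapply(cxg, function(g) {
    y <- sim$dataset$counts[g, ]
    a <- estimate_dispersion(y, X, smp$size_factor)
    f <- fit_nb_glm(y, X, smp$size_factor, a)
    windowed_distance(f, list(species = lv$species[1], organ = "lower"),
                      list(species = lv$species[1], organ = "upper"))
  }, numeric(10)))
  list(selection = sel, truth = sim$truth, coevolution = coev,
       divergence = div, window_distances = dists)
}

pipeline_deconvolution <- function(cfg) {
  dc <- cfg$deconvolution
  tis <- simulate_tissue_counts(n_genes = dc$n_genes,
                                n_marker_each = dc$n_marker_each,
                                l2fc = dc$l2fc,
                                n_per_tissue = dc$n_per_tissue,
                                seed = fanout_seed(cfg$seed, 4))
  sel <- select_markers(tis$counts_a, tis$counts_b)
  markers <- c(sel$markers_a, sel$markers_b)
  S <- build_signature(list(A = tis$counts_a, B = tis$counts_b), markers)
  mix <- simulate_mixture(S, dc$proportions, noise_cv = dc$noise_cv,
                          seed = fanout_seed(cfg$seed, 5))
  boot <- bootstrap_deconvolve(mix$bulk,
                               list(A = tis$counts_a, B = tis$counts_b),
                               markers, B = dc$B,
                               seed = fanout_seed(cfg$seed, 6))
  list(markers = sel, result = boot, truth = mix$truth,
       abs_error = abs(boot$proportions[1] - mix$truth[1]))
}

write_pipeline_outputs <- function(res, cfg) {
  out <- cfg$out_dir
  tsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    tsv(res$profiles$selection$table, "profile_selection.tsv"),
    tsv(res$profiles$divergence$table, "divergence_lower.tsv"),
    tsv(data.frame(window = seq_len(ncol(res$profiles$window_distances)),
                   mean_distance = colMeans(res$profiles$window_distances)),
        "window_distances.tsv"),
    tsv(data.frame(stage = names(res$staging$fit$durations),
                   duration = res$staging$fit$durations,
                   relative = res$staging$fit$relative_durations),
        "stage_durations.tsv"),
    tsv(data.frame(tissue = names(res$deconvolution$result$proportions),
                   proportion = res$deconvolution$result$proportions,
                   ci_lo = res$deconvolution$result$ci[1, ],
                   ci_hi = res$deconvolution$result$ci[2, ]),
        "deconvolution.tsv"))
  summary <- list(
    seed = cfg$seed,
    version = as.character(utils::packageVersion("devodrift")),
    coevolution_index = res$profiles$coevolution$index,
    divergence_proportion = res$profiles$divergence$proportion,
    staging_max_abs_error = res$staging$max_abs_error,
    chronology_mae = res$chronology$mae_vs_truth,
    deconvolution_abs_error = unname(res$deconvolution$abs_error))
  sp <- file.path(out, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    created = "run",
    seed = cfg$seed,
    files = stats::setNames(as.list(unname(tools::md5sum(c(files, sp)))),
                            basename(c(files, sp))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}

#' Plot stage occupancy curves
#'
#' Occupancy probability of each stage over the relative timeline for a
#' fitted or hypothesized stage model.
#'
#' @param plan a [stage_plan()].
#' @param rates rates per rate class.
#' @param window time range to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_occupancy <- function(plan, rates, window = c(0, 10), ...) {
  tt <- seq(window[1], window[2], length.out = 200)
  occ <- stage_occupancy(plan, rates, tt)
  graphics::matplot(tt, occ, type = "l", lty = 1,
                    xlab = "relative developmental time",
                    ylab = "stage occupancy", ...)
  graphics::legend("right", legend = plan$stage_labels, lty = 1,
                   col = seq_len(plan$K), cex = 0.7, bty = "n")
  invisible(occ)
}

#' Plot mean windowed profile distances
#'
#' @param dists gene x window matrix from [windowed_distance()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot_window_distances <- function(dists, ...) {
  m <- colMeans(dists)
  graphics::barplot(m, names.arg = seq_along(m),
                    xlab = "time window", ylab = "mean distance (log scale)",
                    ...)
  invisible(m)
}
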