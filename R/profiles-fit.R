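#' Spline configuration for temporal expression curves
#'
#' Expression time courses are modelled as cubic B-spline curves with 2
#' interior knots placed at the 33/67% quantiles of the observed relative
#' times.  Sparse designs (fewer distinct timepoints than the curve's
#' degrees of freedom, e.g. a 3-timepoint series) automatically reduce to
#' a lower-order polynomial basis with no interior knots.
#'
#' @param degree polynomial degree (default 3).
#' @param interior_knots number of interior knots (default 2).
#' @param boundary boundary knots of the timeline (default `c(0, 10)`).
#' @return A `spline_config`.
#' @export
spline_config <- function(degree = 3, interior_knots = 2,
                          boundary = c(0, 10)) {
  stopifnot(degree >= 1, interior_knots >= 0, length(boundary) == 2,
            boundary[2] > boundary[1])
  structure(list(degree = degree, interior_knots = interior_knots,
                 boundary = boundary,
                 n_basis = degree + interior_knots + 1),
            class = "spline_config")
}

# Freeze knots from observed times; reduce basis for sparse designs so that
# a per-group curve stays identifiable (needs n_distinct >= degree +
# interior_knots + 1 design points per curve).
spline_setup <- function(times, config = spline_config()) {
  ut <- sort(unique(times))
  nd <- length(ut)
  if (nd < 3) stop("spline_setup: need at least 3 distinct timepoints")
  degree <- config$degree
  ik <- config$interior_knots
  while (nd < degree + ik + 1 && ik > 0) ik <- ik - 1
  while (nd < degree + ik + 1 && degree > 1) degree <- degree - 1
  knots <- if (ik > 0)
    unname(stats::quantile(times, seq_len(ik) / (ik + 1), type = 7))
  else numeric(0)
  structure(list(degree = degree, knots = knots,
                 boundary = config$boundary,
                 n_basis = degree + ik + 1), class = "spline_basis")
}

# basis columns excluding the intercept (curve = intercept + these)
curve_basis <- function(basis, t) {
  splines::bs(t, degree = basis$degree,
              knots = basis$knots,
              Boundary.knots = basis$boundary, intercept = FALSE)[, ,
                                                                  drop = FALSE]
}

model_classes <- c("simple", "species", "tooth", "complex",
                   "divergent", "nondivergent")

#' Build the design matrix for a profile model class
#'
#' The four-way family shared by both organs: `simple` fits one curve for
#' all four series plus a species baseline offset; `species` one curve per
#' species; `tooth` one curve per organ plus a species baseline; `complex`
#' one curve per species x organ.  The single-organ divergence family:
#' `nondivergent` is one curve plus a species offset, `divergent` one
#' curve per species.
#'
#' @param samples sample metadata (`species`, `organ`, `relative_time`).
#' @param model_class one of `r paste(model_classes, collapse=", ")`.
#' @param basis a frozen `spline_basis` from `spline_setup()`.
#' @param levels optional list with `species` and `organ` level orders
#'   (taken from the data otherwise); needed so prediction designs align.
#' @param require_groups check that every group the class models is
#'   present (TRUE for fitting; prediction designs evaluate single
#'   groups).
#' @return design matrix with a `roles` attribute mapping columns to
#'   (group, type) where type is `intercept`, `offset` or `basis`.
#' @export
build_design <- function(samples, model_class, basis, levels = NULL,
                         require_groups = TRUE) {
  model_class <- match.arg(model_class, model_classes)
  if (is.null(levels))
    levels <- list(species = sort(unique(samples$species)),
                   organ = sort(unique(samples$organ)))
  if (length(levels$species) != 2)
    stop("build_design: the model family needs exactly 2 species")
  sp <- factor(samples$species, levels = levels$species)
  og <- factor(samples$organ, levels = levels$organ)
  if (anyNA(sp) || anyNA(og))
    stop("build_design: sample metadata outside the declared levels")
  B <- curve_basis(basis, samples$relative_time)
  nb <- ncol(B)
  need_two <- function(f, what) {
    if (require_groups &&
        (nlevels(f) < 2 || !all(levels(f) %in% as.character(f))))
      stop(sprintf("build_design: class '%s' needs both %s present",
                   model_class, what))
  }
  ind <- function(f, l) as.numeric(f == l)

  if (model_class %in% c("simple", "nondivergent")) {
    need_two(sp, "species")
    X <- cbind(intercept = 1,
               species_offset = ind(sp, levels$species[2]),
               B)
    roles <- data.frame(
      group = "all",
      type = c("intercept", "offset", rep("basis", nb)))
  } else if (model_class %in% c("species", "divergent")) {
    need_two(sp, "species")
    X <- do.call(cbind, lapply(levels$species, function(l) {
      cbind(ind(sp, l), ind(sp, l) * B)
    }))
    roles <- data.frame(
      group = rep(levels$species, each = nb + 1),
      type = rep(c("intercept", rep("basis", nb)), 2))
  } else if (model_class == "tooth") {
    need_two(og, "organs")
    need_two(sp, "species")
    X <- cbind(
      do.call(cbind, lapply(levels$organ, function(l) {
        cbind(ind(og, l), ind(og, l) * B)
      })),
      species_offset = ind(sp, levels$species[2]))
    roles <- data.frame(
      group = c(rep(levels$organ, each = nb + 1), "all"),
      type = c(rep(c("intercept", rep("basis", nb)), 2), "offset"))
  } else { # complex
    need_two(sp, "species"); need_two(og, "organs")
    grid <- expand.grid(species = levels$species, organ = levels$organ,
                        stringsAsFactors = FALSE)
    X <- do.call(cbind, lapply(seq_len(nrow(grid)), function(i) {
      g <- ind(sp, grid$species[i]) * ind(og, grid$organ[i])
      cbind(g, g * B)
    }))
    roles <- data.frame(
      group = rep(paste(grid$species, grid$organ, sep = "."),
                  each = nb + 1),
      type = rep(c("intercept", rep("basis", nb)), nrow(grid)))
  }
  colnames(X) <- paste0(roles$group, ".", roles$type,
                        stats::ave(seq_len(nrow(roles)), roles$group,
                                   roles$type, FUN = seq_along))
  attr(X, "roles") <- roles
  attr(X, "model_class") <- model_class
  attr(X, "levels") <- levels
  attr(X, "basis") <- basis
  X
}

#' Per-gene negative-binomial dispersion under the fullest model
#'
#' Dispersion of one gene by Cox-Reid adjusted profile likelihood under
#' the given (fullest) design: the profile log-likelihood is penalized by
#' half the log-determinant of the working information matrix, removing
#' the downward bias of plain ML when the mean model has many
#' coefficients relative to the sample count.  The estimate is floored at
#' 1e-8 and capped at 10, and the same value is reused across all nested
#' fits of the gene so their likelihood-ratio tests share a common
#' nuisance parameter.
#'
#' @param y counts for one gene.
#' @param design design matrix of the fullest model.
#' @param sf size factors.
#' @return scalar dispersion alpha (variance = mu + alpha * mu^2).
#' @export
estimate_dispersion <- function(y, design, sf) {
  if (all(y == 0)) stop("estimate_dispersion: all-zero gene")
  prof <- function(la) {
    alpha <- exp(la)
    f <- try(fit_nb_glm(y, design, sf, alpha), silent = TRUE)
    if (inherits(f, "try-error")) return(1e12)
    w <- f$fitted / (1 + alpha * f$fitted)
    cr <- 0.5 * as.numeric(determinant(crossprod(design * sqrt(w)))$modulus)
    -(f$log_likelihood - cr)
  }
  opt <- stats::optimize(prof, interval = log(c(1e-8, 10)), tol = 1e-3)
  # boundary wins if it beats the interior optimum
  cand <- c(exp(opt$minimum), 1e-8, 10)
  cand[which.min(c(opt$objective, prof(log(1e-8)), prof(log(10))))]
}

#' Dispersion trend by joint estimation in mean-expression bins
#'
#' Genes are binned by mean normalized expression and one dispersion per
#' bin is estimated by maximizing the summed Cox-Reid adjusted profile
#' likelihood of all genes in the bin; the per-gene trend interpolates
#' the bin estimates (log dispersion against log mean).  Joint estimation
#' over tens of genes makes the trend nearly noise-free, which individual
#' per-gene estimates from a few dozen samples are not.
#'
#' @param counts gene x sample count matrix.
#' @param design design matrix of the fullest model.
#' @param sf size factors.
#' @param n_bins maximum number of bins.
#' @param min_per_bin minimum genes per bin.
#' @return per-gene trend dispersions (NA for all-zero genes).
#' @export
dispersion_trend <- function(counts, design, sf, n_bins = 10,
                             min_per_bin = 25) {
  counts <- as.matrix(counts)
  mn <- rowMeans(sweep(counts, 2, sf, "/"))
  usable <- rowSums(counts) > 0
  if (!any(usable)) stop("dispersion_trend: all genes are zero")
  lm10 <- log10(mn + 1e-8)
  nb <- max(1, min(n_bins, floor(sum(usable) / min_per_bin)))
  br <- unique(stats::quantile(lm10[usable], seq(0, 1,
                                                 length.out = nb + 1)))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- cut(lm10, br, labels = FALSE)
  groups <- split(which(usable), bin[usable])
  centers <- vapply(groups, function(i) stats::median(lm10[i]), numeric(1))
  alpha_bin <- vapply(groups, function(idx) {
    obj <- function(la) {
      a <- exp(la)
      s <- 0
      for (g in idx) {
        f <- try(fit_nb_glm(counts[g, ], design, sf, a), silent = TRUE)
        if (inherits(f, "try-error")) next
        w <- f$fitted / (1 + a * f$fitted)
        s <- s - (f$log_likelihood - 0.5 * as.numeric(
          determinant(crossprod(design * sqrt(w)))$modulus))
      }
      s
    }
    exp(stats::optimize(obj, log(c(1e-8, 10)), tol = 1e-3)$minimum)
  }, numeric(1))
  la <- log(pmax(alpha_bin, 1e-8))
  out <- rep(NA_real_, nrow(counts))
  out[usable] <- if (length(centers) == 1) exp(la)
  else exp(stats::approx(centers, la, xout = lm10[usable], rule = 2)$y)
  out
}

#' Moderate per-gene dispersions toward a cohort trend
#'
#' Combines each gene's own Cox-Reid dispersion estimate with the cohort
#' trend on the log scale, weighting the trend by `prior_df`
#' pseudo-observations against the gene's residual degrees of freedom.
#' Individual NB dispersion estimates from a few dozen samples are noisy
#' enough to make fixed-dispersion likelihood-ratio tests
#' anticonservative; borrowing strength across genes restores their
#' calibration while leaving strong per-gene departures visible.
#'
#' @param alphas per-gene dispersion estimates.
#' @param mean_expr per-gene mean normalized expression (trend
#'   covariate, used when no `trend` is supplied).
#' @param resid_df residual degrees of freedom of the fullest fit.
#' @param prior_df weight of the trend, in pseudo-observations; 0
#'   disables moderation.
#' @param trend optional per-gene trend dispersions from
#'   [dispersion_trend()]; otherwise a lowess fit of the raw estimates
#'   over log mean expression is used.
#' @return moderated dispersions, floored at 1e-8 and capped at 10.
#' @export
moderate_dispersions <- function(alphas, mean_expr, resid_df,
                                 prior_df = 200, trend = NULL) {
  stopifnot(length(alphas) == length(mean_expr), prior_df >= 0)
  if (prior_df == 0) return(alphas)
  ok <- !is.na(alphas)
  a <- pmax(alphas[ok], 1e-8)
  if (is.null(trend)) {
    # fallback trend on the natural scale (the raw estimates are roughly
    # unbiased there; averaging logs would bias the trend low)
    trend_ok <- if (sum(ok) >= 50) {
      lo <- stats::lowess(log10(mean_expr[ok] + 1e-8), a, f = 0.5,
                          iter = 0)
      stats::approx(lo$x, lo$y, xout = log10(mean_expr[ok] + 1e-8),
                    rule = 2)$y
    } else rep(mean(a), sum(ok))
  } else {
    stopifnot(length(trend) == length(alphas))
    trend_ok <- trend[ok]
  }
  trend_ok <- pmax(trend_ok, 1e-8)
  w <- prior_df / (prior_df + resid_df)
  out <- alphas
  out[ok] <- pmin(pmax(exp(w * log(trend_ok) + (1 - w) * log(a)), 1e-8),
                  10)
  out
}

#' Fit a negative-binomial GLM with fixed dispersion
#'
#' Log-link NB regression with a log size-factor offset and known
#' dispersion, via iteratively reweighted least squares.  Returns the
#' exact NB log-likelihood used by the nested-model tests.
#'
#' @param y counts for one gene.
#' @param design design matrix (full column rank).
#' @param sf positive size factors.
#' @param alpha NB dispersion (`>= 0`; variance `mu + alpha mu^2`).
#' @return list with `coefficients`, `fitted`, `log_likelihood`, `df`,
#'   `alpha`, and the design attributes needed for prediction.
#' @export
fit_nb_glm <- function(y, design, sf, alpha) {
  stopifnot(all(sf > 0), alpha >= 0)
  qrX <- qr(design)
  if (qrX$rank < ncol(design))
    stop("fit_nb_glm: design is rank deficient (collinear columns: ",
         paste(colnames(design)[-seq_len(qrX$rank)], collapse = ", "), ")")
  theta <- 1 / max(alpha, 1e-10)
  fam <- MASS::negative.binomial(theta = theta)
  off <- log(sf)
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = fam, offset = off,
                   control = stats::glm.control(maxit = 100)))
  if (!fit$converged) {
    # damped restart from a least-squares fit on shifted log counts
    eta0 <- stats::lm.fit(design, log((y + 0.5) / sf))$fitted.values
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = fam, offset = off,
                     etastart = eta0 + off,
                     control = stats::glm.control(maxit = 200)))
    if (!fit$converged)
      stop(sprintf(
        "fit_nb_glm: IRLS failed to converge (deviance %.4g, alpha %.3g)",
        fit$deviance, alpha))
  }
  mu <- fit$fitted.values
  ll <- if (alpha < 1e-8)
    sum(stats::dpois(y, mu, log = TRUE))
  else
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  list(coefficients = fit$coefficients, fitted = mu,
       log_likelihood = ll, df = ncol(design), alpha = alpha,
       model_class = attr(design, "model_class"),
       levels = attr(design, "levels"),
       basis = attr(design, "basis"),
       roles = attr(design, "roles"))
}

#' Likelihood-ratio test between two nested NB fits
#'
#' Statistic `max(0, 2 * (logLik_full - logLik_reduced))` against a
#' chi-square with `df_full - df_reduced` degrees of freedom.  Both fits
#' must come from the same gene with the same fixed dispersion.
#'
#' @param fit_full,fit_reduced results of [fit_nb_glm()].
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  if (fit_full$df <= fit_reduced$df)
    stop("lrt: full model must have more free parameters than the reduced")
  if (!isTRUE(all.equal(fit_full$alpha, fit_reduced$alpha)))
    stop("lrt: fits must share the same dispersion")
  stat <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  df <- fit_full$df - fit_reduced$df
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Predict a fitted temporal curve on the log scale
#'
#' Evaluates the offset-free linear predictor (natural-log scale) of one
#' group's curve at the given relative times.
#'
#' @param fit a [fit_nb_glm()] result carrying design attributes.
#' @param times numeric vector of relative times.
#' @param species,organ the group to evaluate; the organ is ignored by
#'   classes whose curves do not depend on it (and vice versa).
#' @export
predict_curve <- function(fit, times, species = NULL, organ = NULL) {
  if (is.null(fit$model_class))
    stop("predict_curve: fit carries no design information")
  lv <- fit$levels
  if (!is.null(species) && !species %in% lv$species)
    stop("predict_curve: species absent from fit")
  if (!is.null(organ) && !organ %in% lv$organ)
    stop("predict_curve: organ absent from fit")
  nd <- data.frame(
    species = if (is.null(species)) lv$species[1] else species,
    organ = if (is.null(organ)) lv$organ[1] else organ,
    relative_time = times)
  X <- build_design(nd, fit$model_class, fit$basis, levels = lv,
                    require_groups = FALSE)
  drop(X %*% fit$coefficients)
}

#' Windowed distance between two temporal profiles
#'
#' Both curves of a complex-class fit are evaluated at `n_points` equally
#' spaced times on the timeline; the points are split into `n_windows`
#' consecutive windows and each window's distance is the per-point
#' root-mean-square difference (Euclidean norm divided by the square root
#' of the window size), so values are comparable across window widths.
#'
#' @param fit a complex-class [fit_nb_glm()] result.
#' @param group1,group2 lists with `species` and `organ` naming the two
#'   curves.
#' @param n_points,n_windows evaluation grid (defaults 100 points, 10
#'   windows).
#' @param include_baseline if `FALSE`, each curve is centered on its mean
#'   over the evaluation grid before distances are taken, so only the
#'   temporal dynamic is compared.
#' @return numeric vector of `n_windows` distances (log scale).
#' @export
windowed_distance <- function(fit, group1, group2, n_points = 100,
                              n_windows = 10, include_baseline = TRUE) {
  if (!identical(fit$model_class, "complex"))
    stop("windowed_distance: needs a complex-class fit")
  stopifnot(n_points %% n_windows == 0)
  tt <- seq(fit$basis$boundary[1], fit$basis$boundary[2],
            length.out = n_points)
  c1 <- predict_curve(fit, tt, group1$species, group1$organ)
  c2 <- predict_curve(fit, tt, group2$species, group2$organ)
  if (!include_baseline) {
    c1 <- c1 - mean(c1)
    c2 <- c2 - mean(c2)
  }
  d2 <- (c1 - c2)^2
  w <- rep(seq_len(n_windows), each = n_points / n_windows)
  sqrt(as.vector(rowsum(d2, w)) / (n_points / n_windows))
}
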