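#' Calibrate a monotone embryo weight-to-age model
#'
#' Embryo weight is a reliable proxy for developmental age in rodents, so a
#' calibration curve fitted on staged reference embryos can replace direct
#' aging of every sample.  The weight axis is Box-Cox transformed (exponent
#' chosen by profile residual sum of squares over a grid) and a monotone
#' penalized cubic regression spline is fitted on the transformed scale,
#' so that predicted age never decreases with weight.
#'
#' @param pairs data.frame with columns `weight` (mg, > 0) and `age`
#'   (days post-coitum, > 0).
#' @param species species identifier stored with the model.
#' @param k basis dimension of the cubic regression spline.
#' @param lambda_grid Box-Cox exponents profiled over; `0` means log.
#' @return An object of class `chronology_model` with elements `species`,
#'   `transform_lambda`, `training_range` (min/max weight), `rmse`
#'   (in-sample root mean squared error, days) and the fitted smoother.
#' @examples
#' pairs <- data.frame(weight = seq(50, 900, length.out = 60),
#'                     age = 10 + 0.01 * seq(50, 900, length.out = 60))
#' m <- fit_weight_age(pairs, "mouse")
#' predict_age(m, 400)
#' @export
fit_weight_age <- function(pairs, species, k = 10,
                           lambda_grid = seq(-1, 1.5, by = 0.1)) {
  stopifnot(is.data.frame(pairs), all(c("weight", "age") %in% names(pairs)))
  w <- as.numeric(pairs$weight)
  a <- as.numeric(pairs$age)
  if (anyNA(w) || anyNA(a) || any(!is.finite(w)) || any(!is.finite(a)))
    stop("chronology calibration: weights and ages must be finite")
  if (any(w <= 0) || any(a <= 0))
    stop("chronology calibration: weights and ages must be strictly positive")
  if (length(w) < 10)
    stop("chronology calibration: need at least 10 weight-age pairs")
  if (diff(range(w)) <= 0)
    stop("chronology calibration: all weights identical, range is degenerate")

  k <- min(k, length(unique(w)))
  # profile the Box-Cox exponent of the weight axis by in-sample RSS
  fits <- lapply(lambda_grid, function(lam) {
    mono_spline_fit(boxcox_transform(w, lam), a, k = k)
  })
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- which.min(rss)
  fit <- fits[[best]]

  structure(list(
    species = species,
    transform_lambda = lambda_grid[best],
    smoother = fit,
    training_range = range(w),
    n = length(w),
    rmse = sqrt(fit$rss / length(w))
  ), class = "chronology_model")
}

#' @export
print.chronology_model <- function(x, ...) {
  cat(sprintf(
    "chronology model [%s]: n = %d, Box-Cox lambda = %.2f,\n  weight range %.1f-%.1f mg, in-sample RMSE %.3f d\n",
    x$species, x$n, x$transform_lambda,
    x$training_range[1], x$training_range[2], x$rmse))
  invisible(x)
}

boxcox_transform <- function(w, lambda) {
  if (abs(lambda) < 1e-12) log(w) else (w^lambda - 1) / lambda
}

# Monotone increasing penalized cubic regression spline (Wood's pcls recipe):
# smoothing parameter taken from the unconstrained gam fit, then refitted
# under linear monotonicity constraints at the knots.
mono_spline_fit <- function(x, y, k = 10) {
  dat <- data.frame(x = x, y = y)
  g <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat)
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"), data = dat,
                        scale.penalty = TRUE)[[1]]
  con <- mgcv::mono.con(sm$xp, up = TRUE)
  # the identity curve (values = knot positions) satisfies the
  # monotonicity constraints, so it is always a feasible start
  p0 <- sm$xp
  G <- list(X = sm$X, C = matrix(0, 0, 0), sp = g$sp, p = p0, y = y,
            w = rep(1, length(y)), Ain = con$A, bin = con$b,
            S = sm$S, off = 0)
  coefs <- mgcv::pcls(G)
  fitted <- drop(sm$X %*% coefs)
  list(sm = sm, coefs = coefs, rss = sum((y - fitted)^2))
}

mono_spline_predict <- function(fit, x) {
  X <- mgcv::PredictMat(fit$sm, data.frame(x = x))
  drop(X %*% fit$coefs)
}

#' Predict developmental age from embryo weight
#'
#' Deterministic evaluation of a fitted [fit_weight_age()] model.  Weights
#' outside the training range are refused rather than extrapolated: silent
#' extrapolation would bias relative times at the ends of a series.
#'
#' @param model a `chronology_model`.
#' @param weight numeric vector of weights in mg, inside the training range.
#' @return predicted ages in days post-coitum.
#' @export
predict_age <- function(model, weight) {
  stopifnot(inherits(model, "chronology_model"))
  weight <- as.numeric(weight)
  if (anyNA(weight) || any(!is.finite(weight)))
    stop("predict_age: weights must be finite")
  r <- model$training_range
  if (any(weight < r[1]) || any(weight > r[2]))
    stop(sprintf(
      "predict_age: weight outside training range [%.3g, %.3g]; refusing to extrapolate",
      r[1], r[2]))
  mono_spline_predict(model$smoother,
                      boxcox_transform(weight, model$transform_lambda))
}

#' Species milestones anchoring the relative developmental timeline
#'
#' Two morphologically homologous events (an early and a late milestone,
#' e.g. early cap stage and crest formation of the lower molar) anchor the
#' species-specific age axis onto a shared 0-10 relative timeline.
#'
#' @param species species identifier.
#' @param age_at_0 age in days at relative time 0.
#' @param age_at_10 age in days at relative time 10; must exceed `age_at_0`.
#' @export
milestones <- function(species, age_at_0, age_at_10) {
  if (!is.finite(age_at_0) || !is.finite(age_at_10) || age_at_10 <= age_at_0)
    stop("milestones: need age_at_10 > age_at_0, both finite")
  structure(list(species = species, age_at_0 = age_at_0,
                 age_at_10 = age_at_10), class = "milestones")
}

#' Map ages onto the 0-10 relative developmental timeline
#'
#' Affine map sending `age_at_0` to 0 and `age_at_10` to 10:
#' `10 * (age - age_at_0) / (age_at_10 - age_at_0)`.  Values outside
#' \[0, 10\] are returned unchanged but flagged with a warning, since they
#' fall outside the homologous window the milestones define.
#'
#' @param age numeric vector of ages in days.
#' @param milestones a [milestones()] object.
#' @export
to_relative_time <- function(age, milestones) {
  stopifnot(inherits(milestones, "milestones"))
  rt <- (age - milestones$age_at_0) /
    (milestones$age_at_10 - milestones$age_at_0) * 10
  out <- sum(rt < 0 | rt > 10, na.rm = TRUE)
  if (out > 0)
    warning(sprintf("to_relative_time: %d value(s) outside [0, 10]", out))
  rt
}
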