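#' Define an ordered irreversible stage plan
#'
#' Cusp patterning (and comparable morphological sequences) is modelled as a
#' continuous-time Markov chain over an ordered, irreversible sequence of
#' stages.  Each non-terminal stage is expanded into `substates` consecutive
#' exponential sub-states so that its sojourn time follows an Erlang
#' distribution, whose mode is away from zero; the terminal stage is
#' absorbing.  Stages may share transition rates through `rate_class`,
#' giving a family of nested models from one shared rate up to one rate per
#' stage.
#'
#' @param stage_labels ordered character vector of K >= 2 stage names,
#'   e.g. `c("PEK", "1-SEK", ..., "crest")`.
#' @param substates Erlang shape per non-terminal stage (recycled);
#'   integer(s) >= 1.
#' @param rate_class integer vector of length K-1 assigning each
#'   non-terminal stage to a rate class in `1..R`; defaults to one class
#'   per stage (the fullest model).  Every class in `1..R` must be used.
#' @param start_time relative time at which the process enters stage 1.
#' @return A `stage_plan` object.
#' @export
stage_plan <- function(stage_labels, substates = 5, rate_class = NULL,
                       start_time = 0) {
  K <- length(stage_labels)
  if (K < 2) stop("stage_plan: need at least 2 stages")
  if (anyDuplicated(stage_labels)) stop("stage_plan: duplicated stage labels")
  m <- rep_len(as.integer(substates), K - 1)
  if (any(m < 1)) stop("stage_plan: substates must be >= 1")
  if (is.null(rate_class)) rate_class <- seq_len(K - 1)
  rate_class <- as.integer(rate_class)
  if (length(rate_class) != K - 1)
    stop("stage_plan: rate_class must have one entry per non-terminal stage")
  R <- max(rate_class)
  if (!setequal(rate_class, seq_len(R)))
    stop("stage_plan: rate classes must be 1..R with every class used")
  structure(list(stage_labels = stage_labels, K = K,
                 substates = c(m, 1L),  # terminal stage: one absorbing substate
                 rate_class = rate_class, n_classes = R,
                 start_time = start_time), class = "stage_plan")
}

#' @export
print.stage_plan <- function(x, ...) {
  cat(sprintf("stage plan: %d stages (%s), %d rate class(es), start t = %g\n",
              x$K, paste(x$stage_labels, collapse = " > "), x$n_classes,
              x$start_time))
  invisible(x)
}

# per-substate exit rates (length M; 0 for the absorbing terminal substate)
substate_rates <- function(plan, rates) {
  stage_rate <- c(rates[plan$rate_class], 0)
  rep(stage_rate, plan$substates)
}

substate_stage <- function(plan) rep(seq_len(plan$K), plan$substates)

#' Build the generator matrix of a stage plan
#'
#' Pure-birth bidiagonal generator over all Erlang sub-states: sub-state i
#' exits to sub-state i+1 at the rate of its stage's rate class; the final
#' sub-state (terminal stage) is absorbing.  Rows sum to zero.
#'
#' @param plan a [stage_plan()].
#' @param rates positive rate per rate class (length `plan$n_classes`),
#'   per unit relative time.
#' @return M x M generator matrix, M = total number of sub-states.
#' @export
build_generator <- function(plan, rates) {
  stopifnot(inherits(plan, "stage_plan"))
  if (length(rates) != plan$n_classes || any(!is.finite(rates)) ||
      any(rates <= 0))
    stop("build_generator: need one finite positive rate per rate class")
  r <- substate_rates(plan, rates)
  M <- length(r)
  Q <- matrix(0, M, M)
  diag(Q) <- -r
  Q[cbind(seq_len(M - 1), seq_len(M - 1) + 1)] <- r[-M]
  Q
}

#' Stage occupancy probabilities over time
#'
#' Probability of observing each stage at the given relative times,
#' starting from a point mass on the first sub-state at
#' `plan$start_time`.  The transient distribution is computed by
#' uniformization (randomization): the matrix exponential is expanded as a
#' Poisson mixture of powers of the uniformized transition matrix, which
#' is numerically stable (all terms non-negative) and fast for the
#' bidiagonal generators used here.
#'
#' @param plan a [stage_plan()].
#' @param rates positive rate per rate class.
#' @param t numeric vector of relative times, all `>= plan$start_time`.
#' @return matrix `length(t)` x K of stage probabilities (rows sum to 1).
#' @export
stage_occupancy <- function(plan, rates, t) {
  stopifnot(inherits(plan, "stage_plan"))
  if (any(t < plan$start_time - 1e-12))
    stop("stage_occupancy: t before the process start time")
  tau <- pmax(t - plan$start_time, 0)
  r <- substate_rates(plan, rates)
  sub <- occupancy_substates(r, tau)
  grp <- substate_stage(plan)
  out <- t(rowsum(sub, grp))           # times x K
  colnames(out) <- plan$stage_labels
  out
}

# Uniformized transient distribution over substates; returns M x length(tau).
# The power series is truncated once the uniformized chain is (numerically)
# absorbed or the Poisson tail beyond N is negligible; the remaining Poisson
# mass is assigned to the absorbing substate, which the truncated powers
# already equal up to < 1e-15.
occupancy_substates <- function(r, tau, chunk = 4000L) {
  M <- length(r)
  q <- max(r)
  if (q <= 0) stop("occupancy: all rates zero")
  lam_max <- q * max(tau)
  N <- ceiling(lam_max + 10 * sqrt(lam_max + 1) + 25)
  V <- matrix(0, M, min(N, 100000L) + 1)
  v <- c(1, rep(0, M - 1))
  V[, 1] <- v
  stay <- 1 - r / q
  move <- r[-M] / q
  n_eff <- 0L
  while (n_eff < ncol(V) - 1L) {
    v <- stay * v + c(0, move * v[-M])
    n_eff <- n_eff + 1L
    V[, n_eff + 1L] <- v
    if (v[M] > 1 - 1e-15) break
  }
  V <- V[, seq_len(n_eff + 1L), drop = FALSE]
  out <- matrix(0, M, length(tau))
  for (start in seq(1, length(tau), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(tau))
    W <- matrix(stats::dpois(rep(0:n_eff, length(idx)),
                             rep(q * tau[idx], each = n_eff + 1)),
                nrow = n_eff + 1)
    out[, idx] <- V %*% W
    # Poisson mass beyond the truncation: the chain is absorbed there
    out[M, idx] <- out[M, idx] +
      stats::ppois(n_eff, q * tau[idx], lower.tail = FALSE)
  }
  out
}

#' Log-likelihood of staged-embryo observations
#'
#' Cross-sectional likelihood: each embryo contributes the log-probability
#' of its observed stage at its (relative) age.  Observations whose stage
#' has probability zero at their age (staging noise) contribute a floored
#' log-probability of -1e10 instead of -Inf, with a warning.
#'
#' @param plan a [stage_plan()].
#' @param rates positive rate per rate class.
#' @param obs data.frame with columns `t` (relative time) and `stage`
#'   (integer index in `1..K`); rows with `t < start_time` are excluded
#'   with a message.
#' @param warn warn on zero-probability observations (default TRUE).
#' @return scalar log-likelihood.
#' @export
staging_loglik <- function(plan, rates, obs, warn = TRUE) {
  obs <- validate_staging_obs(plan, obs)
  if (nrow(obs) == 0) stop("staging_loglik: no usable observations")
  occ <- stage_occupancy(plan, rates, obs$t)
  p <- occ[cbind(seq_len(nrow(obs)), obs$stage)]
  lp <- log(p)
  bad <- !is.finite(lp)
  if (any(bad)) {
    if (warn)
      warning(sprintf(
        "staging_loglik: %d observation(s) with zero stage probability; floored",
        sum(bad)))
    lp[bad] <- -1e10
  }
  sum(lp)
}

validate_staging_obs <- function(plan, obs) {
  stopifnot(is.data.frame(obs), all(c("t", "stage") %in% names(obs)))
  if (any(obs$stage < 1 | obs$stage > plan$K))
    stop("staging observations: stage index outside 1..K")
  early <- obs$t < plan$start_time
  if (any(early)) {
    message(sprintf("staging: excluded %d observation(s) before start time",
                    sum(early)))
    obs <- obs[!early, , drop = FALSE]
  }
  obs
}

#' Fit stage-transition rates by maximum likelihood
#'
#' Maximizes [staging_loglik()] over log-rates (unconstrained in log space)
#' with L-BFGS-B from several seeded random restarts.  Expected stage
#' durations are `m_k / lambda` of the stage's rate class; relative
#' durations are normalized over non-terminal stages and are the
#' quantity comparable across species (invariant to a common time
#' rescaling).
#'
#' @param plan a [stage_plan()].
#' @param obs staging observations (see [staging_loglik()]).
#' @param init optional initial rates (length `n_classes`).
#' @param n_restarts number of random restarts around the initial guess.
#' @param seed seed for the restart perturbations.
#' @param reltol relative convergence tolerance.
#' @return A `stage_fit` with `rates`, `log_likelihood`, `durations`,
#'   `relative_durations`, `n_obs` and the plan.
#' @export
fit_stage_model <- function(plan, obs, init = NULL, n_restarts = 5,
                            seed = 1L, reltol = 1e-8) {
  obs <- validate_staging_obs(plan, obs)
  if (length(unique(obs$stage)) < 2)
    stop("fit_stage_model: observations must span at least 2 distinct stages (unidentifiable)")
  R <- plan$n_classes
  if (is.null(init)) {
    # moment init: under uniform sampling the fraction of embryos seen in a
    # stage approximates its duration's share of the window
    span <- max(max(obs$t) - plan$start_time, 0.1)
    freq <- tabulate(obs$stage, plan$K)[-plan$K] / nrow(obs)
    d0 <- pmax(freq, 1 / (2 * nrow(obs))) * span
    lam0 <- plan$substates[-plan$K] / d0
    init <- vapply(seq_len(R),
                   function(r) mean(lam0[plan$rate_class == r]), numeric(1))
  }
  # fast path: validation done once, occupancy indexed directly
  tau <- pmax(obs$t - plan$start_time, 0)
  grp <- substate_stage(plan)
  pick <- cbind(obs$stage, seq_along(tau))
  rc <- plan$rate_class
  msub <- plan$substates
  nll <- function(lr) {
    r <- rep(c(exp(lr)[rc], 0), msub)
    p <- rowsum(occupancy_substates(r, tau), grp)[pick]
    lp <- log(p)
    lp[!is.finite(lp)] <- -1e10
    val <- -sum(lp)
    if (!is.finite(val)) 1e12 else val
  }
  starts <- withr::with_seed(seed, {
    c(list(log(init)),
      replicate(n_restarts - 1,
                log(init) + stats::rnorm(R, 0, 1), simplify = FALSE))
  })
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, nll, method = "L-BFGS-B",
                          lower = rep(-10, R), upper = rep(6, R),
                          control = list(factr = reltol / 1e-15,
                                         maxit = 500)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  if (is.null(best))
    stop("fit_stage_model: optimization failed in all restarts")
  rates <- exp(best$par)
  names(rates) <- paste0("class", seq_len(R))
  dur <- plan$substates[-plan$K] / rates[plan$rate_class]
  names(dur) <- plan$stage_labels[-plan$K]
  structure(list(plan = plan, rates = rates,
                 log_likelihood = -best$value, n_obs = nrow(obs),
                 durations = dur,
                 relative_durations = dur / sum(dur),
                 convergence = best$convergence), class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("stage model fit: %d obs, logLik %.2f, %d rate class(es)\n",
              x$n_obs, x$log_likelihood, x$plan$n_classes))
  print(round(rbind(duration = x$durations,
                    relative = x$relative_durations), 3))
  invisible(x)
}

# is `coarse` rate_class a coarsening of `fine`? (classes of fine never split)
is_rate_coarsening <- function(coarse, fine) {
  all(tapply(coarse, fine, function(v) length(unique(v)) == 1))
}

#' Compare nested rate-class models by likelihood-ratio tests
#'
#' Fits each plan of a nesting chain (from fewest to most rate classes) and
#' performs forward LRTs between consecutive models: statistic
#' `2 * (logLik_full - logLik_reduced)` against a chi-square with df equal
#' to the difference in the number of free rates.  The selected model is
#' the simplest one not rejected against the next fuller one at `alpha`.
#'
#' @param obs staging observations.
#' @param plans list of [stage_plan()]s sharing stages and substates,
#'   ordered by increasing number of rate classes; each must be a
#'   coarsening of the next.
#' @param alpha significance level of the forward selection (default 0.05).
#' @param ... passed to [fit_stage_model()].
#' @return A `rate_model_comparison` with `fits`, an `lrt` table and
#'   `selected` (index of the retained plan).
#' @export
compare_rate_models <- function(obs, plans, alpha = 0.05, ...) {
  stopifnot(is.list(plans), length(plans) >= 2)
  R <- vapply(plans, `[[`, integer(1), "n_classes")
  if (is.unsorted(R, strictly = TRUE))
    stop("compare_rate_models: plans must be ordered by increasing rate classes")
  for (i in seq_len(length(plans) - 1)) {
    if (!identical(plans[[i]]$substates, plans[[i + 1]]$substates) ||
        !identical(plans[[i]]$K, plans[[i + 1]]$K))
      stop("compare_rate_models: plans must share stages and substates")
    if (!is_rate_coarsening(plans[[i]]$rate_class, plans[[i + 1]]$rate_class))
      stop("compare_rate_models: plans do not form a nesting chain")
  }
  fits <- lapply(plans, function(p) fit_stage_model(p, obs, ...))
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  stat <- pmax(0, 2 * diff(ll))
  df <- diff(R)
  pval <- stats::pchisq(stat, df, lower.tail = FALSE)
  selected <- length(plans)
  for (i in seq_along(pval)) {
    if (pval[i] >= alpha) { selected <- i; break }
  }
  structure(list(fits = fits,
                 lrt = data.frame(reduced = R[-length(R)], full = R[-1],
                                  statistic = stat, df = df,
                                  p_value = pval),
                 selected = selected, alpha = alpha),
            class = "rate_model_comparison")
}

#' @export
print.rate_model_comparison <- function(x, ...) {
  print(x$lrt)
  cat(sprintf("selected: model %d (%d rate classes)\n", x$selected,
              x$fits[[x$selected]]$plan$n_classes))
  invisible(x)
}
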