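#' Marker-selection configuration
#'
#' Thresholds for calling compartment markers from pure-tissue
#' transcriptomes: BH-adjusted p-value below `alpha` and absolute log2
#' fold change strictly above `lfc_threshold` (3 is appropriate for
#' strongly separated compartments such as epithelium/mesenchyme, 1 for
#' subtler contrasts such as buccal/lingual), with an optional minimum
#' mean normalized expression.
#'
#' @param lfc_threshold positive log2 fold-change bound (strict `>`).
#' @param alpha BH-adjusted significance level.
#' @param min_mean minimum mean normalized expression for eligibility.
#' @export
marker_config <- function(lfc_threshold = 3, alpha = 0.05, min_mean = 0) {
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1, min_mean >= 0)
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 min_mean = min_mean), class = "marker_config")
}

# Wald z and log2FC of the second coefficient of an NB GLM
nb_wald <- function(y, X, sf, alpha) {
  fit <- fit_nb_glm_raw(y, X, sf, alpha)
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  beta <- fit$coefficients[2]
  se <- sqrt(cov[2, 2])
  z <- beta / se
  c(l2fc = beta / log(2), z = z, p = 2 * stats::pnorm(-abs(z)))
}

# glm.fit wrapper returning the qr as well (internal)
fit_nb_glm_raw <- function(y, X, sf, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-10))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = log(sf),
                   control = stats::glm.control(maxit = 100)))
  if (!fit$converged) stop("nb_wald: IRLS did not converge")
  fit
}

#' Select compartment marker genes by differential expression
#'
#' Per-gene NB Wald test of the tissue effect between two pure-tissue
#' count tables (shared median-of-ratios normalization, per-gene ML
#' dispersion).  Markers are genes passing both the adjusted-significance
#' and strict fold-change thresholds, partitioned by the sign of the
#' effect.
#'
#' @param counts_a,counts_b gene x sample count matrices of the two pure
#'   tissues (same genes, >= 2 samples each).
#' @param config a [marker_config()].
#' @return list with `markers_a`, `markers_b` (character vectors, genes
#'   higher in the respective tissue) and the per-gene `table`.
#' @export
select_markers <- function(counts_a, counts_b, config = marker_config()) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2)
    stop("select_markers: need at least 2 samples per tissue")
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stop("select_markers: tissue tables must share gene identifiers")
  counts <- cbind(counts_a, counts_b)
  sf <- size_factors(counts)
  X <- cbind(intercept = 1,
             tissue_b = rep(c(0, 1), c(ncol(counts_a), ncol(counts_b))))
  G <- nrow(counts)
  res <- matrix(NA_real_, G, 3, dimnames = list(rownames(counts),
                                                c("l2fc", "z", "p")))
  norm_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    r <- try({
      a <- estimate_dispersion(y, X, sf)
      res[g, ] <- nb_wald(y, X, sf, a)
    }, silent = TRUE)
  }
  padj <- stats::p.adjust(res[, "p"], method = "BH")
  eligible <- !is.na(padj) & padj < config$alpha &
    abs(res[, "l2fc"]) > config$lfc_threshold &
    norm_mean >= config$min_mean
  tab <- data.frame(gene = rownames(counts), res, padj = padj,
                    mean_norm = norm_mean)
  list(markers_a = rownames(counts)[eligible & res[, "l2fc"] < 0],
       markers_b = rownames(counts)[eligible & res[, "l2fc"] > 0],
       table = tab, config = config)
}

#' Build a signature matrix from pure-tissue transcriptomes
#'
#' Mean normalized expression of each marker gene in each pure tissue.
#'
#' @param counts_list named list of gene x sample count matrices, one per
#'   tissue.
#' @param markers character vector of marker genes (all must be present).
#' @param sf_list optional list of size factors matching `counts_list`;
#'   by default a shared median-of-ratios normalization of the combined
#'   table.
#' @return marker x tissue matrix of mean normalized expression.
#' @export
build_signature <- function(counts_list, markers, sf_list = NULL) {
  stopifnot(is.list(counts_list), length(counts_list) >= 2)
  if (length(markers) == 0) stop("build_signature: empty marker set")
  if (is.null(sf_list)) {
    comb <- do.call(cbind, lapply(counts_list, as.matrix))
    sf <- size_factors(comb)
    idx <- rep(seq_along(counts_list),
               vapply(counts_list, ncol, integer(1)))
    sf_list <- split(sf, idx)
  }
  miss <- setdiff(markers, Reduce(intersect, lapply(counts_list, rownames)))
  if (length(miss) > 0)
    stop("build_signature: markers absent from tables: ",
         paste(utils::head(miss, 5), collapse = ", "))
  S <- do.call(cbind, lapply(seq_along(counts_list), function(i) {
    rowMeans(sweep(as.matrix(counts_list[[i]])[markers, , drop = FALSE],
                   2, sf_list[[i]], "/"))
  }))
  dimnames(S) <- list(markers,
                      names(counts_list) %||% paste0("tissue",
                                                     seq_along(counts_list)))
  S
}

#' Estimate tissue proportions in a bulk sample
#'
#' Solves the simplex-constrained least-squares problem
#' `min || b - S p ||` subject to `p >= 0`, `sum(p) = 1`, on the
#' normalized linear scale (mixtures of counts are linear).  The exact
#' constrained solution is found by enumerating the faces of the simplex
#' and solving the equality-constrained problem on each (exact for the
#' small numbers of compartments used here).  An NNLS-then-renormalize
#' variant is available for comparison; the constrained solution is the
#' authoritative one.
#'
#' @param bulk named numeric vector of normalized bulk expression over
#'   the signature genes.
#' @param signature marker x tissue [build_signature()] matrix.
#' @param method `"qp"` (simplex-constrained, default) or `"nnls"`
#'   (non-negative fit renormalized to sum 1).
#' @return proportion vector over tissues (sums to 1).
#' @export
deconvolve <- function(bulk, signature, method = c("qp", "nnls")) {
  method <- match.arg(method)
  S <- as.matrix(signature)
  b <- as.numeric(bulk)
  stopifnot(length(b) == nrow(S))
  k <- ncol(S)
  # common rescale: the solution is invariant and conditioning improves
  sc <- max(abs(S), 1e-300)
  S <- S / sc; b <- b / sc
  if (qr(S)$rank < k)
    stop("deconvolve: signature columns are collinear")
  if (method == "nnls") {
    p <- solve_nnls(S, b)
    if (sum(p) <= 0) stop("deconvolve: NNLS returned the zero vector")
    return(stats::setNames(p / sum(p), colnames(S)))
  }
  best <- NULL
  for (mask in seq_len(2^k - 1)) {
    F <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    # solve the face's equality-constrained problem by eliminating the
    # sum-to-one constraint
    pf <- if (length(F) == 1) 1 else {
      S1 <- S[, F[1]]
      D <- S[, F[-1], drop = FALSE] - S1
      q <- qr.coef(qr(D), b - S1)
      if (anyNA(q)) next
      c(1 - sum(q), q)
    }
    if (any(pf < -1e-10)) next
    p <- numeric(k); p[F] <- pmax(pf, 0)
    obj <- sum((b - S %*% p)^2)
    if (is.null(best) || obj < best$obj - 1e-12) best <- list(p = p,
                                                              obj = obj)
  }
  if (is.null(best)) stop("deconvolve: no feasible face solution")
  stats::setNames(best$p / sum(best$p), colnames(S))
}

# exact small-k NNLS by face enumeration (KKT-checked via objective)
solve_nnls <- function(S, b) {
  k <- ncol(S)
  best <- list(p = numeric(k), obj = sum(b^2))
  for (mask in seq_len(2^k - 1)) {
    F <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    Sf <- S[, F, drop = FALSE]
    pf <- try(solve(crossprod(Sf), crossprod(Sf, b)), silent = TRUE)
    if (inherits(pf, "try-error") || any(pf < -1e-10)) next
    p <- numeric(k); p[F] <- pmax(pf, 0)
    obj <- sum((b - S %*% p)^2)
    if (obj < best$obj - 1e-12) best <- list(p = p, obj = obj)
  }
  best$p
}

#' Deconvolution with marker-list bootstrap intervals
#'
#' Point proportions from the full marker list, plus percentile intervals
#' (2.5-97.5%) from `B` bootstrap replicates in which the marker list is
#' resampled with replacement and the signature rebuilt, quantifying the
#' sensitivity of the estimate to the marker choice.  Fully reproducible
#' under a fixed seed.
#'
#' @param bulk named normalized bulk expression vector covering the
#'   markers.
#' @param counts_list named list of pure-tissue count matrices (see
#'   [build_signature()]).
#' @param markers character vector of marker genes.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return A `deconvolution_result` with `proportions`, `ci` (2 x tissue
#'   matrix), `B`, `n_markers`.
#' @export
bootstrap_deconvolve <- function(bulk, counts_list, markers, B = 1000,
                                 seed = 1L) {
  if (B < 2) stop("bootstrap_deconvolve: B must be >= 2")
  if (length(markers) < 20)
    warning("bootstrap_deconvolve: fewer than 20 markers; intervals unstable")
  S <- build_signature(counts_list, markers)
  b <- bulk[markers]
  if (anyNA(b)) stop("bootstrap_deconvolve: bulk is missing marker genes")
  point <- deconvolve(b, S)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(length(markers), replace = TRUE)
      p <- try(deconvolve(b[idx], S[idx, , drop = FALSE]), silent = TRUE)
      if (inherits(p, "try-error")) rep(NA_real_, ncol(S)) else p
    }, numeric(ncol(S)))
  })
  ci <- apply(reps, 1, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  structure(list(proportions = point, ci = ci, B = B,
                 n_markers = length(markers),
                 n_failed = sum(colSums(is.na(reps)) > 0)),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution (%d markers, %d bootstraps):\n",
              x$n_markers, x$B))
  out <- rbind(estimate = x$proportions, x$ci)
  print(round(out, 4))
  invisible(x)
}
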