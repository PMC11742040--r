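#' Assemble an orthologue-paired expression dataset
#'
#' Container for a gene x sample count matrix (rows paired 1:1 across
#' species) with per-sample metadata on the shared relative timeline.
#' Size factors are computed by median-of-ratios if not supplied, and are
#' always rescaled to geometric mean 1 so that offsets are comparable
#' across model fits.
#'
#' @param counts integer matrix, genes x samples, non-negative.
#' @param samples data.frame with one row per column of `counts` and
#'   columns `species`, `organ`, `relative_time` (on the 0-10 scale) and
#'   optionally `size_factor`.
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(counts))
  need <- c("species", "organ", "relative_time")
  if (!all(need %in% names(samples)))
    stop("expression_dataset: samples needs columns ",
         paste(need, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("expression_dataset: counts must be non-negative integers")
  for (sp in unique(samples$species)) {
    for (og in unique(samples$organ)) {
      sel <- samples$species == sp & samples$organ == og
      if (any(sel) && length(unique(samples$relative_time[sel])) < 3)
        stop(sprintf(
          "expression_dataset: fewer than 3 distinct timepoints for %s/%s",
          sp, og))
    }
  }
  if (is.null(samples$size_factor)) {
    samples$size_factor <- size_factors(counts)
  } else {
    gm <- exp(mean(log(samples$size_factor)))
    if (abs(gm - 1) > 1e-8)
      stop("expression_dataset: size factors must have geometric mean 1")
  }
  structure(list(counts = counts, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression dataset: %d genes x %d samples (%s | %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$species), collapse = "/"),
              paste(unique(x$samples$organ), collapse = "/")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed by the median-of-ratios
#' method (each sample's counts against the per-gene geometric mean),
#' rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix with at least 2 samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("size_factors: need at least 2 samples")
  if (!any(rowSums(counts > 0) == ncol(counts)))
    stop("size_factors: no gene is positive in all samples")
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  unname(sf / exp(mean(log(sf))))
}
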