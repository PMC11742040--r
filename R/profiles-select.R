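#' Classify temporal expression profiles across species and organs
#'
#' Per gene, fits the four nested NB-spline models (simple, species,
#' tooth, complex), computes four likelihood-ratio tests — t1: species vs
#' simple; t2: tooth vs simple; t3: complex vs tooth; t4: complex vs
#' species — BH-adjusts each test family across genes, and assigns a model
#' class by a bottom-up decision tree:
#'
#' * neither t1 nor t2 significant: `simple`;
#' * t1 only: `species`, escalated to `complex` if t4 is significant;
#' * t2 only: `tooth`, escalated to `complex` if t3 is significant;
#' * both t1 and t2: the better-fitting of the two two-curve models,
#'   escalated to `complex` when that model's own complex test (t4 for
#'   species, t3 for tooth) is significant.
#'
#' Significance is a strict `adjusted p < alpha`.  Genes with total count
#' below `min_total` or failing to fit are excluded (`class = NA`) with
#' their reason recorded.
#'
#' @param dataset an [expression_dataset()] with both species and both
#'   organs.
#' @param config a [spline_config()].
#' @param alpha FDR threshold (default 0.05).
#' @param min_total minimum summed count for a gene to be tested.
#' @param prior_df strength of the cohort dispersion moderation (see
#'   [moderate_dispersions()]); 0 uses raw per-gene estimates.
#' @param keep_fits keep the per-gene complex fit (needed for
#'   [windowed_distance()]); off by default to save memory.
#' @return A `selection_result`: data.frame `table` with per-gene raw and
#'   adjusted p-values of t1-t4, `class`, `informative`, plus `fits` when
#'   requested.
#' @export
select_profile_model <- function(dataset, config = spline_config(),
                                 alpha = 0.05, min_total = 10,
                                 prior_df = 200, keep_fits = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  smp <- dataset$samples
  basis <- spline_setup(smp$relative_time, config)
  levels <- list(species = sort(unique(smp$species)),
                 organ = sort(unique(smp$organ)))
  designs <- lapply(stats::setNames(nm = c("simple", "species", "tooth",
                                           "complex")),
                    function(cl) build_design(smp, cl, basis, levels))
  sf <- smp$size_factor
  G <- nrow(dataset$counts)
  p <- matrix(NA_real_, G, 4, dimnames = list(rownames(dataset$counts),
                                              paste0("t", 1:4)))
  ll <- matrix(NA_real_, G, 4, dimnames = list(NULL, names(designs)))
  reason <- rep(NA_character_, G)
  fits <- if (keep_fits) vector("list", G) else NULL
  # pass 1: per-gene Cox-Reid dispersions, then cohort moderation
  alphas <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- dataset$counts[g, ]
    if (sum(y) < min_total) { reason[g] <- "low_count"; next }
    a <- try(estimate_dispersion(y, designs$complex, sf), silent = TRUE)
    if (inherits(a, "try-error"))
      reason[g] <- sub("\n$", "", attr(a, "condition")$message)
    else alphas[g] <- a
  }
  alphas <- moderate_dispersions(
    alphas, rowMeans(sweep(dataset$counts, 2, sf, "/")),
    resid_df = nrow(smp) - ncol(designs$complex), prior_df = prior_df,
    trend = dispersion_trend(dataset$counts, designs$complex, sf))
  # pass 2: nested fits and tests with the moderated dispersion
  for (g in seq_len(G)) {
    if (is.na(alphas[g])) next
    y <- dataset$counts[g, ]
    res <- try({
      a <- alphas[g]
      f <- lapply(designs, function(X) fit_nb_glm(y, X, sf, a))
      p[g, ] <- c(lrt(f$species, f$simple)$p_value,
                  lrt(f$tooth, f$simple)$p_value,
                  lrt(f$complex, f$tooth)$p_value,
                  lrt(f$complex, f$species)$p_value)
      ll[g, ] <- vapply(f, `[[`, numeric(1), "log_likelihood")
      if (keep_fits) fits[[g]] <- f$complex
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      reason[g] <- sub("\n$", "", attr(res, "condition")$message)
  }
  padj <- apply(p, 2, stats::p.adjust, method = "BH")
  cls <- profile_decision_tree(padj, ll, alpha)
  tab <- data.frame(gene = rownames(dataset$counts) %||%
                      as.character(seq_len(G)),
                    p, stats::setNames(as.data.frame(padj),
                                       paste0("padj_t", 1:4)),
                    class = cls, informative = !is.na(cls) & cls != "simple",
                    excluded_reason = reason)
  n_exc <- sum(!is.na(reason))
  if (n_exc > 0)
    message(sprintf("select_profile_model: %d gene(s) excluded from testing",
                    n_exc))
  structure(list(table = tab, alpha = alpha, basis = basis,
                 levels = levels, fits = fits),
            class = "selection_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

profile_decision_tree <- function(padj, ll, alpha) {
  s1 <- padj[, 1] < alpha
  s2 <- padj[, 2] < alpha
  s3 <- padj[, 3] < alpha
  s4 <- padj[, 4] < alpha
  cls <- rep(NA_character_, nrow(padj))
  ok <- !is.na(s1)
  cls[ok & !s1 & !s2] <- "simple"
  cls[ok & s1 & !s2] <- ifelse(s4[ok & s1 & !s2], "complex", "species")
  cls[ok & !s1 & s2] <- ifelse(s3[ok & !s1 & s2], "complex", "tooth")
  # both t1 and t2: pick the better-fitting two-curve model, then escalate
  # on that model's own complex test (t4 for species, t3 for tooth); the
  # cross test is inflated whenever the two-curve model is misspecified,
  # so it does not enter the escalation
  both <- ok & s1 & s2
  sp_better <- ll[both, "species"] >= ll[both, "tooth"]
  esc <- ifelse(sp_better, s4[both], s3[both])
  cls[both] <- ifelse(esc, "complex", ifelse(sp_better, "species", "tooth"))
  cls
}

#' @export
print.selection_result <- function(x, ...) {
  cat("profile model selection:\n")
  print(table(x$table$class, useNA = "ifany"))
  invisible(x)
}

#' Transcriptome coevolution index
#'
#' Among informative genes (best model not the single shared curve), the
#' fraction whose profiles differ between species but are shared between
#' the two serial organs: `species / (species + tooth + complex)`.  A high
#' index means expression profiles track the species (coevolution of the
#' two organs) rather than the organ.
#'
#' @param selection a [select_profile_model()] result, or a data.frame
#'   with a `class` column.
#' @param gene_sets optional named list of gene identifier vectors; the
#'   index is then also reported per subset.
#' @return list with `index`, the class `counts`, and optionally
#'   `by_set`.
#' @export
coevolution_index <- function(selection, gene_sets = NULL) {
  tab <- if (inherits(selection, "selection_result")) selection$table
         else selection
  stopifnot("class" %in% names(tab))
  idx_of <- function(t) {
    n <- c(species = sum(t$class == "species", na.rm = TRUE),
           tooth = sum(t$class == "tooth", na.rm = TRUE),
           complex = sum(t$class == "complex", na.rm = TRUE))
    if (sum(n) == 0)
      stop("coevolution_index: no informative genes")
    unname(n["species"] / sum(n))
  }
  out <- list(index = idx_of(tab),
              counts = table(factor(tab$class,
                                    c("simple", "species", "tooth",
                                      "complex"))))
  if (!is.null(gene_sets))
    out$by_set <- vapply(gene_sets, function(gs)
      idx_of(tab[tab$gene %in% gs, , drop = FALSE]), numeric(1))
  out
}

#' Per-organ divergence of temporal profiles between species
#'
#' Within one organ, tests each gene's divergent model (one curve per
#' species) against the non-divergent model (a single shared curve with a
#' species baseline offset) by LRT, BH-adjusted across genes.  Returns
#' per-gene flags and the proportion of divergent genes among tested
#' genes.
#'
#' @param dataset an [expression_dataset()]; rows of other organs are
#'   dropped.
#' @param organ the organ to analyse.
#' @inheritParams select_profile_model
#' @return list with `table` (gene, p, padj, divergent), `proportion`,
#'   `n_tested`.
#' @export
divergence_per_organ <- function(dataset, organ, config = spline_config(),
                                 alpha = 0.05, min_total = 10,
                                 prior_df = 200) {
  stopifnot(inherits(dataset, "expression_dataset"))
  keep <- dataset$samples$organ == organ
  if (!any(keep)) stop("divergence_per_organ: organ absent from dataset")
  smp <- dataset$samples[keep, , drop = FALSE]
  counts <- dataset$counts[, keep, drop = FALSE]
  if (length(unique(smp$species)) < 2)
    stop("divergence_per_organ: need both species for the organ")
  basis <- spline_setup(smp$relative_time, config)
  levels <- list(species = sort(unique(smp$species)),
                 organ = unique(smp$organ))
  Xdiv <- build_design(smp, "divergent", basis, levels)
  Xnon <- build_design(smp, "nondivergent", basis, levels)
  sf <- smp$size_factor / exp(mean(log(smp$size_factor)))
  G <- nrow(counts)
  alphas <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (sum(y) < min_total) next
    a <- try(estimate_dispersion(y, Xdiv, sf), silent = TRUE)
    if (!inherits(a, "try-error")) alphas[g] <- a
  }
  alphas <- moderate_dispersions(
    alphas, rowMeans(sweep(counts, 2, sf, "/")),
    resid_df = nrow(smp) - ncol(Xdiv), prior_df = prior_df,
    trend = dispersion_trend(counts, Xdiv, sf))
  p <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    if (is.na(alphas[g])) next
    y <- counts[g, ]
    res <- try({
      p[g] <- lrt(fit_nb_glm(y, Xdiv, sf, alphas[g]),
                  fit_nb_glm(y, Xnon, sf, alphas[g]))$p_value
    }, silent = TRUE)
  }
  padj <- stats::p.adjust(p, method = "BH")
  divergent <- !is.na(padj) & padj < alpha
  tested <- !is.na(p)
  list(table = data.frame(gene = rownames(counts) %||%
                            as.character(seq_len(G)),
                          p_value = p, padj = padj,
                          divergent = ifelse(tested, divergent, NA)),
       proportion = sum(divergent) / sum(tested),
       n_tested = sum(tested), organ = organ)
}

#' Two-sided test comparing two divergence proportions
#'
#' Standard two-proportion z-test (chi-square without continuity
#' correction) for whether the fraction of divergent genes differs
#' between two organs or datasets.
#'
#' @param p1,p2 observed proportions.
#' @param n1,n2 numbers of tested genes.
#' @return list with `statistic` (z), `p_value`, and the counts used.
#' @export
compare_divergence_proportions <- function(p1, n1, p2, n2) {
  if (n1 <= 0 || n2 <= 0)
    stop("compare_divergence_proportions: zero denominator")
  x1 <- round(p1 * n1); x2 <- round(p2 * n2)
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (x1 / n1 - x2 / n2) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       counts = c(x1 = x1, n1 = n1, x2 = x2, n2 = n2))
}

#' Variance decomposition of normalized counts by experimental factors
#'
#' PCA on log-scale normalized counts (samples as observations), followed
#' by a between-group analysis of the component scores: for each factor,
#' the share of each component's variance explained by group membership,
#' plus an overall share weighted by the components' eigenvalues.
#'
#' @param counts gene x sample count matrix.
#' @param factors data.frame of factor labels, one row per sample.
#' @param sf optional size factors (median-of-ratios by default).
#' @param n_components number of components retained.
#' @return list with `shares` (factor x component), `overall` per factor,
#'   and `var_explained` per component.
#' @export
variance_decomposition <- function(counts, factors, sf = NULL,
                                   n_components = 5) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(factors), nrow(factors) == ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  lx <- t(log2(sweep(counts, 2, sf, "/") + 1))
  if (all(apply(lx, 2, stats::sd) == 0))
    stop("variance_decomposition: constant matrix")
  pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x), sum(pc$sdev > 1e-10))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev[seq_len(k)]^2
  shares <- t(vapply(names(factors), function(f) {
    gr <- factor(factors[[f]])
    if (nlevels(gr) < 2)
      stop("variance_decomposition: factor ", f, " has fewer than 2 groups")
    apply(scores, 2, function(s) {
      gm <- tapply(s, gr, mean)
      sum(tabulate(gr) * (gm - mean(s))^2) / sum((s - mean(s))^2)
    })
  }, numeric(k)))
  list(shares = shares,
       overall = drop(shares %*% (ev / sum(ev))),
       var_explained = ev / sum(pc$sdev^2))
}
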