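# Shared fixture builders for the test suite.  All randomness is seeded at
# the call site so fixtures are reproducible.

# tiny cross-species dataset with explicit per-group mean curves (log scale)
make_counts_dataset <- function(eta_fun, times = seq(0, 10, length.out = 8),
                                species = c("spA", "spB"),
                                organs = c("lower", "upper"),
                                dispersion = 0.05, n_genes = 1,
                                seed = 1) {
  smp <- expand.grid(relative_time = times, organ = organs,
                     species = species, stringsAsFactors = FALSE)
  smp$sample <- sprintf("s%02d", seq_len(nrow(smp)))
  counts <- withr::with_seed(seed, {
    t(vapply(seq_len(n_genes), function(g) {
      mu <- exp(eta_fun(smp))
      stats::rnbinom(nrow(smp), mu = mu, size = 1 / dispersion)
    }, numeric(nrow(smp))))
  })
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- smp$sample
  expression_dataset(counts, smp)
}

# brute-force median-of-ratios, written independently of the package path
brute_size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  keep <- is.finite(logg)
  sf <- apply(counts, 2, function(cnt)
    exp(stats::median((log(cnt) - logg)[keep & cnt > 0])))
  sf / exp(mean(log(sf)))
}

# spline basis evaluated from first principles for prediction oracles
brute_basis <- function(basis, t) {
  splines::bs(t, degree = basis$degree, knots = basis$knots,
              Boundary.knots = basis$boundary, intercept = FALSE)
}
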