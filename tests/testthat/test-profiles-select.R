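test_that("the decision tree maps test outcomes to classes", {
  tree <- devodrift:::profile_decision_tree
  mk <- function(t1, t2, t3, t4) matrix(c(t1, t2, t3, t4), 1)
  ll <- matrix(c(-10, -5, -6, -1), 1,
               dimnames = list(NULL, c("simple", "species", "tooth",
                                       "complex")))
  a <- 0.05
  expect_equal(tree(mk(0.5, 0.5, 0.001, 0.001), ll, a), "simple")
  expect_equal(tree(mk(0.001, 0.5, 0.5, 0.5), ll, a), "species")
  expect_equal(tree(mk(0.001, 0.5, 0.001, 0.01), ll, a), "complex")
  expect_equal(tree(mk(0.5, 0.001, 0.5, 0.5), ll, a), "tooth")
  expect_equal(tree(mk(0.5, 0.001, 0.01, 0.5), ll, a), "complex")
  # both significant: better two-curve model decides, then its own test
  expect_equal(tree(mk(0.001, 0.001, 0.5, 0.5), ll, a), "species")
  ll2 <- ll; ll2[1, "tooth"] <- -4
  expect_equal(tree(mk(0.001, 0.001, 0.5, 0.5), ll2, a), "tooth")
  expect_equal(tree(mk(0.001, 0.001, 0.5, 0.01), ll, a), "complex")
  # the boundary p = alpha is not significant (strict <)
  expect_equal(tree(mk(0.05, 0.05, 0.5, 0.5), ll, a), "simple")
})

test_that("genes generated under the species model are recognized", {
  sim <- simulate_profiles(n_per_class = c(species = 60, simple = 60),
                           seed = 19)
  sel <- select_profile_model(sim$dataset)
  m <- merge(sel$table, sim$truth, by = "gene")
  sp <- m$class.y == "species"
  expect_gte(mean(m$class.x[sp] == "species"), 0.85)
  expect_lte(mean(m$class.x[sp] == "complex"), 0.05)
  expect_gte(mean(m$class.x[!sp] == "simple"), 0.9)
})

test_that("low-count genes are excluded with a recorded reason", {
  sim <- simulate_profiles(n_per_class = c(simple = 30), seed = 23)
  sim$dataset$counts[3, ] <- 0L
  sim$dataset$counts[7, ] <- rep(c(0L, 1L), 16)[seq_len(32)] * 0L
  sim$dataset$counts[7, 1] <- 5L
  expect_message(sel <- select_profile_model(sim$dataset), "excluded")
  expect_true(is.na(sel$table$class[3]))
  expect_identical(sel$table$excluded_reason[3], "low_count")
  expect_false(sel$table$informative[3])
})

test_that("adjusted p-values dominate raw p-values per family", {
  sim <- simulate_profiles(n_per_class = c(simple = 40, species = 40),
                           seed = 29)
  sel <- select_profile_model(sim$dataset)
  for (i in 1:4) {
    raw <- sel$table[[paste0("t", i)]]
    adj <- sel$table[[paste0("padj_t", i)]]
    ok <- !is.na(raw)
    expect_true(all(adj[ok] >= raw[ok] - 1e-12))
    # BH is order-preserving
    expect_false(is.unsorted(adj[ok][order(raw[ok])]))
  }
})

test_that("coevolution index equals the class-count ratio", {
  tab <- data.frame(class = rep(c("species", "tooth", "complex"),
                                c(740, 100, 160)))
  expect_equal(coevolution_index(tab)$index, 0.74)
  expect_equal(coevolution_index(
    data.frame(class = rep(c("tooth", "complex"), c(5, 5))))$index, 0)
  expect_error(coevolution_index(data.frame(class = rep("simple", 10))),
               "no informative")
  # random tables match an independent hand computation
  for (seed in 1:5) {
    cls <- withr::with_seed(seed, sample(
      c("simple", "species", "tooth", "complex"), 200, replace = TRUE))
    hand <- sum(cls == "species") /
      sum(cls %in% c("species", "tooth", "complex"))
    expect_identical(coevolution_index(data.frame(class = cls))$index,
                     hand)
  }
  # per-subset reporting
  tab$gene <- as.character(seq_len(nrow(tab)))
  out <- coevolution_index(tab, gene_sets = list(first = tab$gene[1:100]))
  expect_equal(unname(out$by_set["first"]), 1)
})

test_that("identical counts in both species are non-divergent with p = 1", {
  times <- seq(0, 10, length.out = 8)
  smp <- expand.grid(relative_time = times, organ = "lower",
                     species = c("spA", "spB"), stringsAsFactors = FALSE)
  y <- withr::with_seed(3, rnbinom(8, mu = 150, size = 20))
  counts <- matrix(rep(y, 2), 1, dimnames = list("g1", NULL))
  counts <- rbind(counts, withr::with_seed(
    4, matrix(rnbinom(40 * 16, mu = 100, size = 20), 40)))
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  ds <- expression_dataset(counts, smp)
  ds$samples$size_factor <- rep(1, 16)
  div <- divergence_per_organ(ds, "lower")
  expect_equal(div$table$p_value[1], 1)
  expect_false(div$table$divergent[1])
})

test_that("divergence testing is calibrated and powered", {
  null_sim <- simulate_profiles(n_per_class = c(simple = 80), seed = 44)
  dn <- divergence_per_organ(null_sim$dataset, "lower")
  expect_lte(dn$proportion, 0.075)
  alt_sim <- simulate_profiles(n_per_class = c(species = 80), seed = 45)
  da <- divergence_per_organ(alt_sim$dataset, "lower")
  expect_gte(da$proportion, 0.9)
  expect_error(divergence_per_organ(null_sim$dataset, "nosuch"), "absent")
})

test_that("two-proportion comparisons match their reference behavior", {
  expect_equal(compare_divergence_proportions(0.3, 100, 0.3, 100)$p_value,
               1)
  expect_lt(compare_divergence_proportions(0.214, 14532, 0.175,
                                           14532)$p_value, 1e-9)
  expect_lt(compare_divergence_proportions(1, 10, 0, 10)$p_value, 1e-4)
  # agrees with the chi-square two-sample proportion test
  pt <- prop.test(c(214, 175), c(1000, 1000), correct = FALSE)
  expect_equal(compare_divergence_proportions(0.214, 1000, 0.175,
                                              1000)$p_value,
               pt$p.value, tolerance = 1e-10)
  expect_error(compare_divergence_proportions(0.5, 0, 0.5, 10), "zero")
})

test_that("variance decomposition attributes constructed separation", {
  base <- withr::with_seed(7, matrix(rnbinom(200 * 6, mu = 100, size = 10),
                                     200, 6))
  # species B up-regulates the first half of the genes 4-fold: a real
  # expression-pattern difference, not a library-size artefact
  shifted <- base
  shifted[1:100, 4:6] <- 4L * shifted[1:100, 4:6]
  fac <- data.frame(species = rep(c("A", "B"), each = 3),
                    noise = rep(c("x", "y"), 3))
  vd <- variance_decomposition(shifted, fac)
  expect_gt(vd$shares["species", 1], 0.95)
  expect_true(all(vd$shares >= -1e-12 & vd$shares <= 1 + 1e-12))
  # permuted labels carry no structure beyond the permutation envelope
  perm <- withr::with_seed(8, replicate(30, {
    f2 <- data.frame(g = sample(fac$species))
    variance_decomposition(shifted, f2)$shares["g", 1]
  }))
  expect_lt(min(perm), vd$shares["species", 1])
  expect_error(variance_decomposition(matrix(5, 4, 4),
                                      data.frame(g = c(1, 1, 2, 2))),
               "constant")
})
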