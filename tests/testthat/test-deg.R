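test_that("size factors follow the median-of-ratios definition", {
  # hand-computed two-gene example: sample B doubles sample A
  m <- matrix(c(4, 8, 16, 32), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf["A"]), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(sf["B"]), sqrt(2), tolerance = 1e-12)
  expect_equal(unname(sf["B"] / sf["A"]), 2, tolerance = 1e-12)

  # symmetry: identical samples get identical factors
  m2 <- cbind(a = c(3, 9, 27), b = c(3, 9, 27))
  expect_equal(unname(diff(size_factors(m2))), 0)

  # permutation invariance over genes
  m3 <- toy_counts()
  expect_equal(size_factors(m3), size_factors(m3[c(3, 1, 4, 2), ]))

  # equivariance: scaling sample j by c_j rescales factor_j by
  # c_j / geomean(c) because every gene's geometric mean absorbs the rest
  m4 <- toy_counts()
  cvec <- c(1, 3, 1, 1)
  m4 <- sweep(m4, 2, cvec, "*")
  expect_equal(size_factors(m4),
               size_factors(toy_counts()) * cvec / prod(cvec)^(1 / 4),
               tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("condition means average normalized counts per group", {
  m <- matrix(c(10, 20, 5, 7), nrow = 1,
              dimnames = list("g1", c("c1", "c2", "t1", "t2")))
  cm <- condition_means(m, rep(1, 4), c("ctrl", "ctrl", "trt", "trt"))
  expect_equal(cm$mean_ctrl, 15)
  expect_equal(cm$mean_trt, 6)

  # doubling counts and factors cancels
  cm2 <- condition_means(2 * m, rep(2, 4), c("ctrl", "ctrl", "trt", "trt"))
  expect_equal(cm2, cm)

  z <- matrix(0, 1, 4, dimnames = list("g0", colnames(m)))
  cmz <- condition_means(z, rep(1, 4), c("ctrl", "ctrl", "trt", "trt"))
  expect_equal(c(cmz$mean_ctrl, cmz$mean_trt), c(0, 0))

  expect_error(condition_means(m, rep(1, 4), c("a", "b", "c", "d")), "two groups")
})

test_that("log2 fold change reproduces the published worked-example table", {
  tab <- utils::read.delim(system.file("extdata", "dna_damage_response_degs.tsv",
                                       package = "degnet"))
  rec <- degnet:::round_half_away(log2_fold_change(tab$mean_ctrl, tab$mean_trt), 2)
  expect_equal(rec, tab$fold_change)
  # spot values
  expect_equal(rec[tab$gene == "ABRAXAS1"], 0.27)
  expect_equal(rec[tab$gene == "CDKN1A"], 0.53)
  expect_equal(rec[tab$gene == "KDM1A"], -0.09)
})

test_that("log2 fold change is antisymmetric and flags undefined ratios", {
  set.seed(1)
  a <- stats::runif(50, 0.1, 1000)
  b <- stats::runif(50, 0.1, 1000)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_equal(log2_fold_change(5, 5), 0)
  expect_true(is.na(log2_fold_change(0, 10)))
  expect_true(is.na(log2_fold_change(10, 0)))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(202)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("Wald test returns p = 1 for identical groups and respects the design", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  grp <- rep(c("ctrl", "trt"), each = 3)
  wt <- nb_wald_test(m, rep(1, 6), grp, dispersion_mode = "gene")
  expect_equal(wt$log2fc, 0)
  expect_equal(wt$pvalue, 1)

  expect_error(nb_wald_test(m[, c(1, 4, 5, 6), drop = FALSE], rep(1, 4),
                            c("ctrl", "trt", "trt", "trt")),
               ">= 2 replicates")
})

test_that("DEG calling controls error rates and recovers planted effects", {
  # global null: false calls are rare — the mean fraction of genes called
  # across seeded runs stays well under 1%
  n_runs <- 60
  frac_called <- vapply(seq_len(n_runs), function(s) {
    sim <- simulate_counts(sim_config(n_genes = 400, n_reps_per_group = 5,
                                      de_fraction = 0, effect_log2 = 0,
                                      dispersion = 0.1,
                                      mean_log_range = c(log(100), log(5000)),
                                      seed = 1000 + s))
    res <- call_degs(sim$counts, sim$samples$group)
    res$n_deg / nrow(res$table)
  }, numeric(1))
  expect_lt(mean(frac_called), 0.01)

  # planted 10% DE at |log2FC| = 2: high recall, FDR under control,
  # direction matches the planted sign
  sim <- simulate_counts(sim_config(n_genes = 2000, n_reps_per_group = 5,
                                    de_fraction = 0.1, effect_log2 = 2,
                                    dispersion = 0.1,
                                    mean_log_range = c(log(100), log(5000)),
                                    seed = 77))
  res <- call_degs(sim$counts, sim$samples$group)
  called <- res$table$gene[res$table$is_deg]
  planted <- sim$truth$de_genes$gene
  expect_gte(mean(planted %in% called), 0.9)            # power
  expect_lte(mean(!called %in% planted), 0.10)          # empirical FDR
  hit <- res$table[res$table$is_deg & res$table$gene %in% planted, ]
  signs <- sign(sim$truth$de_genes$effect_log2[match(hit$gene, planted)])
  expect_true(all(sign(hit$log2fc) == signs))
  expect_equal(res$n_up + res$n_down, res$n_deg)
})

test_that("q-values dominate p-values and DEG calls are threshold-monotone", {
  sim <- simulate_counts(sim_config(n_genes = 500, n_reps_per_group = 3,
                                    de_fraction = 0.1, seed = 5))
  res <- call_degs(sim$counts, sim$samples$group)
  tab <- res$table
  ok <- !is.na(tab$pvalue)
  expect_true(all(tab$qvalue[ok] >= tab$pvalue[ok]))
  n_at <- vapply(c(0.1, 0.05, 0.01, 0.001),
                 function(a) sum(tab$qvalue[ok] <= a), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})
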