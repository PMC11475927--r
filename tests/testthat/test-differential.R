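test_that("paired Wilcoxon follows the exact signed-rank distribution", {
  # all six differences positive, no ties: p = 2/2^6
  expect_equal(paired_wilcoxon(c(3, 4, 5, 6, 7, 8), rep(2, 6)), 2 / 64)

  # identical profiles: p = 1 with a warning, never an error
  expect_warning(p <- paired_wilcoxon(c(2, 2, 2), c(2, 2, 2)), "zero")
  expect_equal(p, 1)

  # zero differences are discarded before ranking
  expect_equal(paired_wilcoxon(c(2, 3, 4, 5, 6, 7, 8), c(2, 2, 2, 2, 2, 2, 2)),
               2 / 64)

  # matches full enumeration of sign assignments on random tie-free data
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    tumor <- round(runif(n, 1, 4), 3)
    normal <- round(runif(n, 1, 4), 3)
    expect_equal(paired_wilcoxon(tumor, normal),
                 oracle_signed_rank_p(tumor - normal))
  }

  expect_error(paired_wilcoxon(1:3, 1:2), "equal-length")
})

test_that("a consistent +1 copy shift is detected at n = 12", {
  set.seed(404)
  hits <- 0
  for (rep in 1:20) {
    normal <- rnorm(12, 2, 0.2)
    tumor <- rnorm(12, 3, 0.2)
    if (paired_wilcoxon(tumor, normal) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("harmonic mean pools p-values toward the smallest", {
  expect_equal(round(harmonic_mean_p(c(0.003, 0.092)), 3), 0.006)
  expect_equal(round(harmonic_mean_p(c(0.497, 0.216, 1)), 3), 0.393)
  expect_equal(harmonic_mean_p(0.42), 0.42)          # identity on singletons

  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(2:6, 1), 0.001, 1)
    hm <- harmonic_mean_p(p)
    expect_gte(hm, min(p))
    expect_lte(hm, max(p))
    expect_lte(hm, mean(p))       # harmonic <= arithmetic
    expect_equal(harmonic_mean_p(rep(0.3, 4)), 0.3)
  }

  expect_error(harmonic_mean_p(numeric(0)), "empty")
  expect_error(harmonic_mean_p(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(harmonic_mean_p(1.2), "\\(0, 1\\]")
})

test_that("Holm adjustment applies step-down factors with a running maximum", {
  p <- c(0.882, 0.006, 0.393, 0.252, 0.475, 0.573, 0.324)
  expect_equal(holm_adjust(p), c(1, 0.042, 1, 1, 1, 1, 1))

  expect_equal(holm_adjust(0.03), 0.03)              # single p unchanged
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))

  set.seed(21)
  for (rep in 1:20) {
    p <- runif(7, 0.001, 1)
    adj <- holm_adjust(p)
    perm <- sample(7)
    # permutation equivariance
    expect_equal(holm_adjust(p[perm])[order(perm)], adj)
    # dominated by Bonferroni, dominates raw p
    expect_true(all(adj <= p.adjust(p, "bonferroni")))
    expect_true(all(adj >= p))
  }
})

test_that("combine_gene_pvalues pools per gene and corrects across genes", {
  long <- tibble::tribble(
    ~gene, ~method_id, ~p,
    "CCND2", "probes", 0.003,
    "CCND2", "panel", 0.092,
    "CDK6", "evagreen", 0.497,
    "CDK6", "probes", 0.216,
    "CDK6", "panel", 1
  )
  res <- combine_gene_pvalues(long)
  expect_equal(res$gene, c("CCND2", "CDK6"))
  expect_equal(res$n_methods, c(2L, 3L))
  expect_equal(round(res$p_pooled, 3), c(0.006, 0.393))
  expect_equal(res$p_adjusted, pmin(1, sort(res$p_pooled) * c(2, 1)),
               tolerance = 1e-12)
})

test_that("differential_table assembles per-method, pooled, and adjusted columns", {
  pats <- sprintf("P%02d", 1:8)
  set.seed(6)
  ds <- cnv_dataset(dplyr::bind_rows(
    quant_rows("m1", "GUP", pats, rnorm(8, 3.5, 0.1), rnorm(8, 2, 0.1)),
    quant_rows("m2", "GUP", pats, rnorm(8, 3.5, 0.1), rnorm(8, 2, 0.1)),
    quant_rows("m1", "GNULL", pats, rnorm(8, 2, 0.1), rnorm(8, 2, 0.1)),
    quant_rows("m2", "GNULL", pats, rnorm(8, 2, 0.1), rnorm(8, 2, 0.1)),
    quant_rows("m1", "GONE", pats, rnorm(8, 2, 0.1), rnorm(8, 2, 0.1))
  ))
  tab <- differential_table(ds)
  expect_equal(tab$gene, c("GNULL", "GONE", "GUP"))
  # GONE measured by one method only: pooled equals that method's p
  gone <- dplyr::filter(tab, gene == "GONE")
  expect_equal(gone$p_pooled, gone$p_m1)
  expect_true(is.na(gone$p_m2))
  expect_equal(gone$n_methods, 1L)
  # invariants: pooled within per-method range, adjusted >= pooled
  per <- attr(tab, "per_method")
  for (g in tab$gene) {
    ps <- per$p[per$gene == g]
    expect_gte(tab$p_pooled[tab$gene == g], min(ps))
    expect_lte(tab$p_pooled[tab$gene == g], max(ps))
  }
  expect_true(all(tab$p_adjusted >= tab$p_pooled))
  # the shifted gene is the clear signal
  expect_lt(tab$p_adjusted[tab$gene == "GUP"], 0.05)
  expect_true(all(dplyr::filter(tab, gene != "GUP")$p_adjusted > 0.05))
})

test_that("an amplified gene wins the adjusted ranking in seeded cohorts", {
  wins <- 0
  for (s in 1:20) {
    probs <- matrix(rep(c(0, 0, 1, 0, 0), 8), ncol = 5, byrow = TRUE)
    probs[1, ] <- c(0, 0, 0, 0, 1)   # first gene amplified (CN 4) everywhere
    sim <- simulate_cohort(
      n_patients = 12, genes = paste0("G", 1:8),
      platforms = list(
        platform_spec("q1", "quantitative", noise_sd = 0.2),
        platform_spec("q2", "quantitative", noise_sd = 0.2)
      ),
      purity = 0.8, cn_probs = probs, seed = 5000 + s
    )
    tab <- differential_table(sim$dataset)
    if (tab$gene[which.min(tab$p_adjusted)] == "G1") wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("rank_correlation reproduces Spearman's rho", {
  expect_equal(rank_correlation(1:5, (1:5)^2)$rho, 1)
  expect_equal(rank_correlation(1:5, rev(1:5))$rho, -1)
  expect_equal(rank_correlation(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_error(rank_correlation(rep(2, 4), 1:4), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})
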