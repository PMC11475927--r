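test_that("the generator is deterministic given a seed", {
  a <- simulate_cohort(n_patients = 5, genes = paste0("G", 1:4), seed = 123)
  b <- simulate_cohort(n_patients = 5, genes = paste0("G", 1:4), seed = 123)
  c <- simulate_cohort(n_patients = 5, genes = paste0("G", 1:4), seed = 124)
  expect_identical(as.data.frame(a$dataset), as.data.frame(b$dataset))
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$dataset), as.data.frame(c$dataset)))
})

test_that("noise-free identity platforms reproduce the latent truth exactly", {
  sim <- simulate_cohort(
    n_patients = 6, genes = paste0("G", 1:5),
    platforms = list(
      platform_spec("q", "quantitative"),
      platform_spec("c1", "categorical"),
      platform_spec("c2", "categorical")
    ),
    purity = 1, shared_caller_noise_sd = 0,
    cn_probs = c(`0` = 0.1, `1` = 0.2, `2` = 0.4, `3` = 0.2, `4` = 0.1),
    seed = 9
  )
  ds <- tibble::as_tibble(sim$dataset)
  truth <- sim$truth

  # quantitative tumor values equal the latent CN at purity 1
  q_tumor <- dplyr::filter(ds, method_id == "q", tissue == "tumor")
  merged <- dplyr::inner_join(q_tumor, truth, by = c("patient_id", "gene"))
  expect_equal(merged$value, as.numeric(merged$tumor_cn))
  # normals are exactly diploid
  q_norm <- dplyr::filter(ds, method_id == "q", tissue == "normal")
  expect_true(all(q_norm$value == 2))

  # categorical callers agree with the discretized truth, and PABAK = 1
  c1 <- dplyr::filter(ds, method_id == "c1", tissue == "tumor")
  merged_c <- dplyr::inner_join(c1, truth, by = c("patient_id", "gene"))
  expect_equal(merged_c$call, discretize_value(merged_c$tumor_cn))
  pm <- pabak_matrix(discretize_dataset(sim$dataset), c("c1:c2", "c1:q"))
  expect_true(all(pm$pabak == 1))

  # and every relative discrepancy is zero for bias-free platforms
  sim2 <- biased_pair_cohort(a = 0, b = 1, seed = 17)
  panel <- quantitative_panel(sim2$dataset, "ref:test")
  expect_equal(panel$d_median, 0)
  expect_equal(panel$d_q3, 0)
})

test_that("truth table has one row per patient x gene with the dilution formula", {
  sim <- simulate_cohort(seed = 55)
  expect_equal(nrow(sim$truth), 13 * 87)

  expect_equal(sim$truth$effective_tumor_cn,
               sim$truth$purity * sim$truth$tumor_cn +
                 (1 - sim$truth$purity) * 2)
  # a diploid gene reads 2 at any purity
  diploid <- dplyr::filter(sim$truth, tumor_cn == 2)
  expect_true(all(diploid$effective_tumor_cn == 2))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  expect_equal(as.data.frame(read_truth(path)), as.data.frame(sim$truth),
               tolerance = 1e-12)
})

test_that("invalid generator configurations are rejected with named fields", {
  expect_error(simulate_cohort(n_patients = 0), "n_patients")
  expect_error(simulate_cohort(purity = 1.5), "purity")
  expect_error(simulate_cohort(cn_probs = c(0.5, 0.5)), "cn_probs")
  expect_error(simulate_cohort(shared_caller_noise_sd = -1),
               "shared_caller_noise_sd")
  expect_error(platform_spec("x", "categorical",
                             misclassification = matrix(1, 2, 2)),
               "row-stochastic")
  expect_error(misclassification_matrix(1), "rate")
})

test_that("more misclassification lowers the expected PABAK", {
  mean_pabak <- function(rate) {
    vals <- vapply(1:5, function(s) {
      sim <- simulate_cohort(
        n_patients = 13, genes = paste0("G", 1:6),
        platforms = list(
          platform_spec("a", "categorical"),
          platform_spec("b", "categorical",
                        misclassification = misclassification_matrix(rate))
        ),
        shared_caller_noise_sd = 0,
        cn_probs = c(`0` = 0.1, `1` = 0.2, `2` = 0.4, `3` = 0.2, `4` = 0.1),
        seed = 700 + s
      )
      pm <- pabak_matrix(sim$dataset, "a:b")
      median(pm$pabak)
    }, 0)
    mean(vals)
  }
  expect_lt(mean_pabak(0.3), mean_pabak(0.1))
  expect_lt(mean_pabak(0.1), mean_pabak(0))
  expect_equal(mean_pabak(0), 1)
})

test_that("injected platform biases are recovered within the 95% CI", {
  covered <- 0
  for (s in 1:20) {
    sim <- simulate_cohort(
      n_patients = 25, genes = "G1",
      platforms = list(
        platform_spec("ref", "quantitative", noise_sd = 0.1),
        platform_spec("test", "quantitative", constant_bias = 0.4,
                      proportional_bias = 1.2, noise_sd = 0.1)
      ),
      cn_probs = c(`0` = 0.1, `1` = 0.2, `2` = 0.4, `3` = 0.2, `4` = 0.1),
      seed = 900 + s
    )
    panel <- quantitative_panel(sim$dataset, "ref:test")
    if (panel$slope_lo <= 1.2 && 1.2 <= panel$slope_hi &&
        panel$intercept_lo <= 0.4 && 0.4 <= panel$intercept_hi) {
      covered <- covered + 1
    }
  }
  expect_gte(covered, 17)
})
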