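# Small in-code dataset builders.

# Quantitative paired tumor/normal rows for one method.
quant_rows <- function(method, gene, patients, tumor, normal) {
  dplyr::bind_rows(
    tibble::tibble(patient_id = patients, tissue = "tumor",
                   method_id = method, gene = gene,
                   value = as.character(tumor),
                   value_kind = "quantitative"),
    tibble::tibble(patient_id = patients, tissue = "normal",
                   method_id = method, gene = gene,
                   value = as.character(normal),
                   value_kind = "quantitative")
  )
}

# Categorical calls for one method over (patients x tissues).
cat_rows <- function(method, gene, patients, tissue, calls) {
  tibble::tibble(patient_id = patients, tissue = tissue,
                 method_id = method, gene = gene,
                 value = calls, value_kind = "categorical")
}

# Two noise-free quantitative platforms y = a + b * x over a spread of
# effective copy numbers (patients differ in purity and latent CN).
biased_pair_cohort <- function(a = 0, b = 1, noise = 0, n_patients = 6,
                               genes = c("GA", "GB", "GC"), seed = 42) {
  simulate_cohort(
    n_patients = n_patients, genes = genes,
    platforms = list(
      platform_spec("ref", "quantitative", noise_sd = noise),
      platform_spec("test", "quantitative", constant_bias = a,
                    proportional_bias = b, noise_sd = noise)
    ),
    cn_probs = c(`0` = 0.1, `1` = 0.2, `2` = 0.4, `3` = 0.2, `4` = 0.1),
    seed = seed
  )
}
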