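#' Default 87-gene copy-number panel
#'
#' Gene symbols used as the default simulated panel: the size and flavor of
#' a commercial targeted cancer CNV assay (oncogenes, tumor suppressors and
#' pathway genes recurrently copy-number altered in solid tumors).
#'
#' @return Character vector of 87 gene symbols.
#' @export
cnv_gene_panel <- function() {
  c(
    "CCND2", "CDK6", "PAX9", "HMGA2", "KDR", "MET", "C8orf4", "CDKN2A",
    "PTEN", "PTPRD",
    "MAGI3", "PDGFRA", "NKX2-1", "CRKL", "BBC3", "BCL2L1", "AR", "CDK4",
    "ERBB2", "BRCA1",
    "MAPK7", "FGFR1", "ITGB4", "PIK3CA", "AKT1", "AKT2", "AKT3", "MYC",
    "MYCN", "MYCL",
    "EGFR", "KRAS", "NRAS", "HRAS", "BRAF", "RAF1", "CCND1", "CCND3",
    "CCNE1", "CDK2",
    "MDM2", "MDM4", "TP53", "RB1", "BRCA2", "ATM", "ATR", "CHEK1",
    "CHEK2", "PALB2",
    "FGFR2", "FGFR3", "FGFR4", "IGF1R", "ERBB3", "ERBB4", "KIT", "FLT3",
    "JAK2", "STAT3",
    "NOTCH1", "NOTCH2", "NOTCH3", "GLI1", "GLI2", "SMO", "PTCH1", "WNT1",
    "CTNNB1", "APC",
    "SMAD4", "TGFBR2", "VEGFA", "HIF1A", "MTOR", "RICTOR", "RPTOR",
    "STK11", "NF1", "NF2",
    "FBXW7", "EZH2", "ARID1A", "SMARCA4", "BCL2", "MCL1", "AURKA"
  )
}

#' Specify a simulated measurement platform
#'
#' A quantitative platform emits
#' `max(0, a + b * effective_cn + N(0, noise_sd))`, where `a` is a constant
#' (additive) bias, `b` a proportional (multiplicative) bias and the
#' Gaussian noise is truncated at zero (copy numbers cannot be negative).
#' A categorical platform (a microarray calling tool) discretizes a shared
#' noisy copy of the effective copy number under the threshold rule and
#' then passes the call through a row-stochastic 3x3 misclassification
#' channel.
#'
#' @param method_id Platform identifier.
#' @param kind `"quantitative"` or `"categorical"`.
#' @param constant_bias,proportional_bias Quantitative bias parameters
#'   (`a`, `b`); defaults 0 and 1 (no bias).
#' @param noise_sd Gaussian noise standard deviation, in copies (>= 0);
#'   quantitative platforms only.
#' @param misclassification 3x3 row-stochastic matrix (rows = true
#'   category, columns = emitted category) for categorical platforms;
#'   identity by default. See [misclassification_matrix()].
#' @return A list of class `platform_spec`.
#' @export
platform_spec <- function(method_id,
                          kind = c("quantitative", "categorical"),
                          constant_bias = 0, proportional_bias = 1,
                          noise_sd = 0, misclassification = NULL) {
  kind <- match.arg(kind)
  problems <- character(0)
  if (!is.character(method_id) || length(method_id) != 1 ||
      !nzchar(method_id)) {
    problems <- c(problems, "method_id must be a non-empty string")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    problems <- c(problems, "noise_sd must be >= 0")
  }
  if (!is.numeric(constant_bias) || !is.finite(constant_bias)) {
    problems <- c(problems, "constant_bias must be finite")
  }
  if (!is.numeric(proportional_bias) || proportional_bias <= 0) {
    problems <- c(problems, "proportional_bias must be > 0")
  }
  if (is.null(misclassification)) misclassification <- diag(3)
  if (!is.matrix(misclassification) ||
      !all(dim(misclassification) == c(3, 3)) ||
      any(misclassification < 0) ||
      any(abs(rowSums(misclassification) - 1) > 1e-8)) {
    problems <- c(problems,
                  "misclassification must be a 3x3 row-stochastic matrix")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid platform_spec field(s): ",
                 paste(problems, collapse = "; "), "."))
  }
  structure(
    list(method_id = method_id, kind = kind,
         constant_bias = constant_bias,
         proportional_bias = proportional_bias,
         noise_sd = noise_sd, misclassification = misclassification),
    class = "platform_spec"
  )
}

#' Symmetric misclassification channel
#'
#' Convenience constructor: each true category is emitted correctly with
#' probability `1 - rate` and flips to each of the two other categories
#' with probability `rate / 2`.
#'
#' @param rate Total misclassification probability per call, in \[0, 1).
#' @return A 3x3 row-stochastic matrix.
#' @export
misclassification_matrix <- function(rate = 0.05) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("rate must lie in [0, 1).")
  }
  m <- matrix(rate / 2, 3, 3)
  diag(m) <- 1 - rate
  dimnames(m) <- list(cn_categories(), cn_categories())
  m
}

#' Default platform roster for the simulator
#'
#' Mirrors a multi-platform CNV benchmarking study: two categorical
#' microarray calling tools that share one latent microarray signal (each
#' with a mild 5% misclassification channel), one quantitative
#' hybridization panel reading systematically high by half a copy, and two
#' quantitative digital-PCR chemistries with near-identity parameters.
#'
#' @return Named list of [platform_spec()] objects.
#' @export
default_platforms <- function() {
  specs <- list(
    platform_spec("microarray_bcftools", "categorical",
                  misclassification = misclassification_matrix(0.05)),
    platform_spec("microarray_cnvpartition", "categorical",
                  misclassification = misclassification_matrix(0.05)),
    platform_spec("nanostring", "quantitative",
                  constant_bias = 0.5, noise_sd = 0.2),
    platform_spec("ddpcr_probes_rpp30", "quantitative", noise_sd = 0.15),
    platform_spec("ddpcr_evagreen_rpp30", "quantitative", noise_sd = 0.15)
  )
  setNames(specs, vapply(specs, `[[`, "", "method_id"))
}

#' Simulate a multi-platform paired tumor/normal copy-number cohort
#'
#' Generates a cohort with known truth. Each patient x gene draws a latent
#' integer tumor copy number from `cn_probs` (normal tissue is diploid,
#' CN = 2, throughout); bulk measurement dilutes the tumor signal linearly
#' by tumor purity, `effective = purity * CN + (1 - purity) * 2`, so a
#' truly diploid gene reads 2 at any purity. Quantitative platforms add
#' their bias and noise (see [platform_spec()]); categorical platforms
#' discretize one shared noisy copy of the effective value (emulating
#' calling tools run on the same raw microarray signal) and then apply
#' their own misclassification channel.
#'
#' All randomness is governed by `seed`; the same seed and configuration
#' reproduce the cohort exactly. The defaults emulate a small clinical
#' benchmarking cohort: 13 patients, an 87-gene panel, purities between
#' 0.5 and 0.9, and a copy-number spectrum with deletions about 1.6x more
#' frequent than amplifications.
#'
#' @param n_patients Number of patients with paired tumor/normal tissue.
#' @param genes Gene panel; [cnv_gene_panel()] by default.
#' @param platforms List of [platform_spec()]s; [default_platforms()] by
#'   default.
#' @param purity Per-patient tumor purity in (0, 1]; scalar, vector of
#'   length `n_patients`, or `NULL` to draw from Uniform(0.5, 0.9).
#' @param cn_probs Probabilities of latent tumor copy numbers 0..4
#'   (recycled over genes), or a `length(genes)` x 5 matrix of per-gene
#'   probabilities; each row must sum to 1.
#' @param shared_caller_noise_sd SD of the noise shared by all categorical
#'   platforms (the common raw-signal error), in copies.
#' @param rule [conversion_rule()] used to discretize the latent signal for
#'   categorical platforms.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List with `dataset` (a [cnv_dataset()]) and `truth` (tibble with
#'   one row per patient x gene: `patient_id`, `gene`, `purity`,
#'   `tumor_cn`, `effective_tumor_cn`).
#' @export
#' @examples
#' sim <- simulate_cohort(n_patients = 4, genes = c("CCND2", "PTEN"),
#'                        seed = 1)
#' sim$dataset
simulate_cohort <- function(n_patients = 13, genes = cnv_gene_panel(),
                            platforms = default_platforms(),
                            purity = NULL,
                            cn_probs = c(`0` = 0.03, `1` = 0.13, `2` = 0.74,
                                         `3` = 0.07, `4` = 0.03),
                            shared_caller_noise_sd = 0.1,
                            rule = conversion_rule(),
                            seed = NULL) {
  problems <- character(0)
  if (!is.numeric(n_patients) || n_patients < 1) {
    problems <- c(problems, "n_patients must be >= 1")
  }
  if (length(genes) < 1) problems <- c(problems, "genes must be non-empty")
  if (length(platforms) < 1) {
    problems <- c(problems, "platforms must be non-empty")
  }
  if (!all(vapply(platforms, inherits, TRUE, "platform_spec"))) {
    problems <- c(problems, "platforms must be platform_spec objects")
  }
  if (!is.null(purity) &&
      (!is.numeric(purity) || any(purity <= 0) || any(purity > 1))) {
    problems <- c(problems, "purity must lie in (0, 1]")
  }
  if (is.matrix(cn_probs)) {
    ok <- nrow(cn_probs) == length(genes) && ncol(cn_probs) == 5 &&
      all(cn_probs >= 0) && all(abs(rowSums(cn_probs) - 1) < 1e-8)
    if (!ok)

      problems <- c(problems,
                    "cn_probs matrix must be length(genes) x 5 with rows summing to 1")
  } else if (!is.numeric(cn_probs) || length(cn_probs) != 5 ||
             any(cn_probs < 0) || abs(sum(cn_probs) - 1) > 1e-8) {
    problems <- c(problems, "cn_probs must be 5 probabilities summing to 1")
  }
  if (!is.numeric(shared_caller_noise_sd) || shared_caller_noise_sd < 0) {
    problems <- c(problems, "shared_caller_noise_sd must be >= 0")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid simulate_cohort configuration: ",
                 paste(problems, collapse = "; "), "."))
  }

  if (!is.null(seed)) withr::local_seed(seed)

  n_patients <- as.integer(n_patients)
  patients <- sprintf("P%02d", seq_len(n_patients))
  n_genes <- length(genes)

  if (is.null(purity)) {
    purity <- runif(n_patients, 0.5, 0.9)
  } else {
    purity <- rep_len(purity, n_patients)
  }

  prob_matrix <- if (is.matrix(cn_probs)) {
    cn_probs
  } else {
    matrix(cn_probs, nrow = n_genes, ncol = 5, byrow = TRUE)
  }

  # latent tumor copy number, drawn gene-by-gene in panel order
  tumor_cn <- matrix(0L, nrow = n_patients, ncol = n_genes,
                     dimnames = list(patients, genes))
  for (g in seq_len(n_genes)) {
    tumor_cn[, g] <- sample(0:4, n_patients, replace = TRUE,
                            prob = prob_matrix[g, ])
  }

  truth <- tidyr::expand_grid(patient_id = patients, gene = genes)
  truth$purity <- purity[match(truth$patient_id, patients)]
  truth$tumor_cn <- as.integer(tumor_cn[cbind(
    match(truth$patient_id, patients), match(truth$gene, genes)
  )])
  truth$effective_tumor_cn <-
    truth$purity * truth$tumor_cn + (1 - truth$purity) * 2

  samples <- dplyr::bind_rows(
    tibble(patient_id = truth$patient_id, gene = truth$gene,
           tissue = "tumor", effective = truth$effective_tumor_cn),
    tibble(patient_id = truth$patient_id, gene = truth$gene,
           tissue = "normal", effective = 2)
  )
  samples <- dplyr::arrange(samples, .data$patient_id, .data$gene,
                            .data$tissue)

  any_categorical <- any(vapply(platforms, `[[`, "", "kind") == "categorical")
  if (any_categorical) {
    shared_signal <- pmax(
      0, samples$effective + rnorm(nrow(samples), 0, shared_caller_noise_sd)
    )
    shared_call <- discretize_value(shared_signal, rule)
  }

  emitted <- purrr::map(platforms, function(sp) {
    if (sp$kind == "quantitative") {
      value <- pmax(0, sp$constant_bias +
                      sp$proportional_bias * samples$effective +
                      rnorm(nrow(samples), 0, sp$noise_sd))
      tibble(patient_id = samples$patient_id, tissue = samples$tissue,
             method_id = sp$method_id, gene = samples$gene,
             value_kind = "quantitative", value = value,
             call = factor(NA_character_, levels = cn_categories(),
                           ordered = TRUE))
    } else {
      observed <- channel_sample(as.integer(shared_call),
                                 sp$misclassification)
      tibble(patient_id = samples$patient_id, tissue = samples$tissue,
             method_id = sp$method_id, gene = samples$gene,
             value_kind = "categorical", value = NA_real_,
             call = factor(cn_categories()[observed],
                           levels = cn_categories(), ordered = TRUE))
    }
  })

  dataset <- cnv_dataset(dplyr::bind_rows(emitted))
  list(dataset = dataset, truth = truth)
}

# sample emitted category indices through a row-stochastic channel
channel_sample <- function(true_idx, channel) {
  u <- runif(length(true_idx))
  cum <- t(apply(channel, 1, cumsum))
  out <- integer(length(true_idx))
  for (i in 1:3) {
    sel <- true_idx == i
    out[sel] <- 1L + findInterval(u[sel], cum[i, ], left.open = TRUE)
  }
  pmin(out, 3L)
}

#' Write the simulated truth table to a TSV file
#'
#' Persists the latent and effective copy numbers so downstream tests can
#' use them as an oracle.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#'
#' @param path Path to the truth TSV.
#' @return Tibble with the truth columns.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    gene = readr::col_character(),
    purity = readr::col_double(),
    tumor_cn = readr::col_integer(),
    effective_tumor_cn = readr::col_double()
  ), progress = FALSE)
}
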