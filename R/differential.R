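#' Paired Wilcoxon signed-rank test for tumor vs normal copy numbers
#'
#' Two-sided signed-rank test on the per-patient differences
#' `tumor - normal`. Zero differences are discarded before ranking (the
#' classic convention). The exact null distribution is used when, after
#' discarding zeros, at most 25 differences remain and their absolute
#' values are free of ties; otherwise the normal approximation with
#' continuity correction is used. If every difference is zero there is no
#' evidence of a shift and `p = 1` is returned with a warning.
#'
#' @param tumor,normal Equal-length numeric vectors of paired measurements
#'   (one entry per patient).
#' @return The two-sided p-value.
#' @export
#' @examples
#' paired_wilcoxon(c(3, 4, 5, 6, 7, 8), c(2, 2, 2, 2, 2, 2))
paired_wilcoxon <- function(tumor, normal) {
  if (!is.numeric(tumor) || !is.numeric(normal) ||
      length(tumor) != length(normal)) {
    abort("tumor and normal must be equal-length numeric vectors.")
  }
  if (length(tumor) < 1) abort("need at least one pair.")
  d <- tumor - normal
  d <- d[d != 0]
  if (length(d) == 0) {
    warn("all paired differences are zero; returning p = 1.")
    return(1)
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Harmonic mean of p-values
#'
#' Pools the p-values obtained for the same hypothesis by different
#' measurement methods into `m / sum(1/p_i)`. The harmonic mean is
#' dominated by the smallest p-value and always lies between the minimum
#' and maximum of its inputs. Methods without data are simply not included
#' (skipped, never imputed).
#'
#' @param p Non-empty numeric vector of p-values in (0, 1].
#' @return The harmonic mean.
#' @export
#' @examples
#' harmonic_mean_p(c(0.003, 0.092))
harmonic_mean_p <- function(p) {
  if (length(p) == 0) abort("empty p-value set.")
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  length(p) / sum(1 / p)
}

#' Holm step-down multiple-testing adjustment
#'
#' Controls the family-wise error rate: the i-th smallest of m p-values is
#' multiplied by (m - i + 1), a running maximum enforces monotonicity, and
#' values are capped at 1. Thin wrapper over [stats::p.adjust()] with the
#' package's domain checks, returning values in the original order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.882, 0.006, 0.393, 0.252, 0.475, 0.573, 0.324))
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "holm")
}

#' Pool per-method p-values per gene and correct across genes
#'
#' Given per-gene, per-method p-values (e.g. from paired tumor-vs-normal
#' Wilcoxon tests), computes each gene's harmonic-mean pooled p over its
#' available methods, then Holm-adjusts the pooled values across the genes.
#' This is the combination step of [differential_table()], exposed
#' separately so published per-method p-values can be pooled directly.
#'
#' @param p_long Tibble with columns `gene`, `method_id`, `p`; a missing
#'   (gene, method) simply has no row.
#' @return Tibble sorted by gene: `gene`, `n_methods`, `p_pooled`,
#'   `p_adjusted`.
#' @export
#' @examples
#' combine_gene_pvalues(tibble::tribble(
#'   ~gene, ~method_id, ~p,
#'   "CCND2", "pcr", 0.003,
#'   "CCND2", "panel", 0.092,
#'   "CDK6", "pcr", 0.497
#' ))
combine_gene_pvalues <- function(p_long) {
  if (!all(c("gene", "method_id", "p") %in% names(p_long))) {
    abort("p_long must have columns gene, method_id, p.")
  }
  pooled <- dplyr::summarise(
    dplyr::group_by(as_tibble(p_long), .data$gene),
    n_methods = dplyr::n(),
    p_pooled = harmonic_mean_p(.data$p),
    .groups = "drop"
  )
  pooled <- dplyr::arrange(pooled, .data$gene)
  pooled$p_adjusted <- holm_adjust(pooled$p_pooled)
  pooled
}

#' Per-gene differential copy-number table
#'
#' For every gene and quantitative method with paired tumor/normal data,
#' runs the paired Wilcoxon test ([paired_wilcoxon()]), pools each gene's
#' per-method p-values by harmonic mean, and Holm-adjusts the pooled values
#' across genes. Genes with no paired data in any method are omitted.
#'
#' @param ds A [cnv_dataset()] or coercible data frame; apply QC first if
#'   desired (see [apply_qc()]).
#' @param genes Genes to test; defaults to all genes with quantitative data.
#' @param methods Quantitative methods to use; defaults to all.
#' @return Tibble of class `cnv_differential`, one row per gene sorted by
#'   gene name: `gene`, `p_pooled`, `p_adjusted`, `n_methods`, plus one
#'   `p_<method>` column per method (`NA` where the method has no paired
#'   data for the gene). The long per-method table is in attribute
#'   `per_method`.
#' @export
differential_table <- function(ds, genes = NULL, methods = NULL) {
  ds <- as_cnv_dataset(ds)
  kinds <- method_kinds(ds)
  quant_methods <- kinds$method_id[kinds$value_kind == "quantitative"]
  methods <- methods %||% sort(quant_methods)
  bad <- setdiff(methods, quant_methods)
  if (length(bad) > 0) {
    abort(paste0("Not quantitative method(s): ", paste(bad, collapse = ", ")))
  }
  genes <- genes %||% sort(unique(
    ds$gene[ds$method_id %in% methods & ds$value_kind == "quantitative"]
  ))

  grid <- tidyr::expand_grid(gene = genes, method_id = methods)
  long <- purrr::pmap(grid, function(gene, method_id) {
    sub <- dplyr::filter(as_tibble(ds),
                         .data$method_id == !!method_id,
                         .data$gene == !!gene)
    if (nrow(sub) == 0) return(NULL)
    pv <- paired_values(ds, method_id, gene)
    if (nrow(pv) == 0) return(NULL)
    tibble(gene = gene, method_id = method_id, n_pairs = nrow(pv),
           p = paired_wilcoxon(pv$tumor, pv$normal))
  })
  long <- dplyr::bind_rows(long)
  if (nrow(long) == 0) {
    abort("no gene has paired tumor/normal data in the requested methods.")
  }

  pooled <- combine_gene_pvalues(long)
  wide <- tidyr::pivot_wider(
    long[, c("gene", "method_id", "p")],
    names_from = "method_id", values_from = "p", names_prefix = "p_"
  )
  out <- dplyr::left_join(pooled, wide, by = "gene")
  out <- dplyr::arrange(out, .data$gene)
  attr(out, "per_method") <- long
  class(out) <- c("cnv_differential", class(out))
  out
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties and a two-sided p-value from
#' the asymptotic t approximation ([stats::cor.test()]); a small cohort
#' descriptive statistic (e.g. per-patient CNV burden vs age).
#'
#' @param a,b Equal-length numeric vectors, length >= 3, neither constant.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
#' @examples
#' rank_correlation(1:4, c(1, 3, 2, 4))
rank_correlation <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    abort("a and b must be equal-length numeric vectors.")
  }
  if (length(a) < 3) abort("need at least 3 observations.")
  if (length(unique(a)) == 1 || length(unique(b)) == 1) {
    abort("constant input; rank correlation undefined.")
  }
  res <- suppressWarnings(
    cor.test(a, b, method = "spearman", exact = FALSE,
             alternative = "two.sided")
  )
  tibble(rho = unname(res$estimate), p_value = res$p.value, n = length(a))
}
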