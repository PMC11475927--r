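#' Normal-tissue median filter for one (method, gene) group
#'
#' An assay whose normal-tissue copy numbers do not center near the diploid
#' value of 2 is unreliable for that gene. The filter computes the median of
#' the quantitative normal-tissue values for a (method, gene) group and
#' keeps the group iff that median lies in `[lower, upper]` (1.5–2.5 by
#' default, boundaries inclusive). Tumor values never influence the
#' decision.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param method_id A quantitative method present in `ds`.
#' @param gene A gene present in `ds`.
#' @param lower,upper Acceptance range for the normal-tissue median.
#' @return One-row tibble: `method_id`, `gene`, `n_normal`, `normal_median`,
#'   `kept`.
#' @export
normal_median_filter <- function(ds, method_id, gene,
                                 lower = 1.5, upper = 2.5) {
  ds <- as_cnv_dataset(ds)
  check_method(ds, method_id, kind = "quantitative")
  check_gene(ds, gene)
  vals <- dplyr::filter(as_tibble(ds),
                        .data$method_id == !!method_id,
                        .data$gene == !!gene,
                        .data$tissue == "normal")$value
  if (length(vals) == 0) {
    abort(paste0("No normal-tissue values for (", method_id, ", ", gene,
                 "); cannot assess the group."))
  }
  med <- median(vals)
  tibble(
    method_id = method_id, gene = gene,
    n_normal = length(vals), normal_median = med,
    kept = med >= lower & med <= upper
  )
}

#' Normal-median QC report over all quantitative (method, gene) groups
#'
#' Applies [normal_median_filter()] to every quantitative (method, gene)
#' group that has at least one normal-tissue measurement. Groups failing
#' the filter should be removed from all downstream analyses (see
#' [apply_qc()]).
#'
#' @inheritParams normal_median_filter
#' @return Tibble with one row per assessed group: `method_id`, `gene`,
#'   `n_normal`, `normal_median`, `kept`.
#' @export
qc_normal_medians <- function(ds, lower = 1.5, upper = 2.5) {
  ds <- as_cnv_dataset(ds)
  tbl <- dplyr::filter(as_tibble(ds),
                       .data$value_kind == "quantitative",
                       .data$tissue == "normal")
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$method_id, .data$gene),
    n_normal = dplyr::n(),
    normal_median = median(.data$value),
    .groups = "drop"
  )
  out$kept <- out$normal_median >= lower & out$normal_median <= upper
  dplyr::arrange(out, .data$method_id, .data$gene)
}

#' Restrict a dataset to QC-passing (method, gene) groups
#'
#' Drops quantitative measurements belonging to groups that failed the
#' normal-median filter; categorical methods and unassessed groups pass
#' through.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param qc A QC report from [qc_normal_medians()] (computed from `ds` if
#'   omitted).
#' @return A filtered [cnv_dataset()].
#' @export
apply_qc <- function(ds, qc = qc_normal_medians(ds)) {
  ds <- as_cnv_dataset(ds)
  dropped <- qc[!qc$kept, c("method_id", "gene")]
  if (nrow(dropped) == 0) return(ds)
  out <- dplyr::anti_join(as_tibble(ds), dropped,
                          by = c("method_id", "gene"))
  cnv_dataset(out)
}

#' Assess a reference-gene configuration from its normal-tissue behavior
#'
#' Quantitative PCR copy numbers are ratios to a reference gene; a reference
#' whose normalized normal-tissue values frequently leave the diploid range
#' is itself copy-number variable (or poorly assayed) and the whole
#' configuration should be dropped. Pools all quantitative normal-tissue
#' values of the named methods and reports the fraction outside
#' `[lower, upper]`.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param methods Character vector of quantitative method ids sharing the
#'   reference-gene configuration under assessment.
#' @param threshold Flagging threshold on the outside fraction, in (0, 1);
#'   default 0.5.
#' @param lower,upper Diploid acceptance range.
#' @return One-row tibble: `n`, `fraction_outside`, `flagged`.
#' @export
assess_reference_config <- function(ds, methods, threshold = 0.5,
                                    lower = 1.5, upper = 2.5) {
  ds <- as_cnv_dataset(ds)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1).")
  }
  for (m in methods) check_method(ds, m, kind = "quantitative")
  pool <- dplyr::filter(as_tibble(ds),
                        .data$method_id %in% methods,
                        .data$tissue == "normal",
                        .data$value_kind == "quantitative")$value
  if (length(pool) == 0) {
    abort("No normal-tissue values in the named methods; empty pool.")
  }
  fraction <- mean(pool < lower | pool > upper)
  tibble(n = length(pool), fraction_outside = fraction,
         flagged = fraction > threshold)
}
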