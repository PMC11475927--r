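#' Per-gene CNV event counts
#'
#' Tallies deletion and amplification calls per gene over the rows of a
#' categorical dataset (typically tumor-tissue calls from one platform),
#' with grand totals and their deletion/amplification ratio.
#'
#' @param ds A categorical [cnv_dataset()] (discretize first if needed);
#'   filter to one method and tissue for per-platform event counts.
#' @param genes Genes to tally; all genes in `ds` by default.
#' @param tissue Tissue whose calls are counted (`"tumor"` by default).
#' @return Tibble of class `cnv_counts`, one row per gene: `gene`,
#'   `n_deletion`, `n_amplification`, `n_calls`. Attribute `totals` (also
#'   via [glance()]) holds the grand totals and the
#'   deletion-to-amplification `ratio` (`NA` when no amplification was
#'   observed).
#' @export
cnv_count_summary <- function(ds, genes = NULL, tissue = "tumor") {
  ds <- as_cnv_dataset(ds)
  tbl <- dplyr::filter(as_tibble(ds),
                       .data$value_kind == "categorical",
                       .data$tissue %in% !!tissue)
  if (!is.null(genes)) tbl <- dplyr::filter(tbl, .data$gene %in% !!genes)
  if (nrow(tbl) == 0) {
    abort("no categorical calls to count for the requested tissue/genes.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$gene),
    n_deletion = sum(.data$call == "deletion"),
    n_amplification = sum(.data$call == "amplification"),
    n_calls = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$gene)
  del <- sum(out$n_deletion)
  amp <- sum(out$n_amplification)
  totals <- tibble(
    deletions = del, amplifications = amp,
    ratio = if (amp > 0) del / amp else NA_real_
  )
  attr(out, "totals") <- totals
  class(out) <- c("cnv_counts", class(out))
  out
}

#' @rdname cnv_count_summary
#' @param x A `cnv_counts` object.
#' @param ... Unused.
#' @method glance cnv_counts
#' @export
glance.cnv_counts <- function(x, ...) {
  attr(x, "totals")
}

#' Run the full concordance pipeline and write its report tables
#'
#' Orchestrates QC, discretization, categorical and quantitative agreement,
#' and differential testing on one dataset, writing each result as a tidy
#' TSV under `out_dir`:
#'
#' * `qc_report.tsv` — normal-median filter per (method, gene);
#' * `pabak_matrix.tsv` — per-(gene, pair) PABAK, genes in decreasing
#'   median-PABAK order; `pabak_gene_medians.tsv`, `pabak_pair_medians.tsv`;
#' * `passing_bablok.tsv` — per-pair regression with bias flags and
#'   discrepancy quartiles;
#' * `differential.tsv` — per-gene per-method Wilcoxon p, harmonic-mean
#'   pooled p, Holm-corrected p, with 3-decimal display columns alongside
#'   full precision;
#' * `cnv_counts.tsv`, `cnv_count_totals.tsv` — per-gene event tallies;
#' * `run_log.tsv` — versions and every threshold used.
#'
#' Outputs are a pure function of the input and configuration: re-running
#' reproduces them byte for byte. Any stage failure aborts the whole run
#' with the stage name; nothing is silently partial.
#'
#' @param data A [cnv_dataset()], coercible data frame, or a path to a
#'   TSV/CSV readable by [read_cnv_dataset()].
#' @param out_dir Output directory (created if missing).
#' @param cat_pairs Method pairs for the categorical (PABAK) comparison,
#'   as `"a:b"` strings or length-2 vectors; default all pairs of
#'   post-discretization methods.
#' @param quant_pairs Method pairs for the quantitative comparison;
#'   default all pairs of quantitative methods.
#' @param genes Gene panel analysed; default all genes in the data. An
#'   explicitly empty panel is an error.
#' @param rule [conversion_rule()] used for discretization.
#' @param alpha Significance level for regression confidence intervals.
#' @param qc_lower,qc_upper Normal-median acceptance range.
#' @param count_method Categorical method whose tumor calls feed the event
#'   tally; defaults to the first quantitative method's discretized calls
#'   if present, otherwise the first categorical method.
#' @return Invisibly, a named list of the result tables (`qc`, `pabak`,
#'   `pabak_gene_medians`, `pabak_pair_medians`, `quant`, `differential`,
#'   `counts`, `count_totals`, `log`) plus `paths` to the files written.
#' @export
run_pipeline <- function(data, out_dir,
                         cat_pairs = NULL, quant_pairs = NULL,
                         genes = NULL, rule = conversion_rule(),
                         alpha = 0.05, qc_lower = 1.5, qc_upper = 2.5,
                         count_method = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  ds <- stage("input", {
    if (is.character(data)) read_cnv_dataset(data) else as_cnv_dataset(data)
  })
  stage("config", {
    if (!is.null(genes) && length(genes) == 0) {
      abort("config field `genes` is empty.")
    }
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
    }
  })

  qc <- stage("qc", qc_normal_medians(ds, lower = qc_lower, upper = qc_upper))
  ds_q <- stage("qc", apply_qc(ds, qc))

  disc <- stage("discretize", discretize_dataset(ds_q, rule))

  kinds <- method_kinds(ds_q)
  quant_methods <- sort(kinds$method_id[kinds$value_kind == "quantitative"])
  cat_methods <- sort(unique(disc$method_id))
  cat_pairs <- cat_pairs %||% all_pairs(cat_methods)
  quant_pairs <- quant_pairs %||% all_pairs(quant_methods)

  pab <- stage("categorical_agreement",
               pabak_matrix(disc, cat_pairs, genes = genes))
  quant <- stage("quantitative_agreement",
                 quantitative_panel(ds_q, quant_pairs, genes = genes,
                                    alpha = alpha))
  diff <- stage("differential",
                differential_table(ds_q, genes = genes))
  diff_out <- stage("differential", annotate_differential(diff))

  count_method <- count_method %||% {
    if (length(quant_methods) > 0) quant_methods[1] else cat_methods[1]
  }
  counts <- stage("counts", cnv_count_summary(
    dplyr::filter(as_tibble(disc), .data$method_id == !!count_method),
    genes = genes
  ))

  log <- tibble(
    key = c("package", "package_version", "r_version", "rule_mode",
            "rule_lower", "rule_upper", "rule_band_halfwidth", "alpha",
            "qc_lower", "qc_upper", "count_method"),
    value = c("cnvconcord",
              as.character(utils::packageVersion("cnvconcord")),
              paste(R.version$major, R.version$minor, sep = "."),
              rule$mode, format(rule$lower), format(rule$upper),
              format(rule$band_halfwidth), format(alpha),
              format(qc_lower), format(qc_upper), count_method)
  )

  paths <- c(
    qc = file.path(out_dir, "qc_report.tsv"),
    pabak = file.path(out_dir, "pabak_matrix.tsv"),
    pabak_gene_medians = file.path(out_dir, "pabak_gene_medians.tsv"),
    pabak_pair_medians = file.path(out_dir, "pabak_pair_medians.tsv"),
    quant = file.path(out_dir, "passing_bablok.tsv"),
    differential = file.path(out_dir, "differential.tsv"),
    counts = file.path(out_dir, "cnv_counts.tsv"),
    count_totals = file.path(out_dir, "cnv_count_totals.tsv"),
    log = file.path(out_dir, "run_log.tsv")
  )
  stage("write", {
    readr::write_tsv(qc, paths[["qc"]], progress = FALSE)
    readr::write_tsv(as_tibble(pab), paths[["pabak"]], progress = FALSE)
    readr::write_tsv(attr(pab, "gene_medians"),
                     paths[["pabak_gene_medians"]], progress = FALSE)
    readr::write_tsv(attr(pab, "pair_medians"),
                     paths[["pabak_pair_medians"]], progress = FALSE)
    readr::write_tsv(as_tibble(quant), paths[["quant"]], progress = FALSE)
    readr::write_tsv(diff_out, paths[["differential"]], progress = FALSE)
    readr::write_tsv(as_tibble(counts), paths[["counts"]], progress = FALSE)
    readr::write_tsv(glance(counts), paths[["count_totals"]],
                     progress = FALSE)
    readr::write_tsv(log, paths[["log"]], progress = FALSE)
  })

  invisible(list(
    qc = qc, pabak = pab,
    pabak_gene_medians = attr(pab, "gene_medians"),
    pabak_pair_medians = attr(pab, "pair_medians"),
    quant = quant, differential = diff_out, counts = counts,
    count_totals = glance(counts), log = log, paths = paths
  ))
}

all_pairs <- function(methods) {
  if (length(methods) < 2) return(list())
  cmb <- utils::combn(methods, 2, simplify = FALSE)
  lapply(cmb, identity)
}

# display rounding to 3 d.p. alongside full precision; trend band annotated
annotate_differential <- function(diff) {
  out <- as_tibble(diff)
  out$p_pooled_3dp <- round(out$p_pooled, 3)
  out$p_adjusted_3dp <- round(out$p_adjusted, 3)
  out$significance <- dplyr::case_when(
    out$p_adjusted < 0.05 ~ "significant",
    out$p_adjusted < 0.1 ~ "trend",
    TRUE ~ ""
  )
  out
}
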