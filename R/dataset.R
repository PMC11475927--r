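#' Copy-number call categories
#'
#' The three-state classification of a gene's copy number relative to the
#' diploid state: fewer than two copies (`deletion`), two copies (`normal`),
#' or more than two copies (`amplification`). The ordering
#' deletion < normal < amplification is used for display and for the
#' monotonicity of discretization only; no statistic treats the categories
#' as numeric.
#'
#' @return Character vector of the three category labels, in display order.
#' @export
#' @examples
#' cn_categories()
cn_categories <- function() {
  c("deletion", "normal", "amplification")
}

#' Parse copy-number calls into the canonical factor
#'
#' Accepts category labels (case-insensitive) or the integer aliases
#' `1` (deletion), `2` (normal), `3` (amplification), as produced by some
#' microarray calling tools.
#'
#' @param x Character, factor, or integer-like vector of calls.
#' @return An ordered factor with levels `deletion < normal < amplification`.
#' @export
#' @examples
#' cn_factor(c("Deletion", "2", "amplification"))
cn_factor <- function(x) {
  lev <- cn_categories()
  x_chr <- tolower(trimws(as.character(x)))
  alias <- c("1" = "deletion", "2" = "normal", "3" = "amplification")
  is_alias <- x_chr %in% names(alias)
  x_chr[is_alias] <- alias[x_chr[is_alias]]
  bad <- !is.na(x_chr) & !(x_chr %in% lev)
  if (any(bad)) {
    abort(paste0(
      "Unparseable categorical call(s): ",
      paste(unique(as.character(x)[bad]), collapse = ", "),
      ". Expected one of {deletion, normal, amplification} or aliases 1/2/3."
    ))
  }
  factor(x_chr, levels = lev, ordered = TRUE)
}

cnv_dataset_columns <- c(
  "patient_id", "tissue", "method_id", "gene", "value", "value_kind"
)

#' Construct a validated multi-platform copy-number dataset
#'
#' A `cnv_dataset` is a tidy tibble with one row per
#' (patient, tissue, method, gene) measurement. Each method is either
#' *quantitative* (a non-negative copy number per diploid genome, column
#' `value`) or *categorical* (a three-state call, column `call`); a method
#' never mixes the two kinds. Missing measurements are represented by row
#' absence, never by sentinel values.
#'
#' @param x A data frame with columns `patient_id`, `tissue`
#'   (`"tumor"`/`"normal"`), `method_id`, `gene`, `value_kind`
#'   (`"quantitative"`/`"categorical"`), and either a raw `value` column
#'   (numbers for quantitative rows, labels or 1/2/3 aliases for categorical
#'   rows) or already-split `value`/`call` columns.
#' @return A tibble of class `cnv_dataset` with columns `patient_id`,
#'   `tissue`, `method_id`, `gene`, `value_kind`, `value` (double, `NA` on
#'   categorical rows) and `call` (ordered factor, `NA` on quantitative rows),
#'   sorted by (method, gene, patient, tissue).
#' @export
#' @examples
#' cnv_dataset(tibble::tribble(
#'   ~patient_id, ~tissue, ~method_id, ~gene, ~value, ~value_kind,
#'   "P1", "tumor",  "ddpcr", "CCND2", "3.1", "quantitative",
#'   "P1", "normal", "ddpcr", "CCND2", "2.0", "quantitative"
#' ))
cnv_dataset <- function(x) {
  x <- as_tibble(x)
  required <- setdiff(cnv_dataset_columns, "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("value" %in% names(x)) && !("call" %in% names(x))) {
    abort("Need a `value` column (raw) or `value`/`call` columns (split).")
  }

  x$patient_id <- as.character(x$patient_id)
  x$tissue <- tolower(as.character(x$tissue))
  x$method_id <- as.character(x$method_id)
  x$gene <- as.character(x$gene)
  x$value_kind <- tolower(as.character(x$value_kind))

  bad_tissue <- !(x$tissue %in% c("tumor", "normal"))
  if (any(bad_tissue)) {
    abort(paste0("Invalid tissue at row(s) ",
                 paste(head(which(bad_tissue), 5L), collapse = ", "),
                 ": expected 'tumor' or 'normal'."))
  }
  bad_kind <- !(x$value_kind %in% c("quantitative", "categorical"))
  if (any(bad_kind)) {
    abort(paste0("Invalid value_kind at row(s) ",
                 paste(head(which(bad_kind), 5L), collapse = ", "),
                 ": expected 'quantitative' or 'categorical'."))
  }

  quant <- x$value_kind == "quantitative"
  if (!("call" %in% names(x))) {
    # raw single value column: split by value_kind
    raw <- as.character(x$value)
    value <- rep(NA_real_, nrow(x))
    value[quant] <- suppressWarnings(as.numeric(raw[quant]))
    bad_num <- quant & is.na(value) & !is.na(raw)
    if (any(bad_num)) {
      abort(paste0("Unparseable quantitative value at row(s) ",
                   paste(head(which(bad_num), 5L), collapse = ", "), "."))
    }
    call <- rep(NA_character_, nrow(x))
    call[!quant] <- raw[!quant]
    x$value <- value
    x$call <- cn_factor(call)
  } else {
    x$value <- as.numeric(if ("value" %in% names(x)) x$value else NA_real_)
    x$call <- cn_factor(x$call)
  }

  na_quant <- quant & is.na(x$value)
  if (any(na_quant)) {
    abort(paste0("Missing quantitative value at row(s) ",
                 paste(head(which(na_quant), 5L), collapse = ", "),
                 "; represent missing data by row absence."))
  }
  bad_value <- quant & (!is.finite(x$value) | x$value < 0)
  if (any(bad_value)) {
    abort(paste0("Quantitative values must be finite and >= 0; offending row(s) ",
                 paste(head(which(bad_value), 5L), collapse = ", "), "."))
  }
  na_call <- !quant & is.na(x$call)
  if (any(na_call)) {
    abort(paste0("Missing categorical call at row(s) ",
                 paste(head(which(na_call), 5L), collapse = ", "), "."))
  }
  x$value[!quant] <- NA_real_
  x$call[quant] <- NA

  key <- paste(x$patient_id, x$tissue, x$method_id, x$gene, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- x[which(dup)[1L], ]
    abort(paste0(
      "Duplicate measurement for key (",
      first$patient_id, ", ", first$tissue, ", ",
      first$method_id, ", ", first$gene, ")."
    ))
  }

  kinds <- dplyr::distinct(x, .data$method_id, .data$value_kind)
  mixed <- kinds$method_id[duplicated(kinds$method_id)]
  if (length(mixed) > 0) {
    abort(paste0("Mixed value_kind within method(s): ",
                 paste(unique(mixed), collapse = ", "), "."))
  }

  out <- dplyr::arrange(
    x[, c("patient_id", "tissue", "method_id", "gene",
          "value_kind", "value", "call")],
    .data$method_id, .data$gene, .data$patient_id, .data$tissue
  )
  class(out) <- c("cnv_dataset", class(out))
  out
}

#' @export
print.cnv_dataset <- function(x, ...) {
  kinds <- dplyr::distinct(as_tibble(x), .data$method_id, .data$value_kind)
  cat(sprintf(
    "<cnv_dataset> %d measurements | %d patients | %d methods (%d quantitative, %d categorical) | %d genes\n",
    nrow(x), dplyr::n_distinct(x$patient_id), nrow(kinds),
    sum(kinds$value_kind == "quantitative"),
    sum(kinds$value_kind == "categorical"),
    dplyr::n_distinct(x$gene)
  ))
  NextMethod()
}

#' Read a copy-number dataset from a delimited file
#'
#' Expects a UTF-8 TSV or CSV with a header naming the six columns
#' `patient_id`, `tissue`, `method_id`, `gene`, `value`, `value_kind`.
#' Categorical calls may be labels (case-insensitive) or integer aliases
#' 1/2/3.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension, default), `"tsv"`, or `"csv"`.
#' @return A [cnv_dataset()].
#' @export
read_cnv_dataset <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  missing_cols <- setdiff(cnv_dataset_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File ", path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cnv_dataset(raw)
}

#' Write a copy-number dataset to a delimited file
#'
#' Inverse of [read_cnv_dataset()]: quantitative rows write their numeric
#' value, categorical rows write the category label, into a single `value`
#' column.
#'
#' @param ds A [cnv_dataset()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cnv_dataset <- function(ds, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  ds <- as_cnv_dataset(ds)
  out <- tibble(
    patient_id = ds$patient_id,
    tissue = ds$tissue,
    method_id = ds$method_id,
    gene = ds$gene,
    value = ifelse(ds$value_kind == "quantitative",
                   as.character(ds$value), as.character(ds$call)),
    value_kind = ds$value_kind
  )
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(out, path, progress = FALSE)
  invisible(path)
}

as_cnv_dataset <- function(x) {
  if (inherits(x, "cnv_dataset")) x else cnv_dataset(x)
}

#' Tumor/normal paired values for one quantitative method and gene
#'
#' Returns one row per patient that has *both* a tumor and a normal
#' measurement for the given (method, gene); patients missing either tissue
#' are omitted (complete-case pairing). Rows are ordered by ascending
#' `patient_id`, the package's canonical iteration order.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param method_id A quantitative method present in `ds`.
#' @param gene A gene present in `ds`.
#' @return Tibble with columns `patient_id`, `tumor`, `normal`.
#' @export
paired_values <- function(ds, method_id, gene) {
  ds <- as_cnv_dataset(ds)
  check_method(ds, method_id, kind = "quantitative")
  check_gene(ds, gene)
  sub <- dplyr::filter(as_tibble(ds),
                       .data$method_id == !!method_id, .data$gene == !!gene)
  wide <- tidyr::pivot_wider(
    sub[, c("patient_id", "tissue", "value")],
    names_from = "tissue", values_from = "value"
  )
  for (col in c("tumor", "normal")) {
    if (!(col %in% names(wide))) wide[[col]] <- NA_real_
  }
  dplyr::arrange(
    dplyr::filter(wide[, c("patient_id", "tumor", "normal")],
                  !is.na(.data$tumor) & !is.na(.data$normal)),
    .data$patient_id
  )
}

#' Aligned categorical calls for a pair of methods on one gene
#'
#' Returns one row per (patient, tissue) sample called by *both* methods for
#' the given gene (complete-case intersection), ordered by ascending
#' `patient_id` then tissue. Quantitative methods must be discretized first
#' (see [discretize_dataset()]).
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param method_a,method_b Categorical methods present in `ds`.
#' @param gene A gene present in `ds`.
#' @param tissue Which tissues to include; both by default.
#' @return Tibble with columns `patient_id`, `tissue`, `call_a`, `call_b`.
#' @export
aligned_calls <- function(ds, method_a, method_b, gene,
                          tissue = c("tumor", "normal")) {
  ds <- as_cnv_dataset(ds)
  tissue <- match.arg(tissue, several.ok = TRUE)
  check_method(ds, method_a, kind = "categorical")
  check_method(ds, method_b, kind = "categorical")
  check_gene(ds, gene)
  tbl <- dplyr::filter(as_tibble(ds),
                       .data$gene == !!gene, .data$tissue %in% !!tissue)
  a <- dplyr::filter(tbl, .data$method_id == !!method_a)
  b <- dplyr::filter(tbl, .data$method_id == !!method_b)
  joined <- dplyr::inner_join(
    dplyr::select(a, "patient_id", "tissue", call_a = "call"),
    dplyr::select(b, "patient_id", "tissue", call_b = "call"),
    by = c("patient_id", "tissue")
  )
  dplyr::arrange(joined, .data$patient_id, .data$tissue)
}

#' Per-(method, gene) completeness of a dataset
#'
#' Counts, for every method and gene, how many of the possible
#' (patient, tissue) samples carry a measurement — the completeness matrix a
#' data audit starts from.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @return Tibble with columns `method_id`, `gene`, `n_tumor`, `n_normal`.
#' @export
dataset_completeness <- function(ds) {
  ds <- as_cnv_dataset(ds)
  dplyr::summarise(
    dplyr::group_by(as_tibble(ds), .data$method_id, .data$gene),
    n_tumor = sum(.data$tissue == "tumor"),
    n_normal = sum(.data$tissue == "normal"),
    .groups = "drop"
  )
}

method_kinds <- function(ds) {
  dplyr::distinct(as_tibble(ds), .data$method_id, .data$value_kind)
}

check_method <- function(ds, method_id, kind = NULL) {
  kinds <- method_kinds(ds)
  if (!(method_id %in% kinds$method_id)) {
    abort(paste0("Unknown method: ", method_id, "."))
  }
  if (!is.null(kind)) {
    actual <- kinds$value_kind[kinds$method_id == method_id]
    if (actual != kind) {
      abort(paste0("Method ", method_id, " is ", actual, ", expected ",
                   kind, "."))
    }
  }
  invisible(TRUE)
}

check_gene <- function(ds, gene) {
  if (!(gene %in% ds$gene)) {
    abort(paste0("Unknown gene: ", gene, "."))
  }
  invisible(TRUE)
}
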