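#' Cross-classification table of paired categorical calls
#'
#' Tallies aligned call pairs from two methods into a k x k contingency
#' table over the fixed category order deletion, normal, amplification
#' (all three categories are always represented, observed or not).
#'
#' @param pairs A data frame with two call columns (`call_a`, `call_b`, as
#'   returned by [aligned_calls()]), or a factor/character vector of first
#'   calls when `second` is given.
#' @param second Optional vector of second calls.
#' @return A 3 x 3 integer matrix of class `cn_contingency`; rows index the
#'   first method's call, columns the second's.
#' @export
#' @examples
#' cn_contingency(rep("normal", 4), rep("normal", 4))
cn_contingency <- function(pairs, second = NULL) {
  if (is.null(second)) {
    if (!is.data.frame(pairs) || !all(c("call_a", "call_b") %in% names(pairs))) {
      abort("pairs must have columns call_a and call_b (or pass two vectors).")
    }
    a <- pairs$call_a
    b <- pairs$call_b
  } else {
    a <- pairs
    b <- second
  }
  a <- cn_factor(a)
  b <- cn_factor(b)
  if (length(a) != length(b)) abort("call vectors must have equal length.")
  if (length(a) == 0) abort("cannot tabulate an empty sequence of call pairs.")
  if (anyNA(a) || anyNA(b)) abort("call pairs must not contain NA.")
  tab <- table(a, b, dnn = NULL)
  m <- matrix(as.integer(tab), nrow = 3, dimnames = dimnames(tab))
  class(m) <- c("cn_contingency", class(m))
  m
}

#' Prevalence- and bias-adjusted kappa (PABAK)
#'
#' PABAK measures chance-corrected agreement between two raters/methods
#' while being insensitive to category prevalence and marginal bias:
#' \deqn{PABAK = (k \cdot P_o - 1) / (k - 1)}
#' where \eqn{P_o} is the observed proportion of agreement (the diagonal
#' share of the contingency table) and `k` the number of *defined*
#' categories. PABAK is 1 at perfect agreement, 0 at chance-level
#' agreement (\eqn{P_o = 1/k}), and reaches \eqn{-1/(k-1)} when the methods
#' never agree (\eqn{-1} for binary calls). Agreement bands follow the
#' conventional cut-points: negative (< 0), poor [0, 0.20], moderate
#' (0.20, 0.60], substantial (0.60, 0.80], near-perfect (0.80, 1].
#'
#' @param x A `cn_contingency` matrix, any square count matrix, or a data
#'   frame of aligned pairs (see [cn_contingency()]).
#' @param k Number of defined categories; defaults to the table dimension
#'   (3 for copy-number calls). Pass `k = 2` for binary reductions.
#' @return An object of class `pabak`: list with `po`, `pabak`, `k`, `n`,
#'   `band`, and the `table`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' pabak(cn_contingency(rep("normal", 5), rep("normal", 5)))
pabak <- function(x, k = NULL) {
  if (is.data.frame(x)) x <- cn_contingency(x)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("pabak expects a square contingency matrix or a pairs data frame.")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("contingency counts must be non-negative integers.")
  }
  n <- sum(x)
  if (n < 1) abort("contingency table is empty (n = 0).")
  k <- k %||% nrow(x)
  if (!is.numeric(k) || k < 2) abort("k must be an integer >= 2.")
  po <- sum(diag(x)) / n
  val <- (k * po - 1) / (k - 1)
  structure(
    list(po = po, pabak = val, k = as.integer(k), n = as.integer(n),
         band = pabak_band(val), table = unclass(x)),
    class = "pabak"
  )
}

pabak_band <- function(x) {
  band <- as.character(cut(
    x,
    breaks = c(-Inf, 0, 0.20, 0.60, 0.80, Inf),
    labels = c("negative", "poor", "moderate", "substantial", "near_perfect"),
    right = TRUE
  ))
  # cut() puts exactly 0 into "negative" (right-closed); 0 is poor, not negative
  band[!is.na(x) & x == 0] <- "poor"
  band
}

#' @export
print.pabak <- function(x, ...) {
  cat(sprintf("<pabak> PABAK = %.3f (Po = %.3f, k = %d, n = %d) [%s]\n",
              x$pabak, x$po, x$k, x$n, x$band))
  invisible(x)
}

#' @rdname pabak
#' @param x A `pabak` object.
#' @param ... Unused.
#' @method tidy pabak
#' @export
tidy.pabak <- function(x, ...) {
  tibble(n = x$n, k = x$k, po = x$po, pabak = x$pabak, band = x$band)
}

#' Per-gene, per-method-pair PABAK matrix
#'
#' Computes PABAK for every requested (gene, method pair) cell from the
#' aligned categorical calls, together with per-gene medians (over pairs)
#' and per-pair medians (over genes). Cells with no aligned calls are
#' reported with `n = 0` and missing statistics, never as zero agreement.
#' Gene rows are emitted in decreasing order of the per-gene median PABAK.
#'
#' @param ds A [cnv_dataset()] whose relevant methods are categorical
#'   (discretize quantitative methods first).
#' @param method_pairs Pairs to compare: a list of length-2 character
#'   vectors, or a character vector of `"a:b"` strings.
#' @param genes Genes to include; defaults to all genes in `ds`.
#' @param tissue Tissues pooled into each cell; both by default.
#' @param k Number of defined categories passed to [pabak()].
#' @return Tibble of class `pabak_matrix` with columns `gene`, `pair`,
#'   `method_a`, `method_b`, `n`, `po`, `pabak`, `band`, plus attributes
#'   `gene_medians` and `pair_medians` (tibbles of medians over available
#'   cells).
#' @export
pabak_matrix <- function(ds, method_pairs, genes = NULL,
                         tissue = c("tumor", "normal"), k = 3) {
  ds <- as_cnv_dataset(ds)
  tissue <- match.arg(tissue, several.ok = TRUE)
  pairs <- normalize_pairs(method_pairs)
  genes <- genes %||% sort(unique(ds$gene))

  cells <- tidyr::expand_grid(
    gene = genes,
    pair_idx = seq_along(pairs)
  )
  rows <- purrr::pmap(cells, function(gene, pair_idx) {
    pr <- pairs[[pair_idx]]
    al <- aligned_calls(ds, pr[1], pr[2], gene, tissue = tissue)
    if (nrow(al) == 0) {
      tibble(gene = gene, pair = paste(pr, collapse = ":"),
             method_a = pr[1], method_b = pr[2],
             n = 0L, po = NA_real_, pabak = NA_real_,
             band = NA_character_)
    } else {
      res <- pabak(cn_contingency(al), k = k)
      tibble(gene = gene, pair = paste(pr, collapse = ":"),
             method_a = pr[1], method_b = pr[2],
             n = res$n, po = res$po, pabak = res$pabak, band = res$band)
    }
  })
  out <- dplyr::bind_rows(rows)

  gene_medians <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(out, .data$gene),
      median_pabak = median(.data$pabak, na.rm = TRUE),
      n_cells = sum(!is.na(.data$pabak)),
      .groups = "drop"
    ),
    dplyr::desc(.data$median_pabak), .data$gene
  )
  pair_medians <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(out, .data$pair),
      median_pabak = median(.data$pabak, na.rm = TRUE),
      n_cells = sum(!is.na(.data$pabak)),
      .groups = "drop"
    ),
    dplyr::desc(.data$median_pabak), .data$pair
  )

  out <- out[order(match(out$gene, gene_medians$gene),
                   match(out$pair, vapply(pairs, paste, "", collapse = ":"))), ]
  out <- as_tibble(out)
  attr(out, "gene_medians") <- gene_medians
  attr(out, "pair_medians") <- pair_medians
  class(out) <- c("pabak_matrix", class(out))
  out
}

normalize_pairs <- function(method_pairs) {
  if (is.character(method_pairs)) {
    method_pairs <- strsplit(method_pairs, ":", fixed = TRUE)
  }
  if (!is.list(method_pairs) ||
      !all(vapply(method_pairs, length, 0L) == 2L)) {
    abort("method_pairs must be 'a:b' strings or length-2 character vectors.")
  }
  lapply(method_pairs, as.character)
}
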