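#' Number of unordered gene pairs
#'
#' All-pairs construction over `n` genes yields `n * (n - 1) / 2` pairs.
#'
#' @param n_genes Non-negative integer.
#' @return Number of distinct unordered pairs.
#' @examples
#' count_pairs(215)   # 23005
#' @export
count_pairs <- function(n_genes) {
  if (length(n_genes) != 1 || !is.numeric(n_genes) || n_genes < 0 ||
      n_genes != round(n_genes))
    stop("n_genes must be a single non-negative integer", call. = FALSE)
  n_genes * (n_genes - 1) / 2
}

#' Build within-sample binary gene-pair indicators
#'
#' The central rank-based transformation: for every unordered pair of genes
#' the indicator is 1 in a sample when the first gene's expression exceeds
#' the second's, and 0 otherwise (ties score 0). Pairs are enumerated in
#' canonical lexicographic order `gene_a < gene_b` and named
#' `"gene_a|gene_b"`. Because only the within-sample ordering of the two
#' genes enters, the matrix is invariant to any strictly increasing
#' per-sample transform of expression — the property that lets a model
#' built on one platform transfer to another.
#'
#' @param expr Genes x samples matrix.
#' @param genes Genes to pair (at least 2, all present in `expr`).
#' @return A `pair_matrix`: binary pairs x samples matrix with
#'   `"gene_a|gene_b"` rownames.
#' @examples
#' expr <- matrix(c(5, 3.2, 1, 2), 2, 2,
#'                dimnames = list(c("A", "B"), c("s1", "s2")))
#' build_pairs(expr, c("A", "B"))
#' @export
build_pairs <- function(expr, genes) {
  check_expression(expr)
  genes <- as.character(genes)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes))
    stop("gene '", missing_genes[1], "' not found in expression matrix",
         call. = FALSE)
  if (length(genes) < 2) stop("need at least 2 genes to pair", call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicated gene in pairing list",
                                 call. = FALSE)
  genes <- sort(genes)
  idx <- combn(length(genes), 2)
  e <- expr[genes, , drop = FALSE]
  ind <- (e[idx[1, ], , drop = FALSE] > e[idx[2, ], , drop = FALSE]) * 1L
  rownames(ind) <- paste(genes[idx[1, ]], genes[idx[2, ]], sep = "|")
  structure(ind, class = c("pair_matrix", class(ind)))
}

#' Minority-class fraction of each pair
#'
#' @param pairs A binary `pair_matrix`.
#' @return Per-pair `min(freq of 0, freq of 1)`, in `[0, 0.5]`.
#' @export
pair_minority_fraction <- function(pairs) {
  f1 <- rowMeans(pairs)
  pmin(f1, 1 - f1)
}

#' Filter near-constant gene pairs
#'
#' Removes pairs whose minority class (0 or 1) occurs in less than
#' `min_minority_fraction` of samples; the boundary is closed, so a pair at
#' exactly the threshold is retained. Constant pairs (median absolute
#' deviation 0) always have minority fraction 0 and are removed whenever
#' the threshold is positive.
#'
#' @param pairs A `pair_matrix`.
#' @param min_minority_fraction Threshold in `[0, 0.5]` (default 0.2).
#' @return The retained subset, still a `pair_matrix`.
#' @export
filter_pairs <- function(pairs, min_minority_fraction = 0.2) {
  if (min_minority_fraction < 0 || min_minority_fraction > 0.5)
    stop("min_minority_fraction must lie in [0, 0.5]", call. = FALSE)
  keep <- pair_minority_fraction(pairs) >= min_minority_fraction
  out <- pairs[keep, , drop = FALSE]
  structure(out, class = c("pair_matrix", class(unclass(out))))
}

#' Indicators for a risk model's own pair orientation
#'
#' A published risk model stores each pair as `(irg1, irg2)` in the
#' orientation its coefficient was fitted under (indicator = 1 when `irg1`
#' exceeds `irg2`). This builds exactly those indicator rows, named
#' `"irg1|irg2"`, from an expression matrix.
#'
#' @param model A [risk_model()].
#' @param expr Genes x samples matrix containing every model gene.
#' @return Binary pairs x samples matrix in model orientation.
#' @export
build_model_pairs <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  check_expression(expr)
  need <- unique(c(model$pairs$irg1, model$pairs$irg2))
  missing_genes <- setdiff(need, rownames(expr))
  if (length(missing_genes))
    stop("model gene(s) absent from expression: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  ind <- (expr[model$pairs$irg1, , drop = FALSE] >
            expr[model$pairs$irg2, , drop = FALSE]) * 1L
  rownames(ind) <- paste(model$pairs$irg1, model$pairs$irg2, sep = "|")
  ind
}

#' Write a pair indicator matrix to TSV
#'
#' @param pairs A `pair_matrix`.
#' @param path Output path (rows `geneA|geneB`, columns samples).
#' @return Invisibly, `path`.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write_matrix_tsv(pairs, path, id_col = "pair")
  invisible(path)
}
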