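#' Single-sample gene-set (ssGSEA-style) scoring
#'
#' Scores each sample against each gene set with the rank-based
#' single-sample enrichment statistic: per sample, genes are ranked by
#' expression (average ranks for ties, the top gene carrying the largest
#' rank); walking down the ranking, the score is the running sum of the
#' difference between the weighted in-set empirical CDF (weights
#' `rank^exponent`) and the uniform out-of-set empirical CDF. Scores are
#' rank-based, hence invariant to any strictly increasing per-sample
#' transform of expression, and are reported unnormalised.
#'
#' @param expr Genes x samples numeric matrix (log2 scale by convention;
#'   only ranks are used).
#' @param sets Named list of gene identifier vectors (e.g. from
#'   [read_gmt()]); every set must overlap the expression rows.
#' @param exponent Rank weight exponent (default 0.25, the original ssGSEA
#'   choice; 0 gives the unweighted Kolmogorov-Smirnov-style walk).
#' @return Data frame, one row per sample: `sample` plus one `<set>_score`
#'   column per gene set.
#' @export
ssgsea_score <- function(expr, sets, exponent = 0.25) {
  check_expression(expr)
  check_gene_sets(sets)
  overlap <- vapply(sets, function(s) sum(s %in% rownames(expr)), 1L)
  if (any(overlap == 0))
    stop("gene set '", names(sets)[which(overlap == 0)[1]],
         "' shares no genes with the expression matrix", call. = FALSE)
  n_genes <- nrow(expr)
  scores <- matrix(0, ncol(expr), length(sets),
                   dimnames = list(colnames(expr),
                                   paste0(names(sets), "_score")))
  in_set <- lapply(sets, function(s) rownames(expr) %in% s)
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")   # top gene = rank n_genes
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^exponent
    for (k in seq_along(sets)) {
      hit <- in_set[[k]][ord]
      w_hit <- w * hit
      cdf_in <- cumsum(w_hit) / sum(w_hit)
      n_out <- n_genes - sum(hit)
      cdf_out <- if (n_out == 0) rep(0, n_genes) else cumsum(!hit) / n_out
      scores[j, k] <- sum(cdf_in - cdf_out)
    }
  }
  out <- data.frame(sample = colnames(expr), scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of a sample score between two groups
#'
#' Two-sided Wilcoxon rank-sum test on one score column (default the immune
#' score) between two sample groups.
#'
#' @param scores Output of [ssgsea_score()].
#' @param groups Label vector aligned with `scores$sample`.
#' @param set Which set's score to test (default `"immune"`).
#' @return List with `statistic` (rank-sum W) and `p`.
#' @export
score_group_test <- function(scores, groups, set = "immune") {
  col <- paste0(set, "_score")
  if (!col %in% names(scores))
    stop("no score column '", col, "'", call. = FALSE)
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) != 2)
    stop("exactly two groups required for the rank-sum test", call. = FALSE)
  if (any(table(factor(groups, levs)) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  x <- scores[[col]][groups == levs[1]]
  y <- scores[[col]][groups == levs[2]]
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
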