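#' Moderated two-group differential expression
#'
#' Fits a gene-wise two-group comparison on log2 expression with
#' empirical-Bayes variance moderation (limma's `lmFit`/`eBayes`), then
#' flags genes passing both a fold-change and a Benjamini-Hochberg adjusted
#' p-value threshold. The log2 fold change is the difference of group means
#' on the log2 scale, oriented as `contrast minus reference`.
#'
#' @param expr Numeric genes x samples matrix, log2 scale, no missing values.
#' @param groups Two-level label vector aligned with `colnames(expr)`.
#' @param fc_threshold Absolute log2 fold-change cut (default 0.5).
#' @param alpha Adjusted-p cut (default 0.05).
#' @param reference Baseline group level; defaults to `"left"` when present,
#'   otherwise the first sorted level. The fold change is the other level
#'   minus this one.
#' @return Data frame with one row per gene: `gene`, `log2fc`, `t_stat`,
#'   `p_value`, `p_adj`, `is_de`.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_samples_per_group = 25, n_genes = 150,
#'   n_de_genes = 40, module_size = 20, n_planted_pairs = 0,
#'   planted_coefficients = numeric(0), seed = 3))
#' de <- moderated_de(ch$expression, ch$clinical$group)
#' table(de$is_de)
#' @export
moderated_de <- function(expr, groups, fc_threshold = 0.5, alpha = 0.05,
                         reference = NULL) {
  check_expression(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups must have one label per sample", call. = FALSE)
  levs <- sort(unique(groups))
  if (length(levs) != 2)
    stop("exactly two groups required, got: ", paste(levs, collapse = ", "),
         call. = FALSE)
  small <- levs[table(factor(groups, levs)) < 2]
  if (length(small))
    stop("group '", small[1], "' has fewer than 2 samples", call. = FALSE)
  if (is.null(reference)) reference <- if ("left" %in% levs) "left" else levs[1]
  if (!reference %in% levs)
    stop("reference level '", reference, "' not found in groups", call. = FALSE)
  other <- setdiff(levs, reference)

  design <- model.matrix(~ factor(groups, levels = c(reference, other)))
  colnames(design) <- c("intercept", "contrast")
  fit <- limma::eBayes(limma::lmFit(expr, design))
  tab <- limma::topTable(fit, coef = "contrast", number = Inf,
                         sort.by = "none", adjust.method = "BH")
  res <- data.frame(
    gene = rownames(expr),
    log2fc = tab$logFC,
    t_stat = tab$t,
    p_value = tab$P.Value,
    p_adj = tab$adj.P.Val,
    stringsAsFactors = FALSE)
  # a gene that is constant everywhere carries no evidence either way
  flat <- apply(expr, 1, function(x) all(x == x[1]))
  res$log2fc[flat] <- 0
  res$t_stat[flat] <- 0
  res$p_value[flat] <- 1
  res$p_adj <- bh_adjust(res$p_value)
  res$is_de <- abs(res$log2fc) > fc_threshold & res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone after sorting, capped at 1).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad))
    stop("p-value outside [0,1] at index ", bad[1], call. = FALSE)
  p.adjust(p, method = "BH")
}
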