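#' Reference-based immune-cell deconvolution with permutation confidence
#'
#' Estimates per-sample cell-type fractions by non-negative least squares:
#' each sample's linear-scale expression over the signature genes is
#' regressed on the signature matrix with non-negativity constraints and
#' the coefficients are normalised to sum to one. Confidence in the fit is
#' assessed by a Monte-Carlo permutation test: the sample's expression
#' values are permuted across genes `n_perm` times, the fit is repeated,
#' and the p-value is the (add-one smoothed) fraction of permutations whose
#' reconstruction correlation reaches the observed one.
#'
#' @param expr Genes x samples matrix on log2 scale (converted to linear
#'   scale internally).
#' @param sig Signature matrix: genes x cell types, non-negative, at least
#'   2 cell types; at least half of its genes must be present in `expr`.
#' @param n_perm Permutations per sample (default 100).
#' @param seed Seed for the permutations.
#' @return A `deconv_result` data frame: `sample`, one fraction column per
#'   cell type, `p_value`, `rmse`, `correlation`.
#' @export
deconvolve <- function(expr, sig, n_perm = 100, seed = 1) {
  check_expression(expr)
  sig <- as.matrix(sig)
  if (ncol(sig) < 2) stop("signature needs at least 2 cell types",
                          call. = FALSE)
  if (any(sig < 0)) stop("signature matrix must be non-negative",
                         call. = FALSE)
  if (any(rowSums(sig) == 0)) stop("signature has an all-zero gene row",
                                   call. = FALSE)
  if (anyDuplicated(colnames(sig)))
    stop("cell-type names must be unique", call. = FALSE)
  common <- intersect(rownames(sig), rownames(expr))
  if (length(common) < 0.5 * nrow(sig))
    stop("only ", length(common), " of ", nrow(sig),
         " signature genes found in expression (need at least 50%)",
         call. = FALSE)
  S <- sig[common, , drop = FALSE]
  E <- 2^expr[common, , drop = FALSE]     # linear scale
  n_types <- ncol(S)

  fit_one <- function(y) {
    b <- pracma::lsqnonneg(S, y)$x
    yhat <- as.vector(S %*% b)
    r <- suppressWarnings(cor(yhat, y))
    list(b = b, r = if (is.na(r)) 0 else r,
         rmse = sqrt(mean((y - yhat)^2)))
  }

  frac <- matrix(NA_real_, ncol(E), n_types,
                 dimnames = list(colnames(E), colnames(S)))
  pv <- rmse <- rr <- numeric(ncol(E))
  with_seed(seed, {
    for (j in seq_len(ncol(E))) {
      y <- E[, j]
      f <- fit_one(y)
      if (sum(f$b) == 0)
        stop("all-zero coefficients for sample ", colnames(E)[j],
             call. = FALSE)
      frac[j, ] <- f$b / sum(f$b)
      rr[j] <- f$r; rmse[j] <- f$rmse
      null_r <- vapply(seq_len(n_perm),
                       function(i) fit_one(sample(y))$r, 0)
      pv[j] <- (1 + sum(null_r >= f$r)) / (n_perm + 1)
    }
  })
  out <- data.frame(sample = colnames(E), frac, p_value = pv,
                    rmse = rmse, correlation = rr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cell_types = colnames(S),
            class = c("deconv_result", "data.frame"))
}

#' Keep confidently deconvolved samples
#'
#' @param result A `deconv_result`.
#' @param alpha Permutation-p threshold (default 0.05; samples with
#'   `p < alpha` are retained).
#' @return The retained subset, still a `deconv_result`.
#' @export
filter_confident <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "deconv_result"))
  out <- result[result$p_value < alpha, , drop = FALSE]
  structure(out, cell_types = attr(result, "cell_types"),
            class = class(result))
}

#' Per-cell-type comparison of fractions between risk groups
#'
#' Two-sided Wilcoxon rank-sum test of each cell type's fractions between
#' the two groups; `direction` is the sign of the median difference
#' (`high` minus `low`, or first sorted level minus second for other
#' labels).
#'
#' @param result A `deconv_result` (usually after [filter_confident()]).
#' @param groups Named or aligned label vector with two levels.
#' @return Data frame: `cell_type`, `statistic`, `p`, `direction`.
#' @export
group_difference <- function(result, groups) {
  stopifnot(inherits(result, "deconv_result"))
  groups <- as.character(groups)
  if (length(groups) != nrow(result))
    stop("groups must have one label per retained sample", call. = FALSE)
  levs <- sort(unique(groups))
  if (length(levs) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (all(c("high", "low") %in% levs)) levs <- c("high", "low")
  if (any(table(factor(groups, levs)) < 2))
    stop("each group needs at least 2 retained samples", call. = FALSE)
  types <- attr(result, "cell_types")
  rows <- lapply(types, function(ct) {
    x <- result[[ct]][groups == levs[1]]
    y <- result[[ct]][groups == levs[2]]
    wt <- suppressWarnings(wilcox.test(x, y))
    data.frame(cell_type = ct, statistic = unname(wt$statistic),
               p = wt$p.value,
               direction = sign(median(x) - median(y)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a genes x cell-types signature matrix from TSV
#'
#' @param path TSV with gene identifiers in the first column.
#' @return Numeric matrix.
#' @export
read_signature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
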