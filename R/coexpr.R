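#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity vector into equal-width bins across its range,
#' regresses `log10(frequency)` on `log10(mean connectivity)` over the
#' non-empty bins and reports the R-squared — the usual check that a
#' network's degree distribution follows a power law.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of bins (default 10).
#' @return List with `r2` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  stopifnot(length(k) > 1, all(is.finite(k)))
  bins <- cut(k, n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0
  if (sum(keep) < 2) return(list(r2 = 0, slope = NA_real_))
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(r2 = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Unsigned power adjacency of a gene expression matrix
#'
#' `a_ij = |cor(x_i, x_j)|^power` with zero diagonal.
#'
#' @param expr Genes x samples matrix.
#' @param power Soft-threshold exponent.
#' @return Symmetric genes x genes matrix in `[0, 1]`, zero diagonal.
#' @export
adjacency_matrix <- function(expr, power = 1) {
  check_expression(expr)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop("constant gene '", rownames(expr)[which(sds == 0)[1]],
         "': correlation undefined", call. = FALSE)
  a <- abs(cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Scan soft-threshold powers for scale-free topology
#'
#' For each candidate power computes the unsigned adjacency, the per-gene
#' connectivity `k_i = sum_j a_ij`, and the scale-free fit index; the chosen
#' power is the smallest one reaching `r2_target`. When no power reaches the
#' target the scan falls back, with a warning, to the standard
#' sample-size-based default for unsigned networks (6 for 40 or more
#' samples, 8/9/10 for progressively smaller cohorts): at high powers the
#' connectivity of an unstructured network collapses towards zero and its
#' degenerate degree distribution scores spuriously well on the fit index,
#' so "best fit" is not a usable fallback.
#'
#' @param expr Genes x samples matrix (typically the DEG submatrix).
#' @param powers Candidate integer powers (default 1..20).
#' @param r2_target Scale-free R-squared target (default 0.9).
#' @param n_bins Connectivity bins for the fit (default 10).
#' @return List with `scan` (data frame: `power`, `scale_free_r2`,
#'   `mean_connectivity`) and `power` (the chosen value).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.9,
                                n_bins = 10) {
  check_expression(expr)
  if (any(diff(powers) <= 0)) stop("powers must be strictly increasing",
                                   call. = FALSE)
  if (nrow(expr) < 30) stop("need at least 30 genes", call. = FALSE)
  if (ncol(expr) < 20)
    warning("fewer than 20 samples: correlations will be noisy")
  cmat <- abs(cor(t(expr)))
  if (anyNA(cmat)) {
    sds <- apply(expr, 1, sd)
    stop("constant gene '", rownames(expr)[which(sds == 0)[1]],
         "': correlation undefined", call. = FALSE)
  }
  diag(cmat) <- 0
  scan <- data.frame(power = powers, scale_free_r2 = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    k <- colSums(cmat^powers[i])
    scan$scale_free_r2[i] <- scale_free_fit(k, n_bins)$r2
    scan$mean_connectivity[i] <- mean(k)
  }
  hit <- which(scan$scale_free_r2 >= r2_target)
  if (length(hit)) {
    chosen <- powers[hit[1]]
  } else {
    n <- ncol(expr)
    default <- if (n >= 40) 6 else if (n >= 30) 8 else if (n >= 20) 9 else 10
    chosen <- powers[which.min(abs(powers - default))]
    warning("no power reached scale-free R2 ", r2_target,
            "; using the sample-size default (power ", chosen, ")")
  }
  list(scan = scan, power = chosen)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, diagonal 1: the neighbourhood-sharing similarity of an
#' unsigned network adjacency.
#'
#' @param adjacency Symmetric matrix, entries in `[0, 1]`; the diagonal is
#'   zeroed before computation.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-8)
    stop("adjacency is asymmetric beyond 1e-8", call. = FALSE)
  if (min(a) < 0 || max(a) > 1)
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a static cut, and
#' relabelling of undersized clusters as `"grey"`. By default the cut is
#' placed in the middle of the largest gap between consecutive merge
#' heights — the point where the dendrogram separates tight clusters from
#' the merges that join them — which is robust across soft-threshold
#' powers; a fixed fraction of the merge-height range can be requested via
#' `cut_height` instead. Module eigengenes are the first
#' principal component of each module's standardised expression (unit
#' Euclidean norm over samples), sign-oriented to correlate positively with
#' the module's mean expression profile. Module membership (MM) is the
#' correlation of each gene with its own module's eigengene; gene
#' significance (GS) is the correlation of each gene with each supplied
#' trait (a signed `-log10` p variant is stored alongside).
#'
#' @param tom Topological overlap matrix from [topological_overlap()].
#' @param expr The genes x samples matrix the TOM was computed from.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Optional static cut as a fraction of the merge-height
#'   range; `NULL` (default) uses the largest-gap rule.
#' @param traits Optional samples x traits data frame / matrix (rownames or
#'   a `sample` column identify samples) used for GS.
#' @return A `module_assignment`: list with `modules` (named gene -> label
#'   vector; labels `"M1"`, `"M2"`, ... by decreasing size, `"grey"` for
#'   unassigned), `eigengenes` (samples x modules), `mm`, `gs`, `gs_logp`,
#'   and the `hclust` tree.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30,
                           cut_height = NULL, traits = NULL) {
  check_expression(expr)
  stopifnot(nrow(tom) == nrow(expr))
  genes <- rownames(expr)
  tree <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    hs <- sort(tree$height)
    if (length(hs) > 1) {
      gaps <- diff(hs)
      i <- which.max(gaps)
      h <- (hs[i] + hs[i + 1]) / 2
    } else h <- hs / 2
  } else {
    h <- min(tree$height) + cut_height * diff(range(tree$height))
  }
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(raw))
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- paste0("M", i)
  } else {
    warning("no module reached min_module_size; all genes labelled grey")
  }
  names(labels) <- genes

  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(as.integer(sub("M", "", mods)))]
  eig <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), mods))
  for (m in mods) {
    x <- t(scale(t(expr[labels == m, , drop = FALSE])))   # gene-standardised
    sv <- svd(x, nu = 0, nv = 1)
    me <- sv$v[, 1]                                       # unit norm
    ref <- colMeans(expr[labels == m, , drop = FALSE])
    if (cor(me, ref) < 0) me <- -me
    eig[, m] <- me
  }

  mm <- setNames(rep(NA_real_, length(genes)), genes)
  for (m in mods)
    mm[labels == m] <- as.vector(cor(t(expr[labels == m, , drop = FALSE]),
                                     eig[, m]))

  gs <- gs_logp <- NULL
  if (!is.null(traits)) {
    tr <- as_trait_matrix(traits, colnames(expr))
    gs <- cor(t(expr), tr)
    n <- ncol(expr)
    p <- cor_test_p(gs, n)
    gs_logp <- sign(gs) * -log10(pmax(p, .Machine$double.xmin))
    rownames(gs) <- rownames(gs_logp) <- genes
  }

  structure(list(modules = labels, eigengenes = eig, mm = mm,
                 gs = gs, gs_logp = gs_logp, tree = tree),
            class = "module_assignment")
}

# samples x traits numeric matrix aligned to `samples`
as_trait_matrix <- function(traits, samples) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  if ("sample" %in% names(traits)) {
    rownames(traits) <- traits$sample
    traits$sample <- NULL
  }
  missing_ids <- setdiff(samples, rownames(traits))
  if (length(missing_ids))
    stop("traits lack sample(s): ", paste(head(missing_ids, 5),
                                          collapse = ", "), call. = FALSE)
  as.matrix(traits[samples, , drop = FALSE])
}

cor_test_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Module-trait correlation table
#'
#' Pearson correlation of every module eigengene with every trait, with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom.
#'
#' @param assign A `module_assignment` from [detect_modules()].
#' @param traits Samples x traits table (rownames or `sample` column).
#' @return Data frame: `module`, `trait`, `correlation`, `p_value`.
#' @export
module_trait <- function(assign, traits) {
  stopifnot(inherits(assign, "module_assignment"))
  samples <- rownames(assign$eigengenes)
  tr <- as_trait_matrix(traits, samples)
  cc <- cor(assign$eigengenes, tr)
  p <- cor_test_p(cc, length(samples))
  out <- expand.grid(module = colnames(assign$eigengenes),
                     trait = colnames(tr), stringsAsFactors = FALSE)
  out$correlation <- cc[cbind(out$module, out$trait)]
  out$p_value <- p[cbind(out$module, out$trait)]
  out
}

#' Screen module genes on membership and trait significance
#'
#' Retains genes of the target module with `|MM| > mm_min` and
#' `|GS| > gs_min` for the named trait, sorted by `|MM|` descending. GS is
#' the gene-trait correlation by default; set `gs_type = "logp"` to screen
#' on the signed `-log10` p-value instead.
#'
#' @param assign A `module_assignment` built with `traits`.
#' @param target_module Module label (not `"grey"`).
#' @param trait Trait name to screen on.
#' @param mm_min,gs_min Thresholds (default 0.5 each).
#' @param gs_type `"cor"` (default) or `"logp"`.
#' @return Character vector of screened gene identifiers.
#' @export
screen_genes <- function(assign, target_module, trait,
                         mm_min = 0.5, gs_min = 0.5,
                         gs_type = c("cor", "logp")) {
  stopifnot(inherits(assign, "module_assignment"))
  gs_type <- match.arg(gs_type)
  if (identical(target_module, "grey"))
    stop("cannot screen the unassigned 'grey' pseudo-module", call. = FALSE)
  if (!target_module %in% assign$modules)
    stop("unknown module label '", target_module, "'", call. = FALSE)
  if (is.null(assign$gs))
    stop("module assignment carries no trait GS; rerun detect_modules with ",
         "traits", call. = FALSE)
  if (!trait %in% colnames(assign$gs))
    stop("unknown trait '", trait, "'", call. = FALSE)
  in_mod <- names(assign$modules)[assign$modules == target_module]
  gs <- if (gs_type == "cor") assign$gs[, trait] else assign$gs_logp[, trait]
  ok <- in_mod[abs(assign$mm[in_mod]) > mm_min &
                 abs(gs[in_mod]) > gs_min]
  ok[order(abs(assign$mm[ok]), decreasing = TRUE)]
}
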