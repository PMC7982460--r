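# Enrichment statistics: signed maximum deviation of the GSEA running sum.
# `weights` are the per-gene increments |score|^w for the ranked list
# (descending order); `hit_idx` are the in-set positions. Only positions
# adjacent to hits can attain the extremum, so the walk is evaluated there.
calc_es <- function(weights, hit_idx, n) {
  m <- length(hit_idx)
  w_hit <- weights[hit_idx]
  tot <- sum(w_hit)
  if (tot == 0) w_hit <- rep(1 / m, m) else w_hit <- w_hit / tot
  p_hit <- cumsum(w_hit)
  dec <- 1 / (n - m)
  after <- p_hit - (hit_idx - seq_len(m)) * dec         # just after hit i
  before <- c(0, p_hit[-m]) - (hit_idx - seq_len(m)) * dec  # just before
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov-style enrichment score for each
#' gene set against a ranked gene list, with a gene-label permutation null:
#' `n_perm` random same-size sets drawn from the list give the null ES
#' distribution, the normalised enrichment score divides ES by the mean
#' absolute null ES of matching sign, the p-value is the matching-sign
#' permutation tail with add-one smoothing, and FDR is Benjamini-Hochberg
#' across sets. The leading edge is the in-set genes at or before (after,
#' for negative ES) the running-sum extremum.
#'
#' @param ranks Named numeric vector: gene -> ranking score (e.g. log2 fold
#'   change). Sorted internally in decreasing order.
#' @param sets Named list of gene sets.
#' @param n_perm Permutations (default 10000).
#' @param weight Exponent on `|score|` for hit increments (default 1; 0
#'   gives the classic unweighted statistic).
#' @param seed Permutation seed.
#' @param min_size Minimum in-list overlap for a set to be scored
#'   (default 5); smaller sets are skipped with a warning.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p_value`, `fdr`,
#'   `leading_edge` (list column).
#' @export
gsea_preranked <- function(ranks, sets, n_perm = 10000, weight = 1,
                           seed = 1, min_size = 5) {
  if (is.null(names(ranks)) || anyDuplicated(names(ranks)))
    stop("ranks must be a named vector with unique gene names", call. = FALSE)
  if (!all(is.finite(ranks))) stop("ranking scores must be finite",
                                   call. = FALSE)
  check_gene_sets(sets)
  ord <- order(ranks, decreasing = TRUE)
  genes <- names(ranks)[ord]
  weights <- abs(ranks[ord])^weight
  n <- length(genes)

  hit_lists <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(hit_lists)
  skip <- sizes < min_size | sizes >= n
  if (any(skip))
    warning("skipping set(s) with overlap < ", min_size, " or no out-set: ",
            paste(names(sets)[skip], collapse = ", "))
  keep <- which(!skip)
  if (!length(keep))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(), fdr = numeric()))

  res <- with_seed(seed, {
    lapply(keep, function(k) {
      hit_idx <- hit_lists[[k]]
      m <- length(hit_idx)
      es <- calc_es(weights, hit_idx, n)
      null_es <- vapply(seq_len(n_perm), function(i)
        calc_es(weights, sort(sample.int(n, m)), n), 0)
      same <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      # leading edge from the running-sum extremum
      w_hit <- weights[hit_idx]
      tot <- sum(w_hit)
      p_hit <- if (tot == 0) cumsum(rep(1 / m, m)) else cumsum(w_hit) / tot
      dec <- 1 / (n - m)
      if (es >= 0) {
        peak <- which.max(p_hit - (hit_idx - seq_len(m)) * dec)
        le <- genes[hit_idx[seq_len(peak)]]
      } else {
        valley <- which.min(c(0, p_hit[-m]) - (hit_idx - seq_len(m)) * dec)
        le <- genes[hit_idx[seq(valley, m)]]
      }
      list(set = names(sets)[k], size = m, es = es, nes = nes, p = p,
           le = le)
    })
  })
  out <- data.frame(
    set = vapply(res, `[[`, "", "set"),
    size = vapply(res, `[[`, 1L, "size"),
    es = vapply(res, `[[`, 0, "es"),
    nes = vapply(res, `[[`, 0, "nes"),
    p_value = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$leading_edge <- I(lapply(res, `[[`, "le"))
  out
}

#' Rank genes by group log2 fold change
#'
#' Builds the preranked list for [gsea_preranked()] as the difference of
#' group mean expression on the log2 scale (first level minus second, e.g.
#' high-risk minus low-risk).
#'
#' @param expr Genes x samples matrix on log2 scale.
#' @param groups Two-level label vector.
#' @param levels Optional explicit `c(numerator, denominator)` ordering;
#'   defaults to `c("high", "low")` when present, else sorted levels.
#' @return Named numeric vector sorted in decreasing order.
#' @export
preranked_log2fc <- function(expr, groups, levels = NULL) {
  check_expression(expr)
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(levels))
    levels <- if (all(c("high", "low") %in% levs)) c("high", "low") else levs
  fc <- rowMeans(expr[, groups == levels[1], drop = FALSE]) -
    rowMeans(expr[, groups == levels[2], drop = FALSE])
  sort(fc, decreasing = TRUE)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a hit
#' list against a gene universe, BH-adjusted across sets.
#'
#' @param hits Genes of interest (must all belong to `universe`).
#' @param universe Background gene list.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return Data frame: `set`, `overlap`, `set_size`, `p`, `fdr`.
#' @export
ora_hypergeometric <- function(hits, universe, sets) {
  universe <- unique(universe)
  hits <- unique(hits)
  off <- setdiff(hits, universe)
  if (length(off))
    stop("hit(s) not in universe: ", paste(head(off, 5), collapse = ", "),
         call. = FALSE)
  check_gene_sets(sets)
  n_u <- length(universe); n_h <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(hits, s))
    p <- if (length(s) == 0) 1 else
      phyper(k - 1, length(s), n_u - length(s), n_h, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Hub genes of an interaction network
#'
#' Collapses duplicate edges and self-loops, then returns the genes whose
#' degree strictly exceeds `min_degree`, sorted by degree.
#'
#' @param edges Two-column data frame (or matrix) of undirected edges.
#' @param min_degree Strict degree threshold (default 10, i.e. "more than
#'   10 interaction partners").
#' @return Data frame: `gene`, `degree`, sorted by degree descending.
#' @export
hub_genes <- function(edges, min_degree = 10) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 || nrow(edges) == 0)
    stop("edge list must be non-empty with two columns", call. = FALSE)
  bad <- which(!nzchar(as.character(edges[[1]])) |
                 !nzchar(as.character(edges[[2]])) |
                 is.na(edges[[1]]) | is.na(edges[[2]]))
  if (length(bad))
    stop("malformed edge at line ", bad[1], call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  deg <- deg[deg > min_degree]
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$gene), , drop = FALSE]
}

#' Read an undirected edge list from a two-column TSV
#'
#' @param path TSV path, no header, two tab-separated gene symbols per line.
#' @return Two-column data frame.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2)
  if (length(bad))
    stop("malformed edge-list line ", bad[1], call. = FALSE)
  data.frame(from = vapply(fields, `[[`, "", 1),
             to = vapply(fields, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Intersect network hubs with a risk model's genes
#'
#' @param hubs Character vector of hub genes (or output of [hub_genes()]).
#' @param model A `risk_model`.
#' @return Alphabetically sorted intersection with the union of the model's
#'   pair genes.
#' @export
intersect_key_genes <- function(hubs, model) {
  if (is.data.frame(hubs)) hubs <- hubs$gene
  sort(intersect(unique(hubs), model_genes(model)))
}
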