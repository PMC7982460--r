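# Shared fixtures and independent oracles, all built in code.

# A cohort spec small enough for fast unit tests.
small_spec <- function(seed = 1, ...) {
  args <- list(n_samples_per_group = 50, n_genes = 300, n_de_genes = 100,
               n_modules = 3, module_size = 30, within_module_cor = 0.7,
               n_planted_pairs = 2, planted_coefficients = c(1.2, -1),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

# Canonical "a|b" keys of a pair data frame (sorted within pair).
pair_keys <- function(df) {
  apply(df[, c(1, 2)], 1, function(g) paste(sort(g), collapse = "|"))
}

# Independent log-rank oracle: the classic observed-vs-expected tabulation
# over event times, two groups, no approximations shared with survdiff.
logrank_chi2_hand <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Independent Cox oracle: direct numeric maximization of the exact partial
# likelihood (valid when event times are untied).
cox_coef_optim <- function(time, event, x) {
  stopifnot(!any(duplicated(time[event == 1])))
  negpl <- function(beta) {
    eta <- beta * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + eta[i] - log(sum(exp(eta[risk])))
    }
    -s
  }
  stats::optimize(negpl, c(-20, 20), tol = 1e-10)$minimum
}

# Empirical (unweighted) ROC oracle for uncensored data: brute-force
# case-control comparisons.
empirical_roc <- function(scores, is_case) {
  thr <- c(-Inf, sort(unique(scores)))
  tpr <- vapply(thr, function(c) mean(scores[is_case] > c), 0)
  fpr <- vapply(thr, function(c) mean(scores[!is_case] > c), 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tpr[ord][-1]) / 2)
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

# Closed-form expected censoring fraction of the generator's design:
# exponential event times (hazard h_i) against uniform censoring on (0, b).
expected_censoring <- function(cohort) {
  spec <- cohort$spec
  b <- 2 / spec$censoring_rate
  h <- spec$baseline_hazard * exp(cohort$truth$linear_predictor)
  mean((1 - exp(-h * b)) / (h * b))
}

# A toy immune/stromal gene-set list matching a cohort's planted modules.
toy_gene_sets <- function(cohort) {
  labels <- cohort$truth$module_membership
  imm <- cohort$spec$immune_module_index
  other <- setdiff(sort(unique(labels[labels > 0])), imm)[1]
  list(immune = names(labels)[labels == imm],
       stromal = names(labels)[labels == other])
}

# A small random signature matrix and noisy mixtures with known weights.
toy_signature <- function(n_genes = 120, types = c("Tcell", "Bcell", "Mono"),
                          seed = 11) {
  set.seed(seed)
  sig <- matrix(runif(n_genes * length(types), 1, 60), n_genes,
                dimnames = list(sprintf("sg%03d", seq_len(n_genes)), types))
  sig
}
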