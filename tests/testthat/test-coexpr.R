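# Two perfectly separated correlation blocks, optional noise-free copies.
block_expr <- function(n_per_block = 10, n = 40, seed = 2, noise = 0) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- rbind(matrix(rep(f1, each = n_per_block), n_per_block, byrow = FALSE),
             matrix(rep(f2, each = n_per_block), n_per_block, byrow = FALSE))
  x <- x * matrix(runif(2 * n_per_block, 0.5, 2), 2 * n_per_block, n)
  if (noise > 0) x <- x + matrix(rnorm(length(x), 0, noise), nrow(x))
  dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                      sprintf("s%03d", seq_len(n)))
  x + 6
}

test_that("an exactly power-law degree sequence fits with R2 = 1", {
  k <- rep(1:10, times = 2520 / (1:10))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$slope, -1, tolerance = 1e-9)
})

test_that("power-1 adjacency is the absolute Pearson correlation", {
  expr <- block_expr(n_per_block = 1, noise = 0.5)
  a <- adjacency_matrix(expr, power = 1)
  expect_equal(a[1, 2], abs(cor(expr[1, ], expr[2, ])), tolerance = 1e-12)
  expect_equal(diag(a), c(g001 = 0, g002 = 0))
  expr["g001", ] <- 3
  expect_error(adjacency_matrix(expr, 1), "g001")
})

test_that("soft-threshold scan prefers a small power on modular data", {
  ch <- generate_cohort(cohort_spec(n_samples_per_group = 60, n_genes = 220,
                                    n_de_genes = 0, n_modules = 4,
                                    module_size = 50,
                                    within_module_cor = 0.8,
                                    n_planted_pairs = 0,
                                    planted_coefficients = numeric(0),
                                    seed = 41))
  mod_genes <- names(which(truth_report(ch)$module_labels > 0))
  st <- suppressWarnings(
    pick_soft_threshold(ch$expression[mod_genes, ], powers = 1:10))
  expect_lte(st$power, 6)
  expect_identical(st$scan$power, 1:10)
  expect_true(all(is.finite(st$scan$scale_free_r2)))
})

test_that("topological overlap matches the formula on hand and brute-force cases", {
  # all-zero off-diagonal
  z <- matrix(0, 4, 4)
  expect_equal(topological_overlap(z), diag(4))
  # 3-gene hand evaluation: a12=a13=a23=0.5 -> TOM12 = 0.75/1.5
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  expect_equal(topological_overlap(a)[1, 2], 0.5, tolerance = 1e-12)
  # brute-force triple loop on random 12-gene adjacencies
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(runif(144), 12); m <- (m + t(m)) / 2; diag(m) <- 0
    tom <- topological_overlap(m)
    k <- colSums(m)
    brute <- diag(12)
    for (i in 1:12) for (j in 1:12) if (i != j) {
      l <- sum(m[i, ] * m[, j])
      brute[i, j] <- (l + m[i, j]) / (min(k[i], k[j]) + 1 - m[i, j])
    }
    expect_lt(max(abs(tom - brute)), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
  }
  expect_error(topological_overlap(matrix(c(0, 0.2, 0.4, 0), 2)),
               "asymmetric")
})

test_that("perfectly separated blocks give two pure modules", {
  expr <- block_expr()
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  ma <- detect_modules(tom, expr, min_module_size = 5)
  labs <- ma$modules
  expect_setequal(unique(labs), c("M1", "M2"))
  expect_equal(length(unique(labs[1:10])), 1L)
  expect_equal(length(unique(labs[11:20])), 1L)
  expect_false(labs[1] == labs[11])
  # eigengenes are unit norm and as representative as any single gene
  for (m in c("M1", "M2")) {
    me <- ma$eigengenes[, m]
    expect_equal(sum(me^2), 1, tolerance = 1e-12)
    x <- t(scale(t(expr[labs == m, ])))
    var_me <- sum((x %*% me)^2)
    for (g in seq_len(nrow(x))) {
      v <- x[g, ] / sqrt(sum(x[g, ]^2))
      expect_gte(var_me + 1e-8, sum((x %*% v)^2))
    }
  }
})

test_that("negating a module's expression flips its eigengene but not |MM|", {
  expr <- block_expr(noise = 0.3)
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  ma <- detect_modules(tom, expr, min_module_size = 5)
  flipped <- expr
  m1 <- names(ma$modules)[ma$modules == "M1"]
  flipped[m1, ] <- -flipped[m1, ]
  ma2 <- detect_modules(tom, flipped, min_module_size = 5)
  expect_equal(ma2$eigengenes[, "M1"], -ma$eigengenes[, "M1"],
               tolerance = 1e-8)
  expect_equal(abs(ma2$mm[m1]), abs(ma$mm[m1]), tolerance = 1e-8)
})

test_that("module detection is invariant to gene order", {
  expr <- block_expr(noise = 0.4, seed = 9)
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  ma <- detect_modules(tom, expr, min_module_size = 5)
  perm <- sample(nrow(expr))
  ma2 <- detect_modules(tom[perm, perm], expr[perm, ], min_module_size = 5)
  ari <- mclust::adjustedRandIndex(ma$modules,
                                   ma2$modules[names(ma$modules)])
  expect_equal(ari, 1)
})

test_that("module-trait correlations behave at both extremes", {
  expr <- block_expr(noise = 0.3, seed = 5)
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  ma <- detect_modules(tom, expr, min_module_size = 5)
  traits <- data.frame(me_copy = ma$eigengenes[, "M1"],
                       noise = rnorm(ncol(expr)))
  rownames(traits) <- colnames(expr)
  mt <- module_trait(ma, traits)
  self <- mt[mt$module == "M1" & mt$trait == "me_copy", ]
  expect_equal(self$correlation, 1, tolerance = 1e-9)
  expect_lt(self$p_value, 1e-12)
  expect_lt(max(abs(mt$correlation[mt$trait == "noise"])), 0.6)
  expect_equal(nrow(mt), 4)   # every module x trait cell present
  expect_error(module_trait(ma, traits[1:10, , drop = FALSE]), "lack")
})

test_that("the MM/GS screen honors its thresholds and errors", {
  ch <- generate_cohort(small_spec(seed = 13, within_module_cor = 0.8))
  tr <- truth_report(ch)
  mod_genes <- names(which(tr$module_labels > 0))
  expr <- ch$expression[mod_genes, ]
  tom <- topological_overlap(adjacency_matrix(expr, 4))
  traits <- data.frame(sample = colnames(expr),
                       immune = tr$immune_factor)
  ma <- detect_modules(tom, expr, min_module_size = 15, traits = traits)
  mt <- module_trait(ma, traits)
  target <- mt$module[which.max(abs(mt$correlation))]
  all_in <- screen_genes(ma, target, "immune", mm_min = 0, gs_min = 0)
  expect_setequal(all_in, names(ma$modules)[ma$modules == target])
  expect_length(screen_genes(ma, target, "immune", mm_min = 1.01), 0)
  screened <- screen_genes(ma, target, "immune")
  imm_truth <- names(tr$module_labels)[tr$module_labels == tr$immune_module]
  expect_gt(mean(screened %in% imm_truth), 0.9)
  expect_error(screen_genes(ma, "M99", "immune"), "unknown module")
  expect_error(screen_genes(ma, "grey", "immune"), "grey")
  expect_error(screen_genes(ma, target, "nope"), "trait")
})
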