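surv_df <- function(time, event, ids = sprintf("s%03d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("Cox coefficients agree with direct partial-likelihood maximization", {
  set.seed(11)
  n <- 80
  x <- rbinom(n, 1, 0.4)
  time <- rexp(n, 0.05 * exp(0.9 * x))
  stopifnot(!any(duplicated(time)))      # tie-free by construction
  surv <- surv_df(time, rep(1, n))
  fit <- multivariate_cox(surv, data.frame(sample_id = surv$sample_id,
                                           x = x))
  oracle <- cox_coef_optim(time, rep(1, n), x)
  expect_lt(abs(fit$coefficient - oracle), 1e-6)
})

test_that("the univariate screen retains planted pairs and handles edge cases", {
  ch <- generate_cohort(small_spec(seed = 23))
  tr <- truth_report(ch)
  genes <- names(tr$module_labels)[tr$module_labels == tr$immune_module]
  pf <- filter_pairs(build_pairs(ch$expression, genes))
  res <- univariate_cox_screen(pf, ch$clinical)
  expect_true(all(res$p < 0.05))
  expect_false(is.unsorted(res$p))
  expect_true(all(pair_keys(tr$planted_pairs) %in% res$pair))
  # sign sanity: the strongest planted pair has a positive log-hazard
  strongest <- pair_keys(tr$planted_pairs)[which.max(tr$planted_pairs$coefficient)]
  expect_gt(res$coefficient[res$pair == strongest], 0)

  no_events <- surv_df(1:5, rep(0, 5))
  m <- matrix(rbinom(25, 1, 0.5), 5, dimnames = list(
    paste0("p", 1:5), no_events$sample_id))
  expect_error(univariate_cox_screen(m, no_events), "no events")
  expect_error(univariate_cox_screen(m[, 1:2], surv_df(1:2, c(1, 1))),
               "insufficient")
  const <- rbind(flat = rep(1L, 20))
  colnames(const) <- sprintf("s%03d", 1:20)
  expect_warning(
    univariate_cox_screen(const, surv_df(rexp(20, 0.2), rep(1, 20))),
    "constant")
})

test_that("lasso-Cox handles single and duplicated predictors coherently", {
  set.seed(31)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  surv <- surv_df(rexp(n, 0.05 * exp(1.4 * x)), rep(1, n))
  single <- matrix(x, 1, dimnames = list("a|b", surv$sample_id))
  m1 <- lasso_cox_select(single, surv, n_repeats = 5, seed = 1)
  expect_equal(nrow(m1$pairs), 1)
  expect_gt(m1$pairs$coefficient, 0)

  # duplicated copies may split the coefficient mass, but the combined
  # linear predictor must match a single-copy fit of the same design
  set.seed(32)
  noise1 <- rbinom(n, 1, 0.5); noise2 <- rbinom(n, 1, 0.5)
  base <- rbind(`a|b` = x, `n|p` = noise1, `n|q` = noise2)
  dup <- rbind(`a|b` = x, `a|c` = x, `n|p` = noise1, `n|q` = noise2)
  colnames(base) <- colnames(dup) <- surv$sample_id
  mb <- lasso_cox_select(base, surv, n_repeats = 5, seed = 1)
  md <- lasso_cox_select(dup, surv, n_repeats = 5, seed = 1)
  lp_b <- risk_score(mb, base[paste(mb$pairs$irg1, mb$pairs$irg2,
                                    sep = "|"), , drop = FALSE])
  lp_d <- risk_score(md, dup[paste(md$pairs$irg1, md$pairs$irg2,
                                   sep = "|"), , drop = FALSE])
  expect_lt(max(abs((lp_d - mean(lp_d)) - (lp_b - mean(lp_b)))), 1e-3)
})

test_that("risk scores are linear in the indicators and match the packaged model", {
  model <- published_prsm()
  n_pairs <- nrow(model$pairs)
  rn <- paste(model$pairs$irg1, model$pairs$irg2, sep = "|")
  zeros <- matrix(0, n_pairs, 3, dimnames = list(rn, c("a", "b", "c")))
  expect_equal(unname(risk_score(model, zeros)), c(0, 0, 0))
  ones <- zeros + 1
  # oracle: independent summation of the printed coefficient column
  expect_equal(unname(risk_score(model, ones))[1], 1.59, tolerance = 1e-9)
  flip <- zeros
  flip["IL2RB|ODF3B", "b"] <- 1
  expect_equal(risk_score(model, flip)[["b"]], -0.46, tolerance = 1e-12)
  # linearity over the real-valued relaxation
  set.seed(2)
  I <- matrix(runif(n_pairs * 3), n_pairs, 3, dimnames = dimnames(zeros))
  J <- matrix(runif(n_pairs * 3), n_pairs, 3, dimnames = dimnames(zeros))
  expect_equal(risk_score(model, I) + risk_score(model, J),
               risk_score(model, I + J), tolerance = 1e-12)
  expect_error(risk_score(model, zeros[-1, ]), "APBB1IP|SLA")
})

test_that("risk-group assignment uses the strict-greater rule", {
  expect_identical(assign_risk_groups(c(1.2, 0.5), 0.968), c("high", "low"))
  expect_identical(assign_risk_groups(c(0.968, 0.9681), 0.968),
                   c("low", "high"))
  expect_identical(assign_risk_groups(c(1, 2, 3), 5), rep("low", 3))
})

test_that("time-dependent ROC reduces to the empirical ROC without censoring", {
  # uninformative marker
  surv <- surv_df(c(1, 2, 6, 7, 8, 9), c(1, 1, 0, 0, 0, 0))
  flat <- time_roc(rep(2, 6), surv, horizon = 5)
  expect_equal(flat$auc, 0.5)
  # perfect separation
  surv2 <- surv_df(c(1, 2, 3, 9, 9, 9), c(1, 1, 1, 1, 1, 1))
  roc2 <- time_roc(c(10, 9, 8, 2, 1, 3), surv2, horizon = 5)
  expect_equal(roc2$auc, 1)
  expect_gte(roc2$best_cutoff, 3)
  expect_lt(roc2$best_cutoff, 8)
  # brute-force concordance oracle: cases at scores 1, 4, 5
  surv3 <- surv_df(c(1, 9, 9, 2, 3, 9), rep(1, 6))
  roc3 <- time_roc(1:6, surv3, horizon = 5)
  expect_equal(roc3$auc, 4 / 9, tolerance = 1e-12)
  # random uncensored data: full curve equality with the empirical ROC
  set.seed(12)
  sc <- rnorm(40)
  tm <- rexp(40, 0.1)
  sv <- surv_df(tm, rep(1, 40))
  h <- median(tm)
  mine <- time_roc(sc, sv, h)
  emp <- empirical_roc(sc, tm <= h)
  expect_equal(mine$tpr, emp$tpr, tolerance = 1e-12)
  expect_equal(mine$fpr, emp$fpr, tolerance = 1e-12)
  expect_equal(mine$auc, emp$auc, tolerance = 1e-12)
  expect_error(time_roc(sc, sv, max(tm) + 1), "controls")
  expect_error(time_roc(sc, sv, min(tm) / 2), "cases")
})

test_that("Kaplan-Meier curves are proper and the log-rank test matches hand tabulation", {
  # identical groups: duplicate every sample into both labels
  t0 <- c(2, 4, 6, 8); e0 <- c(1, 0, 1, 1)
  surv <- surv_df(c(t0, t0), c(e0, e0))
  res <- km_logrank(surv, rep(c("a", "b"), each = 4))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  toy <- surv_df(c(1, 2, 3, 4, 5, 6), rep(1, 6))
  grp <- rep(c("A", "B"), each = 3)
  res2 <- km_logrank(toy, grp)
  expect_equal(res2$chi2, logrank_chi2_hand(toy$time, toy$event, grp),
               tolerance = 1e-9)
  expect_lt(res2$p, 0.05)

  s <- summary(res2$fit)
  expect_true(all(s$surv <= 1 & s$surv >= 0))
  km_all <- survival::survfit(survival::Surv(time, event) ~ 1,
                              data = toy)
  expect_true(all(diff(km_all$surv) <= 1e-12))   # non-increasing
  expect_equal(min(km_all$time[km_all$surv < 1]) > 0, TRUE)

  expect_error(km_logrank(toy, rep("A", 6)), "2 groups")
})

test_that("multivariate Cox matches the univariate fit and resists noise covariates", {
  ch <- generate_cohort(cohort_spec(n_samples_per_group = 150, seed = 51))
  tr <- truth_report(ch)
  lp <- tr$linear_predictor
  cov1 <- data.frame(sample_id = ch$clinical$sample_id, rs = lp)
  solo <- multivariate_cox(ch$clinical, cov1)
  ref <- survival::coxph(
    survival::Surv(ch$clinical$time, ch$clinical$event) ~ lp, ties = "efron")
  expect_equal(solo$coefficient, unname(coef(ref)), tolerance = 1e-10)

  deltas <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    cov2 <- cov1; cov2$noise <- rnorm(nrow(cov1))
    both <- multivariate_cox(ch$clinical, cov2)
    abs(both$coefficient[both$covariate == "rs"] - solo$coefficient)
  }, 0)
  expect_lt(max(deltas), 0.05)

  cov3 <- cov1; cov3$stage <- sample(c("I", "II"), nrow(cov1), TRUE)
  expect_error(multivariate_cox(ch$clinical, cov3), "stage")
})

test_that("the risk score stays significant after adjusting for the group label", {
  hits <- vapply(1:10, function(s) {
    ch <- generate_cohort(cohort_spec(n_samples_per_group = 150,
                                      seed = 600 + s))
    cov <- data.frame(sample_id = ch$clinical$sample_id,
                      rs = truth_report(ch)$linear_predictor,
                      right = as.numeric(ch$clinical$group == "right"))
    fit <- multivariate_cox(ch$clinical, cov)
    fit$p[fit$covariate == "rs"] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("maxstat cutpoints match exhaustive evaluation", {
  # bimodal marker perfectly separating early from late deaths
  values <- c(1, 1.2, 1.1, 0.9, 5, 5.2, 5.1, 4.9, 5.3, 1.05)
  surv <- surv_df(c(10, 11, 12, 13, 1, 2, 1.5, 2.5, 1.2, 10.5),
                  rep(1, 10))
  res <- maxstat_cutpoint(values, surv)
  expect_gte(res$cutpoint, 1.2)
  expect_lt(res$cutpoint, 5)

  # brute-force oracle over every admissible split of a toy marker
  set.seed(9)
  v <- round(runif(12, 0, 10), 2)
  sv <- surv_df(rexp(12, 0.1 * exp(0.3 * (v > 5))), rbinom(12, 1, 0.8))
  if (sum(sv$event) >= 2) {
    got <- maxstat_cutpoint(v, sv)
    qs <- quantile(v, c(0.1, 0.9))
    cand <- sort(unique(v)); cand <- cand[cand >= qs[1] & cand <= qs[2]]
    stats <- vapply(cand, function(cut) {
      hi <- v > cut
      if (!any(hi) || all(hi)) return(-Inf)
      logrank_chi2_hand(sv$time, sv$event, hi)
    }, 0)
    expect_equal(got$max_statistic, max(stats), tolerance = 1e-9)
    expect_equal(got$cutpoint, cand[which.max(stats)])
  }
  expect_error(maxstat_cutpoint(rep(1, 12), surv_df(1:12, rep(1, 12))),
               "identical")
})

test_that("risk models serialize losslessly and validate their contents", {
  m <- risk_model(data.frame(irg1 = c("A", "B"), irg2 = c("C", "D"),
                             coefficient = c(0.5, -0.25)),
                  cutoff = 0.3, provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  back <- read_risk_model(path)
  expect_equal(back$pairs, m$pairs)
  expect_equal(back$cutoff, 0.3)
  expect_error(risk_model(data.frame(irg1 = "A", irg2 = "A",
                                     coefficient = 1)), "distinct")
  expect_error(risk_model(data.frame(irg1 = c("A", "C"), irg2 = c("C", "A"),
                                     coefficient = c(1, 2))), "duplicate")
  expect_error(risk_model(data.frame(irg1 = "A", irg2 = "B",
                                     coefficient = Inf)), "finite")
})
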