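#' Construct a gene-pair risk model
#'
#' A risk model is an ordered list of gene pairs with log-hazard
#' coefficients plus a dichotomisation cutoff on the risk score. Each pair
#' is stored in the orientation its coefficient was fitted under: the
#' indicator is 1 when `irg1` exceeds `irg2` within a sample.
#'
#' @param pairs Data frame with columns `irg1`, `irg2`, `coefficient`.
#' @param cutoff Risk-score cutoff (strictly-greater rule); `NA` if unset.
#' @param provenance Free-text origin of the model.
#' @return A `risk_model` object.
#' @export
risk_model <- function(pairs, cutoff = NA_real_, provenance = "") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("irg1", "irg2", "coefficient")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns irg1, irg2, coefficient", call. = FALSE)
  if (any(pairs$irg1 == pairs$irg2))
    stop("a pair must reference two distinct genes", call. = FALSE)
  key <- apply(pairs[, c("irg1", "irg2")], 1,
               function(g) paste(sort(g), collapse = "|"))
  if (anyDuplicated(key)) stop("duplicate gene pair in model", call. = FALSE)
  if (!all(is.finite(pairs$coefficient)))
    stop("model coefficients must be finite", call. = FALSE)
  if (!is.na(cutoff) && !is.finite(cutoff))
    stop("cutoff must be finite or NA", call. = FALSE)
  structure(list(pairs = pairs[, need], cutoff = cutoff,
                 provenance = provenance), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model:", nrow(x$pairs), "gene pairs; cutoff =",
      format(x$cutoff), "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  print(x$pairs)
  invisible(x)
}

#' Read / write a risk model as JSON
#'
#' @param path JSON file path.
#' @return `read_risk_model`: a `risk_model`; `write_risk_model`:
#'   invisibly, `path`.
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  risk_model(obj$pairs,
             cutoff = if (is.null(obj$cutoff)) NA_real_ else obj$cutoff,
             provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

#' @rdname read_risk_model
#' @param model A `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(pairs = model$pairs, cutoff = model$cutoff,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' The packaged published 16-pair colon-adenocarcinoma risk model
#'
#' Sixteen immune-related gene pairs with lasso-Cox coefficients and the
#' published risk-score cutoff of 0.968, transcribed from the source
#' publication's model table.
#'
#' @return A `risk_model` with 16 pairs.
#' @export
published_prsm <- function() {
  read_risk_model(system.file("extdata", "published_prsm.json",
                              package = "irgpairs", mustWork = TRUE))
}

#' Genes referenced by a risk model
#'
#' @param model A `risk_model`.
#' @return Sorted unique gene identifiers across both pair positions.
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  sort(unique(c(model$pairs$irg1, model$pairs$irg2)))
}

#' Univariate Cox screen of gene-pair indicators
#'
#' Fits a proportional-hazards model (Efron tie handling) to each binary
#' pair indicator separately and retains pairs with Wald `p < alpha`,
#' sorted by p-value.
#'
#' @param pairs Pairs x samples binary matrix.
#' @param surv Survival table (`sample_id`, `time`, `event`).
#' @param alpha Retention threshold (default 0.05).
#' @return Data frame: `pair`, `coefficient`, `hazard_ratio`, `p`.
#' @export
univariate_cox_screen <- function(pairs, surv, alpha = 0.05) {
  pairs <- align_samples(pairs, surv)
  if (nrow(surv) < 3)
    stop("insufficient risk sets: need at least 3 samples", call. = FALSE)
  if (sum(surv$event) < 1) stop("no events in survival table", call. = FALSE)
  y <- survival::Surv(surv$time, surv$event)
  res <- lapply(rownames(pairs), function(pr) {
    x <- pairs[pr, ]
    if (length(unique(x)) < 2) {
      warning("pair ", pr, " is constant after alignment; skipped")
      return(NULL)
    }
    fit <- suppressWarnings(
      survival::coxph(y ~ x, ties = "efron",
                      control = survival::coxph.control(iter.max = 50)))
    s <- summary(fit)$coefficients
    data.frame(pair = pr, coefficient = s[1, "coef"],
               hazard_ratio = s[1, "exp(coef)"],
               p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(pair = character(), coefficient = numeric(),
                      hazard_ratio = numeric(), p = numeric()))
  res <- res[!is.na(res$p) & res$p < alpha, , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Lasso-Cox selection of prognostic gene pairs
#'
#' Fits the L1-penalised Cox path (`glmnet`) over the screened pair
#' indicators and picks the penalty minimising the cross-validated partial
#' likelihood deviance, where the deviance curve is averaged over
#' `n_repeats` independently randomised fold assignments to stabilise the
#' choice. Pairs with nonzero coefficients at the chosen penalty form the
#' model.
#'
#' @param pairs Screened pairs x samples binary matrix (rownames
#'   `"irg1|irg2"` in fitted orientation).
#' @param surv Survival table.
#' @param n_repeats Fold-randomisation repeats (default 1000; tests and the
#'   pipeline default use far fewer).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignments.
#' @param rule `"min"` (default) for the deviance-minimising penalty or
#'   `"1se"` for the sparsest model within one standard error of it.
#' @return A `risk_model` (cutoff unset).
#' @export
lasso_cox_select <- function(pairs, surv, n_repeats = 1000, n_folds = 10,
                             seed = 1, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  pairs <- align_samples(pairs, surv)
  if (sum(surv$event) < n_folds)
    stop("need at least n_folds events for cross-validation", call. = FALSE)
  y <- survival::Surv(surv$time, surv$event)
  empty <- function() {
    warning("no pair selected at the chosen penalty; returning empty model")
    risk_model(data.frame(irg1 = character(), irg2 = character(),
                          coefficient = numeric()),
               provenance = "lasso_cox_select (empty)")
  }
  if (nrow(pairs) == 1) {
    # the penalty path is degenerate with one predictor; use the
    # unpenalised partial-likelihood fit
    x <- pairs[1, ]
    fit <- survival::coxph(y ~ x, ties = "efron")
    g <- strsplit(rownames(pairs), "|", fixed = TRUE)[[1]]
    return(risk_model(data.frame(irg1 = g[1], irg2 = g[2],
                                 coefficient = unname(coef(fit))),
                      provenance = "single-pair cox fit"))
  }
  x <- t(pairs)
  full <- glmnet::glmnet(x, y, family = "cox", alpha = 1, nlambda = 60)
  lambda <- full$lambda
  cvm_sum <- cvsd_sum <- rep(0, length(lambda))
  hits <- rep(0L, length(lambda))
  with_seed(seed, {
    n <- nrow(x)
    for (r in seq_len(n_repeats)) {
      foldid <- sample(rep_len(seq_len(n_folds), n))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                              lambda = lambda, type.measure = "deviance")
      m <- match(cv$lambda, lambda)
      cvm_sum[m] <- cvm_sum[m] + cv$cvm
      cvsd_sum[m] <- cvsd_sum[m] + cv$cvsd
      hits[m] <- hits[m] + 1L
    }
  })
  ok <- hits == max(hits)
  cvm <- cvm_sum[ok] / hits[ok]
  cvsd <- cvsd_sum[ok] / hits[ok]
  lam <- lambda[ok]
  i_min <- which.min(cvm)
  chosen <- if (rule == "min") lam[i_min] else
    max(lam[cvm <= cvm[i_min] + cvsd[i_min]])
  b <- as.vector(coef(full, s = chosen))
  nz <- which(b != 0)
  if (!length(nz)) return(empty())
  g <- do.call(rbind, strsplit(rownames(pairs)[nz], "|", fixed = TRUE))
  risk_model(data.frame(irg1 = g[, 1], irg2 = g[, 2], coefficient = b[nz],
                        stringsAsFactors = FALSE),
             provenance = sprintf(
               "lasso-Cox, rule=%s, lambda=%.6g, %d repeats x %d folds",
               rule, chosen, n_repeats, n_folds))
}

#' Risk score of samples under a pair model
#'
#' `RS(sample) = sum_k coefficient_k * indicator_k(sample)`, the linear
#' predictor of the pair model. The indicator matrix must contain each
#' model pair as a row named `"irg1|irg2"` in the model's own orientation
#' (see [build_model_pairs()]).
#'
#' @param model A `risk_model`.
#' @param pairs Pairs x samples indicator matrix.
#' @return Named numeric vector of risk scores.
#' @export
risk_score <- function(model, pairs) {
  stopifnot(inherits(model, "risk_model"))
  want <- paste(model$pairs$irg1, model$pairs$irg2, sep = "|")
  missing_pairs <- setdiff(want, rownames(pairs))
  if (length(missing_pairs))
    stop("model pair(s) absent from indicator matrix: ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  colSums(model$pairs$coefficient * pairs[want, , drop = FALSE])
}

#' Dichotomise risk scores
#'
#' Strictly-greater rule: `score > cutoff` is `"high"`, otherwise `"low"`.
#'
#' @param scores Numeric risk scores.
#' @param cutoff Finite cutoff.
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
assign_risk_groups <- function(scores, cutoff) {
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  ifelse(scores > cutoff, "high", "low")
}

# Kaplan-Meier estimate of the censoring survivor function G(t) = P(C > t),
# evaluated with a left limit for case weights.
censoring_km <- function(surv) {
  fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  steps <- stats::stepfun(fit$time, c(1, fit$surv))
  function(t, left = FALSE) {
    g <- if (left) steps(t - .Machine$double.eps^0.5 * max(1, abs(t)))
         else steps(t)
    pmax(g, .Machine$double.eps)
  }
}

#' Time-dependent ROC with censoring-weighted estimates
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' samples with an observed event by the horizon, controls are samples
#' still under observation beyond it. Censoring is handled by weighting
#' each sample inversely by the Kaplan-Meier estimate of the censoring
#' survivor function, which reduces to the empirical ROC when no sample is
#' censored. The optimal cutoff maximises Youden's J (ties resolved to the
#' lower threshold).
#'
#' @param scores Named or plain numeric marker values, aligned with `surv`.
#' @param surv Survival table.
#' @param horizon Evaluation time (same unit as `surv$time`).
#' @return A `time_roc` list: `horizon`, `thresholds`, `fpr`, `tpr`, `auc`,
#'   `best_cutoff`, `youden`.
#' @export
time_roc <- function(scores, surv, horizon) {
  check_survival(surv)
  if (length(scores) != nrow(surv))
    stop("scores and survival table differ in length", call. = FALSE)
  is_case <- surv$time <= horizon & surv$event == 1
  is_control <- surv$time > horizon
  if (!any(is_case)) stop("no cases by horizon ", horizon, call. = FALSE)
  if (!any(is_control)) stop("no controls beyond horizon ", horizon,
                             call. = FALSE)
  G <- censoring_km(surv)
  w <- numeric(nrow(surv))
  w[is_case] <- 1 / G(surv$time[is_case], left = TRUE)
  w[is_control] <- 1 / G(horizon)

  thresholds <- c(-Inf, sort(unique(scores)))
  tpr <- fpr <- numeric(length(thresholds))
  wc <- sum(w[is_case]); wk <- sum(w[is_control])
  for (i in seq_along(thresholds)) {
    pos <- scores > thresholds[i]
    tpr[i] <- sum(w[is_case & pos]) / wc
    fpr[i] <- sum(w[is_control & pos]) / wk
  }
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tpr[ord][-1]) / 2)
  finite <- is.finite(thresholds)
  j <- tpr + (1 - fpr) - 1
  jf <- j[finite]
  thf <- thresholds[finite]
  best <- thf[which(jf == max(jf))]
  structure(list(horizon = horizon, thresholds = thresholds,
                 fpr = fpr, tpr = tpr, auc = auc,
                 best_cutoff = min(best), youden = max(jf)),
            class = "time_roc")
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param surv Survival table.
#' @param groups Group label per sample.
#' @return List: `fit` (a `survfit` object with the product-limit curves),
#'   `chi2`, `df`, `p`.
#' @export
km_logrank <- function(surv, groups) {
  check_survival(surv)
  groups <- as.character(groups)
  if (length(groups) != nrow(surv))
    stop("groups must have one label per sample", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab == 0)) stop("a group has zero samples", call. = FALSE)
  d <- data.frame(time = surv$time, event = surv$event, g = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- length(sd$n) - 1
  list(fit = fit, chi2 = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox regression of survival on covariates
#'
#' Joint proportional-hazards fit (Efron ties) of all supplied numeric
#' covariates, typically the risk score plus clinical factors, reporting
#' Wald confidence intervals and p-values.
#'
#' @param surv Survival table.
#' @param covariates Data frame with `sample_id` plus numeric covariate
#'   columns (encode categorical factors as numeric indicators first).
#' @return Data frame: `covariate`, `coefficient`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
multivariate_cox <- function(surv, covariates) {
  check_survival(surv)
  if (!"sample_id" %in% names(covariates))
    stop("covariates need a sample_id column", call. = FALSE)
  m <- match(surv$sample_id, covariates$sample_id)
  if (anyNA(m))
    stop("covariates lack sample(s): ",
         paste(head(surv$sample_id[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  x <- covariates[m, setdiff(names(covariates), "sample_id"), drop = FALSE]
  bad <- names(x)[!vapply(x, is.numeric, TRUE)]
  if (length(bad))
    stop("non-numeric covariate without encoding: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (sum(surv$event) < 10)
    warning("fewer than 10 events; multivariate estimates will be unstable")
  d <- cbind(data.frame(time = surv$time, event = surv$event), x)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = d,
                         ties = "efron")
  s <- summary(fit)
  data.frame(covariate = rownames(s$coefficients),
             coefficient = s$coefficients[, "coef"],
             hazard_ratio = s$conf.int[, "exp(coef)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every observed marker value inside a quantile window as a
#' candidate two-group split and returns the one maximising the log-rank
#' chi-square statistic (ties resolved to the lower cutpoint).
#'
#' @param values Continuous marker, one value per sample.
#' @param surv Survival table.
#' @param quantile_window Candidate window as marker quantiles
#'   (default `c(0.1, 0.9)`).
#' @return List: `cutpoint`, `max_statistic` (log-rank chi-square).
#' @export
maxstat_cutpoint <- function(values, surv, quantile_window = c(0.1, 0.9)) {
  check_survival(surv)
  if (length(values) != nrow(surv))
    stop("values and survival table differ in length", call. = FALSE)
  if (length(values) < 10) stop("need at least 10 samples", call. = FALSE)
  if (sum(surv$event) < 2) stop("need at least 2 events", call. = FALSE)
  if (length(unique(values)) < 2)
    stop("all marker values identical; no cutpoint exists", call. = FALSE)
  qs <- quantile(values, quantile_window)
  cand <- sort(unique(values))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  d <- data.frame(time = surv$time, event = surv$event)
  best_stat <- -Inf; best_cut <- NA_real_
  for (cut in cand) {
    hi <- values > cut
    if (!any(hi) || all(hi)) next
    d$g <- hi
    stat <- survival::survdiff(survival::Surv(time, event) ~ g,
                               data = d)$chisq
    if (stat > best_stat + 1e-12) {   # strict improvement keeps lower ties
      best_stat <- stat; best_cut <- cut
    }
  }
  if (!is.finite(best_stat))
    stop("no admissible cutpoint inside the quantile window", call. = FALSE)
  list(cutpoint = best_cut, max_statistic = best_stat)
}
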