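#' Specify a synthetic two-arm cohort
#'
#' Defines the generative model for a synthetic transcriptomic cohort with
#' survival follow-up: two sample groups (`left` / `right`) with a block of
#' differentially expressed genes, several co-expressed gene modules each
#' driven by a latent factor (one of which plays the role of the immune
#' axis), and exponential proportional-hazards survival driven by a planted
#' set of binary gene-pair indicators.
#'
#' Expression is generated directly on the log2 scale as
#' `mu_g + noise_sd * (sqrt(rho) * factor_m + sqrt(1 - rho) * eps)`, so
#' `within_module_cor` is the exact pairwise correlation between two genes
#' of the same module. Genes `1..n_de_genes` receive a `+de_log2fc` mean
#' shift in group `right`; modules occupy genes `1..(module_size*n_modules)`,
#' so with the defaults every module gene is differentially expressed — the
#' structure the downstream module-screening stage assumes. Censoring is
#' administrative: uniform on `(0, 2/censoring_rate)`.
#'
#' @param n_samples_per_group Samples per arm.
#' @param n_genes Total genes.
#' @param n_de_genes Genes receiving the group mean shift.
#' @param de_log2fc Mean shift (log2 units) for group `right`.
#' @param n_modules Number of latent-factor modules.
#' @param module_size Genes per module.
#' @param immune_module_index Which module's factor is the true immune score.
#' @param within_module_cor Pairwise correlation within a module, in (0, 1).
#' @param n_planted_pairs Number of prognostic gene pairs planted in the
#'   immune module.
#' @param planted_coefficients Log-hazard coefficient per planted pair.
#' @param baseline_hazard Exponential baseline hazard (events per time unit).
#' @param censoring_rate Censoring intensity; censor times are uniform on
#'   `(0, 2/censoring_rate)` (mean `1/censoring_rate`).
#' @param noise_sd Per-gene standard deviation (log2 units).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @param design_seed Seed for the cohort *design* (per-gene baseline means
#'   and the identity of the planted pairs). Kept separate from `seed` so
#'   that cohorts drawn with different seeds but the same spec share the
#'   same planted prognostic pairs — the setting needed to fit a model on
#'   one cohort and validate it on an independent one.
#' @return A validated `cohort_spec` object.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_samples_per_group = 200,
                        n_genes = 1000,
                        n_de_genes = 300,
                        de_log2fc = 1,
                        n_modules = 4,
                        module_size = 50,
                        immune_module_index = 1,
                        within_module_cor = 0.7,
                        n_planted_pairs = 3,
                        planted_coefficients = c(1.5, 1, -1),
                        baseline_hazard = 0.05,
                        censoring_rate = 0.02,
                        noise_sd = 1,
                        seed = 1,
                        design_seed = 20) {
  spec <- structure(
    list(n_samples_per_group = n_samples_per_group, n_genes = n_genes,
         n_de_genes = n_de_genes, de_log2fc = de_log2fc,
         n_modules = n_modules, module_size = module_size,
         immune_module_index = immune_module_index,
         within_module_cor = within_module_cor,
         n_planted_pairs = n_planted_pairs,
         planted_coefficients = planted_coefficients,
         baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
         noise_sd = noise_sd, seed = seed, design_seed = design_seed),
    class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why)
    stop("invalid cohort_spec: field '", field, "' ", why, call. = FALSE)
  pos_int <- function(field) {
    v <- spec[[field]]
    if (length(v) != 1 || !is.numeric(v) || v < 1 || v != round(v))
      fail(field, "must be a positive integer")
  }
  pos_int("n_samples_per_group"); pos_int("n_genes")
  pos_int("n_modules"); pos_int("module_size")
  if (spec$n_de_genes < 0 || spec$n_de_genes != round(spec$n_de_genes))
    fail("n_de_genes", "must be a non-negative integer")
  if (spec$n_de_genes > spec$n_genes)
    fail("n_de_genes", "exceeds n_genes")
  if (spec$module_size * spec$n_modules > spec$n_genes)
    fail("module_size", "module_size * n_modules exceeds n_genes")
  if (spec$immune_module_index < 1 || spec$immune_module_index > spec$n_modules)
    fail("immune_module_index", "out of range")
  if (spec$within_module_cor <= 0 || spec$within_module_cor >= 1)
    fail("within_module_cor", "must lie strictly between 0 and 1")
  if (spec$n_planted_pairs != length(spec$planted_coefficients))
    fail("planted_coefficients", "length must equal n_planted_pairs")
  if (spec$n_planted_pairs > choose(spec$module_size, 2))
    fail("n_planted_pairs", "exceeds the number of pairs in the immune module")
  if (spec$baseline_hazard <= 0) fail("baseline_hazard", "must be positive")
  if (spec$censoring_rate <= 0) fail("censoring_rate", "must be positive")
  if (spec$noise_sd <= 0) fail("noise_sd", "must be positive")
  if (length(spec$seed) != 1 || !is.numeric(spec$seed))
    fail("seed", "must be a single number")
  if (length(spec$design_seed) != 1 || !is.numeric(spec$design_seed))
    fail("design_seed", "must be a single number")
  spec
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws expression, clinical follow-up and a truth record from a
#' [cohort_spec()]. Survival times are exponential with hazard
#' `baseline_hazard * exp(sum_k coef_k * I_k)`, where `I_k` is the binary
#' within-sample indicator of planted pair `k` (1 when the first gene's
#' expression exceeds the second's, ties scored 0 — the same rule as
#' [build_pairs()], so generation and inference agree).
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `expression` (genes x samples,
#'   log2 scale), `clinical` (`sample_id`, `time`, `event`, `group`, `age`)
#'   and `truth` (DE gene ids, module memberships, per-sample immune factor,
#'   planted pairs with coefficients and the planted linear predictor).
#' @examples
#' ch <- generate_cohort(cohort_spec(n_samples_per_group = 30, n_genes = 200,
#'   n_de_genes = 60, module_size = 20, n_planted_pairs = 1,
#'   planted_coefficients = 1.2, seed = 7))
#' dim(ch$expression)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- 2L * spec$n_samples_per_group
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  samples <- sprintf("s%04d", seq_len(n))
  group <- rep(c("left", "right"), each = spec$n_samples_per_group)

  module_of <- integer(spec$n_genes)            # 0 = background
  n_mod_genes <- spec$module_size * spec$n_modules
  module_of[seq_len(n_mod_genes)] <-
    rep(seq_len(spec$n_modules), each = spec$module_size)
  is_de <- seq_len(spec$n_genes) <= spec$n_de_genes

  # The cohort *design* — baseline means and planted pair identity — is
  # drawn under design_seed so every cohort from the same spec shares it
  # (a model fitted on one cohort is then validatable on another). Pairs
  # are planted between baseline-matched genes of the immune module with
  # equal DE status, so their indicators are balanced in expectation and
  # unconfounded with the group contrast.
  design <- with_seed(spec$design_seed, {
    mu <- runif(spec$n_genes, 4, 10)
    planted_idx <- NULL
    if (spec$n_planted_pairs > 0) {
      imm_idx <- which(module_of == spec$immune_module_index)
      pool <- combn(imm_idx, 2)
      ok <- abs(mu[pool[1, ]] - mu[pool[2, ]]) <= 0.25 * spec$noise_sd &
        is_de[pool[1, ]] == is_de[pool[2, ]]
      if (sum(ok) < spec$n_planted_pairs)
        stop("invalid cohort_spec: field 'n_planted_pairs' exceeds the ",
             "number of baseline-matched pairs available in the immune ",
             "module", call. = FALSE)
      planted_idx <- pool[, sample(which(ok), spec$n_planted_pairs),
                          drop = FALSE]
    }
    list(mu = mu, planted_idx = planted_idx)
  })
  mu <- design$mu

  with_seed(spec$seed, {
    factors <- matrix(rnorm(spec$n_modules * n), spec$n_modules, n)
    rho <- spec$within_module_cor
    eps <- matrix(rnorm(spec$n_genes * n), spec$n_genes, n)
    expr <- mu + spec$noise_sd * eps
    if (n_mod_genes > 0) {
      idx <- seq_len(n_mod_genes)
      expr[idx, ] <- mu[idx] + spec$noise_sd *
        (sqrt(rho) * factors[module_of[idx], , drop = FALSE] +
           sqrt(1 - rho) * eps[idx, , drop = FALSE])
    }
    de_genes <- genes[is_de]
    if (spec$n_de_genes > 0)
      expr[is_de, group == "right"] <-
        expr[is_de, group == "right"] + spec$de_log2fc
    dimnames(expr) <- list(genes, samples)

    planted <- NULL
    lp <- numeric(n)
    if (!is.null(design$planted_idx)) {
      planted <- data.frame(
        gene_a = genes[design$planted_idx[1, ]],
        gene_b = genes[design$planted_idx[2, ]],
        coefficient = spec$planted_coefficients,
        stringsAsFactors = FALSE)
      for (k in seq_len(nrow(planted))) {
        ind <- as.numeric(expr[planted$gene_a[k], ] > expr[planted$gene_b[k], ])
        lp <- lp + planted$coefficient[k] * ind
      }
    }

    hazard <- spec$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    t_cens <- runif(n, 0, 2 / spec$censoring_rate)
    clinical <- data.frame(
      sample_id = samples,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      group = group,
      age = round(rnorm(n, 65, 10), 1),
      stringsAsFactors = FALSE)

    structure(list(
      expression = expr,
      clinical = clinical,
      truth = list(
        de_genes = de_genes,
        module_membership = setNames(module_of, genes),
        immune_factor = setNames(factors[spec$immune_module_index, ], samples),
        planted_pairs = planted,
        linear_predictor = setNames(lp, samples)),
      spec = spec), class = "synthetic_cohort")
  })
}

#' Ground truth of a synthetic cohort, keyed by pipeline stage
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @return Named list: `de_genes`, `module_labels` (named integer vector,
#'   0 = background), `immune_module`, `immune_factor`, `planted_pairs`,
#'   `linear_predictor`.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  list(de_genes = cohort$truth$de_genes,
       module_labels = cohort$truth$module_membership,
       immune_module = cohort$spec$immune_module_index,
       immune_factor = cohort$truth$immune_factor,
       planted_pairs = cohort$truth$planted_pairs,
       linear_predictor = cohort$truth$linear_predictor)
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression goes to `expression.tsv` (genes x samples), clinical to
#' `clinical.tsv`, and the truth record to `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix_tsv(cohort$expression, paths["expression"], id_col = "gene")
  write.table(cohort$clinical, paths["clinical"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(de_genes = truth$de_genes,
         module_membership = as.list(truth$module_membership),
         immune_factor = as.list(truth$immune_factor),
         planted_pairs = truth$planted_pairs),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genes-x-samples expression matrix from TSV
#'
#' First column = gene identifiers, remaining columns = samples.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  check_expression(mat)
}
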