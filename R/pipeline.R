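#' Read a pipeline configuration file
#'
#' Flat YAML: input paths (`expression`, `clinical`, `gene_sets`, optional
#' `signature_matrix`, `edge_list`, `model`), `outdir`, `seed`, `mode`
#' (`fit` or `score`) and optional `<stage>.<parameter>` overrides under a
#' `params` block.
#'
#' @param path YAML file.
#' @return Config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed explicitly",
                              call. = FALSE)
  cfg
}

default_params <- function() {
  list(
    dge = list(fc_threshold = 0.5, alpha = 0.05),
    ssgsea = list(exponent = 0.25),
    coexpr = list(powers = 1:20, r2_target = 0.9, min_module_size = 30,
                  cut_height = NULL, mm_min = 0.5, gs_min = 0.5),
    irgp = list(min_minority_fraction = 0.2),
    surv = list(alpha = 0.05, n_repeats = 25, n_folds = 10, rule = "min",
                horizon = NULL),
    deconv = list(n_perm = 100),
    gsea = list(n_perm = 1000, weight = 1, min_size = 5),
    hubs = list(min_degree = 10))
}

merge_params <- function(user) {
  p <- default_params()
  for (stage in names(user))
    for (key in names(user[[stage]]))
      p[[stage]][[key]] <- user[[stage]][[key]]
  p
}

#' Run the full gene-pair prognostic analysis
#'
#' Orchestrates the end-to-end chain on one cohort. In `fit` mode:
#' differential expression between the two sample groups, per-sample
#' immune/stromal scoring, co-expression module detection on the DEGs,
#' selection of the module most correlated with the immune score, the
#' MM/GS gene screen, all-pairs indicator construction and imbalance
#' filtering, univariate Cox screening, lasso-Cox selection, risk scoring,
#' ROC-derived cutoff, risk-group assignment and Kaplan-Meier/log-rank and
#' multivariate-Cox validation, plus (when inputs are supplied) immune
#' deconvolution, preranked GSEA between risk groups and network hub
#' intersection. In `score` mode an existing model file is applied without
#' any fitting. Every intermediate is written to `outdir` as TSV/JSON and a
#' manifest records the count funnel and all effective parameters.
#'
#' @param config Config list (see [read_pipeline_config()]) or a YAML path.
#'   Inputs may also be passed in-memory via elements `expression_matrix`,
#'   `clinical_table`, `gene_set_list`, `signature` and `model_object`.
#' @param mode `"fit"` or `"score"` (default: `config$mode`, else `"fit"`).
#' @return The manifest list, invisibly; side effect: files under `outdir`.
#' @export
run_pipeline <- function(config, mode = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(mode)) mode <- if (is.null(config$mode)) "fit" else config$mode
  mode <- match.arg(mode, c("fit", "score"))
  if (is.null(config$seed)) stop("config must set a seed explicitly",
                                 call. = FALSE)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must set outdir", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- merge_params(config$params)
  seed <- config$seed

  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_path <- function(f) file.path(outdir, f)

  expr <- stage("input", {
    if (!is.null(config$expression_matrix)) config$expression_matrix
    else read_expression_tsv(config$expression)
  })
  clinical <- stage("input", {
    cl <- if (!is.null(config$clinical_table)) config$clinical_table
          else read.delim(config$clinical, stringsAsFactors = FALSE)
    check_survival(cl)
  })
  expr <- stage("input", align_samples(expr, clinical))

  manifest <- list(mode = mode, seed = seed, params = params,
                   n_samples = ncol(expr), n_genes = nrow(expr),
                   counts = list(), outputs = list())
  record <- function(key, value) {
    manifest$counts[[key]] <<- value
    manifest
  }

  if (mode == "score") {
    model <- stage("model", {
      if (!is.null(config$model_object)) config$model_object
      else read_risk_model(config$model)
    })
    scores <- stage("score", {
      ind <- build_model_pairs(model, expr)
      risk_score(model, ind)
    })
    groups <- stage("score", assign_risk_groups(scores, model$cutoff))
    risk <- data.frame(sample_id = names(scores), risk_score = scores,
                       risk_group = groups, row.names = NULL)
    write.table(risk, out_path("risk.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    km <- stage("km", km_logrank(clinical, groups))
    record("model_pairs", nrow(model$pairs))
    record("high_risk", sum(groups == "high"))
    record("low_risk", sum(groups == "low"))
    manifest$km <- list(chi2 = km$chi2, p = km$p)
    manifest$outputs$risk <- "risk.tsv"
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(manifest))
  }

  # ---- fit mode ----------------------------------------------------------
  de <- stage("dge", moderated_de(expr, clinical$group,
                                  fc_threshold = params$dge$fc_threshold,
                                  alpha = params$dge$alpha))
  write.table(de, out_path("dge.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  degs <- de$gene[de$is_de]
  record("degs", length(degs))

  sets <- stage("ssgsea", {
    if (!is.null(config$gene_set_list)) config$gene_set_list
    else read_gmt(config$gene_sets)
  })
  scores_tab <- stage("ssgsea",
                      ssgsea_score(expr, sets,
                                   exponent = params$ssgsea$exponent))
  write.table(scores_tab, out_path("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  coexpr_out <- stage("coexpr", {
    sub <- expr[degs, , drop = FALSE]
    st <- suppressWarnings(
      pick_soft_threshold(sub, powers = params$coexpr$powers,
                          r2_target = params$coexpr$r2_target))
    tom <- topological_overlap(adjacency_matrix(sub, st$power))
    list(power = st$power,
         assign = detect_modules(
           tom, sub, min_module_size = params$coexpr$min_module_size,
           cut_height = params$coexpr$cut_height, traits = scores_tab))
  })
  manifest$soft_threshold <- list(power = coexpr_out$power)
  assign <- coexpr_out$assign
  mt <- stage("coexpr", module_trait(assign, scores_tab))
  write.table(mt, out_path("module_trait.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  imm <- mt[mt$trait == "immune_score", , drop = FALSE]
  if (!nrow(imm))
    stop("pipeline stage 'coexpr' failed: gene sets must include a set ",
         "named 'immune' to define the immune score", call. = FALSE)
  target <- imm$module[which.max(abs(imm$correlation))]
  manifest$immune_module <- target
  record("module_genes", sum(assign$modules == target))

  screened <- stage("screen",
                    screen_genes(assign, target, trait = "immune_score",
                                 mm_min = params$coexpr$mm_min,
                                 gs_min = params$coexpr$gs_min))
  writeLines(screened, out_path("screened_genes.txt"))
  record("screened_genes", length(screened))

  pairs <- stage("irgp", build_pairs(expr, screened))
  record("built_pairs", nrow(pairs))
  pairs <- stage("irgp",
                 filter_pairs(pairs, params$irgp$min_minority_fraction))
  record("filtered_pairs", nrow(pairs))
  write_pairs_tsv(pairs, out_path("pairs.tsv"))

  uni <- stage("cox_screen",
               univariate_cox_screen(pairs, clinical,
                                     alpha = params$surv$alpha))
  write.table(uni, out_path("univariate_cox.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  record("cox_screened_pairs", nrow(uni))
  if (nrow(uni) == 0)
    stop("pipeline stage 'cox_screen' failed: no pair passed the ",
         "univariate screen", call. = FALSE)

  model <- stage("lasso",
                 lasso_cox_select(pairs[uni$pair, , drop = FALSE], clinical,
                                  n_repeats = params$surv$n_repeats,
                                  n_folds = params$surv$n_folds,
                                  seed = seed, rule = params$surv$rule))
  record("selected_pairs", nrow(model$pairs))
  if (nrow(model$pairs) == 0)
    stop("pipeline stage 'lasso' failed: empty model", call. = FALSE)

  scores <- stage("risk", risk_score(model, pairs))
  horizon <- params$surv$horizon
  if (is.null(horizon)) horizon <- median(clinical$time)
  roc <- stage("roc", time_roc(scores, clinical, horizon))
  model$cutoff <- roc$best_cutoff
  manifest$roc <- list(horizon = horizon, auc = roc$auc,
                       cutoff = roc$best_cutoff)
  write_risk_model(model, out_path("model.json"))
  manifest$outputs$model <- "model.json"

  groups <- assign_risk_groups(scores, model$cutoff)
  risk <- data.frame(sample_id = names(scores), risk_score = scores,
                     risk_group = groups, row.names = NULL)
  write.table(risk, out_path("risk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  record("high_risk", sum(groups == "high"))
  record("low_risk", sum(groups == "low"))

  km <- stage("km", km_logrank(clinical, groups))
  manifest$km <- list(chi2 = km$chi2, p = km$p)
  mc <- stage("multivariate_cox", {
    cov <- data.frame(sample_id = clinical$sample_id,
                      risk_score = scores,
                      group_right = as.numeric(clinical$group == "right"))
    if ("age" %in% names(clinical)) cov$age <- clinical$age
    multivariate_cox(clinical, cov)
  })
  write.table(mc, out_path("multivariate_cox.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(config$signature) || !is.null(config$signature_matrix)) {
    sig <- stage("deconv", {
      if (!is.null(config$signature)) config$signature
      else read_signature_tsv(config$signature_matrix)
    })
    dec <- stage("deconv", deconvolve(expr, sig,
                                      n_perm = params$deconv$n_perm,
                                      seed = seed))
    write.table(dec, out_path("deconvolution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    conf <- filter_confident(dec)
    if (nrow(conf) >= 4) {
      gd <- stage("deconv", group_difference(
        conf, groups[match(conf$sample, names(scores))]))
      write.table(gd, out_path("deconv_group_difference.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    record("confident_samples", nrow(conf))
  }

  gsea_sets <- if (!is.null(config$gsea_set_list)) config$gsea_set_list
               else sets
  gs <- stage("gsea", {
    ranks <- preranked_log2fc(expr, groups)
    suppressWarnings(gsea_preranked(ranks, gsea_sets,
                                    n_perm = params$gsea$n_perm,
                                    weight = params$gsea$weight,
                                    seed = seed,
                                    min_size = params$gsea$min_size))
  })
  write.table(gs[, setdiff(names(gs), "leading_edge")],
              out_path("gsea.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (!is.null(config$edge_list)) {
    edges <- stage("hubs", {
      if (is.character(config$edge_list)) read_edge_list(config$edge_list)
      else config$edge_list
    })
    hubs <- stage("hubs", hub_genes(edges, params$hubs$min_degree))
    key <- intersect_key_genes(hubs, model)
    writeLines(key, out_path("key_genes.txt"))
    record("hub_genes", nrow(hubs))
    record("key_genes", length(key))
  }

  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
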