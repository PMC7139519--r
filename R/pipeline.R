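#' Pipeline configuration
#'
#' One consensus model is fitted per chromatographic column; the
#' cross-column correlation analysis runs once on the shared retention
#' table.
#'
#' @param descriptors Path to a descriptor CSV ([read_descriptors()]
#'   layout) or a descriptor data frame.
#' @param retention Path to a long-format retention CSV
#'   ([read_retention()] layout) or the corresponding data frame.
#' @param columns Column names to model (default: all present).
#' @param out_dir Output directory for artifacts.
#' @param ga Base [ga_config()].
#' @param n_runs GA repeats per column.
#' @param train_fraction Kennard-Stone training fraction.
#' @param lv_policy,lv_tol Latent-variable selection policy.
#' @param df_policy CV-ANOVA degrees-of-freedom policy.
#' @param master_seed Seed driving every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(descriptors, retention, columns = NULL,
                            out_dir = "qsrr_out", ga = ga_config(),
                            n_runs = 1000, train_fraction = 0.7,
                            lv_policy = "knee", lv_tol = 0.02,
                            df_policy = "lv2", master_seed = 1) {
  structure(list(descriptors = descriptors, retention = retention,
                 columns = columns, out_dir = out_dir, ga = ga,
                 n_runs = as.integer(n_runs),
                 train_fraction = train_fraction,
                 lv_policy = lv_policy, lv_tol = lv_tol,
                 df_policy = df_policy,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash of the serialized configuration, for the manifest.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full consensus GA-PLS QSRR pipeline
#'
#' Stages, per chromatographic column: Kennard-Stone split, repeated
#' GA-PLS runs, consensus selection, final model fit, external validation,
#' CV-ANOVA and applicability-domain diagnostics. Artifacts (CSV/JSON) are
#' written under `out_dir/<column>/`; a manifest lists every artifact with
#' the seed and configuration hash. A stage failure aborts with the stage
#' and column name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of per-column results plus the manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  desc <- if (is.character(config$descriptors))
    read_descriptors(config$descriptors) else config$descriptors
  ret <- if (is.character(config$retention))
    read_retention(config$retention) else config$retention
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  columns <- config$columns %||% unique(ret$column_name)
  stage <- function(name, col, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed for column '", col, "': ",
           conditionMessage(e), call. = FALSE))
  }
  corr <- if (length(columns) > 1) retention_correlations(ret) else NULL
  if (!is.null(corr))
    utils::write.csv(corr, file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE)
  results <- list()
  artifacts <- if (!is.null(corr)) "correlations.csv" else character()
  for (col in columns) {
    col_dir <- file.path(config$out_dir, col)
    dir.create(col_dir, showWarnings = FALSE)
    rc <- ret[ret$column_name == col, ]
    ids <- intersect(desc$analyte_id, rc$analyte_id)
    if (length(ids) < 6) stop("pipeline stage 'merge' failed for column '",
                              col, "': fewer than 6 shared analytes")
    Xall <- as.matrix(desc[match(ids, desc$analyte_id), descriptor_names()])
    rownames(Xall) <- ids
    y_all <- ln_transform(rc$t_R_min[match(ids, rc$analyte_id)])
    keep <- stats::complete.cases(Xall)
    if (!all(keep))
      message("column ", col, ": dropping incomplete analytes: ",
              paste(ids[!keep], collapse = ", "))
    Xall <- Xall[keep, , drop = FALSE]; y_all <- y_all[keep]; ids <- ids[keep]

    split <- stage("split", col, kennard_stone_split(Xall, config$train_fraction))
    write_split(split, ids, file.path(col_dir, "split.csv"))
    Xtr <- Xall[split$train, , drop = FALSE]
    ytr <- y_all[split$train]
    Xval <- Xall[split$validation, , drop = FALSE]
    yval <- y_all[split$validation]

    reps <- stage("ga_repeats", col,
                  run_ga_repeats(Xtr, ytr, config$ga, n_runs = config$n_runs,
                                 master_seed = config$master_seed))
    utils::write.csv(data.frame(descriptor = names(reps$occurrence),
                                occurrence = unname(reps$occurrence)),
                     file.path(col_dir, "occurrence.csv"), row.names = FALSE)

    mask <- stage("consensus_select", col, consensus_select(reps$occurrence))
    model <- stage("fit_consensus", col,
                   fit_consensus(Xtr, ytr, mask, lv_policy = config$lv_policy,
                                 lv_tol = config$lv_tol,
                                 occurrence = reps$occurrence))
    write_consensus_model(model, file.path(col_dir, "consensus_model.json"))
    utils::write.csv(data.frame(n_lv = model$cv$n_lv,
                                rmsecv_ln = model$cv$rmsecv,
                                rmsecv_minutes = model$cv$rmsecv_minutes),
                     file.path(col_dir, "cv_curve.csv"), row.names = FALSE)

    valid <- stage("validate", col, external_validate(model, Xval, yval))
    loo_pred <- model$cv$predictions[, match(model$n_lv, model$cv$n_lv)]
    anova <- stage("cv_anova", col, {
      if (config$df_policy == "n_descriptors")
        cv_anova(ytr, loo_pred, df_policy = "n_descriptors",
                 n_descriptors = length(model$selected))
      else cv_anova(ytr, loo_pred, n_lv = model$n_lv, df_policy = "lv2")
    })
    utils::write.csv(cbind(anova$table,
                           F = c(anova$F, NA, NA),
                           p_value = c(anova$p_value, NA, NA)),
                     file.path(col_dir, "anova.csv"), row.names = FALSE)

    ad <- stage("applicability_domain", col,
                applicability_domain(model, Xval, yval))
    utils::write.csv(ad$table, file.path(col_dir, "williams.csv"),
                     row.names = FALSE)

    results[[col]] <- list(split = split, repeats = reps, model = model,
                           validation = valid, anova = anova, ad = ad)
    artifacts <- c(artifacts, file.path(col, c(
      "split.csv", "occurrence.csv", "consensus_model.json", "cv_curve.csv",
      "anova.csv", "williams.csv")))
  }
  manifest <- list(package = "qsrrga",
                   master_seed = config$master_seed,
                   n_runs = config$n_runs,
                   config_hash = config_hash(config),
                   columns = as.list(columns),
                   artifacts = as.list(artifacts))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
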