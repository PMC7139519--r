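#' Repeat GA-PLS runs and tally descriptor occurrence
#'
#' Runs `n_runs` independent GA evolutions with distinct child seeds drawn
#' deterministically from `master_seed`, and reports the percentage of
#' runs in which each descriptor appears in the best mask. The fitness
#' cache is shared across runs (mask fitness is deterministic), so results
#' are identical whether runs execute serially or are merged by index.
#'
#' @param X Descriptor matrix (training set).
#' @param y ln-retention response.
#' @param config Base [ga_config()]; its `seed` is replaced per run.
#' @param n_runs Number of repeats (1000 in a full analysis).
#' @param master_seed Integer seed from which all child seeds derive.
#' @return List with `runs` (list of `ga_run`), `occurrence` (named %
#'   vector), `child_seeds` and `master_seed`.
#' @export
run_ga_repeats <- function(X, y, config = ga_config(), n_runs = 1000,
                           master_seed = 1) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  set.seed(master_seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  cache <- new_fitness_cache()
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- child_seeds[i]
    runs[[i]] <- ga_evolve(X, y, cfg, cache = cache)
  }
  masks <- do.call(rbind, lapply(runs, `[[`, "best_mask"))
  occurrence <- 100 * colMeans(masks)
  names(occurrence) <- colnames(X)
  list(runs = runs, occurrence = occurrence,
       child_seeds = child_seeds, master_seed = master_seed)
}

#' Consensus descriptor selection from occurrence percentages
#'
#' A descriptor enters the consensus model when its occurrence over the
#' repeated GA runs is strictly greater than the arithmetic mean of all
#' occurrences.
#'
#' @param occurrence Named percentage vector from [run_ga_repeats()].
#' @return Integer 0/1 mask, named like `occurrence`.
#' @export
consensus_select <- function(occurrence) {
  if (!length(occurrence)) stop("empty occurrence vector")
  mask <- as.integer(occurrence > mean(occurrence))
  names(mask) <- names(occurrence)
  if (!any(mask == 1L))
    stop("no descriptor exceeds the mean occurrence; inspect the occurrence ",
         "vector (all values may be equal)")
  mask
}

#' Fit the consensus QSRR model
#'
#' Re-optimizes the number of latent variables by LOO-CV on the consensus
#' descriptor subset, then fits the final SIMPLS model on the full
#' training set.
#'
#' @param X Training descriptor matrix.
#' @param y Training ln-retention response.
#' @param mask 0/1 consensus mask over the columns of `X` (>= 2 selected).
#' @param lv_policy,lv_tol Passed to [select_n_lvs()].
#' @param lv_min Smallest candidate number of latent variables.
#' @param occurrence Optional occurrence vector stored alongside.
#' @return Object of class `consensus_model`: the fitted `pls_model`, the
#'   mask and selected names, the CV curve and chosen `n_lv`, plus the
#'   training data used (for downstream diagnostics).
#' @export
fit_consensus <- function(X, y, mask, lv_policy = c("knee", "min"),
                          lv_tol = 0.02, lv_min = 2, occurrence = NULL) {
  lv_policy <- match.arg(lv_policy)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (length(mask) != ncol(X)) stop("mask length must equal ncol(X)")
  sel <- which(mask != 0)
  if (length(sel) < 2) stop("consensus mask must select at least 2 descriptors")
  Xsel <- X[, sel, drop = FALSE]
  cv <- loo_cv_curve(Xsel, y)
  cand <- cv$n_lv >= min(lv_min, max(cv$n_lv))
  cv_sub <- structure(list(n_lv = cv$n_lv[cand], rmsecv = cv$rmsecv[cand],
                           rmsecv_minutes = cv$rmsecv_minutes[cand],
                           predictions = cv$predictions[, cand, drop = FALSE]),
                      class = "cv_result")
  n_lv <- select_n_lvs(cv_sub, policy = lv_policy, tol = lv_tol)
  pls <- simpls_fit(Xsel, y, n_lv)
  structure(list(pls = pls, mask = as.integer(mask != 0),
                 selected = colnames(X)[sel],
                 descriptor_names = colnames(X),
                 n_lv = n_lv, cv = cv, occurrence = occurrence,
                 rmsecv = cv$rmsecv[match(n_lv, cv$n_lv)],
                 rmsecv_minutes = cv$rmsecv_minutes[match(n_lv, cv$n_lv)],
                 X_train = Xsel, y_train = y), class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("Consensus QSRR model\n")
  cat("  descriptors:", paste(x$selected, collapse = ", "), "\n")
  cat("  latent variables:", x$n_lv, "\n")
  cat("  RMSECV:", signif(x$rmsecv, 3), "(ln scale),",
      signif(x$rmsecv_minutes, 3), "min\n")
  cat("  explained variance: X ", round(sum(x$pls$explained_x), 1),
      "%, y ", round(sum(x$pls$explained_y), 1), "%\n", sep = "")
  invisible(x)
}

#' @export
predict.consensus_model <- function(object, newdata, scale = c("ln", "minutes"),
                                    ...) {
  scale <- match.arg(scale)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(object$mask))
    newdata <- newdata[, object$mask == 1L, drop = FALSE]
  predict(object$pls, newdata, scale = scale)
}

#' Serialize a consensus model to JSON
#'
#' Coefficients, scaling, LV count, explained variances and occurrence are
#' written; enough to reproduce predictions.
#'
#' @param model A `consensus_model`.
#' @param path Output path.
#' @export
write_consensus_model <- function(model, path) {
  obj <- list(
    selected = model$selected,
    mask = model$mask,
    descriptor_names = model$descriptor_names,
    n_lv = model$n_lv,
    rmsecv_ln = model$rmsecv,
    rmsecv_minutes = model$rmsecv_minutes,
    coef_scaled = as.list(model$pls$coef_scaled),
    coef_original = as.list(model$pls$coef_original),
    intercept = model$pls$intercept,
    explained_x = model$pls$explained_x,
    explained_y = model$pls$explained_y,
    occurrence = if (!is.null(model$occurrence)) as.list(model$occurrence),
    scaling = list(x_center = as.list(model$pls$scaling$x_center),
                   x_scale = as.list(model$pls$scaling$x_scale),
                   y_center = model$pls$scaling$y_center,
                   y_scale = model$pls$scaling$y_scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Bar chart of descriptor occurrence
#'
#' @param occurrence Named percentage vector.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_occurrence <- function(occurrence, ...) {
  ord <- order(occurrence, decreasing = TRUE)
  graphics::barplot(occurrence[ord], las = 2,
                    ylab = "occurrence (% of runs)",
                    ylim = c(0, 100), ...)
  graphics::abline(h = mean(occurrence), lty = 2)
  invisible(occurrence)
}
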