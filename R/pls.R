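#' Autoscale a descriptor matrix and response
#'
#' Centres each column to mean zero and scales to unit sample standard
#' deviation (n - 1). Autoscaling puts descriptors with different units
#' (kcal/mol, eV, Debye, counts) on a common footing and removes the
#' intercept from the PLS model.
#'
#' @param X Numeric matrix (m x p).
#' @param y Optional response vector.
#' @return List with `X`, `y` (scaled) and `params` (class
#'   `scaling_params`): `x_center`, `x_scale`, `y_center`, `y_scale`.
#' @export
autoscale <- function(X, y = NULL) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  params <- structure(list(x_center = mu, x_scale = sds,
                           y_center = NULL, y_scale = NULL),
                      class = "scaling_params")
  ys <- NULL
  if (!is.null(y)) {
    params$y_center <- mean(y)
    params$y_scale <- stats::sd(y)
    if (params$y_scale == 0) stop("zero-variance response")
    ys <- (y - params$y_center) / params$y_scale
  }
  list(X = Xs, y = ys, params = params)
}

#' Apply / invert stored scaling parameters
#'
#' @param params A `scaling_params` object from [autoscale()].
#' @param X New-data matrix with the training columns.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$x_center))
    stop("column count mismatch with scaling parameters")
  sweep(sweep(X, 2, params$x_center), 2, params$x_scale, "/")
}

#' @rdname apply_scaling
#' @param Xs Scaled matrix to map back to the original units.
#' @export
invert_scaling <- function(params, Xs) {
  Xs <- as.matrix(Xs)
  sweep(sweep(Xs, 2, params$x_scale, "*"), 2, params$x_center, "+")
}

#' Fit a SIMPLS partial least squares model
#'
#' De Jong's SIMPLS algorithm, deflating the X'y cross-product directly,
#' for a single response. Data are autoscaled internally; the reported
#' model carries coefficients on both the autoscaled and the original
#' scale, orthonormal scores, unit-norm weights and percent explained
#' variance in X and y per latent variable.
#'
#' @param X Descriptor matrix (m x p).
#' @param y Response vector (ln retention).
#' @param n_lv Number of latent variables, `1 <= n_lv <= rank(X)`.
#' @return Object of class `pls_model`.
#' @export
simpls_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  sc <- autoscale(X, y)
  rk <- qr(sc$X)$rank
  if (n_lv < 1 || n_lv > rk)
    stop("n_lv must be between 1 and rank(X) = ", rk)
  fit <- simpls_core(sc$X, sc$y, as.integer(n_lv))
  b_s <- fit$coefficients[, n_lv]
  b_orig <- b_s * sc$params$y_scale / sc$params$x_scale
  intercept <- sc$params$y_center - sum(b_orig * sc$params$x_center)
  fitted_ln <- drop(X %*% b_orig) + intercept
  structure(list(
    n_lv = as.integer(n_lv),
    weights = fit$weights[, seq_len(n_lv), drop = FALSE],
    x_loadings = fit$x_loadings[, seq_len(n_lv), drop = FALSE],
    y_loadings = fit$y_loadings[seq_len(n_lv)],
    scores = fit$scores[, seq_len(n_lv), drop = FALSE],
    coef_scaled = stats::setNames(b_s, colnames(X)),
    coef_original = stats::setNames(b_orig, colnames(X)),
    intercept = intercept,
    explained_x = fit$explained_x[seq_len(n_lv)],
    explained_y = fit$explained_y[seq_len(n_lv)],
    scaling = sc$params,
    fitted = fitted_ln,
    residuals = y - fitted_ln,
    feature_names = colnames(X)), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("SIMPLS model:", length(x$coef_scaled), "descriptors,",
      x$n_lv, "latent variable(s)\n")
  cat("  cumulative explained variance: X ",
      round(sum(x$explained_x), 1), "%, y ",
      round(sum(x$explained_y), 1), "%\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the stored training scaling (never re-estimated from new data).
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the training descriptor columns.
#' @param scale `"ln"` for log-minutes (the modelling scale) or
#'   `"minutes"` for back-transformed retention times.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, scale = c("ln", "minutes"), ...) {
  scale <- match.arg(scale)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coef_original))
    stop("newdata must have ", length(object$coef_original), " columns")
  pred <- drop(newdata %*% object$coef_original) + object$intercept
  if (scale == "minutes") exp(pred) else pred
}

#' Root mean square error
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return sqrt(mean((pred - obs)^2)).
#' @export
rmse <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("pred and obs must be non-empty and of equal length")
  sqrt(mean((pred - obs)^2))
}

#' @rdname rmse
#' @param rmse_train,rmse_validation Per-set RMSE values to average.
#' @export
average_rmse <- function(rmse_train, rmse_validation) {
  (rmse_train + rmse_validation) / 2
}

#' Leave-one-out cross-validation curve
#'
#' For every candidate number of latent variables, each analyte is
#' predicted by a SIMPLS model trained on the other m - 1 analytes, with
#' autoscaling re-estimated inside each fold (the held-out row never
#' enters the scaling). RMSECV is reported on the ln scale and, via
#' back-transformation of predictions, on the minute scale.
#'
#' @param X Descriptor matrix (m x p), m >= 3.
#' @param y ln-retention response.
#' @param max_lv Largest candidate; capped at min(p, m - 2) and at the
#'   rank available within each fold.
#' @return Object of class `cv_result`: `n_lv` (candidates), `rmsecv`
#'   (ln units), `rmsecv_minutes`, and the n x A matrix of held-out
#'   predictions.
#' @export
loo_cv_curve <- function(X, y, max_lv = NULL) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 3) stop("need at least 3 analytes for LOO-CV")
  if (length(y) != m) stop("length(y) must equal nrow(X)")
  max_lv <- as.integer(max_lv %||% min(ncol(X), m - 2L))
  pred <- loocv_predictions_core(X, y, max_lv)
  rms <- apply(pred, 2, rmse, obs = y)
  rms_min <- apply(pred, 2, function(p) rmse(exp(p), exp(y)))
  structure(list(n_lv = seq_len(ncol(pred)), rmsecv = unname(rms),
                 rmsecv_minutes = unname(rms_min), predictions = pred),
            class = "cv_result")
}

#' Choose the number of latent variables from a CV curve
#'
#' Policy `"knee"` (default) picks the smallest candidate beyond which the
#' curve has flattened: the first n whose improvement to the next
#' candidate, relative to the first candidate's RMSECV, falls below `tol`.
#' Policy `"min"` picks the RMSECV minimum. Ties always resolve to the
#' smaller model.
#'
#' @param cv A `cv_result`, or a numeric RMSECV vector (candidates taken
#'   as 1..length).
#' @param policy `"knee"` or `"min"`.
#' @param tol Relative-improvement threshold for the knee rule.
#' @return The chosen number of latent variables.
#' @export
select_n_lvs <- function(cv, policy = c("knee", "min"), tol = 0.02) {
  policy <- match.arg(policy)
  if (inherits(cv, "cv_result")) {
    rms <- cv$rmsecv
    cand <- cv$n_lv
  } else {
    rms <- as.numeric(cv)
    cand <- seq_along(rms)
  }
  if (!length(rms)) stop("empty CV curve")
  if (length(rms) == 1 || policy == "min")
    return(cand[which.min(rms)])
  ref <- rms[1]
  if (ref <= 0) return(cand[1])
  gain <- (rms[-length(rms)] - rms[-1]) / ref
  flat <- which(gain < tol)
  if (length(flat)) cand[flat[1]] else cand[length(cand)]
}
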