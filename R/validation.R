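#' Cross-validated ANOVA table
#'
#' Significance test of a cross-validated model: the total variation of
#' the response around its mean is partitioned into the part explained by
#' the cross-validated predictions (Fit) and the predictive residual part,
#' and compared through an F statistic. Internal identities (SS
#' additivity, MS = SS/df, F = MS ratio) are asserted on every table
#' before it is returned.
#'
#' @param y_true Training-set response (ln scale).
#' @param y_loocv_pred Leave-one-out predictions for the same analytes.
#' @param n_lv Number of latent variables of the model (used by the
#'   default df policy).
#' @param df_policy `"lv2"` (df_Fit = 2 * n_lv, default),
#'   `"n_descriptors"` (df_Fit = `n_descriptors`), or `"explicit"` with
#'   `df_fit` supplied.
#' @param n_descriptors Descriptor count for the `"n_descriptors"` policy.
#' @param df_fit Explicit integer df for the Fit row.
#' @return Object of class `anova_table` with a `table` data frame (Total,
#'   Fit, Residual rows), `F`, `p_value` and the policy used.
#' @export
cv_anova <- function(y_true, y_loocv_pred,
                     n_lv = NULL,
                     df_policy = c("lv2", "n_descriptors", "explicit"),
                     n_descriptors = NULL, df_fit = NULL) {
  df_policy <- match.arg(df_policy)
  m <- length(y_true)
  if (length(y_loocv_pred) != m) stop("vectors must have equal length")
  if (m < 3) stop("need at least 3 analytes")
  ss_total <- sum((y_true - mean(y_true))^2)
  ss_resid <- sum((y_true - y_loocv_pred)^2)
  ss_fit <- ss_total - ss_resid
  if (ss_fit < 0) {
    warning("cross-validated predictions worse than the mean; SS_Fit floored at 0")
    ss_fit <- 0
    ss_resid <- ss_total
  }
  df_total <- m - 1L
  df_fit <- switch(df_policy,
    lv2 = {
      if (is.null(n_lv)) stop("df_policy 'lv2' needs n_lv")
      2L * as.integer(n_lv)
    },
    n_descriptors = {
      if (is.null(n_descriptors)) stop("df_policy 'n_descriptors' needs n_descriptors")
      as.integer(n_descriptors)
    },
    explicit = {
      if (is.null(df_fit)) stop("df_policy 'explicit' needs df_fit")
      as.integer(df_fit)
    })
  if (df_fit >= df_total) stop("df_Fit must be smaller than df_Total = m - 1")
  df_resid <- df_total - df_fit
  tab <- anova_table(ss_total, ss_fit, df_total, df_fit)
  tab$df_policy <- df_policy
  tab
}

#' Construct and check an ANOVA table from its SS and df components
#'
#' Computes the MS column, the F statistic (MS_Fit / MS_Residual) and its
#' upper-tail p value, and asserts the internal identities before
#' returning.
#'
#' @param ss_total,ss_fit Sums of squares (Residual = Total - Fit).
#' @param df_total,df_fit Degrees of freedom (Residual = Total - Fit).
#' @return Object of class `anova_table`.
#' @export
anova_table <- function(ss_total, ss_fit, df_total, df_fit) {
  ss_resid <- ss_total - ss_fit
  df_resid <- df_total - df_fit
  if (df_fit <= 0 || df_resid <= 0) stop("degrees of freedom must be positive")
  if (ss_resid < -1e-9) stop("SS_Fit exceeds SS_Total")
  ss_resid <- max(ss_resid, 0)
  ms <- c(ss_total / df_total, ss_fit / df_fit, ss_resid / df_resid)
  F_stat <- if (ms[3] > 0) ms[2] / ms[3] else Inf
  p <- if (is.finite(F_stat)) stats::pf(F_stat, df_fit, df_resid,
                                        lower.tail = FALSE) else 0
  tab <- data.frame(
    source = c("Total", "Fit", "Residual"),
    SS = c(ss_total, ss_fit, ss_resid),
    df = c(df_total, df_fit, df_resid),
    MS = ms, stringsAsFactors = FALSE)
  out <- structure(list(table = tab, F = F_stat, p_value = p),
                   class = "anova_table")
  validate_anova_table(out)
  out
}

#' Assert the internal identities of an ANOVA table
#'
#' SS additivity, df additivity, MS = SS/df and F = MS_Fit/MS_Residual
#' must hold to 1e-9 (relative); violated tables raise an error.
#'
#' @param x An `anova_table`.
#' @return `x`, invisibly.
#' @export
validate_anova_table <- function(x) {
  tab <- x$table
  tol <- 1e-9 * max(1, abs(tab$SS[1]))
  stopifnot(abs(tab$SS[1] - tab$SS[2] - tab$SS[3]) <= tol,
            tab$df[1] == tab$df[2] + tab$df[3],
            all(abs(tab$MS - tab$SS / tab$df) <= tol))
  if (is.finite(x$F) && tab$MS[3] > 0)
    stopifnot(abs(x$F - tab$MS[2] / tab$MS[3]) <=
                1e-9 * max(1, abs(x$F)))
  invisible(x)
}

#' @export
print.anova_table <- function(x, ...) {
  tab <- x$table
  tab$SS <- signif(tab$SS, 4)
  tab$MS <- signif(tab$MS, 4)
  print(tab, row.names = FALSE)
  cat("F =", signif(x$F, 4), ", Pr(>F) =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' External validation of a consensus model
#'
#' @param model A `consensus_model`.
#' @param X_val Validation descriptor matrix (full 13 columns or already
#'   subset to the consensus descriptors).
#' @param y_val Validation ln-retention response.
#' @return List of RMSE values on the ln and minute scales for the
#'   training set, the validation set and their arithmetic mean.
#' @export
external_validate <- function(model, X_val, y_val) {
  if (!inherits(model, "consensus_model")) stop("model must be a consensus_model")
  if (length(y_val) == 0) stop("empty validation set")
  pred_tr <- predict(model, model$X_train)
  pred_val <- predict(model, X_val)
  r_tr <- rmse(pred_tr, model$y_train)
  r_val <- rmse(pred_val, y_val)
  r_tr_min <- rmse(exp(pred_tr), exp(model$y_train))
  r_val_min <- rmse(exp(pred_val), exp(y_val))
  list(rmse_train = r_tr, rmse_validation = r_val,
       rmse_average = average_rmse(r_tr, r_val),
       rmse_train_minutes = r_tr_min, rmse_validation_minutes = r_val_min,
       rmse_average_minutes = average_rmse(r_tr_min, r_val_min))
}

#' Leverages of query analytes relative to a training set
#'
#' h_i = x_i' (X'X)^-1 x_i on the autoscaled, consensus-subset descriptor
#' space; the diagonal of the hat matrix without intercept. A singular
#' cross-product falls back to the Moore-Penrose pseudo-inverse with a
#' warning.
#'
#' @param X_train Autoscaled training matrix (consensus descriptors).
#' @param X_query Autoscaled query matrix with the same columns (defaults
#'   to the training matrix itself).
#' @return Numeric leverage vector, one per query row.
#' @export
leverages <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(X_train)
  X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train)) stop("column count mismatch")
  XtX <- crossprod(X_train)
  inv <- tryCatch(solve(XtX), error = function(e) {
    warning("singular cross-product; using Moore-Penrose pseudo-inverse")
    MASS::ginv(XtX)
  })
  rowSums((X_query %*% inv) * X_query)
}

#' Critical leverage (warning limit) of the applicability domain
#'
#' h* = 3 (n + 1) / m, with n the number of molecular descriptors in the
#' model and m the number of training observations.
#'
#' @param n_descriptors Number of descriptors in the model.
#' @param m_train Training-set size.
#' @return The critical leverage.
#' @export
critical_leverage <- function(n_descriptors, m_train) {
  if (n_descriptors < 1 || m_train < 1) stop("counts must be >= 1")
  3 * (n_descriptors + 1) / m_train
}

#' Applicability-domain (Williams plot) diagnostics
#'
#' Computes leverages and standardized residuals for the training set and
#' an optional query (validation) set, and flags analytes outside the
#' warning limits: leverage above h* = 3(n+1)/m, or absolute standardized
#' residual above `residual_limit` multiples of the training residual
#' standard deviation. Residuals use fitted (not cross-validated)
#' predictions, and both sets are standardized by the training residual
#' SD, the conventional Williams-plot construction.
#'
#' @param model A `consensus_model`.
#' @param X_query,y_query Optional validation descriptors (full or
#'   consensus-subset columns) and responses.
#' @param residual_limit Warning limit in residual SD multiples (default 3).
#' @return Object of class `ad_result`: a data frame with `analyte`,
#'   `set`, `leverage`, `std_residual` and the three logical flags, plus
#'   `h_star` and `residual_sd`.
#' @export
applicability_domain <- function(model, X_query = NULL, y_query = NULL,
                                 residual_limit = 3) {
  if (!inherits(model, "consensus_model")) stop("model must be a consensus_model")
  sc <- model$pls$scaling
  Xt <- apply_scaling(sc, model$X_train)
  res_tr <- model$y_train - predict(model, model$X_train)
  sd_tr <- stats::sd(res_tr)
  if (sd_tr == 0) stop("zero training residual standard deviation")
  h_star <- critical_leverage(length(model$selected), nrow(Xt))
  build <- function(X, y, set) {
    if (ncol(X) == length(model$mask))
      X <- X[, model$mask == 1L, drop = FALSE]
    Xs <- apply_scaling(sc, X)
    h <- leverages(Xt, Xs)
    std_res <- (y - predict(model, X)) / sd_tr
    data.frame(analyte = rownames(X) %||% paste0(set, seq_len(nrow(X))),
               set = set, leverage = h, std_residual = std_res,
               high_leverage = h > h_star,
               outlier = abs(std_res) > residual_limit,
               in_domain = h <= h_star & abs(std_res) <= residual_limit,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- build(model$X_train, model$y_train, "train")
  if (!is.null(X_query)) {
    if (is.null(y_query)) stop("y_query required with X_query")
    out <- rbind(out, build(as.matrix(X_query), y_query, "validation"))
  }
  structure(list(table = out, h_star = h_star, residual_sd = sd_tr,
                 residual_limit = residual_limit), class = "ad_result")
}

#' @export
print.ad_result <- function(x, ...) {
  cat("Applicability domain: h* =", signif(x$h_star, 4),
      ", residual limit = ±", x$residual_limit, "SD\n")
  n_out <- sum(!x$table$in_domain)
  cat(" ", nrow(x$table), "analytes,", n_out, "outside the warning limits\n")
  invisible(x)
}

#' Williams plot of the applicability domain
#'
#' @param ad An `ad_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_williams <- function(ad, ...) {
  tab <- ad$table
  lim <- max(ad$residual_limit + 1, abs(tab$std_residual) + 0.5)
  graphics::plot(tab$leverage, tab$std_residual,
                 col = ifelse(tab$set == "train", "royalblue", "deeppink"),
                 pch = ifelse(tab$set == "train", 19, 18),
                 xlab = "leverage h", ylab = "standardized residual",
                 ylim = c(-lim, lim), ...)
  graphics::abline(v = ad$h_star, lty = 2)
  graphics::abline(h = c(-1, 1) * ad$residual_limit, lty = 2)
  invisible(ad)
}
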