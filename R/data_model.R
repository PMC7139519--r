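#' Natural-log transform of retention times
#'
#' Retention times (minutes) are modelled on the natural-log scale, where
#' their distribution is considerably closer to normal.
#'
#' @param t_R Retention times in minutes, strictly positive.
#' @return ln(t_R).
#' @export
ln_transform <- function(t_R) {
  if (any(!is.finite(t_R)) || any(t_R <= 0))
    stop("retention times must be finite and > 0")
  log(t_R)
}

#' @rdname ln_transform
#' @param ln_t_R Log-scale retention values.
#' @export
inv_ln_transform <- function(ln_t_R) exp(ln_t_R)

#' Pearson correlation with a two-tailed t test
#'
#' @param x,y Numeric vectors of equal length (>= 3) and nonzero variance.
#' @return List with `R`, `p_value` (two-tailed, t distribution with n - 2
#'   df) and `n`.
#' @export
pearson_with_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(R = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pairwise retention-time correlations between columns
#'
#' Computes the Pearson correlation (with two-tailed significance) between
#' every pair of chromatographic columns sharing the same analytes, from a
#' long-format retention table.
#'
#' @param retention Data frame with columns `analyte_id`, `column_name`,
#'   `t_R_min`.
#' @param log_scale Correlate ln-transformed retention (default) or raw
#'   minutes.
#' @return Data frame with one row per column pair: `column_1`,
#'   `column_2`, `R`, `p_value`, `n`.
#' @export
retention_correlations <- function(retention, log_scale = TRUE) {
  need <- c("analyte_id", "column_name", "t_R_min")
  if (!all(need %in% names(retention)))
    stop("retention table must have columns: ", paste(need, collapse = ", "))
  wide <- stats::reshape(retention[need], idvar = "analyte_id",
                         timevar = "column_name", direction = "wide")
  cols <- sub("^t_R_min\\.", "", names(wide)[-1])
  out <- list()
  for (i in seq_along(cols)) for (j in seq_len(i - 1)) {
    xi <- wide[[i + 1]]; xj <- wide[[j + 1]]
    ok <- is.finite(xi) & is.finite(xj)
    if (log_scale) { xi <- ln_transform(xi[ok]); xj <- ln_transform(xj[ok]) }
    else { xi <- xi[ok]; xj <- xj[ok] }
    r <- pearson_with_test(xj, xi)
    out[[length(out) + 1]] <- data.frame(
      column_1 = cols[j], column_2 = cols[i],
      R = r$R, p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' QSRR dataset container
#'
#' Bundles the descriptor matrix, ln-retention response, analyte ids and
#' train/validation membership. Rows with missing descriptor values are
#' dropped (with a message) since the modelling stages require complete
#' rows.
#'
#' @param X Numeric matrix or data frame of descriptors (m x p).
#' @param y ln-retention vector, length m.
#' @param analyte_ids Optional ids (default row numbers).
#' @param split Optional factor/character of `"train"`/`"validation"`
#'   labels per analyte.
#' @return Object of class `qsrr_dataset`.
#' @export
qsrr_dataset <- function(X, y, analyte_ids = NULL, split = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  ids <- as.character(analyte_ids %||% seq_len(nrow(X)))
  keep <- stats::complete.cases(X) & is.finite(y)
  if (!all(keep))
    message("dropping ", sum(!keep), " analyte(s) with missing values: ",
            paste(ids[!keep], collapse = ", "))
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != length(y)) stop("split must have one label per analyte")
    if (!all(split %in% c("train", "validation")))
      stop("split labels must be 'train' or 'validation'")
    split <- split[keep]
  }
  structure(list(X = X[keep, , drop = FALSE], y = y[keep],
                 analyte_ids = ids[keep],
                 descriptor_names = colnames(X), split = split),
            class = "qsrr_dataset")
}

#' @export
print.qsrr_dataset <- function(x, ...) {
  cat("QSRR dataset:", nrow(x$X), "analytes x", ncol(x$X), "descriptors\n")
  if (!is.null(x$split))
    cat("  split:", sum(x$split == "train"), "train /",
        sum(x$split == "validation"), "validation\n")
  invisible(x)
}

#' Kennard-Stone train/validation split
#'
#' Deterministic max-min distance sampling on the autoscaled descriptor
#' matrix: the first two training picks are the most distant pair; each
#' subsequent pick maximizes its minimum Euclidean distance to the points
#' already picked. Ties are broken by the lowest row index. The training
#' size is `round(train_fraction * m)`.
#'
#' @param X Descriptor matrix (m x p), m >= 3.
#' @param train_fraction Fraction in (0, 1).
#' @return List with integer `train` and `validation` index vectors and a
#'   per-row `labels` character vector.
#' @export
kennard_stone_split <- function(X, train_fraction = 0.7) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 3) stop("need at least 3 rows")
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * m)
  n_train <- max(2L, min(m - 1L, as.integer(n_train)))
  sds <- apply(X, 2, stats::sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  D <- as.matrix(stats::dist(Xs))
  # most distant pair; ties resolved to the smallest (i, j)
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  picked <- sort(c(far[1, 1], far[1, 2]))
  while (length(picked) < n_train) {
    remaining <- setdiff(seq_len(m), picked)
    mind <- apply(D[remaining, picked, drop = FALSE], 1, min)
    picked <- c(picked, remaining[which.max(mind)]) # which.max: lowest index on ties
  }
  labels <- rep("validation", m)
  labels[picked] <- "train"
  list(train = sort(picked), validation = setdiff(seq_len(m), picked),
       labels = labels)
}

#' Read / write a long-format retention table
#'
#' @param path CSV path with columns `analyte_id`, `column_name`, `t_R_min`.
#' @return Data frame.
#' @export
read_retention <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte_id", "column_name", "t_R_min")
  if (!all(need %in% names(df)))
    stop("retention CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a train/validation split table
#'
#' @param split Result of [kennard_stone_split()].
#' @param analyte_ids Ids in row order.
#' @param path CSV path (`analyte_id, label`).
#' @export
write_split <- function(split, analyte_ids, path) {
  utils::write.csv(data.frame(analyte_id = analyte_ids,
                              label = split$labels,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
}
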