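# Shared fixtures, built in code.

toy_ref <- function() reference_enthalpies(H_hydrogen_radical = -313.0)

# Build a qm_record from target BDE/PA values per site (inverse construction).
toy_record <- function(id = "a1", bde = c(O1 = 80, O2 = 84),
                       pa = c(O1 = 33, O2 = 36), se = -25,
                       e_homo = -7.2, gap = 5.4, dipole = 4,
                       nbo = -0.65, ref = toy_ref()) {
  H_parent <- -160000
  qm_record(id, H_parent,
            H_radical = bde + H_parent - ref$H_hydrogen_radical,
            H_anion = pa + H_parent - ref$H_proton,
            E_invacuo = H_parent - se, E_solvent = H_parent,
            E_HOMO = e_homo, E_LUMO = e_homo + gap,
            dipole_total = dipole, nbo_min_charge = nbo,
            n_OH = length(bde))
}

# Small random regression dataset with sparse linear signal.
toy_dataset <- function(m = 15, p = 5, support = 1:2, coefs = c(1, -1),
                        noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(m * p), m, p, dimnames = list(NULL, paste0("D", seq_len(p))))
  y <- 2 + drop(scale(X)[, support, drop = FALSE] %*% coefs) +
    rnorm(m, 0, noise)
  list(X = X, y = y)
}

# Independent LOO oracle at full rank: per-fold OLS via lm().
loo_ols_oracle <- function(X, y) {
  vapply(seq_len(nrow(X)), function(i) {
    d <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = d)
    predict(fit, newdata = data.frame(X[i, , drop = FALSE]))
  }, numeric(1))
}

# Exhaustive best-subset search using the same fitness objective.
exhaustive_best <- function(X, y, lv_min = 2) {
  p <- ncol(X)
  best <- list(rmsecv = Inf, mask = NULL)
  for (code in seq_len(2^p) - 1L) {
    mask <- as.integer(intToBits(code)[seq_len(p)])
    if (sum(mask) < 2) next
    f <- ga_fitness(mask, X, y, lv_min = lv_min)
    if (f$rmsecv < best$rmsecv) best <- list(rmsecv = f$rmsecv, mask = mask)
  }
  best
}
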