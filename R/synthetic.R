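#' Specification for a synthetic QSRR dataset
#'
#' Describes a simulated flavonoid-like dataset: 13 mechanistic
#' descriptors with realistic inter-descriptor structure, and ln-scale
#' retention generated as a sparse linear function of a known descriptor
#' subset plus Gaussian noise. Eight base quantities (SE, the latent
#' hydroxyl count, BDE_min, PA, delta_min, M_tot, E_HOMO and the
#' frontier-orbital gap) are drawn from a multivariate Gaussian with the
#' requested correlations; the remaining descriptors (IP, EA, eta, mu,
#' omega and ETE) are derived from them through the exact Koopmans and
#' thermodynamic-cycle identities, exactly as they are in real data.
#'
#' @param m_analytes Number of analytes (default 30, a typical panel).
#' @param true_support Descriptor names carrying signal.
#' @param true_coefficients Signed effect sizes on the autoscaled
#'   ln-retention scale, one per support descriptor.
#' @param noise_sd Gaussian noise SD in ln-minute units (default 0.15,
#'   the middle of the 0.1-0.3 range typical of these models).
#' @param target_correlations Data frame (`i`, `j`, `rho`) of requested
#'   base-quantity correlations; the default includes the strong inverse
#'   hydroxyl-count / minimum-BDE correlation (rho = -0.8).
#' @param intercept Mean ln retention (default 2.3, about 10 min).
#' @param seed Integer seed; same seed, bit-identical dataset.
#' @param preset `"kc18"`, `"kf5"` or `"iam"`: named effect templates
#'   following the qualitative coefficient signs of the three column
#'   chemistries (overrides `true_support`/`true_coefficients`).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m_analytes = 30,
                           true_support = c("SE", "n_OH", "M_tot"),
                           true_coefficients = c(0.6, -0.5, -0.35),
                           noise_sd = 0.15,
                           target_correlations = NULL,
                           intercept = 2.3,
                           seed = 1,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("kc18", "kf5", "iam"))
    tmpl <- switch(preset,
      kc18 = c(SE = 0.6, n_OH = -0.5, M_tot = -0.35),
      kf5 = c(SE = 0.6, n_OH = -0.45, ETE = 0.3, M_tot = -0.3,
              IP = -0.25, EA = 0.15),
      iam = c(SE = 0.55, M_tot = -0.4, n_OH = -0.3, BDE_min = 0.3,
              IP = -0.2, gap_HOMO_LUMO = -0.3))
    true_support <- names(tmpl)
    true_coefficients <- unname(tmpl)
  }
  if (length(true_support) != length(true_coefficients))
    stop("true_coefficients must match true_support")
  if (!all(true_support %in% descriptor_names()))
    stop("unknown descriptor(s) in true_support")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(target_correlations))
    target_correlations <- data.frame(
      i = c("n_OH", "SE", "SE", "n_OH", "PA"),
      j = c("BDE_min", "n_OH", "BDE_min", "M_tot", "BDE_min"),
      rho = c(-0.8, -0.6, 0.45, 0.3, 0.4),
      stringsAsFactors = FALSE)
  structure(list(m_analytes = as.integer(m_analytes),
                 p_descriptors = 13L,
                 true_support = true_support,
                 true_coefficients = true_coefficients,
                 noise_sd = noise_sd,
                 target_correlations = target_correlations,
                 intercept = intercept,
                 seed = as.integer(seed),
                 preset = preset), class = "synthetic_spec")
}

# Base-quantity marginals: plausible SMD-water values for flavonoid panels.
base_marginals <- function() {
  data.frame(
    name = c("SE", "n_OH", "BDE_min", "PA", "delta_min", "M_tot",
             "E_HOMO", "gap"),
    mean = c(-25, 4, 82, 35, -0.68, 4.5, -7.3, 5.5),
    sd = c(3, 1.5, 5, 6, 0.04, 1.8, 0.35, 0.5),
    stringsAsFactors = FALSE)
}

# Reference enthalpies used by the generator (synthetic hydrogen-radical
# enthalpy; proton/electron are the standard SMD-water values).
synthetic_reference <- function() {
  reference_enthalpies(H_hydrogen_radical = -313.0, phase = "smd_water")
}

sample_base <- function(spec, min_oh = 0L) {
  marg <- base_marginals()
  p <- nrow(marg)
  Rho <- diag(p)
  dimnames(Rho) <- list(marg$name, marg$name)
  tc <- spec$target_correlations
  for (k in seq_len(nrow(tc))) {
    i <- tc$i[k]; j <- tc$j[k]
    if (!(i %in% marg$name) || !(j %in% marg$name))
      stop("target correlations must involve base quantities: ",
           paste(marg$name, collapse = ", "))
    Rho[i, j] <- Rho[j, i] <- tc$rho[k]
  }
  ev <- eigen(Rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    Rho <- as.matrix(Matrix::nearPD(Rho, corr = TRUE)$mat)
    ev <- eigen(Rho, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      stop("requested correlation structure is not positive definite")
  }
  Sigma <- diag(marg$sd) %*% Rho %*% diag(marg$sd)
  Z <- MASS::mvrnorm(spec$m_analytes, mu = marg$mean, Sigma = Sigma)
  colnames(Z) <- marg$name
  Z[, "n_OH"] <- pmin(7, pmax(min_oh, round(Z[, "n_OH"])))
  Z[, "gap"] <- pmax(0.5, Z[, "gap"]) # frontier gap stays positive
  Z
}

descriptors_from_base <- function(Z, ref) {
  E_HOMO <- Z[, "E_HOMO"]
  E_LUMO <- E_HOMO + Z[, "gap"]
  IP <- -E_HOMO
  EA <- -E_LUMO
  eta <- (IP - EA) / 2
  mu <- -(IP + EA) / 2
  omega <- mu^2 / (2 * eta)
  cycle_const <- ref$H_hydrogen_radical - ref$H_proton - ref$H_electron
  ETE <- Z[, "BDE_min"] - Z[, "PA"] - cycle_const
  X <- cbind(SE = Z[, "SE"], n_OH = Z[, "n_OH"], BDE_min = Z[, "BDE_min"],
             PA = Z[, "PA"], ETE = ETE, delta_min = Z[, "delta_min"],
             M_tot = Z[, "M_tot"], gap_HOMO_LUMO = Z[, "gap"],
             IP = IP, EA = EA, eta = eta, mu = mu, omega = omega)
  X[, descriptor_names()]
}

#' Generate a synthetic QSRR dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [qsrr_dataset()]), `t_R` (retention in
#'   minutes) and `truth` (support names, coefficients, noise SD,
#'   intercept and the noiseless signal).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ref <- synthetic_reference()
  Z <- sample_base(spec)
  X <- descriptors_from_base(Z, ref)
  Xs <- scale(X)
  signal <- drop(Xs[, spec$true_support, drop = FALSE] %*% spec$true_coefficients)
  y <- spec$intercept + signal + stats::rnorm(spec$m_analytes, 0, spec$noise_sd)
  ids <- sprintf("analyte_%02d", seq_len(spec$m_analytes))
  rownames(X) <- ids
  list(dataset = qsrr_dataset(X, y, analyte_ids = ids),
       t_R = exp(y),
       truth = list(support = spec$true_support,
                    coefficients = spec$true_coefficients,
                    noise_sd = spec$noise_sd,
                    intercept = spec$intercept,
                    signal = signal))
}

#' Generate quantum-chemistry records consistent with a synthetic dataset
#'
#' Inverse construction of the descriptors module: raw species enthalpies
#' and orbital energies are built so that [assemble_descriptors()] on the
#' generated records reproduces the intended descriptor matrix (to 1e-9).
#' Hydroxyl counts are clamped to at least 1 so every analyte carries the
#' HAT/SPLET descriptors. Additional hydroxyl sites receive strictly
#' higher bond-dissociation enthalpies, so the intended minimum-BDE site
#' is always the first.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (list of [qm_record()]), `ref` (the
#'   [reference_enthalpies()] used) and `descriptors` (the intended
#'   matrix, m x 13).
#' @export
generate_qm_records <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ref <- synthetic_reference()
  Z <- sample_base(spec, min_oh = 1L)
  X <- descriptors_from_base(Z, ref)
  ids <- sprintf("analyte_%02d", seq_len(spec$m_analytes))
  rownames(X) <- ids
  records <- lapply(seq_len(nrow(X)), function(i) {
    d <- X[i, ]
    E_invacuo <- -155000 - 10 * i
    E_solvent <- E_invacuo + d[["SE"]]
    H_parent <- E_solvent
    n_sites <- min(as.integer(d[["n_OH"]]), 3L)
    sites <- paste0("O", seq_len(n_sites))
    bde_site <- d[["BDE_min"]] + 1.5 * (seq_len(n_sites) - 1)
    pa_site <- d[["PA"]] + 2.0 * (seq_len(n_sites) - 1)
    H_radical <- stats::setNames(bde_site + H_parent - ref$H_hydrogen_radical,
                                 sites)
    H_anion <- stats::setNames(pa_site + H_parent - ref$H_proton, sites)
    qm_record(analyte_id = ids[i], H_parent = H_parent,
              H_radical = H_radical, H_anion = H_anion,
              E_invacuo = E_invacuo, E_solvent = E_solvent,
              E_HOMO = -d[["IP"]], E_LUMO = -d[["EA"]],
              dipole_total = d[["M_tot"]],
              nbo_min_charge = d[["delta_min"]],
              n_OH = as.integer(d[["n_OH"]]))
  })
  list(records = records, ref = ref, descriptors = X)
}
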