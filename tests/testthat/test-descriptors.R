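test_that("solvation energy is the solvent-vacuo difference", {
  expect_equal(solvation_energy(-100, -100), 0)
  expect_equal(solvation_energy(-12.34, -2.30), -10.04)
  # magnitude invariant to the common energy offset
  for (E in c(-160000, -5, 1234.5))
    expect_equal(solvation_energy(-27.785 + E, E), -27.785)
  expect_error(solvation_energy(NA_real_, 0), "finite")
  expect_error(solvation_energy(Inf, 0), "finite")
})

test_that("bond dissociation enthalpies and their site minimum", {
  ref <- toy_ref()
  # exact cancellation: radical enthalpy chosen so BDE = 0
  rec0 <- qm_record("z", H_parent = -100,
                    H_radical = c(O1 = -100 - ref$H_hydrogen_radical),
                    H_anion = c(O1 = -50), E_invacuo = -90, E_solvent = -100,
                    E_HOMO = -7, E_LUMO = -2, dipole_total = 1,
                    nbo_min_charge = -0.5, n_OH = 1)
  expect_equal(bond_dissociation_enthalpies(rec0, ref)$BDE_min, 0)

  rec <- toy_record(bde = c(a = 85.0, b = 78.2), pa = c(a = 30, b = 31))
  out <- bond_dissociation_enthalpies(rec, ref)
  expect_equal(out$BDE_min, 78.2)
  expect_equal(out$site_min, "b")

  # brute-force site scan on random sites
  set.seed(42)
  bde <- setNames(runif(3, 70, 95), c("s1", "s2", "s3"))
  rec3 <- toy_record(bde = bde, pa = setNames(runif(3, 25, 40), names(bde)))
  out3 <- bond_dissociation_enthalpies(rec3, ref)
  expect_equal(out3$per_site, bde)
  expect_equal(out3$BDE_min, min(bde))

  # no hydroxyls: missing marker, not an error
  rec_no_oh <- qm_record("f", H_parent = -100, E_invacuo = -90,
                         E_solvent = -100, E_HOMO = -7, E_LUMO = -2,
                         dipole_total = 1, nbo_min_charge = -0.5, n_OH = 0)
  expect_true(is.na(bond_dissociation_enthalpies(rec_no_oh, ref)$BDE_min))
})

test_that("electron transfer enthalpy and proton affinity", {
  ref <- toy_ref()
  rec <- qm_record("e", H_parent = -740,
                   H_radical = c(O1 = -500),
                   H_anion = c(O1 = -520),
                   E_invacuo = -700, E_solvent = -740, E_HOMO = -7,
                   E_LUMO = -2, dipole_total = 1, nbo_min_charge = -0.5,
                   n_OH = 1)
  # ETE = -500 + (-17.816) - (-520)
  expect_equal(electron_transfer_enthalpy(rec, ref, "O1"), 2.184)
  expect_error(electron_transfer_enthalpy(rec, ref, "O9"), "missing")

  rec2 <- qm_record("p", H_parent = -740, H_radical = c(O1 = -500),
                    H_anion = c(O1 = -480), E_invacuo = -700,
                    E_solvent = -740, E_HOMO = -7, E_LUMO = -2,
                    dipole_total = 1, nbo_min_charge = -0.5, n_OH = 1)
  expect_equal(proton_affinity(rec2, ref, "O1"), -480 - 250.574 + 740)
  # zero cases by construction
  recz <- qm_record("z", H_parent = -740,
                    H_radical = c(O1 = -740 - ref$H_electron - 250),
                    H_anion = c(O1 = -740 - ref$H_proton),
                    E_invacuo = -700, E_solvent = -740, E_HOMO = -7,
                    E_LUMO = -2, dipole_total = 1, nbo_min_charge = -0.5,
                    n_OH = 1)
  expect_equal(proton_affinity(recz, ref, "O1"), 0)
  # PA is linear (increasing) in the anion enthalpy
  pas <- vapply(c(-490, -485, -480), function(h) {
    r <- recz; r$H_anion["O1"] <- h
    proton_affinity(r, ref, "O1")
  }, numeric(1))
  expect_true(all(diff(pas) > 0))
})

test_that("thermodynamic cycle: BDE - (PA + ETE) is a reference constant", {
  ref <- toy_ref()
  const_expected <- ref$H_hydrogen_radical - ref$H_proton - ref$H_electron
  set.seed(7)
  for (k in 1:20) {
    rec <- toy_record(id = paste0("r", k),
                      bde = c(O1 = runif(1, 70, 95)),
                      pa = c(O1 = runif(1, 25, 45)))
    b <- bond_dissociation_enthalpies(rec, ref)
    pa <- proton_affinity(rec, ref, "O1")
    ete <- electron_transfer_enthalpy(rec, ref, "O1")
    expect_equal(b$BDE_min - (pa + ete), const_expected, tolerance = 1e-9)
  }
})

test_that("Koopmans IP/EA and the frontier gap", {
  k <- koopmans_ip_ea(-0.25, 0.05)
  expect_equal(k$IP, 0.25)
  expect_equal(k$EA, -0.05)
  expect_equal(k$gap, 0.30)
  # gap = IP - EA identity on random inputs
  set.seed(3)
  for (i in 1:10) {
    eh <- runif(1, -10, -5); el <- eh + runif(1, 0.1, 6)
    ki <- koopmans_ip_ea(eh, el)
    expect_equal(ki$gap, ki$IP - ki$EA)
  }
  expect_warning(koopmans_ip_ea(-2, -3), "gap")
})

test_that("global reactivity indices follow the conceptual-DFT definitions", {
  g <- global_reactivity(9, 1)
  expect_equal(g$eta, 4)
  expect_equal(g$mu, -5)
  expect_equal(g$omega, 25 / 8)
  expect_equal(g$electronegativity, 5)
  expect_true(is.na(global_reactivity(3, 3)$omega))
  set.seed(5)
  for (i in 1:20) {
    ip <- runif(1, 4, 10); ea <- ip - runif(1, 0.1, 6)
    expect_gte(global_reactivity(ip, ea)$omega, 0)
  }
})

test_that("descriptor assembly yields a fixed-order 13-column table", {
  ref <- toy_ref()
  recs <- list(toy_record("a"), toy_record("b", bde = c(O1 = 90), pa = c(O1 = 40)))
  tab <- assemble_descriptors(recs, ref)
  expect_equal(dim(tab), c(2, 14))
  expect_identical(names(tab), c("analyte_id", descriptor_names()))
  expect_equal(tab$BDE_min, c(80, 90))
  expect_equal(tab$gap_HOMO_LUMO, tab$IP - tab$EA)
  expect_equal(tab$eta, tab$gap_HOMO_LUMO / 2)
  expect_error(assemble_descriptors(list(toy_record("a"), toy_record("a")), ref),
               "duplicate")
  one <- assemble_descriptors(list(toy_record("solo")), ref)
  expect_equal(nrow(one), 1)
})

test_that("descriptor CSV round trip preserves values", {
  ref <- toy_ref()
  tab <- assemble_descriptors(list(toy_record("a"), toy_record("b")), ref)
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(tab, path)
  back <- read_descriptors(path)
  for (nm in descriptor_names())
    expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-6)
})

test_that("qm-record CSV round trip and Hartree unit conversion", {
  ref <- toy_ref()
  recs <- list(toy_record("a"), toy_record("b", bde = c(O1 = 88), pa = c(O1 = 42)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_qm_records(recs, path)
  back <- read_qm_records(path)
  d1 <- assemble_descriptors(recs, ref)
  d2 <- assemble_descriptors(unname(back), ref)
  expect_equal(d2[descriptor_names()], d1[descriptor_names()], tolerance = 1e-9)

  # the same enthalpies expressed in Hartree reproduce the kcal/mol pipeline
  df <- read.csv(path, stringsAsFactors = FALSE)
  is_h <- df$quantity == "H"
  df$value[is_h] <- df$value[is_h] / 627.5095
  df$unit[is_h] <- "hartree"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  d3 <- assemble_descriptors(unname(read_qm_records(path2)), ref)
  for (nm in descriptor_names())
    expect_equal(d3[[nm]], d1[[nm]], tolerance = 1e-6)
})
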