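## an H2 molecular crystal (one molecule per P1 cell) whose geometry
## matches the Molden fixture exactly
h2_crystal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b2a <- 0.52917721067
      tmp <- tempfile(fileext = ".cif")
      write_cif(unit_cell(4, 4, 5), list(parse_symop("x,y,z")),
                data.frame(element = c("H", "H"), label = c("H1", "H2"),
                           fx = 0, fy = 0, fz = c(0, 1.4 * b2a / 5)), tmp)
      cache <<- read_cif(tmp)
    }
    cache
  }
})

## independently coded D2 oracle: explicit double loop over the pair
d2_oracle <- function(elemA, xyzA, elemB, xyzB) {
  C6 <- hirshfeldr:::D2_C6; R0 <- hirshfeldr:::D2_R0
  e <- 0
  for (i in seq_along(elemA)) for (j in seq_along(elemB)) {
    r <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
    c6 <- sqrt(C6[[elemA[i]]] * C6[[elemB[j]]]) * 1000
    rr <- R0[[elemA[i]]] + R0[[elemB[j]]]
    e <- e - c6 / r^6 / (1 + exp(-20 * (r / rr - 1)))
  }
  e
}

test_that("D2 dispersion matches the term-by-term oracle and decays", {
  a <- list(element = "C", xyz = rbind(c(0, 0, 0)))
  b <- list(element = "C", xyz = rbind(c(3.5, 0, 0)))
  e <- dispersion_d2(a, b)
  expect_lt(abs(e - d2_oracle("C", a$xyz, "C", b$xyz)) / abs(e), 1e-10)
  expect_lt(e, 0)
  far <- dispersion_d2(a, list(element = "C", xyz = rbind(c(100, 0, 0))))
  expect_lt(abs(far), 1e-8)
  ## multi-atom molecules
  cr <- fixture_crystal("urea_like")
  mols <- complete_molecules(cr)
  e2 <- dispersion_d2(mols[[1]], mols[[2]])
  expect_lt(abs(e2 - d2_oracle(mols[[1]]$element, mols[[1]]$xyz,
                               mols[[2]]$element, mols[[2]]$xyz)) / abs(e2), 1e-10)
  expect_error(dispersion_d2(a, list(element = "U", xyz = rbind(c(3, 0, 0)))),
               "unsupported element")
})

test_that("undamped dispersion scales as R^-6 when coordinates double", {
  a <- list(element = "Ne", xyz = rbind(c(0, 0, 0)))
  e1 <- dispersion_d2(a, list(element = "Ne", xyz = rbind(c(12, 0, 0))))
  e2 <- dispersion_d2(a, list(element = "Ne", xyz = rbind(c(24, 0, 0))))
  expect_close(e2 / e1, 2^-6, 1e-4, "R^-6 scaling")
})

test_that("polarization energy reproduces the point-charge closed form", {
  ## single +1 charge at r from one polarizable Ne atom:
  ## E = -1/2 alpha (q/r^2)^2 in a.u.
  b2a <- 0.52917721067
  r_ang <- 3.0; r_bohr <- r_ang / b2a
  a <- list(element = "Ne", xyz = rbind(c(0, 0, 0)))
  b <- list(element = "H", xyz = rbind(c(r_ang, 0, 0)))
  e <- polarization_energy(a, b, chargesA = 0, chargesB = 1)
  alpha <- hirshfeldr:::ATOMIC_POLARIZABILITY[["Ne"]]
  closed <- -0.5 * alpha * (1 / r_bohr^2)^2 * 2625.499639
  expect_equal(as.numeric(e), closed, tolerance = 1e-10)
  expect_true(attr(e, "approximate"))
  ## zero-charge monomer induces nothing
  e0 <- polarization_energy(a, b, chargesA = 0, chargesB = 0)
  expect_equal(as.numeric(e0), 0)
  ## A <-> B exchange symmetry
  e_ab <- polarization_energy(a, b, chargesA = 0.3, chargesB = -0.4)
  e_ba <- polarization_energy(b, a, chargesA = -0.4, chargesB = 0.3)
  expect_equal(as.numeric(e_ab), as.numeric(e_ba), tolerance = 1e-12)
  expect_error(polarization_energy(a, b), "wavefunction or point charges")
})

test_that("wavefunction polarization is negative at contact and vanishes far away", {
  wfn <- fixture_h2_wfn()
  molA <- list(element = wfn$element, xyz = wfn$xyz)
  mk <- function(d) shifted_h2(c(d, 0, 0))
  wB <- mk(3.0)
  eB <- polarization_energy(molA, list(element = wB$element, xyz = wB$xyz),
                            wfnA = wfn, wfnB = wB)
  expect_lt(as.numeric(eB), 0)
  wF <- mk(40)
  eF <- polarization_energy(molA, list(element = wF$element, xyz = wF$xyz),
                            wfnA = wfn, wfnB = wF)
  expect_lt(abs(as.numeric(eF)), 1e-6)
})

test_that("electrostatic energy hits the point-charge Coulomb limit", {
  ## two bare protons at 10 A: q^2/r = 1389.35 kJ/mol / 10
  proton <- function(x) {
    w <- fixture_h2_wfn()
    w$element <- "H"; w$Z <- 1
    w$xyz <- rbind(c(x, 0, 0))
    w$shells$center <- rbind(c(x, 0, 0) / 0.52917721067, (c(x, 0, 0) + c(0, 0, 0.7408)) / 0.52917721067)
    w$occupations <- w$occupations * 0
    w$D <- w$D * 0
    w
  }
  e <- electrostatic_energy(proton(0), proton(10))
  expect_close(e, 138.935, 0.05 * 138.935, "Coulomb limit")
})

test_that("electrostatic energy is symmetric and vanishes for far neutral pairs", {
  wfn <- fixture_h2_wfn()
  far <- shifted_h2(c(100, 0, 0))
  expect_lt(abs(electrostatic_energy(wfn, far)), 0.01)
  near <- shifted_h2(c(2.5, 0, 0))
  e_ab <- electrostatic_energy(wfn, near)
  e_ba <- electrostatic_energy(near, wfn)
  expect_equal(e_ab, e_ba, tolerance = 1e-8)
})

test_that("exchange-repulsion matches an independent dense-matrix assembly", {
  wfnA <- fixture_h2_wfn()
  wfnB <- shifted_h2(c(2.0, 0, 0))
  e <- repulsion_energy(wfnA, wfnB)
  expect_gt(e, 0)
  ## oracle: Loewdin-orthogonalized occupied orbitals, energies assembled
  ## in the MO basis from dimer AO matrices
  sh <- hirshfeldr:::dimer_shells(wfnA$shells, wfnB$shells)
  na <- nrow(wfnA$C)
  C <- matrix(0, 2 * na, 2)
  C[1:na, 1] <- wfnA$C[, 1]
  C[na + 1:na, 2] <- wfnB$C[, 1]
  oe <- hirshfeldr:::one_electron_cpp(sh)
  M <- crossprod(C, oe$S %*% C)
  es <- eigen(M, symmetric = TRUE)
  Minvhalf <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  Ct <- C %*% Minvhalf
  D_AS <- 2 * tcrossprod(Ct)
  Z <- c(1, 1, 1, 1); R <- rbind(wfnA$xyz, wfnB$xyz)
  e_hl <- hirshfeldr:::hf_like_energy(sh, D_AS, Z, R)
  e_a <- hirshfeldr:::hf_like_energy(wfnA$shells, wfnA$D, wfnA$Z, wfnA$xyz)
  e_b <- hirshfeldr:::hf_like_energy(wfnB$shells, wfnB$D, wfnB$Z, wfnB$xyz)
  e_ele <- electrostatic_energy(wfnA, wfnB) / 2625.499639
  oracle <- (e_hl - e_a - e_b - e_ele) * 2625.499639
  expect_lt(abs(e - oracle) / abs(e), 1e-8)
})

test_that("exchange-repulsion decays monotonically and vanishes far away", {
  wfnA <- fixture_h2_wfn()
  es <- vapply(seq(2, 6, 1), function(d) repulsion_energy(wfnA, shifted_h2(c(d, 0, 0))), 0)
  expect_true(all(diff(es) < 0))
  expect_true(all(es > 0))
  expect_lt(abs(repulsion_energy(wfnA, shifted_h2(c(50, 0, 0)))), 1e-6)
})

test_that("pair energy combines scaled terms per the model", {
  unit_model <- list(name = "unit", k_ele = 1, k_pol = 1, k_dis = 1, k_rep = 1)
  a <- list(element = "C", xyz = rbind(c(0, 0, 0)))
  b <- list(element = "C", xyz = rbind(c(3.5, 0, 0)))
  pe <- pair_energy(a, b, model = unit_model,
                    overrides = list(E_ele = -10, E_pol = -2, E_dis = -8, E_rep = 12))
  expect_equal(pe$E_tot, -8)
  ## all-zero terms give zero total
  pe0 <- pair_energy(a, b, model = energy_model("CE-B3LYP"),
                     overrides = list(E_ele = 0, E_pol = 0, E_dis = 0, E_rep = 0))
  expect_equal(pe0$E_tot, 0)
  ## computed four-term pair obeys the linear combination invariant
  wfnA <- fixture_h2_wfn()
  wfnB <- shifted_h2(c(2.5, 0, 0))
  molA <- list(element = wfnA$element, xyz = wfnA$xyz)
  molB <- list(element = wfnB$element, xyz = wfnB$xyz)
  m <- energy_model("CE-B3LYP")
  pe2 <- pair_energy(molA, molB, wfnA, wfnB, m)
  expect_equal(pe2$E_tot,
               m$k_ele * pe2$E_ele + m$k_pol * pe2$E_pol +
                 m$k_dis * pe2$E_dis + m$k_rep * pe2$E_rep, tolerance = 1e-12)
  expect_lte(pe2$E_dis, 0)
  expect_lte(pe2$E_pol, 0)
  expect_gte(pe2$E_rep, 0)
  ## quantum terms without wavefunctions are a clear error
  expect_error(pair_energy(molA, molB, model = m), "wavefunction")
})

test_that("energy tables cover every symmetry-unique pair consistently", {
  cr <- h2_crystal()
  seed <- complete_molecules(cr)[[1]]
  tab <- interaction_energy_table(cr, seed, wfn = NULL, radius = 4.2,
                                  terms = "dis")
  up <- unique_molecule_pairs(cr, seed, 4.2)
  expect_equal(nrow(tab), nrow(up))
  ## dispersion-only rows equal direct per-pair calls
  pairs <- attr(up, "pairs")
  for (k in seq_len(nrow(tab))) {
    expect_equal(tab$E_dis[k], dispersion_d2(seed, pairs[[k]]), tolerance = 1e-12)
    expect_equal(tab$E_tot[k], energy_model("CE-B3LYP")$k_dis * tab$E_dis[k],
                 tolerance = 1e-12)
  }
  ## invariance to the seed image choice
  seed2 <- hirshfeldr:::translate_molecule(seed, cr$cell, c(0, 1, 1))
  tab2 <- interaction_energy_table(cr, seed2, wfn = NULL, radius = 4.2,
                                   terms = "dis")
  expect_equal(sort(round(tab$E_tot, 9)), sort(round(tab2$E_tot, 9)))
  expect_equal(sort(tab$n_class), sort(tab2$n_class))
})

test_that("full four-term table runs with the monomer wavefunction mapped by symmetry", {
  cr <- h2_crystal()
  seed <- complete_molecules(cr)[[1]]
  wfn <- fixture_h2_wfn()
  tab <- interaction_energy_table(cr, seed, wfn, radius = 4.2)
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$E_rep >= 0))
  expect_true(all(tab$E_dis < 0))
  expect_true(all(is.finite(tab$E_tot)))
  ## CSV and JSON exports
  csv <- tempfile(fileext = ".csv")
  write_energy_table(tab, csv, "csv")
  expect_equal(nrow(utils::read.csv(csv)), nrow(tab))
  js <- tempfile(fileext = ".json")
  write_energy_table(tab, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$model$name, "CE-B3LYP")
  expect_equal(parsed$rows$E_tot, tab$E_tot, tolerance = 1e-9)
})

test_that("level mismatches warn but do not stop", {
  cr <- h2_crystal()
  seed <- complete_molecules(cr)[[1]]
  wfn <- read_molden(make_fixture("molden_h2"), level = "HF/STO-3G toy")
  expect_warning(interaction_energy_table(cr, seed, wfn, radius = 4.2,
                                          model = energy_model("CE-B3LYP"),
                                          terms = "dis"),
                 "does not match")
})

test_that("lattice energy halves the multiplicity-weighted pair sum and converges", {
  expect_equal(lattice_energy(NULL)$energy, 0)
  cr <- fixture_crystal("cubic_atom")  # Ne lattice, dispersion only
  seed <- complete_molecules(cr)[[1]]
  tab <- interaction_energy_table(cr, seed, radius = 15, terms = "dis")
  lat <- lattice_energy(tab)
  expect_equal(lat$energy, 0.5 * sum(tab$n_class * tab$E_tot), tolerance = 1e-12)
  ## linearity: doubling pair energies doubles the lattice energy
  tab2 <- tab; tab2$E_tot <- 2 * tab$E_tot
  expect_equal(lattice_energy(tab2)$energy, 2 * lat$energy, tolerance = 1e-12)
  ## radial convergence: later shells contribute less
  e8 <- lattice_energy(tab[tab$R <= 8, ])$energy
  e12 <- lattice_energy(tab[tab$R <= 12, ])$energy
  e15 <- lat$energy
  expect_lt(abs(e15 - e12), abs(e12 - e8))
})

test_that("the model constants file exposes both calibrated models", {
  for (nm in c("CE-HF", "CE-B3LYP")) {
    m <- energy_model(nm)
    expect_true(all(c(m$k_ele, m$k_pol, m$k_dis, m$k_rep) > 0))
    expect_match(m$level, "monomer wavefunctions")
    expect_match(m$version, "\\d")
  }
  expect_match(energy_model("CE-HF")$level, "3-21G")
  expect_match(energy_model("CE-B3LYP")$level, "6-31G")
})
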