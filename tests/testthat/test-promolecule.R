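test_that("atomic densities integrate to Z (adaptive quadrature oracle)", {
  for (el in c("H", "C", "N", "O", "S", "Cl", "Fe", "Kr")) {
    I <- stats::integrate(function(r) 4 * pi * r^2 * atomic_density(el, r),
                          0, 60, rel.tol = 1e-7, subdivisions = 1000L,
                          stop.on.error = FALSE)$value
    expect_close(I, atomic_number(el), 1e-3, paste(el, "electron count"))
  }
})

test_that("atomic densities are positive, smooth and decay", {
  r <- exp(seq(log(1e-3), log(12), length.out = 400))
  for (el in c("H", "C", "O")) {
    rho <- atomic_density(el, r)
    expect_true(all(rho >= 0))
    expect_lt(atomic_density(el, 50), 1e-10)
    ## no grid artifacts: log-density locally monotone beyond 1 bohr
    tail <- rho[r > 1]
    expect_true(all(diff(log(tail)) < 0))
  }
  expect_error(atomic_density("Xx", 1), "unsupported element")
})

test_that("the shipped HF tabulations drive the default density source", {
  expect_match(atomic_density_provenance("O"), "atomic-uhf")
  ## analytic STO source remains available and integrates to Z too
  I <- stats::integrate(function(r) 4 * pi * r^2 * atomic_density("O", r, source = "sto"),
                        0, 60, rel.tol = 1e-9, subdivisions = 500L)$value
  expect_close(I, 8, 1e-3, "STO O electron count")
})

test_that("density grid files round-trip through the documented format", {
  tmp <- tempfile(fileext = ".tsv")
  write_density_grid("C", tmp)
  ref <- atomic_density("C", c(0.5, 1, 2, 4))
  read_density_grid(tmp)
  on.exit(clear_density_grid("C"))
  expect_equal(atomic_density("C", c(0.5, 1, 2, 4)), ref, tolerance = 1e-3)
})

test_that("promolecule density is an additive superposition", {
  ## single atom equals the radial density
  one <- list(element = "C", xyz = rbind(c(0, 0, 0)))
  p <- rbind(c(1.2, 0.3, -0.4))
  r <- sqrt(sum(p^2)) / 0.52917721067
  expect_equal(promolecule_density(one, p), atomic_density("C", r), tolerance = 1e-9)
  ## symmetric midpoint between two identical atoms: exactly twice one atom
  two <- list(element = c("N", "N"), xyz = rbind(c(0, 0, 0), c(0, 0, 2)))
  mid <- rbind(c(0, 0, 1))
  expect_equal(promolecule_density(two, mid),
               2 * promolecule_density(list(element = "N", xyz = rbind(c(0, 0, 0))), mid),
               tolerance = 1e-12)
  ## 3-atom fixture at random points matches the term-by-term sum
  set.seed(42)
  sites <- list(element = c("C", "O", "H"),
                xyz = rbind(c(0, 0, 0), c(1.2, 0, 0), c(-0.5, 0.9, 0)))
  pts <- matrix(runif(60, -2, 3), ncol = 3)
  brute <- rowSums(vapply(1:3, function(i) {
    d <- sqrt(colSums((t(pts) - sites$xyz[i, ])^2)) / 0.52917721067
    atomic_density(sites$element[i], d)
  }, numeric(nrow(pts))))
  expect_equal(promolecule_density(sites, pts), brute, tolerance = 1e-9)
})

test_that("procrystal density is lattice periodic and matches brute force", {
  cr <- fixture_crystal("diatomic")
  set.seed(11)
  pts <- cbind(runif(20, 0, 5.6), runif(20, 0, 4), runif(20, 0, 4))
  rho <- procrystal_density(cr, pts)
  ## periodicity under each lattice vector
  for (tvec in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    shift <- frac_to_cart(cr$cell, tvec)
    rho2 <- procrystal_density(cr, sweep(pts, 2, as.numeric(shift), `+`))
    expect_lt(max(abs(rho2 - rho) / rho), 1e-8)
  }
  ## brute-force 7x7x7 supercell oracle
  ua <- expand_unit_cell(cr)
  brute <- numeric(nrow(pts))
  for (t1 in -3:3) for (t2 in -3:3) for (t3 in -3:3) {
    at <- frac_to_cart(cr$cell, sweep(as.matrix(ua[, c("fx", "fy", "fz")]), 2,
                                      c(t1, t2, t3), `+`))
    brute <- brute + promolecule_density(list(element = ua$element, xyz = at), pts)
  }
  expect_lt(max(abs(brute - rho) / rho), 1e-6)
  ## value on an atom dominated by that atom
  at1 <- as.numeric(frac_to_cart(cr$cell, as.numeric(ua[1, c("fx", "fy", "fz")])))
  expect_equal(procrystal_density(cr, rbind(at1)),
               atomic_density("N", 0) * (1 + 1e-9), tolerance = 0.01)
})

test_that("stockholder weight is 0.5 midway between symmetric molecules and ~1 on nuclei", {
  ## two identical single-atom molecules far from every lattice image, so
  ## only the symmetric pair contributes at the midpoint
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(20, 20, 20), list(parse_symop("x,y,z")),
            data.frame(element = c("N", "N"), label = c("N1", "N2"),
                       fx = c(0.425, 0.575), fy = 0.5, fz = 0.5), tmp)
  cr <- read_cif(tmp)
  mols <- complete_molecules(cr)
  expect_length(mols, 2)
  mid <- rbind(c(10, 10, 10))
  w_mid <- stockholder_weight(cr, mols[[1]], mid)
  expect_lt(abs(w_mid - 0.5), 1e-6)
  ## at the molecule's own nucleus
  expect_gt(stockholder_weight(cr, mols[[1]], mols[[1]]$xyz), 0.99)
  ## periodic crystal: junction regions push the weight below 0.5, never above
  crd <- fixture_crystal("diatomic")
  mold <- complete_molecules(crd)[[1]]
  midb <- sweep(mold$xyz, 2, as.numeric(frac_to_cart(crd$cell, c(0, 0.5, 0))), `+`)
  wb <- stockholder_weight(crd, mold, midb)
  expect_true(all(wb <= 0.5 & wb > 0.45))
})

test_that("stockholder weights form a partition of unity", {
  for (kind in c("diatomic", "urea_like")) {
    cr <- fixture_crystal(kind)
    set.seed(3)
    n <- 1000
    fr <- matrix(runif(3 * n), ncol = 3)
    pts <- frac_to_cart(cr$cell, fr)
    W <- stockholder_weight_matrix(cr, pts)
    expect_true(all(W >= 0 & W <= 1))
    expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
  }
})

test_that("procrystal bounds the promolecule of every constituent molecule", {
  cr <- fixture_crystal("urea_like")
  mols <- complete_molecules(cr)
  set.seed(5)
  pts <- frac_to_cart(cr$cell, matrix(runif(150), ncol = 3))
  rho_c <- procrystal_density(cr, pts)
  for (m in mols) {
    expect_true(all(promolecule_density(m, pts) <= rho_c * (1 + 1e-12)))
  }
})
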