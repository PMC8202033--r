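## shared decorated urea surface (medium resolution keeps these fast)
urea_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cr <- fixture_crystal("urea_like")
      mol <- complete_molecules(cr)[[1]]
      cache <<- fragment_patches(hirshfeld_surface_properties(cr, mol, "medium"))
    }
    cache
  }
})

test_that("d_norm follows the vdW-normalized formula exactly", {
  ## hand evaluation: d_i = 1.1 (H, 1.09), d_e = 1.7 (O, 1.52)
  dn <- (1.1 - 1.09) / 1.09 + (1.7 - 1.52) / 1.52
  expect_close(dn, 0.1276, 5e-4, "hand d_norm")
  mesh <- urea_mesh()
  asg <- mesh$meta$assignment
  recomputed <- (asg$d_i - vdw_radius(asg$internal_element)) /
    vdw_radius(asg$internal_element) +
    (asg$d_e - vdw_radius(asg$external_element)) / vdw_radius(asg$external_element)
  expect_equal(mesh$props$d_norm, recomputed, tolerance = 1e-12)
})

test_that("nearest-atom assignment matches a brute-force all-pairs scan", {
  mesh <- urea_mesh()
  mol <- mesh$meta$molecule
  idx <- seq(1, nrow(mesh$vertices), by = 17)
  for (i in idx) {
    d <- sqrt(colSums((t(mol$xyz) - mesh$vertices[i, ])^2))
    expect_equal(mesh$props$d_i[i], min(d), tolerance = 1e-10)
  }
  env_xyz <- do.call(rbind, lapply(mesh$meta$cluster, `[[`, "xyz"))
  for (i in idx) {
    d <- sqrt(colSums((t(env_xyz) - mesh$vertices[i, ])^2))
    expect_equal(mesh$props$d_e[i], min(d), tolerance = 1e-10)
  }
})

test_that("swapping molecule roles swaps d_i and d_e (inversion dimer)", {
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(6, 5, 5), lapply(c("x,y,z", "-x,-y,-z"), parse_symop),
            data.frame(element = c("C", "O"), label = c("C1", "O1"),
                       fx = c(0.20, 0.38), fy = c(0.25, 0.28), fz = c(0.25, 0.22)),
            tmp)
  cr <- read_cif(tmp)
  mols <- complete_molecules(cr)
  m1 <- hirshfeld_surface_properties(cr, mols[[1]], 0.3)
  m2 <- hirshfeld_surface_properties(cr, mols[[2]], 0.3)
  ## the two surfaces are inversion images: compare area-weighted means
  s1i <- property_statistics(m1, "d_i"); s1e <- property_statistics(m1, "d_e")
  s2i <- property_statistics(m2, "d_i"); s2e <- property_statistics(m2, "d_e")
  expect_close(s1i$mean, s2i$mean, 5e-3, "d_i means")
  expect_close(s1e$mean, s2e$mean, 5e-3, "d_e means")
  ## where the two molecules face each other the fields swap roles:
  ## vertex-for-vertex under the inversion x -> T - x relating the two
  ## molecules (T = lattice shift of the wrapped image)
  Tvec <- as.numeric(frac_to_cart(cr$cell, c(1, 1, 1)))
  v2 <- sweep(-m2$vertices, 2, Tvec, `+`)
  nn <- hirshfeldr:::nn_brute_cpp(m1$vertices, v2)
  close_pairs <- which(nn$distance < 0.05)
  expect_gt(length(close_pairs), 100)
  expect_lt(max(abs(m1$props$d_i[close_pairs] - m2$props$d_i[nn$index[close_pairs]])),
            0.02)
})

test_that("empty environment raises the documented error", {
  mesh <- urea_mesh()
  expect_error(distance_properties(mesh, mesh$meta$molecule, list()),
               "empty environment")
})

test_that("fragment patches partition the surface area", {
  mesh <- urea_mesh()
  tab <- mesh$meta$patch_table
  expect_equal(sum(tab$percent), 100, tolerance = 1e-6)
  expect_equal(sum(tab$area), mesh$area, tolerance = 1e-6 * mesh$area)
  ## sorted by area descending, patch ids consecutive
  expect_true(all(diff(tab$area) <= 1e-9))
  expect_equal(tab$patch_id, seq_len(nrow(tab)))
  ## patch channel consistent with the table
  pid <- mesh$props$patch_id
  a1 <- sum(mesh$vertex_area[pid == 1])
  expect_equal(a1, tab$area[1], tolerance = 1e-9)
})

test_that("a single neighbor yields one 100% patch", {
  ## isolated pair in a big P1 box: environment is exactly one molecule
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(14, 12, 12), list(parse_symop("x,y,z")),
            data.frame(element = c("Ne", "Ne"), label = c("Ne1", "Ne2"),
                       fx = c(0.35, 0.55), fy = 0.5, fz = 0.5), tmp)
  cr <- read_cif(tmp)
  mols <- complete_molecules(cr)
  ## the sparse box has genuine deep-void regions; those warnings are the
  ## documented floor behavior
  mesh <- suppressWarnings(hirshfeld_surface(cr, mols[[1]], 0.3))
  mesh <- distance_properties(mesh, mols[[1]], mols[2])
  mesh <- fragment_patches(mesh)
  expect_equal(nrow(mesh$meta$patch_table), 1)
  expect_equal(mesh$meta$patch_table$percent, 100, tolerance = 1e-9)
})

test_that("curvature: spheres are +1 shape-index umbilics, flat regions very negative curvedness", {
  g <- make_grid(c(-3, -3, -3), c(3, 3, 3), 0.25)
  m <- extract_isosurface(sphere_field, g, 2.0, inside = "low")
  m <- curvature_properties(m)
  si <- m$props$shape_index
  expect_true(all(abs(si - 1) < 0.05, na.rm = TRUE))
  ## curvedness of a R=2 sphere: (2/pi) ln(1/2) = -0.44
  expect_close(stats::median(m$props$curvedness, na.rm = TRUE),
               (2 / pi) * log(0.5), 0.05, "sphere curvedness")
  ## much larger sphere = locally plane-like: strongly negative curvedness
  g2 <- make_grid(c(-13, -13, -13), c(13, 13, 13), 0.8)
  m2 <- curvature_properties(extract_isosurface(sphere_field, g2, 12, inside = "low"))
  expect_lt(stats::median(m2$props$curvedness, na.rm = TRUE),
            (2 / pi) * log(0.5))
})

test_that("shape index is ~0 at a saddle and bounded in [-1, 1]", {
  saddle <- function(p) p[, 3] - (p[, 1]^2 - p[, 2]^2) / 4
  g <- make_grid(c(-2, -2, -2.5), c(2, 2, 2.5), 0.2)
  m <- extract_isosurface(saddle, g, 0, inside = "low")
  m <- curvature_properties(m)
  ## vertex nearest the saddle point (origin)
  i <- which.min(rowSums(m$vertices^2))
  expect_lt(abs(m$props$shape_index[i]), 0.1)
  mesh <- urea_mesh()
  mesh <- curvature_properties(mesh)
  expect_true(all(mesh$props$shape_index >= -1 & mesh$props$shape_index <= 1,
                  na.rm = TRUE))
  expect_true(all(is.finite(mesh$props$curvedness[!is.na(mesh$props$curvedness)])))
})

test_that("property statistics are area-weighted and channel-checked", {
  mesh <- urea_mesh()
  mesh <- mesh_set_channel(mesh, "const", rep(2.5, nrow(mesh$vertices)))
  s <- property_statistics(mesh, "const")
  expect_equal(s$mean, 2.5, tolerance = 1e-12)
  expect_equal(s$min, 2.5)
  expect_error(property_statistics(mesh, "nope"), "no channel")
  ## mean of patch percentages = 100 / patch count
  tab <- mesh$meta$patch_table
  expect_equal(mean(tab$percent), 100 / nrow(tab), tolerance = 1e-9)
})
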