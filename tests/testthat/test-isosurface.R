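sphere_field <- function(p) sqrt(rowSums(p^2))

test_that("isosurface of a distance field reproduces the analytic sphere", {
  g <- make_grid(c(-3, -3, -3), c(3, 3, 3), 0.2)
  m <- extract_isosurface(sphere_field, g, 2.0, inside = "low",
                          refine_tol = 1e-5)
  expect_true(m$closed)
  mm <- mesh_measures(m)
  expect_lt(abs(mm$area - 4 * pi * 4) / (4 * pi * 4), 0.02)
  expect_lt(abs(mm$volume - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.02)
  expect_close(mm$globularity, 1, 0.02, "sphere globularity")
  expect_lt(mm$asphericity, 1e-3)
  ## refined vertices sit on the isosurface
  expect_lt(max(abs(sphere_field(m$vertices) - 2)), 1e-4)
})

test_that("area and volume errors shrink as the grid is refined", {
  errs <- vapply(c(0.8, 0.4, 0.2), function(h) {
    g <- make_grid(c(-3, -3, -3), c(3, 3, 3), h)
    mm <- mesh_measures(extract_isosurface(sphere_field, g, 2.0, inside = "low"))
    abs(mm$area - 4 * pi * 4)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("isovalue outside the field range is an empty-mesh error", {
  g <- make_grid(c(-1, -1, -1), c(1, 1, 1), 0.25)
  expect_error(extract_isosurface(sphere_field, g, 10), "empty mesh")
})

test_that("signed volume is positive (outward winding) for closed outputs", {
  g <- make_grid(c(-3, -3, -3), c(3, 3, 3), 0.3)
  for (inside in c("low", "high")) {
    f <- if (inside == "low") sphere_field else function(p) -sphere_field(p)
    iso <- if (inside == "low") 2 else -2
    m <- extract_isosurface(f, g, iso, inside = inside)
    expect_gt(m$volume, 0)
  }
})

test_that("Hirshfeld surface vertices satisfy the 0.5 weight condition", {
  cr <- fixture_crystal("diatomic")
  mol <- complete_molecules(cr)[[1]]
  mesh <- hirshfeld_surface(cr, mol, "high")
  expect_true(mesh$closed)
  expect_lt(max(abs(mesh$props$w - 0.5)), 1e-3)
  expect_equal(mesh$meta$isovalue, 0.5)
})

test_that("inversion-related molecules have equal Hirshfeld surface areas", {
  ## P-1 crystal: two symmetry-equivalent images of a CO-like molecule
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(6, 5, 5), lapply(c("x,y,z", "-x,-y,-z"), parse_symop),
            data.frame(element = c("C", "O"), label = c("C1", "O1"),
                       fx = c(0.20, 0.38), fy = c(0.25, 0.28), fz = c(0.25, 0.22)),
            tmp)
  cr <- read_cif(tmp)
  mols <- complete_molecules(cr)
  expect_length(mols, 2)
  a1 <- hirshfeld_surface(cr, mols[[1]], 0.3)$area
  a2 <- hirshfeld_surface(cr, mols[[2]], 0.3)$area
  expect_lt(abs(a1 - a2) / a1, 5e-3)
})

test_that("HS volumes plus void volume tile the well-packed unit cell", {
  cr <- fixture_crystal("urea_like")
  mols <- complete_molecules(cr)
  hsvol <- sum(vapply(mols, function(m) hirshfeld_surface(cr, m, "high")$volume, 0))
  vv <- void_surface(cr, 0.002, resolution = "high")$void_volume
  expect_lt(abs(hsvol + vv - cr$cell$volume) / cr$cell$volume, 0.02)
})

test_that("promolecule density isosurface of one atom is the analytic sphere", {
  iso <- 0.002
  r_iso <- stats::uniroot(function(r) atomic_density("C", r) - iso,
                          c(0.1, 30), tol = 1e-10)$root * 0.52917721067
  m <- density_isosurface(list(element = "C", xyz = rbind(c(0, 0, 0))),
                          isovalue = iso, resolution = "high")
  rad <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rad - r_iso)), 0.02)
  ## isovalue above rho(0) -> empty-mesh error
  expect_error(density_isosurface(list(element = "C", xyz = rbind(c(0, 0, 0))),
                                  isovalue = 1e4), "empty mesh")
})

test_that("two far-apart atoms give two disjoint closed components", {
  m <- density_isosurface(list(element = c("Ne", "Ne"),
                               xyz = rbind(c(0, 0, 0), c(8, 0, 0))),
                          isovalue = 0.002, resolution = "medium")
  comp <- igraph::components(igraph::graph_from_edgelist(
    rbind(m$faces[, 1:2], m$faces[, 2:3]), directed = FALSE))
  expect_equal(comp$no, 2)
  expect_true(m$closed)
})

test_that("void volume matches the brute-force voxel count oracle", {
  cr <- fixture_crystal("diatomic")
  vs <- void_surface(cr, 0.002, resolution = "high")
  fr <- as.matrix(expand.grid(seq(0, 0.995, 0.01) + 0.005,
                              seq(0, 0.99, 0.02) + 0.01,
                              seq(0, 0.99, 0.02) + 0.01))
  rho <- procrystal_density(cr, frac_to_cart(cr$cell, fr))
  voxel <- mean(rho < 0.002) * cr$cell$volume
  expect_lt(abs(vs$void_volume - voxel) / voxel, 0.03)
})

test_that("void volume is translation invariant and grows with the cell", {
  cr <- fixture_crystal("cubic_atom")          # Ne atom in a 4 A cube
  v1 <- void_surface(cr, 0.002, resolution = 0.15)$void_volume
  ## same crystal, shifted atom (origin choice must not matter)
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(4, 4, 4), list(parse_symop("x,y,z")),
            data.frame(element = "Ne", label = "Ne1",
                       fx = 0.23, fy = 0.41, fz = 0.77), tmp)
  v2 <- void_surface(read_cif(tmp), 0.002, resolution = 0.15)$void_volume
  expect_lt(abs(v1 - v2) / v1, 0.01)
  ## bigger cell, same atom -> more void
  tmp2 <- tempfile(fileext = ".cif")
  write_cif(unit_cell(6, 6, 6), list(parse_symop("x,y,z")),
            data.frame(element = "Ne", label = "Ne1", fx = 0, fy = 0, fz = 0), tmp2)
  v3 <- void_surface(read_cif(tmp2), 0.002, resolution = 0.15)$void_volume
  expect_gt(v3, v1)
  ## no void at a tiny isovalue floor in a dense crystal
  vs0 <- void_surface(fixture_crystal("urea_like"), 1e-8, resolution = "medium")
  expect_equal(vs0$void_volume, 0)
  expect_null(vs0$mesh)
})

test_that("mesh measures: cube volume is exact, per-vertex areas sum to total", {
  ## unit cube as 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  m <- hirshfeldr:::new_trimesh(v, f)
  expect_true(m$closed)
  mm <- mesh_measures(m)
  expect_equal(mm$volume, 1, tolerance = 1e-12)
  expect_equal(mm$area, 6, tolerance = 1e-12)
  expect_equal(sum(m$vertex_area), m$area, tolerance = 1e-8)
})

test_that("mesh export formats round-trip geometry", {
  g <- make_grid(c(-3, -3, -3), c(3, 3, 3), 0.5)
  m <- extract_isosurface(sphere_field, g, 2.0, inside = "low")
  m <- mesh_set_channel(m, "d_i", sphere_field(m$vertices))
  ply <- tempfile(fileext = ".ply")
  write_mesh(m, ply, "ply")
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl("property float d_i", lines)))
  nv <- as.integer(sub("element vertex ", "", lines[grepl("element vertex", lines)]))
  expect_equal(nv, nrow(m$vertices))
  obj <- tempfile(fileext = ".obj")
  write_mesh(m, obj, "obj")
  expect_equal(sum(startsWith(readLines(obj), "v ")), nrow(m$vertices))
  plyb <- tempfile(fileext = ".ply")
  write_mesh(m, plyb, "ply_binary")
  expect_gt(file.size(plyb), 0)
})
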