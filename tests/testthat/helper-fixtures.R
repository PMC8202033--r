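## shared fixtures, built once per test run

fixture_crystal <- local({
  cache <- list()
  function(kind, ...) {
    key <- kind
    if (is.null(cache[[key]])) {
      cache[[key]] <<- read_cif(make_fixture(kind, ...))
    }
    cache[[key]]
  }
})

fixture_h2_wfn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_molden(make_fixture("molden_h2"))
    cache
  }
})

## H2 wavefunction rigidly shifted by `shift` (Angstrom)
shifted_h2 <- function(shift) {
  hirshfeldr:::transform_wavefunction(fixture_h2_wfn(), diag(3), shift)
}

## radial distance field (isosurfaces are spheres); shared across files
sphere_field <- function(p) sqrt(rowSums(p^2))

## numerical 3D quadrature of a function over a centered cube, for
## integral oracles on tiny systems (midpoint rule)
cube_quadrature <- function(f, half_width, n = 60) {
  g <- seq(-half_width, half_width, length.out = n + 1)
  mid <- (g[-1] + g[-length(g)]) / 2
  h <- mid[2] - mid[1]
  pts <- as.matrix(expand.grid(x = mid, y = mid, z = mid))
  sum(f(pts)) * h^3
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_true(abs(actual - expected) <= tol,
              label = paste0(label %||% "value", ": ", actual,
                             " vs ", expected, " (tol ", tol, ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
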