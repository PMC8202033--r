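## Spherical atomic electron densities for the stockholder partition.
##
## Default source: radial densities from spherically averaged
## (fractional-occupation, restricted) Hartree-Fock atoms computed with
## the package's own Gaussian-integral engine in a large even-tempered
## basis (see atomic_scf() and the regeneration script in
## inst/extdata/atomic-densities/README), shipped as plain-text log-grid
## tabulations keyed by element.  Fallback / reference source: analytic
## single-zeta Slater-type-orbital shell densities (Clementi-Raimondi
## exponents for H-Ar, Slater's rules for K-Kr), which integrate to Z
## exactly and define the documented "sum of exponential terms"
## representation
##
##   rho_at(r) = sum_k  occ_k * N_k^2 * r^(2 n_k - 2) * exp(-2 zeta_k r) / (4 pi)
##
## Users can swap in their own tabulations via read_density_grid().

## Clementi-Raimondi single-zeta exponents, H-Ar.  Rows: shell label, zeta.
CR_EXPONENTS <- list(
  H  = list(c("1s", 1.0000)),
  He = list(c("1s", 1.6875)),
  Li = list(c("1s", 2.6906), c("2s", 0.6396)),
  Be = list(c("1s", 3.6848), c("2s", 0.9560)),
  B  = list(c("1s", 4.6795), c("2s", 1.2881), c("2p", 1.2107)),
  C  = list(c("1s", 5.6727), c("2s", 1.6083), c("2p", 1.5679)),
  N  = list(c("1s", 6.6651), c("2s", 1.9237), c("2p", 1.9170)),
  O  = list(c("1s", 7.6579), c("2s", 2.2458), c("2p", 2.2266)),
  F  = list(c("1s", 8.6501), c("2s", 2.5638), c("2p", 2.5500)),
  Ne = list(c("1s", 9.6421), c("2s", 2.8792), c("2p", 2.8792)),
  Na = list(c("1s", 10.6259), c("2s", 3.2857), c("2p", 3.4409), c("3s", 0.8358)),
  Mg = list(c("1s", 11.6089), c("2s", 3.6960), c("2p", 3.9129), c("3s", 1.1025)),
  Al = list(c("1s", 12.5910), c("2s", 4.1068), c("2p", 4.4817), c("3s", 1.3724), c("3p", 1.3552)),
  Si = list(c("1s", 13.5745), c("2s", 4.5100), c("2p", 4.9725), c("3s", 1.6344), c("3p", 1.4284)),
  P  = list(c("1s", 14.5578), c("2s", 4.9125), c("2p", 5.4806), c("3s", 1.8806), c("3p", 1.6288)),
  S  = list(c("1s", 15.5409), c("2s", 5.3144), c("2p", 5.9885), c("3s", 2.1223), c("3p", 1.8273)),
  Cl = list(c("1s", 16.5239), c("2s", 5.7152), c("2p", 6.4966), c("3s", 2.3561), c("3p", 2.0387)),
  Ar = list(c("1s", 17.5075), c("2s", 6.1152), c("2p", 7.0041), c("3s", 2.5856), c("3p", 2.2547))
)

## ground-state shell occupations for H-Ar, keyed like the exponent table
SHELL_OCCUPATIONS <- list(
  H = c("1s" = 1), He = c("1s" = 2),
  Li = c("1s" = 2, "2s" = 1), Be = c("1s" = 2, "2s" = 2),
  B = c("1s" = 2, "2s" = 2, "2p" = 1), C = c("1s" = 2, "2s" = 2, "2p" = 2),
  N = c("1s" = 2, "2s" = 2, "2p" = 3), O = c("1s" = 2, "2s" = 2, "2p" = 4),
  F = c("1s" = 2, "2s" = 2, "2p" = 5), Ne = c("1s" = 2, "2s" = 2, "2p" = 6),
  Na = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 1),
  Mg = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2),
  Al = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 1),
  Si = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 2),
  P  = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 3),
  S  = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 4),
  Cl = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 5),
  Ar = c("1s" = 2, "2s" = 2, "2p" = 6, "3s" = 2, "3p" = 6)
)

## valence configuration beyond [Ar] for K-Kr: c(n3d, n4sp)
POST_AR_CONFIG <- list(
  K = c(0, 1), Ca = c(0, 2), Sc = c(1, 2), Ti = c(2, 2), V = c(3, 2),
  Cr = c(5, 1), Mn = c(5, 2), Fe = c(6, 2), Co = c(7, 2), Ni = c(8, 2),
  Cu = c(10, 1), Zn = c(10, 2), Ga = c(10, 3), Ge = c(10, 4),
  As = c(10, 5), Se = c(10, 6), Br = c(10, 7), Kr = c(10, 8)
)

## Slater's-rules shells for K-Kr: groups (1s)(2sp)(3sp)(3d)(4sp),
## effective principal number 3.7 for n = 4
slater_shells <- function(Z, symbol) {
  cfg <- POST_AR_CONFIG[[symbol]]
  nd <- cfg[1]; n4 <- cfg[2]
  shells <- list(
    list(n = 1,   occ = 2,  S = 0.30),
    list(n = 2,   occ = 8,  S = 0.35 * 7 + 0.85 * 2),
    list(n = 3,   occ = 8,  S = 0.35 * 7 + 0.85 * 8 + 1.00 * 2)
  )
  if (nd > 0) shells <- c(shells, list(list(n = 3, occ = nd, S = 0.35 * (nd - 1) + 1.00 * 18)))
  if (n4 > 0) shells <- c(shells, list(list(n = 3.7, occ = n4,
                                            S = 0.35 * (n4 - 1) + 0.85 * (8 + nd) + 1.00 * 10)))
  do.call(rbind, lapply(shells, function(s) {
    data.frame(n = s$n, zeta = (Z - s$S) / s$n, occ = s$occ)
  }))
}

## per-element shell table: data.frame(n, zeta, occ) + provenance attribute
atomic_shells <- function(element) {
  z <- atomic_number(element)
  if (!is.null(CR_EXPONENTS[[element]])) {
    sh <- CR_EXPONENTS[[element]]
    occ <- SHELL_OCCUPATIONS[[element]]
    out <- do.call(rbind, lapply(sh, function(row) {
      lbl <- row[1]
      data.frame(n = as.numeric(substring(lbl, 1, 1)),
                 zeta = as.numeric(row[2]),
                 occ = unname(occ[lbl]))
    }))
    attr(out, "provenance") <- "clementi-raimondi-1963-single-zeta"
  } else {
    out <- slater_shells(z, element)
    attr(out, "provenance") <- "slater-rules-1930"
  }
  stopifnot(abs(sum(out$occ) - z) < 1e-12)
  out
}

.density_cache <- new.env(parent = emptyenv())

sto_density_terms <- function(element) {
  key <- paste0("sto_", element)
  if (!is.null(.density_cache[[key]])) return(.density_cache[[key]])
  sh <- atomic_shells(element)
  ## N^2 = (2 zeta)^(2n+1) / Gamma(2n+1)
  n2 <- (2 * sh$zeta)^(2 * sh$n + 1) / gamma(2 * sh$n + 1)
  terms <- list(kind = "sto",
                coef = sh$occ * n2 / (4 * pi),
                pow = 2 * sh$n - 2,
                expo = 2 * sh$zeta,
                provenance = attr(sh, "provenance"))
  terms$rcut <- density_cutoff_radius(terms)
  .density_cache[[key]] <- terms
  terms
}

packaged_density_terms <- function(element) {
  key <- paste0("packaged_", element)
  if (!is.null(.density_cache[[key]])) {
    t <- .density_cache[[key]]
    return(if (identical(t, "absent")) NULL else t)
  }
  f <- system.file("extdata", "atomic-densities", paste0(element, ".tsv"),
                   package = "hirshfeldr")
  if (!nzchar(f)) {
    .density_cache[[key]] <- "absent"
    return(NULL)
  }
  terms <- load_unilog_grid(f)
  .density_cache[[key]] <- terms
  terms
}

## active density representation for an element, by precedence:
## user-registered grid > packaged HF tabulation > analytic STO shells
density_terms <- function(element) {
  ov <- .density_cache[[paste0("override_", element)]]
  if (!is.null(ov)) return(ov)
  packaged_density_terms(element) %||% sto_density_terms(element)
}

## resample a (r, rho) table onto a uniform log(r) grid for fast
## interpolation (C++ kernel) and register cutoff/provenance
make_unilog_terms <- function(r, rho, provenance, n = 1600) {
  ok <- rho > 0 & r > 0
  r <- r[ok]; rho <- rho[ok]
  lf <- stats::splinefun(log(r), log(rho), method = "natural")
  lr <- seq(log(min(r)), log(max(r)), length.out = n)
  terms <- list(kind = "unilog", logr0 = lr[1], dlog = lr[2] - lr[1],
                logrho = lf(lr), provenance = provenance)
  terms$rcut <- density_cutoff_radius(terms)
  terms
}

load_unilog_grid <- function(path) {
  hdr <- readLines(path, n = 3)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  make_unilog_terms(d$r_bohr, d$rho_e_bohr3,
                    sub("^# provenance\t", "", hdr[3]))
}

density_cutoff_radius <- function(terms, threshold = 1e-10) {
  f <- function(r) eval_density_terms(terms, r) - threshold
  upper <- 80
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(0.5, upper), tol = 1e-6)$root
}

eval_density_terms <- function(terms, r) {
  if (terms$kind == "unilog") {
    n <- length(terms$logrho)
    t <- (log(pmax(r, 1e-300)) - terms$logr0) / terms$dlog
    t[t < 0] <- 0
    ## linear tail extrapolation beyond the grid
    slope <- terms$logrho[n] - terms$logrho[n - 1]
    hi <- t >= n - 1
    out <- numeric(length(r))
    out[hi] <- exp(terms$logrho[n] + slope * (t[hi] - (n - 1)))
    k <- pmin(floor(t[!hi]), n - 2)
    f <- t[!hi] - k
    out[!hi] <- exp(terms$logrho[k + 1] * (1 - f) + terms$logrho[k + 2] * f)
    return(out)
  }
  out <- numeric(length(r))
  for (k in seq_along(terms$coef)) {
    out <- out + terms$coef[k] * r^terms$pow[k] * exp(-terms$expo[k] * r)
  }
  out
}

#' Spherically averaged atomic electron density
#'
#' @param element Element symbol (H through Kr).
#' @param r Radial distance(s) in bohr.
#' @param source `"active"` (default: user override, then the shipped
#'   Hartree-Fock tabulation, then analytic STO), `"sto"` for the
#'   analytic single-zeta representation.
#' @return Density in electrons/bohr^3 at each `r`.
#' @export
atomic_density <- function(element, r, source = c("active", "sto")) {
  stopifnot(length(element) == 1, all(r >= 0))
  check_elements(element)
  source <- match.arg(source)
  terms <- if (source == "sto") sto_density_terms(element) else density_terms(element)
  eval_density_terms(terms, r)
}

#' Effective cutoff radius of an atomic density
#'
#' Radius beyond which the atomic density falls below `threshold`
#' (electrons/bohr^3); atoms farther than this from a query point are
#' ignored by the promolecule/procrystal sums.
#'
#' @param element Element symbol.
#' @param threshold Density floor (default 1e-10 e/bohr^3).
#' @return Radius in bohr.
#' @export
atomic_density_cutoff <- function(element, threshold = 1e-10) {
  check_elements(element)
  if (threshold == 1e-10) return(density_terms(element)$rcut)
  density_cutoff_radius(density_terms(element), threshold)
}

#' Provenance of the active atomic density table
#' @param element Element symbol.
#' @return Character provenance tag.
#' @export
atomic_density_provenance <- function(element) {
  check_elements(element)
  density_terms(element)$provenance
}

#' Export / import atomic density tables as radial grids
#'
#' The columnar plain-text format (`element`, `Z`, `provenance` header
#' lines, then `r_bohr` / `rho_e_bohr3` rows) lets the shipped densities
#' be inspected, regenerated or replaced by other tabulations.
#' `read_density_grid` registers the file as the active density for its
#' element (until [clear_density_grid()]).
#'
#' @param element Element symbol.
#' @param path File path.
#' @param r Radial grid in bohr used when writing (default: 400-point
#'   log-spaced grid, 1e-3 to 25 bohr).
#' @return `path` (write) or the registered element (read), invisibly.
#' @export
write_density_grid <- function(element, path,
                               r = exp(seq(log(1e-3), log(25), length.out = 400))) {
  rho <- atomic_density(element, r)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# element\t", element),
               paste0("# Z\t", atomic_number(element)),
               paste0("# provenance\t", density_terms(element)$provenance),
               "r_bohr\trho_e_bohr3"), con)
  writeLines(sprintf("%.6e\t%.6e", r, rho), con)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  hdr <- readLines(path, n = 1)
  element <- sub("^# element\t", "", hdr[1])
  check_elements(element)
  .density_cache[[paste0("override_", element)]] <- load_unilog_grid(path)
  invisible(element)
}

#' Remove a registered density override, restoring the default source
#' @param element Element symbol.
#' @export
clear_density_grid <- function(element) {
  rm(list = intersect(paste0("override_", element), ls(.density_cache)),
     envir = .density_cache)
  invisible(element)
}

## --- promolecule / procrystal evaluation ---------------------------------

## sites: list(element = chr, xyz = n x 3 Angstrom) or a molecule
as_sites <- function(sites) {
  if (inherits(sites, "molecule")) return(list(element = sites$element, xyz = sites$xyz))
  if (is.data.frame(sites)) return(list(element = sites$element,
                                        xyz = as.matrix(sites[, c("x", "y", "z")])))
  stopifnot(is.list(sites), !is.null(sites$element), !is.null(sites$xyz))
  sites$xyz <- rbind3(sites$xyz)
  sites
}

#' Promolecule electron density
#'
#' Superposition of spherical atomic densities at the given sites.
#'
#' @param sites A `molecule`, a data frame with `element`/`x`/`y`/`z`, or a
#'   list with `element` and `xyz` (Cartesian Angstrom).
#' @param points m x 3 matrix (or length-3 vector) of Cartesian Angstrom.
#' @return Numeric vector of densities in electrons/bohr^3.
#' @export
promolecule_density <- function(sites, points) {
  s <- as_sites(sites)
  stopifnot(length(s$element) >= 1)
  pts <- rbind3(points) * ANGSTROM_TO_BOHR
  pos <- s$xyz * ANGSTROM_TO_BOHR
  elems <- unique(s$element)
  tl <- lapply(elems, density_terms)
  kinds <- vapply(tl, function(t) if (t$kind == "unilog") 1L else 0L, 0L)
  nterms <- vapply(tl, function(t) if (t$kind == "sto") length(t$coef) else 0L, 0L)
  ngrid <- vapply(tl, function(t) if (t$kind == "unilog") length(t$logrho) else 0L, 0L)
  promolecule_density_cpp(
    pts, pos, match(s$element, elems) - 1L,
    kinds,
    c(0L, cumsum(nterms)),
    unlist(lapply(tl, function(t) if (t$kind == "sto") t$coef else numeric(0))),
    unlist(lapply(tl, function(t) if (t$kind == "sto") t$pow else numeric(0))),
    unlist(lapply(tl, function(t) if (t$kind == "sto") t$expo else numeric(0))),
    c(0L, cumsum(ngrid)),
    unlist(lapply(tl, function(t) if (t$kind == "unilog") t$logrho else numeric(0))),
    vapply(tl, function(t) if (t$kind == "unilog") t$logr0 else 0, 0),
    vapply(tl, function(t) if (t$kind == "unilog") t$dlog else 1, 0),
    vapply(tl, `[[`, 0, "rcut"))
}

## all crystal atoms (symmetry + lattice images) whose density can reach
## any point of the Cartesian box [lo, hi]
crystal_atoms_in_box <- function(cr, lo, hi) {
  ua <- expand_unit_cell(cr)
  margin <- max(vapply(unique(ua$element), function(e) density_terms(e)$rcut, 0)) *
    BOHR_TO_ANGSTROM
  corners <- as.matrix(expand.grid(c(lo[1] - margin, hi[1] + margin),
                                   c(lo[2] - margin, hi[2] + margin),
                                   c(lo[3] - margin, hi[3] + margin)))
  fc <- cart_to_frac(cr$cell, corners)
  tmin <- floor(apply(fc, 2, min)) - 1L
  tmax <- ceiling(apply(fc, 2, max))
  fr <- as.matrix(ua[, c("fx", "fy", "fz")])
  out_e <- character(0); out_xyz <- list()
  for (t1 in tmin[1]:tmax[1]) for (t2 in tmin[2]:tmax[2]) for (t3 in tmin[3]:tmax[3]) {
    cart <- frac_to_cart(cr$cell, sweep(fr, 2, c(t1, t2, t3), `+`))
    keep <- cart[, 1] >= lo[1] - margin & cart[, 1] <= hi[1] + margin &
      cart[, 2] >= lo[2] - margin & cart[, 2] <= hi[2] + margin &
      cart[, 3] >= lo[3] - margin & cart[, 3] <= hi[3] + margin
    if (any(keep)) {
      out_e <- c(out_e, ua$element[keep])
      out_xyz[[length(out_xyz) + 1L]] <- cart[keep, , drop = FALSE]
    }
  }
  list(element = out_e, xyz = if (length(out_xyz)) do.call(rbind, out_xyz) else matrix(0, 0, 3))
}

#' Procrystal electron density
#'
#' Promolecule density extended over all atoms of the crystal (every
#' symmetry and lattice image whose density reaches the query points).
#'
#' @param cr A `crystal`.
#' @param points m x 3 Cartesian Angstrom.
#' @return Numeric vector in electrons/bohr^3.
#' @export
procrystal_density <- function(cr, points) {
  pts <- rbind3(points)
  env <- crystal_atoms_in_box(cr, apply(pts, 2, min), apply(pts, 2, max))
  promolecule_density(env, pts)
}

## all molecule images with at least one atom within the density cutoff of
## the point box; used for the stockholder partition
contributing_molecules <- function(cr, points) {
  pts <- rbind3(points)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  base <- complete_molecules(cr)
  ua <- expand_unit_cell(cr)
  margin <- max(vapply(unique(ua$element), function(e) density_terms(e)$rcut, 0)) *
    BOHR_TO_ANGSTROM
  ext <- max(vapply(base, function(m)
    max(sqrt(rowSums(sweep(m$xyz, 2, m$centroid)^2))), 0))
  corners <- as.matrix(expand.grid(c(lo[1] - margin - ext, hi[1] + margin + ext),
                                   c(lo[2] - margin - ext, hi[2] + margin + ext),
                                   c(lo[3] - margin - ext, hi[3] + margin + ext)))
  fc <- cart_to_frac(cr$cell, corners)
  tmin <- floor(apply(fc, 2, min)) - 1L
  tmax <- ceiling(apply(fc, 2, max)) + 1L
  out <- list()
  for (t1 in tmin[1]:tmax[1]) for (t2 in tmin[2]:tmax[2]) for (t3 in tmin[3]:tmax[3]) {
    for (b in seq_along(base)) {
      cand <- translate_molecule(base[[b]], cr$cell, c(t1, t2, t3))
      ## distance from each atom to the bounding box of the points
      dx <- pmax(0, lo[1] - cand$xyz[, 1], cand$xyz[, 1] - hi[1])
      dy <- pmax(0, lo[2] - cand$xyz[, 2], cand$xyz[, 2] - hi[2])
      dz <- pmax(0, lo[3] - cand$xyz[, 3], cand$xyz[, 3] - hi[3])
      if (min(sqrt(dx^2 + dy^2 + dz^2)) <= margin) {
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Stockholder weights of every contributing molecule
#'
#' Weights of all molecule images whose density reaches the query points,
#' all against the shared procrystal formed by exactly those molecules:
#' rows sum to 1 wherever the procrystal is above the floor.
#'
#' @param cr A `crystal`.
#' @param points m x 3 Cartesian Angstrom.
#' @return m x n_molecules matrix of weights; the molecule list is
#'   attached as attribute `molecules`.
#' @export
stockholder_weight_matrix <- function(cr, points) {
  pts <- rbind3(points)
  mols <- contributing_molecules(cr, pts)
  env <- list(element = unlist(lapply(mols, `[[`, "element")),
              xyz = do.call(rbind, lapply(mols, `[[`, "xyz")))
  den <- promolecule_density(env, pts)
  W <- vapply(mols, function(m) {
    num <- promolecule_density(m, pts)
    ifelse(den > 1e-15, num / den, 0)
  }, numeric(nrow(pts)))
  W <- matrix(W, nrow = nrow(pts))
  attr(W, "molecules") <- mols
  W
}

#' Stockholder weight function
#'
#' `w(x)` is the promolecule density of `molecule` divided by the
#' procrystal density at `x`; its 0.5 isosurface is the Hirshfeld surface.
#'
#' @param cr A `crystal`.
#' @param molecule A `molecule` belonging to the crystal.
#' @param points m x 3 Cartesian Angstrom.
#' @param env Optional precomputed environment sites (list with `element`,
#'   `xyz`) to reuse across calls on the same region.
#' @param floor Procrystal density floor; below it (deep void) the weight
#'   is returned as 0 with a warning.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
stockholder_weight <- function(cr, molecule, points, env = NULL, floor = 1e-15) {
  pts <- rbind3(points)
  if (is.null(env)) {
    env <- crystal_atoms_in_box(cr, apply(pts, 2, min), apply(pts, 2, max))
  }
  num <- promolecule_density(molecule, pts)
  den <- promolecule_density(env, pts)
  w <- numeric(length(num))
  ok <- den > floor
  if (!all(ok)) warning("procrystal density below floor at ", sum(!ok),
                        " point(s); weight set to 0 (deep void)")
  w[ok] <- num[ok] / den[ok]
  pmin(pmax(w, 0), 1)
}
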