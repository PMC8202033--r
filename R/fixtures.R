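## Synthetic fixtures: small, fully synthetic crystal structures and a
## minimal Molden wavefunction, so every part of the package can be
## exercised offline.  The urea-like structure embeds published cell and
## neutron-quality coordinates as an offline stand-in (fixture data, not a
## database deposit); the acetic-acid-like structure uses an idealized
## constructed geometry in the published cell setting and is synthetic.

## STO-3G hydrogen primitives (zeta = 1.24 scaling)
H_STO3G_EXPO <- c(3.42525091, 0.62391373, 0.16885540)
H_STO3G_COEF <- c(0.15432897, 0.53532814, 0.44463454)

#' Generate a synthetic fixture file
#'
#' Kinds:
#' \describe{
#'   \item{cubic_atom}{P1 cubic cell, one atom at the origin.}
#'   \item{diatomic}{P1 cell holding one N2-like molecule split across the
#'     a-axis cell boundary (tests periodic molecule completion).}
#'   \item{hbond_dimer_crystal}{P1 cell with two HF molecules forming an
#'     F-H...F hydrogen bond.}
#'   \item{urea_like}{tetragonal P-4 21 m urea structure (embedded
#'     published cell/coordinates; offline stand-in).}
#'   \item{acetic_like}{Pna2_1 cell with an idealized acetic-acid monomer
#'     (synthetic geometry; structural tests only).}
#'   \item{molden_h2}{minimal H2/STO-3G Molden file with coefficients
#'     from the analytic minimal-basis MO.}
#' }
#'
#' @param kind Fixture kind.
#' @param path Output file path (default: tempfile with a fitting
#'   extension).
#' @param a Cell length for `cubic_atom` (Angstrom).
#' @param element Element for `cubic_atom`.
#' @param bond Bond length for `molden_h2` (bohr).
#' @return The path, invisibly.
#' @export
make_fixture <- function(kind = c("cubic_atom", "diatomic", "hbond_dimer_crystal",
                                  "urea_like", "acetic_like", "molden_h2"),
                         path = NULL, a = 4, element = "Ne", bond = 1.4) {
  kind <- match.arg(kind)
  if (is.null(path)) {
    path <- tempfile(kind, fileext = if (kind == "molden_h2") ".molden" else ".cif")
  }
  switch(kind,
    cubic_atom = {
      write_cif(unit_cell(a, a, a), list(parse_symop("x,y,z")),
                data.frame(element = element, label = paste0(element, "1"),
                           fx = 0, fy = 0, fz = 0), path, name = "cubic_atom")
    },
    diatomic = {
      ## N2-like molecule crossing the a boundary (bond 1.10 A); the cell
      ## is chosen well packed so the Hirshfeld partition closes at
      ## vdW-like contact distances
      write_cif(unit_cell(5.5, 4, 4), list(parse_symop("x,y,z")),
                data.frame(element = c("N", "N"), label = c("N1", "N2"),
                           fx = c(0.98, 0.18), fy = c(0, 0), fz = c(0, 0)),
                path, name = "diatomic")
    },
    hbond_dimer_crystal = {
      ## two HF molecules, F-H...F = 1.6 A along a
      write_cif(unit_cell(10, 6, 6), list(parse_symop("x,y,z")),
                data.frame(element = c("F", "H", "F", "H"),
                           label = c("F1", "H1", "F2", "H2"),
                           fx = c(0.200, 0.292, 0.452, 0.544),
                           fy = 0.5, fz = 0.5),
                path, name = "hbond_dimer")
    },
    urea_like = {
      ops <- lapply(SPACEGROUP_TABLE[["P -4 21 m"]], parse_symop)
      atoms <- data.frame(
        element = c("C", "O", "N", "H", "H"),
        label = c("C1", "O1", "N1", "H1", "H2"),
        fx = c(0, 0, 0.1459, 0.2575, 0.1441),
        fy = c(0.5, 0.5, 0.6459, 0.7575, 0.6441),
        fz = c(0.3260, 0.5953, 0.1766, 0.2827, -0.0380))
      write_cif(unit_cell(5.578, 5.578, 4.686), ops, atoms, path, name = "urea_like")
    },
    acetic_like = {
      ops <- lapply(SPACEGROUP_TABLE[["P n a 21"]], parse_symop)
      cell <- unit_cell(13.31, 5.80, 5.77)
      mol <- rbind(  # idealized planar acetic acid, Angstrom
        C1 = c(0.000, 0.000, 0.000),
        O1 = c(0.630, 1.046, 0.000),
        O2 = c(0.660, -1.190, 0.000),
        H1 = c(1.630, -1.160, 0.000),
        C2 = c(-1.503, 0.015, 0.000),
        H2 = c(-1.880, 1.020, 0.000),
        H3 = c(-1.850, -0.490, 0.880),
        H4 = c(-1.850, -0.490, -0.880))
      ctr <- frac_to_cart(cell, c(0.11, 0.18, 0.05))
      fr <- cart_to_frac(cell, sweep(mol, 2, as.numeric(ctr), `+`))
      atoms <- data.frame(element = c("C", "O", "O", "H", "C", "H", "H", "H"),
                          label = rownames(mol),
                          fx = fr[, 1], fy = fr[, 2], fz = fr[, 3])
      write_cif(cell, ops, atoms, path, name = "acetic_like_synthetic")
    },
    molden_h2 = {
      write_molden_h2(path, bond)
    })
  invisible(path)
}

## minimal H2/STO-3G Molden file; the bonding MO coefficient is the
## analytic minimal-basis value 1/sqrt(2 (1 + S12)) with S12 from the
## integral engine
write_molden_h2 <- function(path, bond = 1.4) {
  sh <- list(l = c(0L, 0L),
             center = rbind(c(0, 0, 0), c(0, 0, bond)),
             prim_start = c(0L, 3L, 6L),
             expo = rep(H_STO3G_EXPO, 2), coef = rep(H_STO3G_COEF, 2))
  S <- one_electron_cpp(sh)$S
  s12 <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  cg <- 1 / sqrt(2 * (1 + s12))
  cu <- 1 / sqrt(2 * (1 - s12))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[Molden Format]")
  w("[Title]")
  w(" synthetic H2/STO-3G fixture")
  w("[Atoms] AU")
  w(" H 1 1 0.000000 0.000000 0.000000")
  w(" H 2 1 0.000000 0.000000 %.6f", bond)
  w("[GTO]")
  for (at in 1:2) {
    w(" %d 0", at)
    w("  s 3 1.00")
    for (k in 1:3) w("   %.8f %.8f", H_STO3G_EXPO[k], H_STO3G_COEF[k])
    w("")
  }
  w("[MO]")
  w(" Sym= A1")
  w(" Ene= -0.578")
  w(" Spin= Alpha")
  w(" Occup= 2.0")
  w("   1 %.10f", cg)
  w("   2 %.10f", cg)
  w(" Sym= A2")
  w(" Ene= 0.670")
  w(" Spin= Alpha")
  w(" Occup= 0.0")
  w("   1 %.10f", cu)
  w("   2 %.10f", -cu)
  invisible(path)
}
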