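## Molden ingestion and quantum surface properties.
##
## The engine works over Cartesian Gaussian shells; Molden MOs (spherical
## or Cartesian d) are mapped onto that basis by a per-shell
## transformation, and every contracted function is renormalized to unit
## self-overlap on load, which absorbs the normalization quirks of the
## various Molden writers (checked downstream by Tr(PS) = N).

#' Read a monomer wavefunction from a Molden file
#'
#' Supports `[Atoms]` (AU or Angs), `[GTO]` (s, p, d and sp shells) and
#' `[MO]` sections, with `[5D]`/`[6D]` spherical/Cartesian d conventions.
#' Open-shell files (alpha/beta) are spin-summed into the total density.
#' ECPs and shells beyond d are rejected.
#'
#' @param path Path to a Molden file.
#' @param level Optional theory-level descriptor (e.g.
#'   `"B3LYP/6-31G(d,p) monomer wavefunctions"`); Molden files do not
#'   record it, so provenance is the user's responsibility.  Recorded on
#'   the object and checked (warning only) against the energy model.
#' @return A `wavefunction`: atoms (`element`, `xyz` Angstrom, `Z`),
#'   engine `shells`, MO matrix in the raw Cartesian basis (`C`),
#'   `occupations`, `energies`, overlap `S`, spin-summed density `D` and
#'   electron count `nelec`.
#' @export
read_molden <- function(path, level = NULL) {
  if (!file.exists(path)) stop("Molden file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  up <- toupper(trimws(lines))
  if (any(grepl("^\\[(ECP|PSEUDO|CORE)\\]", up))) stop("ECPs are not supported")
  sec <- function(name) {
    i <- grep(paste0("^\\[", name, "\\]"), up, ignore.case = TRUE)
    if (!length(i)) stop("Molden file lacks [", name, "] section")
    j <- grep("^\\[", up)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1 else length(lines)
    lines[(i[1] + 1):end]
  }
  hdr_i <- grep("^\\[ATOMS\\]", up)
  if (!length(hdr_i)) stop("Molden file lacks [Atoms] section")
  unit <- if (grepl("AU", up[hdr_i[1]])) "au" else "angs"
  spherical_d <- any(grepl("^\\[5D", up))

  ## atoms
  at <- strsplit(trimws(sec("ATOMS")), "[[:space:]]+")
  at <- at[lengths(at) >= 6]
  element <- normalize_element(vapply(at, `[`, "", 1))
  Z <- as.numeric(vapply(at, `[`, "", 3))
  xyz <- do.call(rbind, lapply(at, function(v) as.numeric(v[4:6])))
  if (unit == "au") xyz <- xyz * BOHR_TO_ANGSTROM

  ## GTO basis
  gto <- sec("GTO")
  shells <- parse_molden_gto(gto, xyz)
  if (any(shells$l > 2)) stop("shells with l > 2 (f and higher) are not supported")

  ## MO section
  mos <- parse_molden_mos(sec("MO"))
  wfn <- wavefunction_from_parts(element, xyz, Z, shells, mos, spherical_d)
  wfn$level <- level
  wfn
}

parse_molden_gto <- function(gto, xyz) {
  l_map <- c(s = 0L, p = 1L, d = 2L, f = 3L, g = 4L)
  l <- integer(0); center_idx <- integer(0)
  pstart <- 0L; expo <- numeric(0); coef <- numeric(0)
  starts <- integer(0)
  i <- 1
  cur_atom <- NA_integer_
  to_num <- function(s) as.numeric(gsub("[dD]", "e", s))
  while (i <= length(gto)) {
    ln <- trimws(gto[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (grepl("^[0-9]+$", tok[1]) && length(tok) <= 2) {
      cur_atom <- as.integer(tok[1]); i <- i + 1; next
    }
    type <- tolower(tok[1])
    if (!type %in% names(c(l_map, sp = 99))) stop("unrecognized GTO line: ", ln)
    np <- as.integer(tok[2])
    prim <- do.call(rbind, lapply(gto[(i + 1):(i + np)], function(s) {
      to_num(strsplit(trimws(s), "[[:space:]]+")[[1]])
    }))
    if (type == "sp") {
      for (part in 1:2) {
        l <- c(l, if (part == 1) 0L else 1L)
        center_idx <- c(center_idx, cur_atom)
        starts <- c(starts, length(expo))
        expo <- c(expo, prim[, 1]); coef <- c(coef, prim[, part + 1])
      }
    } else {
      l <- c(l, l_map[[type]])
      center_idx <- c(center_idx, cur_atom)
      starts <- c(starts, length(expo))
      expo <- c(expo, prim[, 1]); coef <- c(coef, prim[, 2])
    }
    i <- i + np + 1
  }
  list(l = l, center = xyz[center_idx, , drop = FALSE] * ANGSTROM_TO_BOHR,
       center_idx = center_idx,
       prim_start = as.integer(c(starts, length(expo))),
       expo = expo, coef = coef)
}

parse_molden_mos <- function(mo_lines) {
  occ <- numeric(0); ene <- numeric(0); spin <- character(0)
  cmat <- list(); cur <- numeric(0)
  flush <- function() {
    if (length(cur)) cmat[[length(cmat) + 1]] <<- cur
    cur <<- numeric(0)
  }
  for (ln in trimws(mo_lines)) {
    if (!nzchar(ln)) next
    if (grepl("^(Sym|Ene|Spin|Occup)", ln, ignore.case = TRUE)) {
      kv <- strsplit(ln, "=")[[1]]
      key <- tolower(trimws(kv[1]))
      if (key == "ene") { flush(); ene <- c(ene, as.numeric(kv[2])) }
      if (key == "occup") occ <- c(occ, as.numeric(kv[2]))
      if (key == "spin") spin <- c(spin, trimws(kv[2]))
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) >= 2) cur[as.integer(tok[1])] <- as.numeric(gsub("[dD]", "e", tok[2]))
  }
  flush()
  if (!length(cmat)) stop("Molden [MO] section holds no orbitals")
  nb <- max(lengths(cmat))
  C <- vapply(cmat, function(v) { length(v) <- nb; v[is.na(v)] <- 0; v }, numeric(nb))
  if (length(occ) != ncol(C)) stop("orbital count and occupation count disagree")
  list(C = C, occ = occ, ene = if (length(ene) == ncol(C)) ene else rep(NA_real_, ncol(C)),
       spin = if (length(spin) == ncol(C)) spin else rep("Alpha", ncol(C)))
}

## real solid harmonic d functions over raw monomial coefficients,
## engine cart order (xx, xy, xz, yy, yz, zz); Molden sph order
## (z2, xz, yz, x2-y2, xy)
SPH_D_POLY <- rbind(
  z2   = c(-0.5, 0, 0, -0.5, 0, 1),
  xz   = c(0, 0, 1, 0, 0, 0),
  yz   = c(0, 0, 0, 0, 1, 0),
  x2y2 = c(1, 0, 0, -1, 0, 0),
  xy   = c(0, 1, 0, 0, 0, 0))
## Molden cartesian d order -> engine order
MOLDEN_CART_D <- c(1, 4, 6, 2, 3, 5)  # xx,yy,zz,xy,xz,yz -> engine slots

wavefunction_from_parts <- function(element, xyz, Z, shells, mos, spherical_d) {
  oe <- one_electron_cpp(shells)
  S <- oe$S
  ncart <- nrow(S)
  ## per-shell blocks mapping file AOs onto raw Cartesian AOs
  blocks <- list(); cart0 <- 0
  dfd <- sqrt(c(3, 1, 1, 3, 1, 3))  # sqrt(dfact) per engine d component
  for (s in seq_along(shells$l)) {
    l <- shells$l[s]
    nc <- (l + 1) * (l + 2) / 2
    if (l <= 1) {
      B <- diag(nc)
    } else if (spherical_d) {
      B <- sweep(SPH_D_POLY, 2, dfd, `*`)
    } else {
      B <- matrix(0, 6, 6); B[cbind(1:6, MOLDEN_CART_D)] <- 1
    }
    cols <- cart0 + seq_len(nc)
    blocks[[s]] <- list(B = B, cols = cols)
    cart0 <- cart0 + nc
  }
  nfile <- sum(vapply(blocks, function(b) nrow(b$B), 0L))
  M <- matrix(0, nfile, ncart)
  r0 <- 0
  for (b in blocks) {
    M[r0 + seq_len(nrow(b$B)), b$cols] <- b$B
    r0 <- r0 + nrow(b$B)
  }
  ## renormalize every file AO to unit self-overlap
  nrm <- sqrt(diag(M %*% S %*% t(M)))
  M <- M / nrm
  if (nrow(mos$C) != nfile) {
    stop("MO coefficient length (", nrow(mos$C), ") does not match basis dimension (",
         nfile, "); mixed or unflagged shell conventions?")
  }
  C <- t(M) %*% mos$C
  D <- C %*% (mos$occ * t(C))
  wfn <- list(element = element, xyz = xyz, Z = Z, shells = shells,
              C = C, occupations = mos$occ, energies = mos$ene,
              spin = mos$spin, S = S, D = D, nelec = sum(mos$occ))
  class(wfn) <- "wavefunction"
  wfn
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf("wavefunction: %d atoms, %d basis functions (cart), %d MOs, %g electrons\n",
              length(x$element), nrow(x$C), ncol(x$C), x$nelec))
  invisible(x)
}

## raw Cartesian basis values at points (bohr in, values in a.u.)
basis_values <- function(shells, pts_bohr) {
  n <- nrow(pts_bohr)
  cols <- list()
  for (s in seq_along(shells$l)) {
    l <- shells$l[s]
    ctr <- shells$center[s, ]
    dx <- pts_bohr[, 1] - ctr[1]; dy <- pts_bohr[, 2] - ctr[2]; dz <- pts_bohr[, 3] - ctr[3]
    r2 <- dx^2 + dy^2 + dz^2
    pr <- (shells$prim_start[s] + 1):shells$prim_start[s + 1]
    comps <- cart_components(l)
    for (k in seq_len(nrow(comps))) {
      i <- comps[k, 1]; j <- comps[k, 2]; m <- comps[k, 3]
      val <- numeric(n)
      for (p in pr) {
        a <- shells$expo[p]
        nrm <- (2 * a / pi)^0.75 * (4 * a)^(0.5 * l) /
          sqrt(dfact2(i) * dfact2(j) * dfact2(m))
        val <- val + shells$coef[p] * nrm * exp(-a * r2)
      }
      cols[[length(cols) + 1]] <- val * dx^i * dy^j * dz^m
    }
  }
  do.call(cbind, cols)
}

cart_components <- function(l) {
  out <- NULL
  for (i in l:0) for (j in (l - i):0) out <- rbind(out, c(i, j, l - i - j))
  out
}
dfact2 <- function(n) if (n < 2) 1 else prod(seq(2 * n - 1, 1, by = -2))

#' Electron density of a wavefunction
#'
#' `rho(x) = sum_i n_i |phi_i(x)|^2` over occupied MOs.
#'
#' @param wfn A `wavefunction`.
#' @param points n x 3 Cartesian Angstrom.
#' @return Densities in e/bohr^3.
#' @export
electron_density <- function(wfn, points) {
  pts <- rbind3(points) * ANGSTROM_TO_BOHR
  B <- basis_values(wfn$shells, pts)
  rowSums((B %*% wfn$D) * B)
}

#' Probability density of one molecular orbital
#'
#' @param wfn A `wavefunction`.
#' @param index 1-based orbital index in energy order, or `"HOMO"`.
#' @param points n x 3 Cartesian Angstrom.
#' @return `|phi|^2` in 1/bohr^3.
#' @export
mo_density <- function(wfn, index, points) {
  if (identical(index, "HOMO")) index <- max(which(wfn$occupations > 0))
  if (!is.numeric(index) || index < 1 || index > ncol(wfn$C)) {
    stop("orbital index out of range 1..", ncol(wfn$C))
  }
  pts <- rbind3(points) * ANGSTROM_TO_BOHR
  (basis_values(wfn$shells, pts) %*% wfn$C[, index])[, 1]^2
}

#' Electrostatic potential of a wavefunction
#'
#' `V(x) = sum_A Z_A/|x-R_A| - int rho(r')/|x-r'| dr'`, the electronic
#' part through density-contracted nuclear-attraction integrals.
#'
#' @param wfn A `wavefunction`.
#' @param points n x 3 Cartesian Angstrom.
#' @return Potential in atomic units (hartree/e).
#' @export
electrostatic_potential <- function(wfn, points) {
  pts <- rbind3(points) * ANGSTROM_TO_BOHR
  nuc <- numeric(nrow(pts))
  R <- wfn$xyz * ANGSTROM_TO_BOHR
  for (a in seq_along(wfn$Z)) {
    r <- sqrt(colSums((t(pts) - R[a, ])^2))
    nuc <- nuc + wfn$Z[a] / pmax(r, 1e-12)
  }
  nuc - esp_density_cpp(wfn$shells, wfn$D, pts)
}

#' Electric field of a wavefunction's charge distribution
#'
#' Central-difference gradient of the electrostatic potential,
#' `F = -grad V`.
#'
#' @param wfn A `wavefunction`.
#' @param points n x 3 Cartesian Angstrom.
#' @param h Step in bohr.
#' @return n x 3 field components in atomic units.
#' @export
electric_field <- function(wfn, points, h = 1e-3) {
  pts <- rbind3(points)
  ha <- h * BOHR_TO_ANGSTROM
  F <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    p1 <- pts; p1[, d] <- p1[, d] + ha
    p2 <- pts; p2[, d] <- p2[, d] - ha
    F[, d] <- -(electrostatic_potential(wfn, p1) -
                  electrostatic_potential(wfn, p2)) / (2 * h)
  }
  F
}

#' Map a quantum property onto a surface
#'
#' @param mesh A `trimesh`.
#' @param wfn A `wavefunction`.
#' @param kind `"rho"` (electron density), `"esp"` (electrostatic
#'   potential), `"mo_density"` (needs `orbital`), or `"rho_def"`
#'   (deformation density, `rho - rho_promol`, needs `promol` sites).
#' @param orbital Orbital index or `"HOMO"` for `kind = "mo_density"`.
#' @param promol Sites for the promolecule reference (defaults to the
#'   wavefunction's own atoms) for `kind = "rho_def"`.
#' @return The mesh with the new channel (named as `kind`).
#' @export
surface_property_channel <- function(mesh, wfn, kind = c("rho", "esp", "mo_density", "rho_def"),
                                     orbital = "HOMO", promol = NULL) {
  kind <- match.arg(kind)
  v <- mesh$vertices
  vals <- switch(kind,
    rho = electron_density(wfn, v),
    esp = electrostatic_potential(wfn, v),
    mo_density = mo_density(wfn, orbital, v),
    rho_def = {
      sites <- if (is.null(promol)) list(element = wfn$element, xyz = wfn$xyz) else as_sites(promol)
      electron_density(wfn, v) - promolecule_density(sites, v)
    })
  mesh_set_channel(mesh, kind, vals)
}

## rigid transformation of a wavefunction: rotate atoms, shell centers and
## MO coefficients (s unchanged, p by R, cartesian d by the symmetric
## square of R); valid for proper and improper rotations
transform_wavefunction <- function(wfn, rot, shift) {
  w <- wfn
  w$xyz <- sweep(wfn$xyz %*% t(rot), 2, shift, `+`)
  w$shells$center <- sweep(wfn$shells$center %*% t(rot), 2,
                           shift * ANGSTROM_TO_BOHR, `+`)
  Td <- cart_d_transform(rot)
  rows <- list(); r0 <- 0
  C <- wfn$C
  for (s in seq_along(wfn$shells$l)) {
    l <- wfn$shells$l[s]
    nc <- (l + 1) * (l + 2) / 2
    idx <- r0 + seq_len(nc)
    blk <- switch(as.character(l), "0" = diag(1), "1" = rot, "2" = Td)
    C[idx, ] <- blk %*% C[idx, , drop = FALSE]
    r0 <- r0 + nc
  }
  w$C <- C
  w$D <- C %*% (w$occupations * t(C))
  ## overlap is invariant under rigid motion; keep S as is
  w
}

## transformation of raw cartesian d monomials under linear map rot:
## component order xx, xy, xz, yy, yz, zz; includes the sqrt(dfact)
## normalization difference between diagonal and cross components
cart_d_transform <- function(rot) {
  comps <- cart_components(2)
  nrm <- sqrt(apply(comps, 1, function(k) prod(vapply(k, dfact2, 1))))
  T <- matrix(0, 6, 6)
  for (b in 1:6) {  # transform monomial b
    kb <- comps[b, ]
    ## expand (sum_a rot[a,1] x_a)^i ... via polynomial multiplication
    poly <- c(1)
    names(poly) <- "000"
    for (d in 1:3) for (rep in seq_len(kb[d])) {
      newpoly <- numeric(0)
      for (nm in names(poly)) for (a in 1:3) {
        key <- as.integer(strsplit(nm, "")[[1]])
        key[a] <- key[a] + 1
        k2 <- paste(key, collapse = "")
        newpoly[k2] <- (if (is.na(newpoly[k2])) 0 else newpoly[k2]) +
          poly[[nm]] * rot[a, d]
      }
      poly <- newpoly
    }
    for (nm in names(poly)) {
      key <- as.integer(strsplit(nm, "")[[1]])
      a <- which(apply(comps, 1, function(k) all(k == key)))
      T[a, b] <- T[a, b] + poly[[nm]]
    }
  }
  ## convert from raw monomial basis to engine-normalized components:
  ## chi_norm = monomial / nrm (up to a common factor)
  diag(1 / nrm) %*% T %*% diag(nrm)
}
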