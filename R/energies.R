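## Four-term pairwise intermolecular interaction energies:
##   E_tot = k_ele E_ele + k_pol E_pol + k_dis E_dis + k_rep E_rep
## with model-specific scale factors calibrated against counterpoise-
## corrected reference interaction energies (constants transcribed from
## the published calibration; see energy_model()).

## versioned scale-factor constants
CE_MODELS_VERSION <- "2017-1"
CE_MODELS <- list(
  "CE-HF" = list(k_ele = 1.019, k_pol = 0.651, k_dis = 0.901, k_rep = 0.811,
                 level = "HF/3-21G monomer wavefunctions"),
  "CE-B3LYP" = list(k_ele = 1.057, k_pol = 0.740, k_dis = 0.871, k_rep = 0.618,
                    level = "B3LYP/6-31G(d,p) monomer wavefunctions")
)

#' Interaction-energy model constants
#'
#' @param name `"CE-HF"` or `"CE-B3LYP"`.
#' @return List with the four scale factors (`k_ele`, `k_pol`, `k_dis`,
#'   `k_rep`), the expected wavefunction `level` and the constants
#'   `version`.
#' @export
energy_model <- function(name = c("CE-B3LYP", "CE-HF")) {
  name <- match.arg(name)
  m <- CE_MODELS[[name]]
  m$name <- name
  m$version <- CE_MODELS_VERSION
  m
}

#' Grimme D2 pairwise dispersion energy between two molecules
#'
#' `E = -sum_{i in A, j in B} f_damp(R_ij) C6_ij / R_ij^6` with
#' `C6_ij = sqrt(C6_i C6_j)`, damping
#' `f = 1/(1 + exp(-d (R/R_r - 1)))`, `R_r` the sum of the D2 vdW radii
#' and `d = 20`.  The global s6 scaling is left to the model's `k_dis`.
#'
#' @param molA,molB `molecule`s (or lists with `element` and `xyz`).
#' @return Energy in kJ/mol (always <= 0).
#' @export
dispersion_d2 <- function(molA, molB) {
  a <- as_sites(molA); b <- as_sites(molB)
  c6a <- element_property(a$element, D2_C6, "D2 C6")
  c6b <- element_property(b$element, D2_C6, "D2 C6")
  r0a <- element_property(a$element, D2_R0, "D2 R0")
  r0b <- element_property(b$element, D2_R0, "D2 R0")
  e <- 0
  for (i in seq_along(a$element)) {
    r <- sqrt(colSums((t(b$xyz) - a$xyz[i, ])^2))
    c6 <- sqrt(c6a[i] * c6b) * 1000  # J nm^6/mol -> kJ A^6/mol
    rr <- r0a[i] + r0b
    f <- 1 / (1 + exp(-D2_DAMPING_D * (r / rr - 1)))
    e <- e - sum(f * c6 / r^6)
  }
  e
}

## electric field (a.u.) at Angstrom points from point charges (e, Angstrom)
point_charge_field <- function(charges, charge_xyz, points) {
  pts <- rbind3(points) * ANGSTROM_TO_BOHR
  pos <- rbind3(charge_xyz) * ANGSTROM_TO_BOHR
  F <- matrix(0, nrow(pts), 3)
  for (q in seq_along(charges)) {
    d <- sweep(pts, 2, pos[q, ])
    r <- sqrt(rowSums(d^2))
    F <- F + charges[q] * d / r^3
  }
  F
}

#' Polarization energy from isotropic atomic polarizabilities
#'
#' `E_pol = -1/2 [ sum_{A} alpha_A |F_B(A)|^2 + sum_{B} alpha_B
#' |F_A(B)|^2 ]`, the field on each atom coming from the other monomer's
#' full charge distribution (wavefunction ESP gradient) or, as an
#' approximate fallback, from user-supplied atomic point charges.
#'
#' @param molA,molB `molecule`s.
#' @param wfnA,wfnB Optional `wavefunction`s providing the fields.
#' @param chargesA,chargesB Optional point charges (e, one per atom) used
#'   when a wavefunction is absent.
#' @return Energy in kJ/mol (<= 0); attribute `approximate` flags the
#'   point-charge fallback.
#' @export
polarization_energy <- function(molA, molB, wfnA = NULL, wfnB = NULL,
                                chargesA = NULL, chargesB = NULL) {
  a <- as_sites(molA); b <- as_sites(molB)
  alA <- element_property(a$element, ATOMIC_POLARIZABILITY, "polarizability")
  alB <- element_property(b$element, ATOMIC_POLARIZABILITY, "polarizability")
  field_from <- function(wfn, charges, sites, at_pts) {
    if (!is.null(wfn)) return(electric_field(wfn, at_pts))
    if (!is.null(charges)) return(point_charge_field(charges, sites$xyz, at_pts))
    stop("polarization needs a wavefunction or point charges for the field source")
  }
  FB <- field_from(wfnB, chargesB, b, a$xyz)  # field of B at A's nuclei
  FA <- field_from(wfnA, chargesA, a, b$xyz)
  e_h <- -0.5 * (sum(alA * rowSums(FB^2)) + sum(alB * rowSums(FA^2)))
  e <- e_h * HARTREE_TO_KJMOL
  attr(e, "approximate") <- is.null(wfnA) || is.null(wfnB)
  e
}

dimer_shells <- function(sa, sb) {
  list(l = c(sa$l, sb$l),
       center = rbind(sa$center, sb$center),
       prim_start = c(sa$prim_start, sa$prim_start[length(sa$prim_start)] +
                        sb$prim_start[-1]),
       expo = c(sa$expo, sb$expo), coef = c(sa$coef, sb$coef))
}

nuclear_repulsion <- function(Za, Ra, Zb, Rb) {
  e <- 0
  Ra <- Ra * ANGSTROM_TO_BOHR; Rb <- Rb * ANGSTROM_TO_BOHR
  for (i in seq_along(Za)) {
    r <- sqrt(colSums((t(Rb) - Ra[i, ])^2))
    e <- e + sum(Za[i] * Zb / r)
  }
  e
}

#' Classical electrostatic (Coulomb) energy between monomer densities
#'
#' Nuclear-nuclear, nuclear-electron (both directions) and
#' electron-electron Coulomb interaction between the two unperturbed
#' monomer charge distributions.
#'
#' @param wfnA,wfnB `wavefunction`s.
#' @return Energy in kJ/mol.
#' @export
electrostatic_energy <- function(wfnA, wfnB) {
  e_nn <- nuclear_repulsion(wfnA$Z, wfnA$xyz, wfnB$Z, wfnB$xyz)
  ## nuclear-electron cross terms in each monomer's own basis
  VB_on_A <- charge_attraction_cpp(wfnA$shells, wfnB$Z, wfnB$xyz * ANGSTROM_TO_BOHR)
  VA_on_B <- charge_attraction_cpp(wfnB$shells, wfnA$Z, wfnA$xyz * ANGSTROM_TO_BOHR)
  e_ne <- -sum(wfnA$D * VB_on_A) - sum(wfnB$D * VA_on_B)
  ## electron-electron Coulomb via the dimer basis with block densities
  sh <- dimer_shells(wfnA$shells, wfnB$shells)
  na <- nrow(wfnA$D); nb <- nrow(wfnB$D); n <- na + nb
  DA <- matrix(0, n, n); DA[1:na, 1:na] <- wfnA$D
  DB <- matrix(0, n, n); DB[na + 1:nb, na + 1:nb] <- wfnB$D
  JB <- coulomb_JK_cpp(sh, DB, FALSE)$J
  e_ee <- sum(DA * JB)
  (e_nn + e_ne + e_ee) * HARTREE_TO_KJMOL
}

## closed-shell one-determinant energy for density D over shells/nuclei
hf_like_energy <- function(sh, D, Z, R_ang) {
  oe <- one_electron_cpp(sh)
  V <- charge_attraction_cpp(sh, Z, R_ang * ANGSTROM_TO_BOHR)
  jk <- coulomb_JK_cpp(sh, D, TRUE)
  e1 <- sum(D * (oe$T - V))
  e2 <- 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K)
  enn <- 0
  Rb <- rbind3(R_ang) * ANGSTROM_TO_BOHR
  if (length(Z) > 1) {
    for (i in 1:(length(Z) - 1)) for (j in (i + 1):length(Z)) {
      enn <- enn + Z[i] * Z[j] / norm2(Rb[i, ] - Rb[j, ])
    }
  }
  e1 + e2 + enn
}

#' Exchange-repulsion energy between two monomer wavefunctions
#'
#' First-order Heitler-London energy of the antisymmetrized product of
#' the two (frozen, closed-shell) monomer determinants minus the monomer
#' energies and the classical Coulomb term - the operational form of the
#' exchange + repulsion sum used with these scaled energy models.
#'
#' @param wfnA,wfnB Closed-shell `wavefunction`s.
#' @return Energy in kJ/mol (>= 0 at chemically sensible separations).
#' @export
repulsion_energy <- function(wfnA, wfnB) {
  occA <- which(wfnA$occupations > 0)
  occB <- which(wfnB$occupations > 0)
  if (any(abs(wfnA$occupations[occA] - 2) > 1e-8) ||
      any(abs(wfnB$occupations[occB] - 2) > 1e-8)) {
    stop("exchange-repulsion requires closed-shell monomers (all occupations 2)")
  }
  sh <- dimer_shells(wfnA$shells, wfnB$shells)
  na <- nrow(wfnA$C); nb <- nrow(wfnB$C)
  C <- matrix(0, na + nb, length(occA) + length(occB))
  C[1:na, seq_along(occA)] <- wfnA$C[, occA, drop = FALSE]
  C[na + 1:nb, length(occA) + seq_along(occB)] <- wfnB$C[, occB, drop = FALSE]
  S <- one_electron_cpp(sh)$S
  M <- crossprod(C, S %*% C)
  D_AS <- 2 * C %*% solve(M, t(C))
  Z <- c(wfnA$Z, wfnB$Z); R <- rbind(wfnA$xyz, wfnB$xyz)
  e_hl <- hf_like_energy(sh, D_AS, Z, R)
  e_a <- hf_like_energy(wfnA$shells, wfnA$D, wfnA$Z, wfnA$xyz)
  e_b <- hf_like_energy(wfnB$shells, wfnB$D, wfnB$Z, wfnB$xyz)
  e_ele <- electrostatic_energy(wfnA, wfnB) / HARTREE_TO_KJMOL
  (e_hl - e_a - e_b - e_ele) * HARTREE_TO_KJMOL
}

#' Scaled four-term pair interaction energy
#'
#' @param molA,molB `molecule`s.
#' @param wfnA,wfnB Monomer `wavefunction`s (required for the
#'   electrostatic and repulsion terms and for wavefunction-derived
#'   polarization fields).
#' @param model An [energy_model()].
#' @param terms Which raw terms to compute; omitted terms enter as 0.
#' @param overrides Named list of precomputed raw term values (kJ/mol),
#'   e.g. `list(E_ele = -10)`; overrides win over computation.
#' @param chargesA,chargesB Point-charge fallback for polarization.
#' @return An `energy_components` list: raw `E_ele`, `E_pol`, `E_dis`,
#'   `E_rep`, scaled total `E_tot` (kJ/mol), the model and metadata.
#' @export
pair_energy <- function(molA, molB, wfnA = NULL, wfnB = NULL,
                        model = energy_model("CE-B3LYP"),
                        terms = c("ele", "pol", "dis", "rep"),
                        overrides = list(), chargesA = NULL, chargesB = NULL) {
  want <- function(t) t %in% terms
  get0 <- function(nm, fn) {
    if (!is.null(overrides[[nm]])) return(overrides[[nm]])
    fn()
  }
  need_wfn <- function(which_term) {
    if (is.null(wfnA) || is.null(wfnB)) {
      stop("the ", which_term, " term requires monomer wavefunctions ",
           "(supply Molden files or a term override)")
    }
  }
  e_dis <- if (want("dis")) get0("E_dis", function() dispersion_d2(molA, molB)) else 0
  e_pol <- if (want("pol")) get0("E_pol", function() {
    as.numeric(polarization_energy(molA, molB, wfnA, wfnB, chargesA, chargesB))
  }) else 0
  e_ele <- if (want("ele")) get0("E_ele", function() {
    need_wfn("electrostatic"); electrostatic_energy(wfnA, wfnB)
  }) else 0
  e_rep <- if (want("rep")) get0("E_rep", function() {
    need_wfn("exchange-repulsion"); repulsion_energy(wfnA, wfnB)
  }) else 0
  out <- list(E_ele = e_ele, E_pol = e_pol, E_dis = e_dis, E_rep = e_rep,
              E_tot = model$k_ele * e_ele + model$k_pol * e_pol +
                model$k_dis * e_dis + model$k_rep * e_rep,
              model = model,
              R = norm2(colMeans(rbind3(as_sites(molB)$xyz)) -
                          colMeans(rbind3(as_sites(molA)$xyz))))
  class(out) <- "energy_components"
  out
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("pair energy (%s, kJ/mol): E_ele %.2f  E_pol %.2f  E_dis %.2f  E_rep %.2f  ->  E_tot %.2f\n",
              x$model$name, x$E_ele, x$E_pol, x$E_dis, x$E_rep, x$E_tot))
  invisible(x)
}

symop_to_cartesian <- function(cell, op) {
  rot <- cell$ortho %*% op$rot %*% cell$frac
  shift <- as.numeric(cell$ortho %*% op$trans)
  list(rot = rot, shift = shift)
}

#' Interaction energies over all symmetry-unique neighbor pairs
#'
#' One row per symmetry-unique pair of `seed` with a neighbor within
#' `radius` (closest-contact criterion); symmetry-equivalent pairs share
#' a computed row.  The seed wavefunction is mapped onto each neighbor by
#' the rigid crystallographic operation (rotation of basis-function
#' coefficients).
#'
#' @param cr A `crystal`.
#' @param seed A `molecule`.
#' @param wfn Monomer `wavefunction` of the seed species (optional; without
#'   it only the dispersion and point-charge polarization terms are
#'   available).
#' @param radius Neighbor radius, Angstrom.
#' @param model An [energy_model()].
#' @param terms Raw terms to compute.
#' @param charges Optional per-atom point charges for the polarization
#'   fallback.
#' @return Data frame: `class`, `symop`, `R`, `n_class`, raw terms,
#'   `E_tot`, with attribute `pairs` (the representative neighbor
#'   molecules) and `model`.
#' @export
interaction_energy_table <- function(cr, seed, wfn = NULL, radius = 3.8,
                                     model = energy_model("CE-B3LYP"),
                                     terms = c("ele", "pol", "dis", "rep"),
                                     charges = NULL) {
  if (!is.null(wfn) && !is.null(model$level)) {
    ## provenance is the user's responsibility; mismatches only warn
    if (!is.null(wfn$level) && !identical(wfn$level, model$level)) {
      warning("wavefunction level '", wfn$level, "' does not match the ",
              model$name, " calibration (", model$level, ")")
    }
  }
  if (!is.null(wfn) && !same_molecule(list(element = wfn$element,
                                           xyz = wfn$xyz,
                                           centroid = colMeans(wfn$xyz)),
                                      seed, tol = 1e-3)) {
    warning("wavefunction geometry does not coincide with the seed molecule; ",
            "transformed copies will inherit the mismatch")
  }
  up <- unique_molecule_pairs(cr, seed, radius)
  pairs <- attr(up, "pairs")
  rows <- list()
  for (k in seq_along(pairs)) {
    nbr <- pairs[[k]]
    wfnB <- NULL
    if (!is.null(wfn)) {
      op <- find_mapping_symop(cr, seed, nbr)
      if (is.null(op)) stop("no symmetry operation maps the seed onto neighbor class ", k)
      tc <- symop_to_cartesian(cr$cell, op)
      wfnB <- transform_wavefunction(wfn, tc$rot, tc$shift)
    }
    pe <- pair_energy(seed, nbr, wfn, wfnB, model, terms,
                      chargesA = charges, chargesB = charges)
    rows[[k]] <- data.frame(class = up$class[k], symop = up$symop[k],
                            R = up$R[k], n_class = up$n_class[k],
                            E_ele = pe$E_ele, E_pol = pe$E_pol,
                            E_dis = pe$E_dis, E_rep = pe$E_rep,
                            E_tot = pe$E_tot)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(0), symop = character(0), R = numeric(0),
               n_class = integer(0), E_ele = numeric(0), E_pol = numeric(0),
               E_dis = numeric(0), E_rep = numeric(0), E_tot = numeric(0))
  attr(out, "pairs") <- pairs
  attr(out, "model") <- model
  out
}

#' Lattice-energy estimate from a pair-energy table
#'
#' `E_lat = 1/2 sum (multiplicity x E_tot)` over all neighbor pairs of
#' one molecule out to `R_max`, reported with a radial convergence trace.
#'
#' @param table Output of [interaction_energy_table()] (computed to the
#'   desired `R_max`).
#' @return List: `energy` (kJ/mol per molecule), `R_max`, `trace` (data
#'   frame of partial sums vs radius).
#' @export
lattice_energy <- function(table) {
  if (is.null(table) || !nrow(table)) {
    return(list(energy = 0, R_max = 0,
                trace = data.frame(R = numeric(0), E = numeric(0))))
  }
  ord <- order(table$R)
  part <- 0.5 * cumsum((table$n_class * table$E_tot)[ord])
  list(energy = part[length(part)], R_max = max(table$R),
       trace = data.frame(R = table$R[ord], E = part))
}

#' Export an interaction-energy table
#'
#' @param table Output of [interaction_energy_table()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  model <- attr(table, "model")
  tab <- table
  tab$model <- model$name
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(model = model, rows = tab), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
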