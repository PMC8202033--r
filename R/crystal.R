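#' Construct a crystal object
#'
#' @param cell A `unit_cell`.
#' @param symops List of `symop` objects; the identity is added when absent.
#' @param asym_atoms Data frame of asymmetric-unit atoms with columns
#'   `element`, `label`, `fx`, `fy`, `fz` and optional `occupancy`.
#' @param name Identifier (e.g. a CSD refcode or fixture name).
#' @return A `crystal` object: list with `cell`, `symops`, `asym`, `name`
#'   and an internal cache environment.
#' @export
crystal <- function(cell, symops, asym_atoms, name = "crystal") {
  stopifnot(inherits(cell, "unit_cell"), length(symops) >= 1)
  check_elements(asym_atoms$element)
  if (is.null(asym_atoms$occupancy)) asym_atoms$occupancy <- 1
  if (any(asym_atoms$occupancy <= 0)) stop("occupancies must be > 0")
  keys <- vapply(symops, symop_key, character(1))
  id_key <- symop_key(new_symop(diag(3), c(0, 0, 0)))
  if (!id_key %in% keys) symops <- c(list(new_symop(diag(3), c(0, 0, 0))), symops)
  ## wrap fractional coordinates into [0, 1)
  for (cn in c("fx", "fy", "fz")) asym_atoms[[cn]] <- asym_atoms[[cn]] %% 1
  x <- list(cell = cell, symops = symops, asym = asym_atoms, name = name,
            cache = new.env(parent = emptyenv()))
  class(x) <- "crystal"
  x
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("crystal '%s': %d asymmetric-unit atom(s), %d symop(s)\n",
              x$name, nrow(x$asym), length(x$symops)))
  print(x$cell)
  invisible(x)
}

#' Expand the asymmetric unit into the full unit-cell contents
#'
#' Applies every symmetry operator, wraps into the unit cell, and removes
#' duplicate sites (same element within 1e-3 Angstrom, periodicity aware).
#'
#' @param cr A `crystal`.
#' @return Data frame with columns `element`, `label`, `fx`, `fy`, `fz`,
#'   `x`, `y`, `z` (Cartesian Angstrom), `asym_idx`, `symop_idx`.
#' @export
expand_unit_cell <- function(cr) {
  if (!is.null(cr$cache$unit_atoms)) return(cr$cache$unit_atoms)
  asym <- cr$asym
  frac0 <- as.matrix(asym[, c("fx", "fy", "fz")])
  rows <- list()
  for (s in seq_along(cr$symops)) {
    f <- apply_symop(cr$symops[[s]], frac0) %% 1
    f[abs(f - 1) < 1e-9] <- 0
    rows[[s]] <- data.frame(element = asym$element, label = asym$label,
                            fx = f[, 1], fy = f[, 2], fz = f[, 3],
                            asym_idx = seq_len(nrow(asym)), symop_idx = s,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  ## periodic-aware dedupe
  keep <- logical(nrow(all))
  kept_frac <- matrix(0, 0, 3); kept_elem <- character(0)
  fr <- as.matrix(all[, c("fx", "fy", "fz")])
  for (i in seq_len(nrow(all))) {
    dup <- FALSE
    if (nrow(kept_frac)) {
      d <- sweep(kept_frac, 2, fr[i, ], `-`)
      d <- d - round(d)
      cart <- d %*% t(cr$cell$ortho)
      dd <- sqrt(rowSums(cart^2))
      dup <- any(dd < 1e-3 & kept_elem == all$element[i])
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_frac <- rbind(kept_frac, fr[i, ])
      kept_elem <- c(kept_elem, all$element[i])
    }
  }
  out <- all[keep, , drop = FALSE]
  cart <- frac_to_cart(cr$cell, as.matrix(out[, c("fx", "fy", "fz")]))
  out$x <- cart[, 1]; out$y <- cart[, 2]; out$z <- cart[, 3]
  rownames(out) <- NULL
  cr$cache$unit_atoms <- out
  out
}

#' Perceive covalent bonds from geometry
#'
#' Atoms i, j are bonded when their distance is at most the sum of covalent
#' radii plus `tolerance`.
#'
#' @param element Character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param tolerance Bond tolerance in Angstrom (default 0.4).
#' @return m x 2 integer matrix of bonded atom index pairs (i < j).
#' @export
perceive_bonds <- function(element, xyz, tolerance = 0.4) {
  xyz <- rbind3(xyz)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  rc <- covalent_radius(element)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rc, rc, `+`) + tolerance
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  bonds <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  dimnames(bonds) <- NULL
  ## exclude spurious H-H "bonds" shorter than realistic (e.g. water H..H)
  bonds
}

new_molecule <- function(element, xyz, label, generator, tolerance = 0.4) {
  xyz <- rbind3(xyz)
  bonds <- perceive_bonds(element, xyz, tolerance)
  m <- list(element = element, xyz = xyz, label = label,
            bonds = bonds, generator = generator,
            centroid = colMeans(xyz))
  class(m) <- "molecule"
  m
}

#' @export
print.molecule <- function(x, ...) {
  f <- table(x$element)
  cat(sprintf("molecule: %s (%d atoms, %d bonds)\n",
              paste0(names(f), ifelse(f > 1, f, ""), collapse = ""),
              length(x$element), nrow(x$bonds)))
  invisible(x)
}

## species fingerprint: formula + rounded sorted distance multiset
molecule_species_key <- function(mol) {
  f <- table(mol$element)
  formula <- paste0(names(f), f, collapse = "")
  if (length(mol$element) > 1) {
    dists <- sort(round(stats::dist(mol$xyz), 2))
    paste(formula, paste(sprintf("%.2f", dists), collapse = ","), sep = "|")
  } else formula
}

## lattice translations T such that |cart(df + T)| could be <= cutoff
translation_range <- function(cell, cutoff) {
  ## perpendicular widths of the cell along each axis
  m <- cell$ortho
  v <- cell$volume
  widths <- c(v / norm2(cross3(m[, 2], m[, 3])),
              v / norm2(cross3(m[, 3], m[, 1])),
              v / norm2(cross3(m[, 1], m[, 2])))
  ceiling(cutoff / widths)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
norm2 <- function(v) sqrt(sum(v^2))

#' Complete all molecules touching the unit cell
#'
#' Grows bonded molecules across symmetry images and lattice translations
#' so that every molecule whose bond graph touches the unit cell is
#' returned whole.  Symmetry-equivalent molecules are identified as one
#' species via the `species` attribute on each molecule.
#'
#' @param cr A `crystal`.
#' @param tolerance Bond tolerance in Angstrom.
#' @param atom_limit Growth limit; exceeding it raises an error (polymeric
#'   or infinite bond network).
#' @return List of `molecule` objects, each with fields `species` (integer
#'   species id) and `generator` (data frame: `asym_idx`, `symop_idx`,
#'   `t1`, `t2`, `t3` recording crystallographic provenance per atom).
#' @export
complete_molecules <- function(cr, tolerance = 0.4, atom_limit = 1000L) {
  key <- paste0("molecules_", tolerance)
  if (!is.null(cr$cache[[key]])) return(cr$cache[[key]])
  ua <- expand_unit_cell(cr)
  n <- nrow(ua)
  fr <- as.matrix(ua[, c("fx", "fy", "fz")])
  rc <- covalent_radius(ua$element)
  maxcut <- 2 * max(rc) + tolerance
  trange <- translation_range(cr$cell, maxcut)
  tgrid <- as.matrix(expand.grid(t1 = -trange[1]:trange[1],
                                 t2 = -trange[2]:trange[2],
                                 t3 = -trange[3]:trange[3]))
  assigned <- rep(FALSE, n)
  molecules <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    ## BFS over nodes (base atom index, lattice shift)
    shift <- list(); shift[[as.character(seed)]] <- c(0L, 0L, 0L)
    queue <- seed
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      si <- shift[[as.character(i)]]
      fi <- fr[i, ] + si
      ci <- as.numeric(frac_to_cart(cr$cell, fi))
      ## candidate neighbours: every base atom in every nearby image
      for (j in seq_len(n)) {
        cutoff <- rc[i] + rc[j] + tolerance
        dj <- fi - fr[j, ]
        t0 <- round(dj)
        for (k in seq_len(nrow(tgrid))) {
          tj <- t0 + tgrid[k, ]
          cj <- as.numeric(frac_to_cart(cr$cell, fr[j, ] + tj))
          dd <- norm2(ci - cj)
          if (dd > 1e-4 && dd <= cutoff) {
            jkey <- as.character(j)
            if (is.null(shift[[jkey]])) {
              shift[[jkey]] <- as.integer(tj)
              queue <- c(queue, j)
              if (length(shift) > atom_limit) {
                stop("molecule growth did not terminate within ", atom_limit,
                     " atoms; structure appears polymeric")
              }
            } else if (any(shift[[jkey]] != as.integer(tj))) {
              ## the same base atom is reachable under two different
              ## lattice shifts: the bond network is periodic
              stop("bond network is periodic (polymeric); cannot complete molecules")
            }
          }
        }
      }
      assigned[i] <- TRUE
    }
    idx <- as.integer(names(shift))
    ord <- order(idx)
    idx <- idx[ord]
    shifts <- do.call(rbind, shift)[ord, , drop = FALSE]
    f <- fr[idx, , drop = FALSE] + shifts
    cart <- frac_to_cart(cr$cell, f)
    gen <- data.frame(asym_idx = ua$asym_idx[idx], symop_idx = ua$symop_idx[idx],
                      t1 = shifts[, 1], t2 = shifts[, 2], t3 = shifts[, 3])
    molecules[[length(molecules) + 1L]] <-
      new_molecule(ua$element[idx], cart, ua$label[idx], gen, tolerance)
  }
  ## deterministic order: by first base-atom index (already BFS order)
  ## assign species ids by fingerprint
  keys <- vapply(molecules, molecule_species_key, character(1))
  species <- match(keys, unique(keys))
  for (i in seq_along(molecules)) molecules[[i]]$species <- species[i]
  cr$cache[[key]] <- molecules
  molecules
}

translate_molecule <- function(mol, cell, tvec) {
  shift <- as.numeric(frac_to_cart(cell, tvec))
  m2 <- mol
  m2$xyz <- sweep(mol$xyz, 2, shift, `+`)
  m2$centroid <- mol$centroid + shift
  if (!is.null(m2$generator)) {
    m2$generator$t1 <- m2$generator$t1 + tvec[1]
    m2$generator$t2 <- m2$generator$t2 + tvec[2]
    m2$generator$t3 <- m2$generator$t3 + tvec[3]
  }
  m2$lattice_shift <- (mol$lattice_shift %||% c(0L, 0L, 0L)) + as.integer(tvec)
  m2
}

same_molecule <- function(a, b, tol = 1e-3) {
  if (length(a$element) != length(b$element)) return(FALSE)
  if (norm2(a$centroid - b$centroid) > tol * length(a$element)) return(FALSE)
  ## nearest-atom matching
  for (i in seq_along(a$element)) {
    d <- sqrt(colSums((t(b$xyz) - a$xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] > tol || b$element[j] != a$element[i]) return(FALSE)
  }
  TRUE
}

#' All whole molecules with an atom within a radius of a seed molecule
#'
#' Enumerates lattice images of the unit-cell molecules and keeps those
#' (excluding the seed itself) with at least one atom within `radius` of
#' any seed atom.  Output order is deterministic: centroid distance, then
#' the generating translation.
#'
#' @param cr A `crystal`.
#' @param seed A `molecule` from [complete_molecules()].
#' @param radius Radius in Angstrom.
#' @param max_neighbors Resource cap; exceeding it raises an error.
#' @return List of `molecule` objects.
#' @export
cluster_within_radius <- function(cr, seed, radius, max_neighbors = 2000L) {
  stopifnot(radius > 0)
  base <- complete_molecules(cr)
  ## molecular extent bounds the search box
  ext <- max(vapply(base, function(m) max(sqrt(rowSums(sweep(m$xyz, 2, m$centroid)^2))), 0))
  trange <- translation_range(cr$cell, radius + 2 * ext + max(sqrt(rowSums(sweep(seed$xyz, 2, seed$centroid)^2))))
  neighbors <- list()
  for (t1 in -trange[1]:trange[1]) for (t2 in -trange[2]:trange[2]) for (t3 in -trange[3]:trange[3]) {
    for (b in seq_along(base)) {
      cand <- translate_molecule(base[[b]], cr$cell, c(t1, t2, t3))
      if (same_molecule(cand, seed)) next
      dmin <- min_intermolecular_distance(seed$xyz, cand$xyz)
      if (dmin <= radius) {
        cand$base_index <- b
        cand$min_contact <- dmin
        neighbors[[length(neighbors) + 1L]] <- cand
        if (length(neighbors) > max_neighbors) {
          stop("neighbor count exceeds cap (", max_neighbors, "); radius too large")
        }
      }
    }
  }
  if (!length(neighbors)) return(neighbors)
  cd <- vapply(neighbors, function(m) norm2(m$centroid - seed$centroid), 0)
  tkey <- vapply(neighbors, function(m) sprintf("%d|%+03d%+03d%+03d", m$base_index,
                                                m$lattice_shift[1], m$lattice_shift[2], m$lattice_shift[3]), "")
  neighbors[order(cd, tkey)]
}

min_intermolecular_distance <- function(a, b) {
  min(vapply(seq_len(nrow(a)), function(i) min(sqrt(colSums((t(b) - a[i, ])^2))), 0))
}

#' Generate a slab of complete unit cells
#'
#' @param cr A `crystal`.
#' @param ranges Integer vector of three cell multiples (each >= 1).
#' @return Data frame of atoms (`element`, `label`, `x`, `y`, `z`, cell
#'   index columns `t1`, `t2`, `t3`).
#' @export
generate_slab <- function(cr, ranges = c(1, 1, 1)) {
  stopifnot(length(ranges) == 3, all(ranges >= 1))
  ua <- expand_unit_cell(cr)
  out <- list()
  for (t1 in 0:(ranges[1] - 1)) for (t2 in 0:(ranges[2] - 1)) for (t3 in 0:(ranges[3] - 1)) {
    cart <- frac_to_cart(cr$cell, sweep(as.matrix(ua[, c("fx", "fy", "fz")]), 2, c(t1, t2, t3), `+`))
    out[[length(out) + 1L]] <- data.frame(element = ua$element, label = ua$label,
                                          x = cart[, 1], y = cart[, 2], z = cart[, 3],
                                          t1 = t1, t2 = t2, t3 = t3,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## default neutron-derived X-H bond lengths (Angstrom)
XH_NORMALIZED_LENGTHS <- c(C = 1.083, N = 1.009, O = 0.983, B = 1.180)

#' Normalize X-H bond lengths to standard neutron-derived values
#'
#' X-ray structures systematically foreshorten X-H bonds; each X-H bond
#' (X in C, N, O, B) is rescaled along its direction to the standard
#' length.  Heavy atoms are untouched.  Hydrogens bonded to two or more
#' heavy atoms (bridging) are left unchanged with a warning.
#'
#' @param mol A `molecule`.
#' @param lengths Named vector of target lengths in Angstrom.
#' @return The molecule with repositioned hydrogens.
#' @export
normalize_h_positions <- function(mol, lengths = XH_NORMALIZED_LENGTHS) {
  h <- which(mol$element == "H")
  if (!length(h) || !nrow(mol$bonds)) return(mol)
  for (i in h) {
    rows <- which(mol$bonds[, 1] == i | mol$bonds[, 2] == i)
    partners <- setdiff(as.vector(mol$bonds[rows, , drop = FALSE]), i)
    heavies <- partners[mol$element[partners] != "H"]
    if (length(heavies) >= 2) {
      warning("H atom ", i, " bridges ", length(heavies), " heavy atoms; left unchanged")
      next
    }
    if (length(heavies) != 1) next
    x <- heavies[1]
    tgt <- lengths[mol$element[x]]
    if (is.na(tgt)) next
    v <- mol$xyz[i, ] - mol$xyz[x, ]
    mol$xyz[i, ] <- mol$xyz[x, ] + v / norm2(v) * tgt
  }
  mol$centroid <- colMeans(mol$xyz)
  mol
}

## find the space-group operation (rot, trans incl. lattice part) mapping
## molecule `from` onto molecule `to`; NULL when none matches
find_mapping_symop <- function(cr, from, to, tol = 1e-3) {
  f_cent <- as.numeric(cart_to_frac(cr$cell, from$centroid))
  t_cent <- as.numeric(cart_to_frac(cr$cell, to$centroid))
  for (op in cr$symops) {
    gc <- as.numeric(apply_symop(op, f_cent))
    tvec <- round(t_cent - gc)
    full <- new_symop(op$rot, op$trans + tvec)
    moved <- from
    fr <- apply_symop(full, cart_to_frac(cr$cell, from$xyz))
    moved$xyz <- frac_to_cart(cr$cell, fr)
    moved$centroid <- colMeans(moved$xyz)
    if (same_molecule(moved, to, tol)) return(full)
  }
  NULL
}

#' Symmetry-unique molecular pairs around a seed molecule
#'
#' Groups the neighbors of `seed` (within `radius`, closest-contact
#' criterion) into symmetry-equivalence classes.  Pairs related by
#' interchange of the two molecules (A->B vs B->A) belong to one class.
#'
#' @param cr A `crystal`.
#' @param seed A `molecule`.
#' @param radius Neighbor search radius in Angstrom (closest atom-atom
#'   contact).
#' @return Data frame with one row per class: `class`, `n_class`
#'   (multiplicity), `R` (centroid-centroid distance, Angstrom), `symop`
#'   (human-readable operator mapping seed onto the representative
#'   neighbor), plus a `pairs` attribute listing the representative
#'   `molecule` of each class and `members` giving each neighbor's class.
#' @export
unique_molecule_pairs <- function(cr, seed, radius = 3.8) {
  nbrs <- cluster_within_radius(cr, seed, radius)
  if (!length(nbrs)) {
    out <- data.frame(class = integer(0), n_class = integer(0),
                      R = numeric(0), symop = character(0))
    attr(out, "pairs") <- list()
    attr(out, "members") <- integer(0)
    return(out)
  }
  ## exact classification: two neighbors are equivalent when a space-group
  ## operation maps the unordered pair {seed, M_k} onto {seed, M_l}
  cls <- integer(length(nbrs))
  reps <- integer(0)
  for (i in seq_along(nbrs)) {
    for (k in seq_along(reps)) {
      if (is_equivalent_pair(cr, seed, nbrs[[reps[k]]], nbrs[[i]])) {
        cls[i] <- k; break
      }
    }
    if (cls[i] == 0L) { reps <- c(reps, i); cls[i] <- length(reps) }
  }
  out <- data.frame(class = seq_along(reps),
                    n_class = as.integer(table(cls)[as.character(seq_along(reps))]),
                    R = vapply(nbrs[reps], function(m) norm2(m$centroid - seed$centroid), 0))
  out$symop <- vapply(nbrs[reps], function(m) {
    op <- find_mapping_symop(cr, seed, m)
    if (is.null(op)) "unresolved" else symop_to_string(op)
  }, character(1))
  attr(out, "pairs") <- nbrs[reps]
  attr(out, "members") <- cls
  out
}

## does a space-group operation map the unordered pair (seed, m1) onto
## (seed, m2)?
is_equivalent_pair <- function(cr, seed, m1, m2, tol = 1e-3) {
  targets <- list(list(seed, m2), list(m2, seed))
  for (op in cr$symops) {
    for (tg in targets) {
      full <- op_mapping_centroids(cr, op, seed, tg[[1]], tol)
      if (is.null(full)) next
      if (molecule_maps_to(cr, full, seed, tg[[1]], tol) &&
          molecule_maps_to(cr, full, m1, tg[[2]], tol)) return(TRUE)
    }
  }
  FALSE
}

## complete `op` with the lattice translation taking from's centroid onto
## to's; NULL when no integer translation does
op_mapping_centroids <- function(cr, op, from, to, tol = 1e-3) {
  fc <- as.numeric(apply_symop(op, cart_to_frac(cr$cell, from$centroid)))
  tc <- as.numeric(cart_to_frac(cr$cell, to$centroid))
  tvec <- tc - fc
  rt <- round(tvec)
  miss <- norm2(as.numeric(frac_to_cart(cr$cell, tvec - rt)))
  if (miss > tol * 10) return(NULL)
  new_symop(op$rot, op$trans + rt)
}

molecule_maps_to <- function(cr, full, from, to, tol = 1e-3) {
  fr <- apply_symop(full, cart_to_frac(cr$cell, from$xyz))
  moved <- from
  moved$xyz <- frac_to_cart(cr$cell, fr)
  moved$centroid <- colMeans(moved$xyz)
  same_molecule(moved, to, tol)
}

#' Write molecules or atom sets as an XYZ block
#'
#' @param element Character vector of element symbols (or a `molecule`).
#' @param xyz n x 3 Cartesian coordinates; ignored when `element` is a
#'   molecule.
#' @param path Output file path.
#' @param comment Second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(element, xyz = NULL, path, comment = "") {
  if (inherits(element, "molecule")) { xyz <- element$xyz; element <- element$element }
  xyz <- rbind3(xyz)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(element)), comment), con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}
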