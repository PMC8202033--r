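#' Contact-distance properties on a Hirshfeld surface
#'
#' Adds the Table-style distance channels: `d_i` (distance to the nearest
#' atom of the surface's own molecule), `d_e` (nearest atom of the
#' environment) and the vdW-normalized contact distance
#' `d_norm = (d_i - r_vdw_I)/r_vdw_I + (d_e - r_vdw_E)/r_vdw_E`.
#'
#' @param mesh A `trimesh` (typically from [hirshfeld_surface()]).
#' @param molecule The `molecule` inside the surface.
#' @param environment List of neighbor `molecule`s (e.g. from
#'   [cluster_within_radius()]); must contain every molecule that can host
#'   a nearest external atom.
#' @return The mesh with channels `d_i`, `d_e`, `d_norm` and a
#'   `meta$assignment` data frame recording per vertex the internal and
#'   external atom indices, elements and the external molecule index.
#' @export
distance_properties <- function(mesh, molecule, environment) {
  if (!length(environment)) {
    stop("empty environment: no external atoms; grow the cluster radius")
  }
  env_elem <- unlist(lapply(environment, `[[`, "element"))
  env_xyz <- do.call(rbind, lapply(environment, `[[`, "xyz"))
  env_mol <- rep(seq_along(environment),
                 vapply(environment, function(m) length(m$element), 0L))
  nin <- nn_brute_cpp(mesh$vertices, molecule$xyz)
  nex <- nn_brute_cpp(mesh$vertices, env_xyz)
  d_i <- nin$distance; d_e <- nex$distance
  r_i <- vdw_radius(molecule$element[nin$index])
  r_e <- vdw_radius(env_elem[nex$index])
  d_norm <- (d_i - r_i) / r_i + (d_e - r_e) / r_e
  mesh <- mesh_set_channel(mesh, "d_i", d_i)
  mesh <- mesh_set_channel(mesh, "d_e", d_e)
  mesh <- mesh_set_channel(mesh, "d_norm", d_norm)
  mesh$meta$assignment <- data.frame(
    internal_atom = nin$index, internal_element = molecule$element[nin$index],
    d_i = d_i,
    external_atom = nex$index, external_element = env_elem[nex$index],
    external_molecule = env_mol[nex$index],
    d_e = d_e, d_norm = d_norm,
    stringsAsFactors = FALSE)
  mesh
}

#' Hirshfeld surface with distance properties, growing the environment
#'
#' Convenience pipeline: builds the neighbor cluster, expanding its radius
#' until every vertex's nearest external atom lies well inside the search
#' range, then computes the distance channels.
#'
#' @param cr A `crystal`.
#' @param molecule A `molecule`.
#' @param resolution Preset name or spacing (Angstrom).
#' @param radius Initial cluster radius (Angstrom).
#' @return The decorated mesh; `meta$cluster` holds the neighbor list.
#' @export
hirshfeld_surface_properties <- function(cr, molecule, resolution = "high",
                                         radius = 3.8) {
  mesh <- hirshfeld_surface(cr, molecule, resolution)
  repeat {
    cluster <- cluster_within_radius(cr, molecule, radius)
    if (length(cluster)) {
      mesh <- distance_properties(mesh, molecule, cluster)
      if (max(mesh$props$d_e) <= 0.8 * radius) break
    }
    radius <- radius + 2
    if (radius > 30) stop("environment search radius grew beyond 30 A")
  }
  mesh$meta$cluster <- cluster
  mesh
}

#' Fragment patches: surface regions by nearest external molecule
#'
#' Labels every vertex by the neighbor molecule owning its nearest
#' external atom and splits same-label regions into connected components
#' over mesh edges.
#'
#' @param mesh A mesh with distance properties computed.
#' @return The mesh with channel `patch_id` and `meta$patch_table`, a data
#'   frame (patch id, external molecule index, area in A^2, percent of
#'   total area) sorted by area descending; percentages sum to 100.
#' @export
fragment_patches <- function(mesh) {
  asg <- mesh$meta$assignment
  if (is.null(asg)) stop("distance_properties must be computed first")
  lab <- asg$external_molecule
  comp <- label_components(mesh, lab)
  area <- tapply(mesh$vertex_area, comp, sum)
  ord <- order(-area)
  tab <- data.frame(patch_id = seq_along(ord),
                    external_molecule = as.integer(tapply(lab, comp, `[`, 1))[ord],
                    area = as.numeric(area[ord]))
  tab$percent <- 100 * tab$area / sum(mesh$vertex_area)
  remap <- integer(length(area)); remap[ord] <- seq_along(ord)
  mesh <- mesh_set_channel(mesh, "patch_id", remap[comp])
  mesh$meta$patch_table <- tab
  mesh
}

## connected components of vertices over mesh edges, split by label
label_components <- function(mesh, lab) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  same <- lab[e[, 1]] == lab[e[, 2]]
  g <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nrow(mesh$vertices))]
}

#' Koenderink curvature properties: shape index and curvedness
#'
#' Principal curvatures are estimated per vertex by a local quadric fit
#' over the 2-ring neighborhood in the tangent frame of the vertex normal
#' (3-ring fallback for degenerate neighborhoods).  Convention: normals
#' outward, convex regions have positive curvature, so spheres have shape
#' index +1.  Shape index `S = (2/pi) atan((k1+k2)/(k1-k2))` (clamped to
#' `[-1, 1]`, +/-1 at umbilics); curvedness
#' `C = (2/pi) ln(((k1^2+k2^2)/2)^(1/2))`.
#'
#' @param mesh A closed `trimesh`.
#' @return The mesh with channels `shape_index` and `curvedness`.
#' @export
curvature_properties <- function(mesh) {
  nv <- nrow(mesh$vertices)
  adj <- vertex_adjacency(mesh)
  si <- numeric(nv); cv <- numeric(nv)
  for (v in seq_len(nv)) {
    ring <- ring_neighborhood(adj, v, 2L)
    k <- fit_principal_curvatures(mesh, v, ring)
    if (is.null(k)) {
      ring <- ring_neighborhood(adj, v, 3L)
      k <- fit_principal_curvatures(mesh, v, ring)
    }
    if (is.null(k)) { si[v] <- NA; cv[v] <- NA; next }
    k1 <- k[1]; k2 <- k[2]
    if (abs(k1 - k2) < 1e-8) {
      si[v] <- sign(k1 + k2)
    } else {
      si[v] <- (2 / pi) * atan((k1 + k2) / (k1 - k2))
    }
    si[v] <- max(-1, min(1, si[v]))
    cv[v] <- (2 / pi) * log(sqrt((k1^2 + k2^2) / 2))
  }
  mesh <- mesh_set_channel(mesh, "shape_index", si)
  mesh_set_channel(mesh, "curvedness", cv)
}

vertex_adjacency <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], e[, 1])
}

ring_neighborhood <- function(adj, v, k) {
  seen <- v
  frontier <- v
  for (i in seq_len(k)) {
    frontier <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
  }
  setdiff(seen, v)
}

fit_principal_curvatures <- function(mesh, v, ring) {
  if (length(ring) < 5) return(NULL)
  n <- mesh$normals[v, ]
  ## tangent frame
  t1 <- cross3(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  t1 <- t1 / norm2(t1)
  t2 <- cross3(n, t1)
  d <- sweep(mesh$vertices[ring, , drop = FALSE], 2, mesh$vertices[v, ])
  x <- d %*% t1; y <- d %*% t2; z <- d %*% n
  A <- cbind(x^2, x * y, y^2, x, y)
  fit <- tryCatch(qr.solve(A, z, tol = 1e-10), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  a <- fit[1]; b <- fit[2]; cc <- fit[3]; dd <- fit[4]; ee <- fit[5]
  W <- sqrt(1 + dd^2 + ee^2)
  I1 <- matrix(c(1 + dd^2, dd * ee, dd * ee, 1 + ee^2), 2)
  II <- matrix(c(2 * a, b, b, 2 * cc), 2) / W
  S <- II %*% solve(I1)
  ## symmetrize before the eigendecomposition (S is similar to symmetric)
  ev <- sort(Re(eigen(S, only.values = TRUE)$values), decreasing = TRUE)
  ## outward normal + surface bending away from it => negative z; flip so
  ## convex regions are positive
  k <- sort(-ev, decreasing = TRUE)
  k
}

#' Summary statistics of a property channel
#'
#' @param mesh A `trimesh`.
#' @param channel Channel name.
#' @return List with `min`, `max` and the area-weighted `mean`.
#' @export
property_statistics <- function(mesh, channel) {
  v <- mesh_channel(mesh, channel)
  list(min = min(v), max = max(v),
       mean = sum(v * mesh$vertex_area) / sum(mesh$vertex_area))
}
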