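## Energy frameworks: pairwise energies in a supercell drawn as a graph of
## molecule centroids joined by cylinders whose radius is proportional to
## the interaction magnitude.

## does a space-group operation map unordered pair (a1, a2) onto (b1, b2)?
pairs_equivalent <- function(cr, a1, a2, b1, b2, tol = 1e-3) {
  for (op in cr$symops) {
    for (tg in list(list(b1, b2), list(b2, b1))) {
      full <- op_mapping_centroids(cr, op, a1, tg[[1]], tol)
      if (is.null(full)) next
      if (molecule_maps_to(cr, full, a1, tg[[1]], tol) &&
          molecule_maps_to(cr, full, a2, tg[[2]], tol)) return(TRUE)
    }
  }
  FALSE
}

#' Build an energy framework over a supercell
#'
#' Places a node at every whole molecule of the supercell and an edge
#' wherever the selected (scaled) energy component of the pair class has
#' magnitude at least `cutoff`; edge energies are copied from the table by
#' symmetry class, never recomputed.
#'
#' @param cr A `crystal`.
#' @param table An [interaction_energy_table()] computed for one seed
#'   molecule (its radius bounds which contacts can become edges).
#' @param seed The seed `molecule` the table refers to.
#' @param supercell Integer cell multiples.
#' @param component `"total"`, `"electrostatic"` or `"dispersion"`.
#' @param cutoff Minimum `|E|` (kJ/mol) for an edge.
#' @return A `framework_graph`: `nodes` (centroids + provenance), `edges`
#'   (node pairs, class, component energies, selected `value`),
#'   `component`, `cutoff`, `model`.
#' @export
build_framework <- function(cr, table, seed, supercell = c(3, 3, 1),
                            component = c("total", "electrostatic", "dispersion"),
                            cutoff = 5) {
  component <- match.arg(component)
  model <- attr(table, "model")
  pairs <- attr(table, "pairs")
  base <- complete_molecules(cr)
  nodes <- list(); mols <- list()
  for (t1 in 0:(supercell[1] - 1)) for (t2 in 0:(supercell[2] - 1))
    for (t3 in 0:(supercell[3] - 1)) for (b in seq_along(base)) {
      m <- translate_molecule(base[[b]], cr$cell, c(t1, t2, t3))
      mols[[length(mols) + 1]] <- m
      nodes[[length(nodes) + 1]] <- data.frame(
        id = length(nodes) + 1, x = m$centroid[1], y = m$centroid[2],
        z = m$centroid[3], base = b, t1 = t1, t2 = t2, t3 = t3)
    }
  nodes <- do.call(rbind, nodes)
  comp_value <- function(row) {
    switch(component,
           total = row$E_tot,
           electrostatic = model$k_ele * row$E_ele,
           dispersion = model$k_dis * row$E_dis)
  }
  keep_cls <- which(vapply(seq_len(nrow(table)),
                           function(k) abs(comp_value(table[k, ])) >= cutoff, TRUE))
  edges <- list()
  if (length(keep_cls)) {
    rmax <- max(table$R) + 1e-6
    n <- nrow(nodes)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      Rij <- norm2(as.numeric(nodes[i, c("x", "y", "z")]) -
                     as.numeric(nodes[j, c("x", "y", "z")]))
      if (Rij > rmax) next
      for (k in keep_cls) {
        if (abs(Rij - table$R[k]) > 0.05) next
        if (pairs_equivalent(cr, mols[[i]], mols[[j]], seed, pairs[[k]])) {
          row <- table[k, ]
          edges[[length(edges) + 1]] <- data.frame(
            from = i, to = j, class = row$class,
            E_ele = row$E_ele, E_pol = row$E_pol, E_dis = row$E_dis,
            E_rep = row$E_rep, E_tot = row$E_tot, value = comp_value(row))
          break
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), class = integer(0),
               E_ele = numeric(0), E_pol = numeric(0), E_dis = numeric(0),
               E_rep = numeric(0), E_tot = numeric(0), value = numeric(0))
  g <- list(nodes = nodes, edges = edges, component = component,
            cutoff = cutoff, model = model$name,
            scaled_components = TRUE)
  class(g) <- "framework_graph"
  g
}

#' @export
print.framework_graph <- function(x, ...) {
  cat(sprintf("energy framework (%s): %d nodes, %d edges (cutoff %g kJ/mol)\n",
              x$component, nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

framework_edge_color <- function(graph, value) {
  switch(graph$component,
         electrostatic = c(200, 30, 30),
         dispersion = c(30, 160, 30),
         total = if (value < 0) c(40, 80, 220) else c(212, 175, 55))
}

#' Export an energy framework as a colored PLY scene plus JSON sidecar
#'
#' Every edge becomes a 16-gon cylinder with radius `|E| * scale`, capped
#' at half the shortest edge length; colors follow the component rule
#' (electrostatic red, dispersion green, total blue when binding / gold
#' when non-binding).  The JSON sidecar round-trips the full graph.
#'
#' @param graph A `framework_graph`.
#' @param path Output path for the PLY; the sidecar gets extension
#'   `.json`.
#' @param scale Cylinder radius per kJ/mol (Angstrom).
#' @return Paths, invisibly.
#' @export
export_framework <- function(graph, path, scale = 0.02) {
  stopifnot(scale > 0)
  json_path <- sub("\\.ply$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  jsonlite::write_json(unclass(graph), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  verts <- list(); faces <- list(); colors <- list(); v0 <- 0
  rcap <- if (nrow(graph$edges)) {
    lens <- vapply(seq_len(nrow(graph$edges)), function(k) {
      p <- as.numeric(graph$nodes[graph$edges$from[k], c("x", "y", "z")])
      q <- as.numeric(graph$nodes[graph$edges$to[k], c("x", "y", "z")])
      norm2(q - p)
    }, 0)
    min(lens) / 2
  } else Inf
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    p <- as.numeric(graph$nodes[e$from, c("x", "y", "z")])
    q <- as.numeric(graph$nodes[e$to, c("x", "y", "z")])
    r <- min(abs(e$value) * scale, rcap)
    cyl <- cylinder_mesh(p, q, r, n = 16)
    verts[[k]] <- cyl$vertices
    faces[[k]] <- cyl$faces + v0
    colors[[k]] <- matrix(rep(framework_edge_color(graph, e$value),
                              each = nrow(cyl$vertices)), ncol = 3)
    v0 <- v0 + nrow(cyl$vertices)
  }
  V <- if (length(verts)) do.call(rbind, verts) else matrix(0, 0, 3)
  F <- if (length(faces)) do.call(rbind, faces) else matrix(0L, 0, 3)
  C <- if (length(colors)) do.call(rbind, colors) else matrix(0, 0, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(V)) {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d", V[, 1], V[, 2], V[, 3],
                       C[, 1], C[, 2], C[, 3]), con)
  }
  if (nrow(F)) writeLines(paste("3", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  invisible(c(ply = path, json = json_path))
}

#' Rebuild a framework graph from its JSON sidecar
#' @param path Sidecar path from [export_framework()].
#' @return A `framework_graph`.
#' @export
read_framework_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  g$nodes <- as.data.frame(g$nodes)
  g$edges <- as.data.frame(g$edges)
  class(g) <- "framework_graph"
  g
}

cylinder_mesh <- function(p, q, r, n = 16) {
  axis <- q - p
  len <- norm2(axis)
  az <- axis / len
  ax <- cross3(az, if (abs(az[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  ax <- ax / norm2(ax)
  ay <- cross3(az, ax)
  th <- 2 * pi * (0:(n - 1)) / n
  ring <- outer(cos(th), ax) * r + outer(sin(th), ay) * r
  bot <- sweep(ring, 2, p, `+`)
  top <- sweep(ring, 2, q, `+`)
  V <- rbind(bot, top, p, q)
  ib <- 1:n; it <- n + 1:n; cb <- 2 * n + 1; ct <- 2 * n + 2
  nxt <- c(2:n, 1)
  F <- rbind(cbind(ib, ib[nxt], it[nxt]), cbind(ib, it[nxt], it),
             cbind(cb, ib[nxt], ib), cbind(ct, it, it[nxt]))
  list(vertices = V, faces = F)
}
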