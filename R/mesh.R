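## Triangulated surface container: vertices/faces plus per-vertex scalar
## property channels and per-vertex areas (one third of incident triangle
## areas), the quantity fingerprints and contact percentages are weighted
## by.

new_trimesh <- function(vertices, faces, meta = list()) {
  vd <- mesh_vertex_data_cpp(vertices, faces)
  m <- list(vertices = vertices, faces = faces,
            normals = vd$normals, vertex_area = vd$vertex_area,
            area = vd$area, volume = vd$volume,
            closed = is_closed_mesh(faces),
            props = list(), meta = meta)
  class(m) <- "trimesh"
  m
}

is_closed_mesh <- function(faces) {
  if (!nrow(faces)) return(FALSE)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

## flip face winding so the signed volume is positive (outward normals)
orient_outward <- function(mesh) {
  if (mesh$closed && mesh$volume < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
    vd <- mesh_vertex_data_cpp(mesh$vertices, mesh$faces)
    mesh$normals <- vd$normals
    mesh$vertex_area <- vd$vertex_area
    mesh$volume <- vd$volume
  }
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, area %.3f A^2%s\n",
              nrow(x$vertices), nrow(x$faces), x$area,
              if (x$closed) sprintf(", volume %.3f A^3", x$volume) else " (open)"))
  if (length(x$props)) cat("  channels:", paste(names(x$props), collapse = ", "), "\n")
  invisible(x)
}

#' Set or get a per-vertex property channel
#'
#' @param mesh A `trimesh`.
#' @param name Channel name.
#' @param values Numeric vector, one value per vertex.
#' @return The updated mesh (`mesh_set_channel`) or the channel vector.
#' @export
mesh_set_channel <- function(mesh, name, values) {
  stopifnot(length(values) == nrow(mesh$vertices))
  mesh$props[[name]] <- values
  mesh
}

#' @rdname mesh_set_channel
#' @export
mesh_channel <- function(mesh, name) {
  if (!name %in% names(mesh$props)) {
    stop("no channel '", name, "'; available: ",
         paste(names(mesh$props), collapse = ", "))
  }
  mesh$props[[name]]
}

#' Global shape measures of a triangulated surface
#'
#' Area is the triangle-area sum; the enclosed volume comes from the
#' divergence theorem (closed meshes only); globularity is
#' `(36 pi V^2)^(1/3) / A` (1 for a sphere); asphericity is the relative
#' anisotropy of the area-weighted vertex covariance (0 for a sphere).
#'
#' @param mesh A `trimesh`.
#' @return List with `area` (A^2), `volume` (A^3 or NA for open meshes),
#'   `globularity`, `asphericity`.
#' @export
mesh_measures <- function(mesh) {
  vol <- if (mesh$closed) mesh$volume else NA_real_
  glob <- if (mesh$closed) (36 * pi * vol^2)^(1 / 3) / mesh$area else NA_real_
  wts <- mesh$vertex_area / sum(mesh$vertex_area)
  ctr <- colSums(mesh$vertices * wts)
  d <- sweep(mesh$vertices, 2, ctr)
  cov <- crossprod(d * sqrt(wts))
  lam <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  asp <- ((lam[1] - lam[2])^2 + (lam[1] - lam[3])^2 + (lam[2] - lam[3])^2) /
    (2 * sum(lam)^2)
  list(area = mesh$area, volume = vol, globularity = glob, asphericity = asp)
}

#' Export a mesh as PLY (with property channels) or OBJ
#'
#' PLY files carry every property channel as a per-vertex attribute;
#' `format = "ply"` writes ASCII, `"ply_binary"` little-endian binary,
#' `"obj"` drops properties.
#'
#' @param mesh A `trimesh`.
#' @param path Output path.
#' @param format One of `"ply"`, `"ply_binary"`, `"obj"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "ply_binary", "obj")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  if (format == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
    return(invisible(path))
  }
  chan <- names(mesh$props)
  hdr <- c("ply",
           if (format == "ply") "format ascii 1.0" else "format binary_little_endian 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           sprintf("property float %s", chan),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vdata <- cbind(mesh$vertices, mesh$normals,
                 if (length(chan)) do.call(cbind, mesh$props[chan]))
  if (format == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(vdata, 1, function(r) paste(sprintf("%.6g", r), collapse = " ")), con)
    writeLines(paste("3", mesh$faces[, 1] - 1, mesh$faces[, 2] - 1, mesh$faces[, 3] - 1), con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(vdata)), con, size = 4, endian = "little")
    fdat <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.integer(fdat[1, i]), con, size = 1)
      writeBin(as.integer(fdat[2:4, i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
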