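#' Area-weighted 2D fingerprint of a Hirshfeld surface
#'
#' Bins every vertex's area into the (d_i, d_e) histogram.  Default axis
#' range 0.4-2.6 Angstrom with 0.01 Angstrom bins (the conventional plot
#' bounds; an expanded 0.4-3.0 range suits long contacts).
#'
#' @param mesh A mesh with `d_i`/`d_e` channels ([distance_properties()]).
#' @param range Axis range (Angstrom), shared by both axes.
#' @param bin Bin width (Angstrom).
#' @return A `fingerprint` object: `breaks`, bin matrix `area` (d_i rows,
#'   d_e columns, A^2), `total_area`, `out_of_range` area.
#' @export
compute_fingerprint <- function(mesh, range = c(0.4, 2.6), bin = 0.01) {
  if (!all(c("d_i", "d_e") %in% names(mesh$props))) {
    stop("mesh lacks d_i/d_e channels; run distance_properties() first")
  }
  di <- mesh$props$d_i; de <- mesh$props$d_e
  breaks <- seq(range[1], range[2], by = bin)
  nb <- length(breaks) - 1
  ix <- findInterval(di, breaks, rightmost.closed = TRUE)
  iy <- findInterval(de, breaks, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  if (!all(ok)) {
    warning(sum(!ok), " vertex(es) outside the fingerprint range; ",
            "area accumulated separately")
  }
  m <- matrix(0, nb, nb)
  if (any(ok)) {
    acc <- tapply(mesh$vertex_area[ok], list(factor(ix[ok], levels = 1:nb),
                                             factor(iy[ok], levels = 1:nb)), sum)
    acc[is.na(acc)] <- 0
    m <- unclass(acc)
  }
  fp <- list(breaks = breaks, area = m,
             total_area = sum(mesh$vertex_area),
             out_of_range = sum(mesh$vertex_area[!ok]))
  class(fp) <- "fingerprint"
  fp
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint: %d x %d bins over [%.2f, %.2f] A, total area %.3f A^2\n",
              nrow(x$area), ncol(x$area), min(x$breaks), max(x$breaks), x$total_area))
  invisible(x)
}

#' Decompose a fingerprint by an element-pair contact filter
#'
#' A vertex matches when its (internal element, external element) pair
#' equals the filter (wildcards `"*"` allowed); with
#' `include_reciprocal = TRUE` the swapped pair also matches.  The percent
#' contribution is matched vertex area over total area; areas are exact
#' vertex areas, not bin counts.
#'
#' @param mesh A mesh with distance properties.
#' @param inside,outside Element symbols or `"*"`.
#' @param include_reciprocal Also count the swapped-role contacts.
#' @param range,bin Passed to [compute_fingerprint()].
#' @return List: `percent`, `matched` and `rest` (`fingerprint` objects of
#'   the highlighted and greyed-out parts), `vertices` (matched vertex
#'   indices), `filter`.
#' @export
decompose_fingerprint <- function(mesh, inside = "*", outside = "*",
                                  include_reciprocal = FALSE,
                                  range = c(0.4, 2.6), bin = 0.01) {
  asg <- mesh$meta$assignment
  if (is.null(asg)) stop("mesh lacks a contact assignment; run distance_properties() first")
  if (inside != "*") check_elements(inside)
  if (outside != "*") check_elements(outside)
  if (!is.null(mesh$meta$resolution) && mesh$meta$resolution > RESOLUTION_PRESETS[["high"]]) {
    warning("mesh resolution (", mesh$meta$resolution,
            " A) is coarser than the high preset; contact percentages may be inaccurate")
  }
  sel <- (inside == "*" | asg$internal_element == inside) &
    (outside == "*" | asg$external_element == outside)
  if (include_reciprocal) {
    sel <- sel | ((inside == "*" | asg$external_element == inside) &
                    (outside == "*" | asg$internal_element == outside))
  }
  sub <- function(keep) {
    m2 <- mesh
    m2$vertex_area <- ifelse(keep, mesh$vertex_area, 0)
    compute_fingerprint(m2, range, bin)
  }
  matched <- sub(sel)
  rest <- sub(!sel)
  list(percent = 100 * sum(mesh$vertex_area[sel]) / sum(mesh$vertex_area),
       matched = matched, rest = rest, vertices = which(sel),
       filter = list(inside = inside, outside = outside,
                     include_reciprocal = include_reciprocal))
}

#' Contact-percentage table over all element pairs
#'
#' Percent contribution of every unordered element pair (reciprocal
#' contacts merged); percentages sum to 100.
#'
#' @param mesh A mesh with distance properties.
#' @return Data frame: `inside`, `outside`, `percent`, sorted descending.
#' @export
contact_percentages <- function(mesh) {
  asg <- mesh$meta$assignment
  if (is.null(asg)) stop("mesh lacks a contact assignment")
  a <- pmin(asg$internal_element, asg$external_element)
  b <- pmax(asg$internal_element, asg$external_element)
  pct <- tapply(mesh$vertex_area, paste(a, b), sum) * 100 / sum(mesh$vertex_area)
  pair <- strsplit(names(pct), " ")
  out <- data.frame(inside = vapply(pair, `[`, "", 1),
                    outside = vapply(pair, `[`, "", 2),
                    percent = as.numeric(pct))
  out[order(-out$percent), ]
}

## ---- deterministic plot writers ----------------------------------------

## blue -> green -> red ramp on a log-like scale with a fixed reference so
## plots of different structures are comparable
fingerprint_colors <- function(area, ref = 0.02) {
  x <- pmin(log1p(area / ref) / log1p(50), 1)
  r <- pmin(pmax(2 * x - 0.8, 0), 1)
  g <- pmin(pmax(1.6 - abs(2.4 * x - 1.3), 0), 1)
  b <- pmin(pmax(1.2 - 2.4 * x, 0), 1)
  cbind(r, g, b)
}

#' Export a fingerprint plot
#'
#' Writers emit deterministic bytes (no timestamps): PNG via a rendered
#' raster, SVG/EPS as vector rectangles.  Occupied bins are colored on a
#' fixed blue-green-red ramp; when `masked` (the greyed-out remainder from
#' [decompose_fingerprint()]) is supplied its bins render grey.
#'
#' @param fp A `fingerprint` (the highlighted part, when decomposed).
#' @param path Output path.
#' @param format `"png"`, `"svg"` or `"eps"`.
#' @param masked Optional `fingerprint` of the greyed-out bins.
#' @param pixels_per_bin PNG magnification.
#' @return `path`, invisibly.
#' @export
export_fingerprint <- function(fp, path, format = c("png", "svg", "eps"),
                               masked = NULL, pixels_per_bin = 3L) {
  format <- match.arg(format)
  if (all(fp$area == 0) && (is.null(masked) || all(masked$area == 0))) {
    stop("empty fingerprint grid")
  }
  nb <- nrow(fp$area)
  occ <- which(fp$area > 0, arr.ind = TRUE)
  cols <- fingerprint_colors(fp$area[occ])
  grey <- if (!is.null(masked)) which(masked$area > 0 & fp$area == 0, arr.ind = TRUE)
  if (format == "png") {
    img <- array(1, dim = c(nb, nb, 3))
    ## row = d_e from top; bin [i (d_i), j (d_e)] -> raster row nb+1-j, col i
    for (k in seq_len(nrow(occ))) {
      img[nb + 1 - occ[k, 2], occ[k, 1], ] <- cols[k, ]
    }
    if (!is.null(grey) && nrow(grey)) {
      for (k in seq_len(nrow(grey))) img[nb + 1 - grey[k, 2], grey[k, 1], ] <- 0.8
    }
    if (pixels_per_bin > 1) {
      idx <- rep(seq_len(nb), each = pixels_per_bin)
      img <- img[idx, idx, , drop = FALSE]
    }
    png::writePNG(img, path)
    return(invisible(path))
  }
  ## vector writers: unit = one bin, origin bottom-left, y up
  rects <- function(ind, colstr) {
    if (is.null(ind) || !nrow(ind)) return(character(0))
    sprintf(if (format == "svg")
      "<rect x='%d' y='%d' width='1' height='1' fill='%s'/>"
      else "%d %d 1 1 %s rect", ind[, 1] - 1,
      if (format == "svg") nb - ind[, 2] else ind[, 2] - 1, colstr)
  }
  colstr <- grDevices::rgb(cols[, 1], cols[, 2], cols[, 3])
  if (format == "svg") {
    lines <- c(sprintf("<svg xmlns='http://www.w3.org/2000/svg' viewBox='0 0 %d %d'>", nb, nb),
               sprintf("<rect x='0' y='0' width='%d' height='%d' fill='white'/>", nb, nb),
               rects(grey, "#cccccc"), rects(occ, colstr), "</svg>")
    writeLines(lines, path)
  } else {
    lines <- c("%!PS-Adobe-3.0 EPSF-3.0",
               sprintf("%%%%BoundingBox: 0 0 %d %d", nb, nb),
               "/rect { setrgbcolor rectfill } def",
               "1 1 1 setrgbcolor 0 0 %d %d rectfill" |> sprintf(nb, nb),
               if (!is.null(grey) && nrow(grey))
                 sprintf("%d %d 1 1 0.8 0.8 0.8 rect", grey[, 1] - 1, grey[, 2] - 1),
               sprintf("%d %d 1 1 %.3f %.3f %.3f rect", occ[, 1] - 1, occ[, 2] - 1,
                       cols[, 1], cols[, 2], cols[, 3]),
               "showpage")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Export fingerprint data as CSV
#'
#' @param fp A `fingerprint`.
#' @param path Output path.
#' @param nonzero_only Drop empty bins.
#' @return `path`, invisibly.
#' @export
write_fingerprint_csv <- function(fp, path, nonzero_only = TRUE) {
  mid <- fp$breaks[-length(fp$breaks)] + diff(fp$breaks) / 2
  ind <- if (nonzero_only) which(fp$area > 0, arr.ind = TRUE) else
    as.matrix(expand.grid(seq_along(mid), seq_along(mid)))
  d <- data.frame(d_i = mid[ind[, 1]], d_e = mid[ind[, 2]],
                  area = fp$area[ind])
  utils::write.csv(d[order(d$d_i, d$d_e), ], path, row.names = FALSE)
  invisible(path)
}
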