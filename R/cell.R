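#' Construct a unit cell
#'
#' Builds a unit-cell object with the standard crystallographic
#' orthogonalization matrix (a along x, b in the xy plane), the
#' fractional-to-Cartesian map used throughout the package.
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the 3x3 orthogonalization matrix `ortho`
#'   (fractional -> Cartesian, Angstrom), its inverse `frac` and `volume`
#'   (Angstrom^3).
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (!all(c(alpha, beta, gamma) > 0 & c(alpha, beta, gamma) < 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("cell angles are geometrically inconsistent")
  m <- matrix(c(a, 0, 0,
                b * cg, b * sg, 0,
                cx, cy, sqrt(cz2)), nrow = 3)
  cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
               ortho = m, frac = solve(m), volume = det(m))
  class(cell) <- "unit_cell"
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#' @param cell A `unit_cell`.
#' @param frac n x 3 matrix (or length-3 vector) of fractional coordinates.
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- rbind3(frac)
  frac %*% t(cell$ortho)
}

#' Cartesian to fractional coordinates
#' @param cell A `unit_cell`.
#' @param cart n x 3 matrix (or length-3 vector) of Cartesian Angstrom.
#' @return n x 3 matrix of fractional coordinates.
#' @export
cart_to_frac <- function(cell, cart) {
  cart <- rbind3(cart)
  cart %*% t(cell$frac)
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Parse a symmetry operator from its xyz string
#'
#' Accepts the usual CIF forms such as `"x,y,z"`, `"-x,-y,z"` or
#' `"1/2-y, 1/2+x, z"`.
#'
#' @param s Operator string with three comma-separated components.
#' @return A `symop`: list with integer-valued 3x3 `rot` (fractional basis)
#'   and length-3 `trans` translation vector.
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have 3 components: ", s)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    comp <- parts[i]
    ## split into signed terms
    terms <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    for (term in terms) {
      sign <- 1
      body <- term
      if (startsWith(term, "-")) { sign <- -1; body <- substring(term, 2) }
      else if (startsWith(term, "+")) body <- substring(term, 2)
      if (grepl("[xyz]", body)) {
        axis <- match(regmatches(body, regexpr("[xyz]", body)), c("x", "y", "z"))
        coefstr <- sub("\\*?[xyz]", "", body)
        coef <- if (coefstr == "") 1 else parse_fraction(coefstr)
        rot[i, axis] <- rot[i, axis] + sign * coef
      } else {
        trans[i] <- trans[i] + sign * parse_fraction(body)
      }
    }
  }
  new_symop(rot, trans)
}

parse_fraction <- function(s) {
  if (grepl("/", s)) {
    ab <- as.numeric(strsplit(s, "/")[[1]])
    ab[1] / ab[2]
  } else as.numeric(s)
}

new_symop <- function(rot, trans) {
  if (abs(abs(det(rot)) - 1) > 1e-10) {
    stop("symmetry rotation must have determinant +/-1")
  }
  op <- list(rot = rot, trans = as.numeric(trans))
  class(op) <- "symop"
  op
}

#' Format a symmetry operator as an xyz string
#' @param op A `symop`.
#' @return Character string such as `"-x+1/2, y+1/2, z+1/2"`.
#' @export
symop_to_string <- function(op) {
  axes <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    out <- ""
    for (j in 1:3) {
      cij <- op$rot[i, j]
      if (cij == 0) next
      sgn <- if (cij < 0) "-" else if (nchar(out)) "+" else ""
      mag <- if (abs(cij) == 1) "" else format(abs(cij))
      out <- paste0(out, sgn, mag, axes[j])
    }
    t <- op$trans[i]
    if (abs(t) > 1e-9) {
      fr <- format_fraction(abs(t))
      out <- paste0(out, if (t < 0) "-" else "+", fr)
    }
    if (out == "") out <- "0"
    out
  }, character(1))
  paste(comps, collapse = ", ")
}

format_fraction <- function(x) {
  if (abs(x - round(x)) < 1e-9) return(format(round(x)))
  for (den in c(2, 3, 4, 6, 8, 12)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) {
      g <- gcd2(round(num), den)
      return(paste0(round(num) / g, "/", den / g))
    }
  }
  format(x)
}

gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)

#' @export
print.symop <- function(x, ...) {
  cat("symop:", symop_to_string(x), "\n")
  invisible(x)
}

#' Compose two symmetry operators
#'
#' Returns the operator applying `b` first, then `a` (matrix convention
#' `(a*b)(x) = a(b(x))`).
#' @param a,b `symop` objects.
#' @return A `symop`.
#' @export
compose_symops <- function(a, b) {
  new_symop(a$rot %*% b$rot, as.numeric(a$rot %*% b$trans) + a$trans)
}

#' Apply a symmetry operator to fractional coordinates
#' @param op A `symop`.
#' @param frac n x 3 fractional coordinates.
#' @return n x 3 transformed fractional coordinates.
#' @export
apply_symop <- function(op, frac) {
  frac <- rbind3(frac)
  sweep(frac %*% t(op$rot), 2, op$trans, `+`)
}

symop_key <- function(op, mod_trans = TRUE) {
  t <- op$trans
  if (mod_trans) {
    t <- t %% 1
    t[abs(t - 1) < 1e-9] <- 0
  }
  paste(c(sprintf("%.0f", op$rot), sprintf("%.6f", t)), collapse = ",")
}

#' Check group closure of a symmetry-operator set
#'
#' Verifies that the set is closed under composition (translations compared
#' modulo lattice vectors) and contains the identity.
#' @param ops List of `symop` objects.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
check_symop_closure <- function(ops) {
  keys <- vapply(ops, symop_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate symmetry operators")
  id <- symop_key(new_symop(diag(3), c(0, 0, 0)))
  if (!id %in% keys) stop("identity operator missing")
  for (a in ops) for (b in ops) {
    if (!symop_key(compose_symops(a, b)) %in% keys) {
      stop("operator set not closed under composition: (",
           symop_to_string(a), ") o (", symop_to_string(b), ")")
    }
  }
  invisible(TRUE)
}
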