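## Minimal CIF 1.1 reader covering the core-dictionary tags needed to build
## a crystal: cell lengths/angles, symmetry operators (explicit xyz loop or
## a Hermann-Mauguin symbol resolvable through the internal table below) and
## the atom-site loop.  Semicolon text fields are skipped as opaque blocks.

#' Read a crystal structure from a CIF file
#'
#' Parses cell parameters, symmetry operators and asymmetric-unit atom
#' sites.  Symmetry is taken from `_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`; when only a Hermann-Mauguin symbol is
#' present it is resolved through a small internal table of common space
#' groups.  Disordered structures keep the highest-occupancy disorder
#' component; sites still below 0.5 occupancy are dropped with a warning.
#'
#' @param path Path to a CIF file.
#' @param name Optional identifier; defaults to the CIF data block name.
#' @return A `crystal` object (see [crystal()]).
#' @export
read_cif <- function(path, name = NULL) {
  if (!file.exists(path)) stop("CIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- parse_cif_block(lines)
  tags <- parsed$tags
  loops <- parsed$loops

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  missing <- need[!need %in% names(tags)]
  if (length(missing)) stop("CIF parse error: missing tag(s) ", paste(missing, collapse = ", "))
  num <- function(tag) cif_numeric(tags[[tag]])
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"), num("_cell_length_c"),
                    num("_cell_angle_alpha"), num("_cell_angle_beta"), num("_cell_angle_gamma"))

  symops <- cif_symops(tags, loops)
  atoms <- cif_atoms(loops)
  if (is.null(name)) name <- if (nzchar(parsed$block)) parsed$block else basename(path)
  crystal(cell, symops, atoms, name = name)
}

cif_numeric <- function(x) {
  ## strip s.u. parentheses: "5.578(3)" -> 5.578
  as.numeric(sub("\\(.*\\)$", "", x))
}

parse_cif_block <- function(lines) {
  lines <- sub("#.*$", "", lines)
  tags <- list(); loops <- list(); block <- ""
  i <- 1L; n <- length(lines)
  next_nonblank <- function(i) { while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L; i }
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (startsWith(line, ";")) {  # skip semicolon text field
      i <- i + 1L
      while (i <= n && !startsWith(trimws(lines[i]), ";")) i <- i + 1L
      i <- i + 1L; next
    }
    if (grepl("^data_", line)) { block <- sub("^data_", "", line); i <- i + 1L; next }
    if (tolower(line) == "loop_") {
      i <- i + 1L
      hdr <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        hdr <- c(hdr, strsplit(trimws(lines[i]), "[[:space:]]+")[[1]][1])
        i <- i + 1L
      }
      rows <- list()
      buf <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2)) { i <- i + 1L; next }
        if (grepl("^(_|loop_|data_)", l2, ignore.case = TRUE)) break
        buf <- c(buf, cif_tokens(l2))
        while (length(buf) >= length(hdr)) {
          rows[[length(rows) + 1L]] <- buf[seq_along(hdr)]
          buf <- buf[-seq_along(hdr)]
        }
        i <- i + 1L
      }
      if (length(rows)) {
        m <- do.call(rbind, rows)
        colnames(m) <- tolower(hdr)
        loops[[length(loops) + 1L]] <- m
      }
      next
    }
    if (startsWith(line, "_")) {
      toks <- cif_tokens(line)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        tags[[tag]] <- paste(toks[-1], collapse = " ")
      } else {
        i <- i + 1L
        i <- next_nonblank(i)
        if (i <= n) {
          l2 <- trimws(lines[i])
          if (startsWith(l2, ";")) {
            val <- character(0); i <- i + 1L
            while (i <= n && !startsWith(trimws(lines[i]), ";")) {
              val <- c(val, lines[i]); i <- i + 1L
            }
            tags[[tag]] <- paste(val, collapse = "\n")
          } else tags[[tag]] <- cif_tokens(l2)[1]
        }
      }
      i <- i + 1L; next
    }
    i <- i + 1L
  }
  list(tags = tags, loops = loops, block = block)
}

cif_tokens <- function(line) {
  toks <- character(0)
  rest <- line
  while (nzchar(rest <- trimws(rest, which = "left"))) {
    first <- substring(rest, 1, 1)
    if (first %in% c("'", "\"")) {
      end <- regexpr(paste0(first, "([[:space:]]|$)"), substring(rest, 2))
      if (end < 0) { toks <- c(toks, substring(rest, 2)); rest <- "" }
      else {
        toks <- c(toks, substring(rest, 2, end))
        rest <- substring(rest, end + 2)
      }
    } else {
      sp <- regexpr("[[:space:]]", rest)
      if (sp < 0) { toks <- c(toks, rest); rest <- "" }
      else { toks <- c(toks, substring(rest, 1, sp - 1)); rest <- substring(rest, sp) }
    }
  }
  toks
}

cif_symops <- function(tags, loops) {
  symtags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  for (lp in loops) {
    hit <- intersect(symtags, colnames(lp))
    if (length(hit)) {
      return(lapply(lp[, hit[1]], parse_symop))
    }
  }
  ## single-value form (P1 CIFs sometimes give one op outside a loop)
  for (tg in symtags) if (!is.null(tags[[tg]])) return(list(parse_symop(tags[[tg]])))
  hm <- tags[["_symmetry_space_group_name_h-m"]] %||%
    tags[["_space_group_name_h-m_alt"]]
  if (!is.null(hm)) return(spacegroup_symops(hm))
  stop("CIF parse error: no symmetry operators (tags ",
       paste(symtags, collapse = " / "), ") and no resolvable H-M symbol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Internal table of common space groups: H-M symbol -> generators as xyz
## strings (full operator lists).
SPACEGROUP_TABLE <- list(
  "P 1" = c("x,y,z"),
  "P -1" = c("x,y,z", "-x,-y,-z"),
  "P 21" = c("x,y,z", "-x,y+1/2,-z"),
  "P 21/c" = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
  "P 21/n" = c("x,y,z", "-x+1/2,y+1/2,-z+1/2", "-x,-y,-z", "x+1/2,-y+1/2,z+1/2"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "P n a 21" = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y+1/2,z", "-x+1/2,y+1/2,z+1/2"),
  "P -4 21 m" = c("x,y,z", "-x,-y,z", "y,-x,-z", "-y,x,-z",
                  "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z",
                  "-y+1/2,-x+1/2,z", "y+1/2,x+1/2,z"),
  "C 2/c" = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
              "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
              "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2"),
  "P b c a" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z",
                "-x,-y,-z", "x+1/2,y,-z+1/2", "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z")
)

spacegroup_symops <- function(hm) {
  key <- toupper(gsub("[[:space:]]+", " ", trimws(hm)))
  key <- sub("^([A-Z])([^ ])", "\\1 \\2", key)  # "Pna21" -> "P NA21" guard below
  names(SPACEGROUP_TABLE) <- toupper(names(SPACEGROUP_TABLE))
  squash <- function(s) gsub(" ", "", s)
  idx <- match(squash(key), vapply(names(SPACEGROUP_TABLE), squash, ""))
  if (is.na(idx)) {
    stop("space-group symbol not in the internal table: '", hm,
         "'; supply explicit _symmetry_equiv_pos_as_xyz operators")
  }
  lapply(SPACEGROUP_TABLE[[idx]], parse_symop)
}

cif_atoms <- function(loops) {
  at <- NULL
  for (lp in loops) {
    if ("_atom_site_fract_x" %in% colnames(lp)) { at <- lp; break }
  }
  if (is.null(at)) stop("CIF parse error: missing atom-site loop (_atom_site_fract_x)")
  col <- function(tag, default = NULL) {
    if (tag %in% colnames(at)) at[, tag] else default
  }
  label <- col("_atom_site_label", paste0("X", seq_len(nrow(at))))
  elem <- col("_atom_site_type_symbol")
  if (is.null(elem)) elem <- sub("^([A-Za-z]{1,2}).*$", "\\1", label)
  elem <- normalize_element(elem)
  frac <- cbind(cif_numeric(col("_atom_site_fract_x")),
                cif_numeric(col("_atom_site_fract_y")),
                cif_numeric(col("_atom_site_fract_z")))
  occ <- col("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(at)) else {
    o <- cif_numeric(occ); o[is.na(o)] <- 1; o
  }
  keep <- rep(TRUE, nrow(at))
  dg <- col("_atom_site_disorder_group")
  if (!is.null(dg)) {
    dg <- sub("^-", "", dg)
    real <- !dg %in% c(".", "?", "", NA)
    if (any(real)) {
      grp_occ <- tapply(occ[real], dg[real], mean)
      best <- names(grp_occ)[which.max(grp_occ)]
      keep[real] <- dg[real] == best
    }
  }
  low <- keep & occ < 0.5
  if (any(low)) {
    warning("dropping ", sum(low), " atom site(s) with occupancy < 0.5")
    keep <- keep & !low
  }
  data.frame(element = elem[keep], label = label[keep],
             fx = frac[keep, 1], fy = frac[keep, 2], fz = frac[keep, 3],
             occupancy = occ[keep], stringsAsFactors = FALSE)
}

normalize_element <- function(elem) {
  elem <- sub("^([A-Za-z]+).*$", "\\1", elem)
  paste0(toupper(substring(elem, 1, 1)), tolower(substring(elem, 2)))
}

#' Write a minimal CIF file
#'
#' Emits the core tags read back by [read_cif()]; used by the fixture
#' generator and for round-trip debugging.
#'
#' @param cell A `unit_cell`.
#' @param symops List of `symop` objects.
#' @param atoms Data frame with columns `element`, `label`, `fx`, `fy`,
#'   `fz` and optionally `occupancy`.
#' @param path Output path.
#' @param name Data block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(cell, symops, atoms, path, name = "fixture") {
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_%s", name)
  w("_cell_length_a    %.6f", cell$a)
  w("_cell_length_b    %.6f", cell$b)
  w("_cell_length_c    %.6f", cell$c)
  w("_cell_angle_alpha %.6f", cell$alpha)
  w("_cell_angle_beta  %.6f", cell$beta)
  w("_cell_angle_gamma %.6f", cell$gamma)
  w("loop_")
  w("_symmetry_equiv_pos_as_xyz")
  for (op in symops) w("  '%s'", symop_to_string(op))
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  w("_atom_site_occupancy")
  for (k in seq_len(nrow(atoms))) {
    w("  %-6s %-2s %10.6f %10.6f %10.6f %6.4f", atoms$label[k], atoms$element[k],
      atoms$fx[k], atoms$fy[k], atoms$fz[k], atoms$occupancy[k])
  }
  invisible(path)
}
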