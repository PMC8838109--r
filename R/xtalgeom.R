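# Minimal core-CIF reader: cell block, symmetry operator loop, atom_site
# loop. Covers the dialect written by write_cif() plus standard CSD-style
# files with _symmetry_equiv_pos_as_xyz / _space_group_symop_operation_xyz.

.cif_tokens <- function(line) {
  # split on whitespace, honoring single/double quoted tokens
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character())
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

.cif_number <- function(x) as.numeric(sub("\\(.*\\)$", "", x))  # strip esds

.parse_symop <- function(op) {
  # "x, 1/2+y, -z" -> function on an Nx3 fractional matrix
  parts <- strsplit(tolower(gsub("\\s", "", op)), ",")[[1]]
  if (length(parts) != 3) stop_invalid("cannot parse symmetry operator '%s'", op)
  exprs <- lapply(parts, function(p) parse(text = p)[[1]])
  function(frac) {
    env <- list(x = frac[, 1], y = frac[, 2], z = frac[, 3])
    out <- vapply(exprs, function(e) eval(e, env), numeric(nrow(frac)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
    out %% 1
  }
}

.read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  get_item <- function(tag) {
    i <- grep(paste0("^", tag, "\\b"), lines)
    if (!length(i)) return(NA)
    tok <- .cif_tokens(lines[i[1]])
    if (length(tok) < 2) return(NA)
    tok[2]
  }
  cellv <- unname(vapply(c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                           "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"),
                         function(t) .cif_number(get_item(t)), numeric(1)))
  if (any(is.na(cellv))) stop_invalid("CIF %s is missing cell parameters", path)

  # loops: collect header tags and data rows
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^loop_", lines[i])) {
      j <- i + 1
      tags <- character()
      while (j <= length(lines) && grepl("^_", lines[j])) {
        tags <- c(tags, .cif_tokens(lines[j])[1]); j <- j + 1
      }
      rows <- list()
      while (j <= length(lines) && !grepl("^(loop_|_|data_)", lines[j])) {
        rows[[length(rows) + 1]] <- .cif_tokens(lines[j]); j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      i <- j
    } else i <- i + 1
  }
  find_loop <- function(tag_re) {
    for (lp in loops) if (any(grepl(tag_re, lp$tags))) return(lp)
    NULL
  }
  sym_lp <- find_loop("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz")
  symops <- "x, y, z"
  if (!is.null(sym_lp)) {
    col <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", sym_lp$tags)
    ops <- vapply(sym_lp$rows, function(r) r[col], character(1))
    if (length(ops)) symops <- ops
  }
  at_lp <- find_loop("_atom_site_fract_x")
  sites <- NULL
  if (!is.null(at_lp)) {
    tg <- at_lp$tags
    pick <- function(t) match(t, tg)
    ix <- pick("_atom_site_fract_x"); iy <- pick("_atom_site_fract_y")
    iz <- pick("_atom_site_fract_z")
    il <- pick("_atom_site_label"); ie <- pick("_atom_site_type_symbol")
    rows <- Filter(function(r) length(r) >= max(ix, iy, iz, na.rm = TRUE), at_lp$rows)
    lab <- vapply(rows, function(r) if (!is.na(il)) r[il] else NA_character_, character(1))
    elem <- vapply(rows, function(r) if (!is.na(ie)) r[ie] else NA_character_, character(1))
    if (all(is.na(elem))) elem <- gsub("[0-9']+.*$", "", lab)
    sites <- data.frame(
      element = gsub("[^A-Za-z].*$", "", elem),
      x = vapply(rows, function(r) .cif_number(r[ix]), numeric(1)),
      y = vapply(rows, function(r) .cif_number(r[iy]), numeric(1)),
      z = vapply(rows, function(r) .cif_number(r[iz]), numeric(1)),
      label = if (all(is.na(lab))) paste0(elem, seq_along(elem)) else lab)
  }
  list(cell = cellv, symops = symops, sites = sites)
}

#' Read a crystal structure into a unit cell
#'
#' Reads a CIF (core dictionary subset: cell, symmetry-operator loop,
#' atom_site loop) or a PDB file (fixed-column CRYST1 + ATOM/HETATM
#' records). Symmetry is expanded to P1: every operator is applied to
#' every site and duplicates closer than `merge_tol` Angstrom are merged.
#'
#' @param path file path.
#' @param format `"cif"` or `"pdb"`; guessed from the extension by default.
#' @param merge_tol duplicate-merge distance, Angstrom.
#' @return a [unit_cell()] in P1.
#' @export
read_structure <- function(path, format = c("auto", "cif", "pdb"), merge_tol = 0.3) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "cif"
  if (format == "cif") {
    parsed <- .read_cif(path)
    cell <- unit_cell(parsed$cell[1], parsed$cell[2], parsed$cell[3],
                      parsed$cell[4], parsed$cell[5], parsed$cell[6])
    sites <- parsed$sites
    if (!is.null(sites) && nrow(sites)) {
      frac <- as.matrix(sites[, c("x", "y", "z")]) %% 1
      allfrac <- list(); allmeta <- list()
      for (op in parsed$symops) {
        f <- .parse_symop(op)(frac)
        allfrac[[length(allfrac) + 1]] <- f
        allmeta[[length(allmeta) + 1]] <- sites[, c("element", "label")]
      }
      frac_all <- do.call(rbind, allfrac)
      meta_all <- do.call(rbind, allmeta)
      keep <- .dedupe_sites(frac_all, cell, merge_tol)
      sites <- data.frame(element = meta_all$element[keep],
                          x = frac_all[keep, 1], y = frac_all[keep, 2],
                          z = frac_all[keep, 3])
      sites$label <- make.unique(meta_all$label[keep])
    }
    return(unit_cell(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                     sites = sites))
  }
  # PDB: fixed-column CRYST1 + ATOM/HETATM records
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)[1]
  if (is.na(cr)) stop_invalid("PDB %s has no CRYST1 record", path)
  num <- function(s, a, b) as.numeric(substr(s, a, b))
  cell <- unit_cell(num(cr, 7, 15), num(cr, 16, 24), num(cr, 25, 33),
                    num(cr, 34, 40), num(cr, 41, 47), num(cr, 48, 54))
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  xyz <- cbind(vapply(at, num, numeric(1), 31, 38),
               vapply(at, num, numeric(1), 39, 46),
               vapply(at, num, numeric(1), 47, 54))
  elem <- trimws(substr(at, 77, 78))
  lab <- trimws(substr(at, 13, 16))
  elem[!nzchar(elem)] <- gsub("[^A-Za-z].*", "", lab[!nzchar(elem)])
  M <- cell_matrix(cell)
  frac <- t(solve(M) %*% t(xyz)) %% 1
  # title-case element symbols (PDB uses upper case)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  sites <- data.frame(element = elem, x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      label = make.unique(lab))
  unit_cell(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma, sites = sites)
}

# internal: indices of sites to keep after merging periodic duplicates
.dedupe_sites <- function(frac, cell, tol) {
  n <- nrow(frac)
  keep <- rep(TRUE, n)
  if (n < 2) return(which(keep))
  M <- cell_matrix(cell)
  for (i in 2:n) {
    if (!keep[i]) next
    d <- frac[seq_len(i - 1), , drop = FALSE][keep[seq_len(i - 1)], , drop = FALSE]
    dd <- sweep(d, 2, frac[i, ])
    dd <- dd - round(dd)                       # minimum image in fractional space
    cart <- dd %*% t(M)
    if (any(sqrt(rowSums(cart^2)) < tol)) keep[i] <- FALSE
  }
  which(keep)
}

#' Unit-cell volume
#'
#' Triclinic closed form
#' `V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param cell a [unit_cell()].
#' @return volume, cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta)); cg <- cos(deg2rad(cell$gamma))
  cell$a * cell$b * cell$c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Periodic interatomic contacts
#'
#' All element-A ... element-B pairs whose minimum-image periodic distance
#' is at most `cutoff`, each reported once with the lattice-image shift of
#' the closest image. Images are enumerated far enough to cover the cutoff
#' in oblique cells.
#'
#' @param cell a [unit_cell()].
#' @param elem_a,elem_b element symbols.
#' @param cutoff maximum distance, Angstrom.
#' @return data.frame (class `contact_list`) with `label_a`, `label_b`,
#'   `shift_a`, `shift_b`, `shift_c` (integer image shift applied to site
#'   b) and `dist_A`. Empty (with a message) when an element is absent.
#' @export
contacts <- function(cell, elem_a = "O", elem_b = "O", cutoff = 3.2) {
  stopifnot(inherits(cell, "unit_cell"))
  s <- cell$sites
  ia <- which(s$element == elem_a)
  ib <- which(s$element == elem_b)
  empty <- data.frame(label_a = character(), label_b = character(),
                      shift_a = integer(), shift_b = integer(),
                      shift_c = integer(), dist_A = numeric())
  class(empty) <- c("contact_list", "data.frame")
  if (!length(ia) || !length(ib)) {
    message(sprintf("no %s-%s pairs: element absent from the cell", elem_a, elem_b))
    return(empty)
  }
  M <- cell_matrix(cell)
  # image range sufficient for the cutoff along each axis
  perp <- abs(diag(solve(M)))  # rows of inverse give reciprocal axes; conservative
  nimg <- pmax(1, ceiling(cutoff * apply(abs(solve(M)), 1, max)))
  grid <- expand.grid(i = -nimg[1]:nimg[1], j = -nimg[2]:nimg[2], k = -nimg[3]:nimg[3])
  out <- list()
  same <- identical(elem_a, elem_b)
  for (p in ia) for (q in ib) {
    if (same && q < p) next
    df <- c(s$x[q], s$y[q], s$z[q]) - c(s$x[p], s$y[p], s$z[p])
    shifts <- as.matrix(grid)
    dd <- sweep(shifts, 2, -df)  # df + shift
    cart <- dd %*% t(M)
    dist <- sqrt(rowSums(cart^2))
    if (p == q) dist[shifts[, 1] == 0 & shifts[, 2] == 0 & shifts[, 3] == 0] <- Inf
    m <- which.min(dist)
    if (dist[m] <= cutoff) {
      out[[length(out) + 1]] <- data.frame(
        label_a = s$label[p], label_b = s$label[q],
        shift_a = shifts[m, 1], shift_b = shifts[m, 2], shift_c = shifts[m, 3],
        dist_A = dist[m])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  class(res) <- c("contact_list", "data.frame")
  res
}

# internal: signed margin of grid points to the nearest exclusion surface,
# min over atoms and periodic images of (distance - vdW - probe), Angstrom
.void_margin <- function(pts, sites, radii, probe_radius, M) {
  margin <- rep(Inf, nrow(pts))
  rmax <- max(radii[sites$element]) + probe_radius
  nimg <- pmax(1, ceiling(rmax * apply(abs(solve(M)), 1, max)))
  img <- as.matrix(expand.grid(i = -nimg[1]:nimg[1], j = -nimg[2]:nimg[2],
                               k = -nimg[3]:nimg[3]))
  for (a in seq_len(nrow(sites))) {
    rex <- radii[[sites$element[a]]] + probe_radius
    fa <- c(sites$x[a], sites$y[a], sites$z[a])
    for (m in seq_len(nrow(img))) {
      d <- sweep(pts, 2, fa + img[m, ]) %*% t(M)
      margin <- pmin(margin, sqrt(rowSums(d^2)) - rex)
    }
  }
  margin
}

#' Probe-occupiable void fraction of a unit cell
#'
#' Fraction of the cell volume whose points lie farther than
#' `vdW(element) + probe_radius` from every atom (periodic images
#' included), estimated on a regular fractional grid. Points closer to an
#' exclusion surface than half a grid-cell diagonal are refined once on a
#' 2 x 2 x 2 subgrid, so the boundary is resolved at twice the nominal
#' resolution.
#'
#' @param cell a [unit_cell()].
#' @param probe_radius probe radius, Angstrom.
#' @param grid_spacing target grid spacing, Angstrom; must be at most
#'   `probe_radius / 2` for adequate resolution.
#' @param radii_set vdW radii set name or named vector (see [vdw_radii()]).
#' @return object of class `void_result`: list with `fraction` (percent),
#'   `probe_radius`, `grid_spacing`, `n_grid`.
#' @export
void_fraction <- function(cell, probe_radius = 0.6, grid_spacing = 0.2,
                          radii_set = "bondi") {
  stopifnot(inherits(cell, "unit_cell"))
  if (grid_spacing > probe_radius / 2)
    stop_invalid("grid_spacing %g A too coarse for probe radius %g A (need <= probe/2)",
                 grid_spacing, probe_radius)
  radii <- vdw_radii(radii_set)
  s <- cell$sites
  M <- cell_matrix(cell)
  nd <- pmax(2L, ceiling(c(cell$a, cell$b, cell$c) / grid_spacing))
  gx <- (seq_len(nd[1]) - 0.5) / nd[1]
  gy <- (seq_len(nd[2]) - 0.5) / nd[2]
  gz <- (seq_len(nd[3]) - 0.5) / nd[3]
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  if (nrow(s) == 0) {
    return(structure(list(fraction = 100, probe_radius = probe_radius,
                          grid_spacing = grid_spacing, n_grid = nrow(pts)),
                     class = "void_result"))
  }
  margin <- .void_margin(pts, s, radii, probe_radius, M)
  # half diagonal of one grid cell in Cartesian space
  half_diag <- 0.5 * sqrt(sum((M %*% (1 / nd))^2))
  sure_free <- margin > half_diag
  sure_hit <- margin < -half_diag
  unsure <- which(!sure_free & !sure_hit)
  n_free <- sum(sure_free)
  if (length(unsure)) {
    off <- as.matrix(expand.grid(x = c(-0.25, 0.25), y = c(-0.25, 0.25),
                                 z = c(-0.25, 0.25)))
    sub_free <- 0
    for (o in seq_len(nrow(off))) {
      sub <- sweep(pts[unsure, , drop = FALSE], 2, off[o, ] / nd, "+")
      sub_free <- sub_free + sum(.void_margin(sub, s, radii, probe_radius, M) > 0)
    }
    n_free <- n_free + sub_free / 8
  }
  structure(list(fraction = 100 * n_free / nrow(pts), probe_radius = probe_radius,
                 grid_spacing = grid_spacing, n_grid = nrow(pts)),
            class = "void_result")
}

#' @export
print.void_result <- function(x, ...) {
  cat(sprintf("<void_result> %.2f%% of cell volume free to a %.2g A probe (%d grid points, %.2g A spacing)\n",
              x$fraction, x$probe_radius, x$n_grid, x$grid_spacing))
  invisible(x)
}
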