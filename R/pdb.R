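# Atomic structures: PDB input (via bio3d) and a Gaussian-density
# isosurface standing in for the solvent-excluded molecular surface.

# van der Waals radii (Angstrom) for the elements that matter here;
# anything unknown falls back to 1.7 (carbon-like)
VDW_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               SE = 1.9, FE = 1.5, ZN = 1.39, MG = 1.73, CA = 2.31)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(trimws(element))]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM and HETATM records of the first model. Alternate locations
#' other than `' '` or `'A'` are dropped. For every chain the first and last
#' alpha-carbon (CA) in record order are identified; these serve as the
#' N- and C-terminus attachment points for connectors.
#'
#' @param path path to a PDB file.
#' @return An object of class `atomic_structure`: a list with `atoms` (a
#'   data frame with `element`, `chain`, `resno`, `name`, `x`, `y`, `z`) and
#'   `termini` (per chain, the atom row indices of the first and last CA).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("empty structure: no ATOM records in ",
                                           path, call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty structure: no ATOM records in ", path, call. = FALSE)
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no ATOM records in ", path, call. = FALSE)
  elem <- toupper(trimws(at$elesy))
  # fall back to the first letter of the atom name when the element column
  # is blank (common in hand-written fixtures)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- toupper(substr(trimws(at$elety[blank]), 1, 1))
  atoms <- data.frame(element = elem,
                      chain = as.character(at$chain),
                      resno = at$resno,
                      name = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  chains <- unique(atoms$chain)
  termini <- lapply(chains, function(ch) {
    ca <- which(atoms$chain == ch & atoms$name == "CA" & atoms$element == "C")
    if (length(ca) == 0) return(NULL)
    list(first_ca = ca[1], last_ca = ca[length(ca)])
  })
  names(termini) <- chains
  termini <- termini[!vapply(termini, is.null, logical(1))]
  structure(list(atoms = atoms, termini = termini), class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("<atomic structure> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Terminal alpha-carbon coordinate of a chain
#'
#' @param structure an `atomic_structure`.
#' @param chain chain identifier.
#' @param terminus `"N"` (first CA in record order) or `"C"` (last CA).
#' @return The CA coordinate as a 3-vector (Angstrom, structure frame).
#' @export
terminus_position <- function(structure, chain, terminus = c("N", "C")) {
  terminus <- match.arg(terminus)
  ti <- structure$termini[[as.character(chain)]]
  if (is.null(ti)) stop("chain ", chain, " has no CA atoms", call. = FALSE)
  i <- if (terminus == "N") ti$first_ca else ti$last_ca
  as.numeric(structure$atoms[i, c("x", "y", "z")])
}

#' Approximate molecular surface from atom positions
#'
#' Builds a Gaussian-density field
#' `sum_i exp(-(|p - c_i|^2 - (r_i + probe)^2) / sigma^2)` on a regular grid
#' and extracts the level-1 isosurface with marching tetrahedra. For a single
#' atom the surface sits at radius `r_vdw + probe`; overlapping atoms blend
#' smoothly. This is a deliberately simple, closed-surface approximation to
#' the solvent-excluded surface, adequate for rigid-body layout and
#' collision work, not for surface-area chemistry.
#'
#' @param structure an `atomic_structure`.
#' @param probe_radius probe sphere radius (Angstrom), default 1.4 (water).
#' @param grid_spacing grid step (Angstrom), default 0.5.
#' @param sigma blending length (Angstrom) controlling how smoothly
#'   neighbouring atoms merge.
#' @return A watertight `triangle_mesh` enclosing all atom centers.
#' @export
surface_from_atoms <- function(structure, probe_radius = 1.4,
                               grid_spacing = 0.5, sigma = 1.0) {
  atoms <- structure$atoms
  if (nrow(atoms) < 1) stop("structure has no atoms", call. = FALSE)
  if (grid_spacing <= 0) stop("grid_spacing must be positive", call. = FALSE)
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- vdw_radius(atoms$element) + probe_radius

  pad <- max(radii) + 3 * sigma
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / grid_spacing)) + 1L)
  gx <- lo[1] + grid_spacing * (seq_len(dims[1]) - 1)
  gy <- lo[2] + grid_spacing * (seq_len(dims[2]) - 1)
  gz <- lo[3] + grid_spacing * (seq_len(dims[3]) - 1)

  vals <- numeric(prod(dims))
  # accumulate per atom over its local support only
  for (i in seq_len(nrow(centers))) {
    ci <- centers[i, ]; Ri <- radii[i]
    reach <- Ri + 3 * sigma
    ix <- which(abs(gx - ci[1]) <= reach)
    iy <- which(abs(gy - ci[2]) <= reach)
    iz <- which(abs(gz - ci[3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - ci[1])^2
    dy2 <- (gy[iy] - ci[2])^2
    dz2 <- (gz[iz] - ci[3])^2
    block <- exp(-(outer(outer(dx2, dy2, "+"), dz2, "+") - Ri^2) / sigma^2)
    idx <- as.vector(outer(outer(ix, (iy - 1L) * dims[1], "+"),
                           (iz - 1L) * dims[1] * dims[2], "+"))
    vals[idx] <- vals[idx] + as.vector(block)
  }

  iso <- marching_tets_cpp(vals, dims, lo, grid_spacing, 1.0)
  if (nrow(iso$faces) == 0)
    stop("degenerate surface: grid too coarse to resolve any atom", call. = FALSE)
  mesh_new(iso$vertices, iso$faces)
}
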