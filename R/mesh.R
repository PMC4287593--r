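# Triangle meshes: construction, synthetic fixtures, Wavefront OBJ I/O,
# oriented bounding boxes and a few mesh diagnostics.  Vertices are n x 3
# matrices in Angstrom; faces are m x 3 integer matrices of 1-based vertex
# indices (the native R convention; the OBJ format on disk is also 1-based).

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (Angstrom).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
mesh_new <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]))
      stop("degenerate face: repeated vertex index", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Transform a mesh by a rigid transform
#' @param mesh a `triangle_mesh`.
#' @param T a `rigid_transform`.
#' @return The transformed mesh.
#' @export
mesh_transform <- function(mesh, T) {
  mesh_new(rt_apply(T, mesh$vertices), mesh$faces)
}

#' Signed mesh volume by the divergence theorem
#'
#' Exact for closed, consistently outward-oriented meshes.
#'
#' @param mesh a `triangle_mesh`.
#' @return Volume in cubic Angstrom (negative if orientation is inward).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Connected components of a mesh
#' @param mesh a `triangle_mesh`.
#' @return Number of vertex-connected components among faces.
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    a <- find(f[1]); b <- find(f[2]); c <- find(f[3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  used <- unique(as.integer(mesh$faces))
  length(unique(vapply(used, find, integer(1))))
}

# TRUE when every undirected edge is shared by exactly two faces
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# ---- synthetic fixtures ---------------------------------------------------

# evaluate `code` under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_sphere <- function(v, f) {
  edge_mid <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- edge_mid[[key]]
    if (!is.null(id)) return(id)
    m <- (verts[[i]] + verts[[j]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1]] <<- m
    id <- length(verts)
    edge_mid[[key]] <- id
    id
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  r <- 1L
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[r, ] <- c(a, ab, ca)
    newf[r + 1L, ] <- c(b, bc, ab)
    newf[r + 2L, ] <- c(c, ca, bc)
    newf[r + 3L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = do.call(rbind, verts), faces = newf)
}

unit_icosphere <- function(subdivisions) {
  s <- icosahedron()
  for (i in seq_len(subdivisions)) s <- subdivide_sphere(s$vertices, s$faces)
  s
}

#' Generate a synthetic surface fixture
#'
#' Deterministic stand-ins for molecular surfaces: an icosphere, a scaled
#' ellipsoid, or a seeded random "blob" (an ellipsoid with a smooth random
#' radial perturbation, mimicking a lumpy protein surface).
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"blob"`.
#' @param radius sphere radius (Angstrom).
#' @param semi_axes length-3 semi-axes for ellipsoid/blob (Angstrom).
#' @param subdivisions icosphere subdivision level (0 = icosahedron,
#'   each level quadruples the face count).
#' @param bumpiness relative amplitude of the blob's radial perturbation.
#' @param seed integer seed controlling the blob shape; fixtures are
#'   identical for identical seeds.
#' @return A `triangle_mesh`.
#' @export
#' @examples
#' m <- make_fixture("sphere", radius = 1, subdivisions = 2)
#' range(sqrt(rowSums(m$vertices^2)))
make_fixture <- function(kind = c("sphere", "ellipsoid", "blob"),
                         radius = 1, semi_axes = c(1.5, 1, 0.75),
                         subdivisions = 2, bumpiness = 0.12, seed = 1) {
  kind <- match.arg(kind)
  if (subdivisions < 0 || subdivisions != round(subdivisions))
    stop("subdivisions must be a non-negative integer", call. = FALSE)
  s <- unit_icosphere(subdivisions)
  if (kind == "sphere") {
    if (radius <= 0) stop("radius must be positive", call. = FALSE)
    return(mesh_new(s$vertices * radius, s$faces))
  }
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be 3 positive lengths", call. = FALSE)
  V <- sweep(s$vertices, 2, semi_axes, "*")
  if (kind == "ellipsoid") return(mesh_new(V, s$faces))
  # blob: radial scale from a few seeded cosine bumps on the unit sphere
  dirs_amp <- with_seed(seed, {
    k <- 6L
    d <- matrix(stats::rnorm(3 * k), k, 3)
    d <- d / sqrt(rowSums(d^2))
    list(dirs = d, amp = stats::runif(k, -1, 1), sharp = stats::runif(k, 2, 5))
  })
  u <- s$vertices  # unit directions
  scale <- rep(1, nrow(u))
  for (i in seq_len(nrow(dirs_amp$dirs))) {
    ca <- pmax(u %*% dirs_amp$dirs[i, ], 0)
    scale <- scale + bumpiness * dirs_amp$amp[i] * as.numeric(ca)^dirs_amp$sharp[i]
  }
  mesh_new(V * scale, s$faces)
}

# ---- Wavefront OBJ --------------------------------------------------------

#' Read / write Wavefront OBJ triangle meshes
#'
#' A minimal OBJ dialect: `v x y z` vertex lines and `f i j k` triangular
#' face lines (1-based indices, as the format specifies). Normals, texture
#' coordinates and `i/j/k`-style face references are ignored on read and
#' never written. Coordinates are written with 9 significant digits, so a
#' write/read round trip preserves topology exactly and coordinates to
#' better than 1e-8 for unit-scale meshes.
#'
#' @param path file path.
#' @return `read_obj`: a `triangle_mesh`.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  verts <- list(); faces <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    if (parts[1] == "v") {
      if (length(parts) < 4) stop("malformed vertex at line ", ln, call. = FALSE)
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(xyz))) stop("malformed vertex at line ", ln, call. = FALSE)
      verts[[length(verts) + 1L]] <- xyz
    } else if (parts[1] == "f") {
      if (length(parts) != 4) stop("malformed face at line ", ln,
                                   " (only triangles supported)", call. = FALSE)
      idx <- suppressWarnings(as.integer(sub("/.*$", "", parts[2:4])))
      if (any(is.na(idx))) stop("malformed face at line ", ln, call. = FALSE)
      faces[[length(faces) + 1L]] <- idx
    }
    # other element types (vn, vt, o, g, s, mtllib, usemtl) are skipped
  }
  if (length(verts) == 0) stop("no vertices in OBJ file: ", path, call. = FALSE)
  V <- do.call(rbind, verts)
  F <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  if (nrow(F) > 0 && (min(F) < 1L || max(F) > nrow(V)))
    stop("face index out of range in OBJ file: ", path, call. = FALSE)
  mesh_new(V, F)
}

#' @rdname read_obj
#' @param mesh a `triangle_mesh` to write.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

# ---- oriented bounding box ------------------------------------------------

#' Oriented bounding box of a mesh
#'
#' Axes are the eigenvectors of the vertex covariance matrix (principal
#' axes), ordered by decreasing eigenvalue; the box is the tight interval
#' along each axis. This is the covariance OBB common in interactive
#' graphics, not the minimum-volume box.
#'
#' @param mesh a `triangle_mesh` with at least 3 non-collinear vertices.
#' @return A list of class `oriented_bounding_box` with `center`, `axes`
#'   (columns, orthonormal, det +1) and `half_extents`.
#' @export
compute_obb <- function(mesh) {
  V <- mesh$vertices
  if (nrow(V) < 3) stop("degenerate geometry: need at least 3 vertices", call. = FALSE)
  C <- stats::cov(V)
  eg <- eigen(C, symmetric = TRUE)
  ext_scale <- max(1, max(abs(V)))
  if (eg$values[2] <= 1e-12 * max(eg$values[1], 1))
    stop("degenerate geometry: vertices are collinear", call. = FALSE)
  A <- eg$vectors
  if (det(A) < 0) A[, 3] <- -A[, 3]
  P <- V %*% A
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  center_local <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2, 1e-9 * ext_scale)
  structure(list(center = as.numeric(A %*% center_local),
                 axes = A,
                 half_extents = as.numeric(half)),
            class = "oriented_bounding_box")
}

#' @export
print.oriented_bounding_box <- function(x, ...) {
  cat("<oriented bounding box>\n")
  cat("center:      ", paste(signif(x$center, 6), collapse = " "), "\n")
  cat("half extents:", paste(signif(x$half_extents, 6), collapse = " "), "\n")
  invisible(x)
}

obb_volume <- function(obb) 8 * prod(obb$half_extents)

obb_contains <- function(obb, points, tol = 1e-6) {
  local <- sweep(points, 2, obb$center) %*% obb$axes
  all(abs(local) <= matrix(obb$half_extents + tol, nrow(local), 3, byrow = TRUE))
}
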