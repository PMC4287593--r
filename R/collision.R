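# Collision detection.  Pairwise mesh tests use an axis-aligned box tree
# built once per mesh in its local frame; at query time the relative pose is
# folded into the traversal, so moving objects never invalidates a tree.
# Scene queries implement the pose-mode filter (only pairs involving a moving
# object are tested, <= m*n tests) and the chain shortcut (n-1 tests cover
# all internal pairs of a repeated structure, because the relative pose of
# copies i and i+k is the same for every i).

#' Build a bounding volume hierarchy for a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param leaf_size maximum triangles per leaf.
#' @return An object of class `bvh` (a flat axis-aligned box tree in the
#'   mesh's local frame, plus a reference to the mesh).
#' @export
build_bvh <- function(mesh, leaf_size = 4L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("cannot build a BVH for an empty mesh", call. = FALSE)
  tree <- bvh_build_cpp(mesh$vertices, mesh$faces, as.integer(leaf_size))
  structure(list(tree = tree, mesh = mesh), class = "bvh")
}

#' @export
print.bvh <- function(x, ...) {
  cat(sprintf("<bvh> %d triangles, %d nodes\n",
              x$tree$n_faces, length(x$tree$left)))
  invisible(x)
}

# depth of the tree (root = 1), for construction diagnostics
bvh_depth <- function(bvh) {
  left <- bvh$tree$left; right <- bvh$tree$right
  depth <- integer(length(left)); depth[1] <- 1L
  # nodes are created parent-before-child, so one forward pass suffices
  for (i in seq_along(left)) {
    if (left[i] > 0) depth[left[i]] <- depth[i] + 1L
    if (right[i] > 0) depth[right[i]] <- depth[i] + 1L
  }
  max(depth)
}

#' Contacts between two posed meshes
#'
#' @param bvhA,bvhB `bvh` objects (see [build_bvh()]).
#' @param poseA,poseB `rigid_transform` world poses of the two meshes.
#' @param mode `"all"` returns every intersecting world-space triangle pair;
#'   `"first"` stops at the first contact found.
#' @return Integer matrix with columns `tri_a`, `tri_b` (1-based triangle
#'   indices); zero rows when the meshes do not intersect. Triangles that
#'   merely touch count as colliding.
#' @export
collide_pair <- function(bvhA, poseA, bvhB, poseB, mode = c("all", "first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bvhA, "bvh"), inherits(bvhB, "bvh"))
  rel <- rt_compose(rt_invert(poseA), poseB)  # B local -> A local
  out <- bvh_collide_cpp(bvhA$tree, bvhA$mesh$vertices, bvhA$mesh$faces,
                         bvhB$tree, bvhB$mesh$vertices, bvhB$mesh$faces,
                         rel$R, rel$t, mode == "first")
  colnames(out) <- c("tri_a", "tri_b")
  out
}

#' Exhaustive all-triangle-pairs contact reference
#'
#' Brute-force counterpart of [collide_pair()]: tests every triangle of A
#' against every triangle of B with no spatial culling. Quadratic in the
#' face counts; intended as an independent reference for validating the
#' tree-accelerated queries on small meshes.
#'
#' @param meshA,meshB `triangle_mesh` objects.
#' @param poseA,poseB `rigid_transform` world poses.
#' @return Integer matrix with columns `tri_a`, `tri_b`.
#' @export
collide_pair_brute <- function(meshA, poseA, meshB, poseB) {
  rel <- rt_compose(rt_invert(poseA), poseB)
  out <- tri_collide_brute_cpp(meshA$vertices, meshA$faces,
                               meshB$vertices, meshB$faces, rel$R, rel$t)
  colnames(out) <- c("tri_a", "tri_b")
  out
}

new_collision_report <- function(pairs, contacts, tests) {
  structure(list(colliding_pairs = pairs, contacts = contacts,
                 tests_performed = tests),
            class = "collision_report")
}

#' @export
print.collision_report <- function(x, ...) {
  np <- if (is.null(x$colliding_pairs)) 0L else nrow(x$colliding_pairs)
  cat(sprintf("<collision report> %d colliding pair(s), %d pair test(s)\n",
              np, x$tests_performed))
  if (np > 0) {
    for (i in seq_len(np))
      cat(sprintf("  %s -- %s (%d triangle contact(s))\n",
                  x$colliding_pairs[i, 1], x$colliding_pairs[i, 2],
                  nrow(x$contacts[[i]])))
  }
  invisible(x)
}

empty_pairs <- function() {
  data.frame(id1 = character(0), id2 = character(0), stringsAsFactors = FALSE)
}

ordered_pair <- function(a, b) if (a < b) c(a, b) else c(b, a)

#' Scene collisions with pose-mode filtering
#'
#' Tests only object pairs with at least one member in `moving_ids`;
#' everything else is static and cannot have entered a new collision. The
#' number of object-pair tests is therefore at most `m * n` for `m` moving
#' objects among `n`.
#'
#' @param scene a `scene`.
#' @param moving_ids character vector of object ids being manipulated.
#' @return A `collision_report`: `colliding_pairs` (data frame of id pairs,
#'   `id1 < id2`), `contacts` (per pair, the triangle-pair matrix, indices
#'   referring to `id1`'s and `id2`'s meshes) and `tests_performed` (number
#'   of object-pair queries).
#' @export
scene_collisions <- function(scene, moving_ids) {
  ids <- scene_object_ids(scene)
  unknown <- setdiff(moving_ids, ids)
  if (length(unknown)) stop("unknown object id(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  moving_ids <- unique(moving_ids)
  pairs <- empty_pairs()
  contacts <- list()
  tests <- 0L
  if (length(moving_ids) == 0)
    return(new_collision_report(pairs, contacts, 0L))
  seen <- character(0)
  for (m in moving_ids) {
    for (o in ids) {
      if (o == m) next
      key <- paste(ordered_pair(m, o), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      tests <- tests + 1L
      om <- scene_object(scene, m); oo <- scene_object(scene, o)
      p <- ordered_pair(m, o)
      if (identical(p[1], m)) {
        cts <- collide_pair(om$bvh, om$pose, oo$bvh, oo$pose)
      } else {
        cts <- collide_pair(oo$bvh, oo$pose, om$bvh, om$pose)
      }
      if (nrow(cts) > 0) {
        pairs <- rbind(pairs, data.frame(id1 = p[1], id2 = p[2],
                                         stringsAsFactors = FALSE))
        contacts[[length(contacts) + 1L]] <- cts
      }
    }
  }
  new_collision_report(pairs, contacts, tests)
}

#' Internal collisions of a repeated chain in n-1 pair tests
#'
#' Copies of a chain built from one inter-copy transform all stand in the
#' same relative pose to their k-th neighbour, so if copy 1 collides with
#' copy 1+k then copy i collides with copy i+k for every i — with the same
#' contact triangles. Only the n-1 pairs (1, 2), (1, 3), ..., (1, n) are
#' tested; hits are expanded to all implied pairs.
#'
#' @param chain a `crystal_chain` (see [chain_from_pair()]).
#' @return A `collision_report` whose pair ids are copy indices (1-based,
#'   as character); `tests_performed` is exactly `n - 1`.
#' @export
chain_internal_collisions <- function(chain) {
  stopifnot(inherits(chain, "crystal_chain"))
  n <- chain$n
  if (n < 2) stop("chain must have at least 2 copies", call. = FALSE)
  bvh <- chain$bvh
  pairs <- empty_pairs()
  contacts <- list()
  for (k in seq_len(n - 1)) {
    cts <- collide_pair(bvh, chain$copy_poses[[1]], bvh, chain$copy_poses[[1 + k]])
    if (nrow(cts) > 0) {
      for (i in seq_len(n - k)) {
        pairs <- rbind(pairs, data.frame(id1 = as.character(i),
                                         id2 = as.character(i + k),
                                         stringsAsFactors = FALSE))
        contacts[[length(contacts) + 1L]] <- cts
      }
    }
  }
  new_collision_report(pairs, contacts, n - 1L)
}

#' Collisions between a chain and the rest of the scene
#'
#' Every chain copy must be tested against every external object (the
#' repetition argument gives no shortcut here since external objects stand
#' in arbitrary poses relative to the copies).
#'
#' @param chain a `crystal_chain`.
#' @param scene a `scene` whose objects are external to the chain.
#' @return A `collision_report`; pair ids are `copy:<i>` vs scene object id.
#' @export
chain_external_collisions <- function(chain, scene) {
  stopifnot(inherits(chain, "crystal_chain"), inherits(scene, "scene"))
  ids <- scene_object_ids(scene)
  pairs <- empty_pairs()
  contacts <- list()
  tests <- 0L
  for (i in seq_len(chain$n)) {
    for (o in ids) {
      tests <- tests + 1L
      oo <- scene_object(scene, o)
      cts <- collide_pair(chain$bvh, chain$copy_poses[[i]], oo$bvh, oo$pose)
      if (nrow(cts) > 0) {
        pairs <- rbind(pairs, data.frame(id1 = paste0("copy:", i), id2 = o,
                                         stringsAsFactors = FALSE))
        contacts[[length(contacts) + 1L]] <- cts
      }
    }
  }
  new_collision_report(pairs, contacts, tests)
}
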