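# Crystal-by-example: a repeated structure defined by the placement of two
# example copies of a monomer.  The inter-copy transform T_AB is recovered
# from the example pair and applied repeatedly, so copy i (1-based) sits at
# T_A * T_AB^(i-1).  Editing either the example pair or T_AB regenerates the
# whole chain, which is what makes interactive exploration of helical
# packings cheap.

new_chain <- function(mesh, bvh, T_A, T_AB, n) {
  poses <- vector("list", n)
  step <- rt_identity()
  for (i in seq_len(n)) {
    poses[[i]] <- rt_compose(T_A, step)
    step <- rt_compose(step, T_AB)
  }
  structure(list(base_mesh = mesh, bvh = bvh, T_A = T_A, T_AB = T_AB,
                 n = as.integer(n), copy_poses = poses),
            class = "crystal_chain")
}

#' @export
print.crystal_chain <- function(x, ...) {
  sp <- describe_helix(x)
  cat(sprintf("<crystal chain> %d copies; repeat twist %.2f deg, rise %.3f A\n",
              x$n, sp$angle * 180 / pi, sp$rise))
  invisible(x)
}

#' Build a repeated chain from an example pair of placements
#'
#' Copy 1 takes pose `TA` and copy 2 takes pose `TB`; every further copy
#' repeats the relative transform `T_AB = TA^-1 TB`, so copy i sits at
#' `TA * T_AB^(i-1)`. A screw-like `T_AB` traces a helix (actin, fibrin,
#' microtubules all fit this description).
#'
#' @param mesh the monomer surface, a `triangle_mesh` (shared by all copies).
#' @param TA,TB `rigid_transform` world poses of the first two copies.
#' @param n total number of copies, at least 2.
#' @return An object of class `crystal_chain` with elements `base_mesh`,
#'   `T_A`, `T_AB`, `n` and `copy_poses` (list of `n` poses, 1-based copy
#'   indexing).
#' @export
#' @examples
#' m <- make_fixture("sphere", radius = 1, subdivisions = 1)
#' ch <- chain_from_pair(m, rt_identity(), rt_translation(0, 0, 27.5), n = 4)
#' vapply(ch$copy_poses, function(p) p$t[3], numeric(1))
chain_from_pair <- function(mesh, TA, TB, n) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (length(n) != 1 || n < 2 || n != round(n))
    stop("n must be an integer >= 2", call. = FALSE)
  rt_validate(TA); rt_validate(TB)
  T_AB <- rt_relative(TA, TB)
  if (rt_distance(T_AB, rt_identity()) < 1e-12)
    warning("inter-copy transform is the identity: all copies coincide")
  new_chain(mesh, build_bvh(mesh), TA, T_AB, n)
}

#' Replace the inter-copy transform of a chain
#'
#' Direct numeric entry of the repeat transform, for structures whose
#' monomer-to-monomer transform is known (e.g. from deposited helical
#' symmetry parameters) rather than placed by hand.
#'
#' @param chain a `crystal_chain`.
#' @param T_AB the new inter-copy `rigid_transform`.
#' @return The chain with all copy poses regenerated from the stored first
#'   pose and the new `T_AB`.
#' @export
set_internal_transform <- function(chain, T_AB) {
  stopifnot(inherits(chain, "crystal_chain"))
  rt_validate(T_AB)
  if (rt_distance(T_AB, rt_identity()) < 1e-12)
    warning("inter-copy transform is the identity: all copies coincide")
  new_chain(chain$base_mesh, chain$bvh, chain$T_A, T_AB, chain$n)
}

#' Move a whole chain as a unit
#'
#' Left-multiplies every copy pose by `T`; the internal structure (all
#' relative transforms between copies) is unchanged.
#'
#' @param chain a `crystal_chain`.
#' @param T a `rigid_transform` in world frame.
#' @return The moved chain.
#' @export
move_chain <- function(chain, T) {
  stopifnot(inherits(chain, "crystal_chain"))
  rt_validate(T)
  new_chain(chain$base_mesh, chain$bvh, rt_compose(T, chain$T_A),
            chain$T_AB, chain$n)
}

#' Twist and rise of a chain's repeat
#'
#' Screw decomposition of the inter-copy transform: the rotation per subunit
#' about the helix axis and the translation per subunit along it.
#'
#' @param chain a `crystal_chain`.
#' @return A `screw_parameters` object, see [screw_decompose()].
#' @export
describe_helix <- function(chain) {
  stopifnot(inherits(chain, "crystal_chain"))
  screw_decompose(chain$T_AB)
}

#' Assemble the chain into one concatenated mesh
#'
#' @param chain a `crystal_chain`.
#' @return A `triangle_mesh` containing all transformed copies.
#' @export
chain_as_mesh <- function(chain) {
  nv <- nrow(chain$base_mesh$vertices)
  V <- do.call(rbind, lapply(chain$copy_poses, function(p)
    rt_apply(p, chain$base_mesh$vertices)))
  F <- do.call(rbind, lapply(seq_len(chain$n) - 1L, function(i)
    chain$base_mesh$faces + i * nv))
  mesh_new(V, F)
}

#' Insert the copies of a chain into a scene as individual objects
#'
#' @param chain a `crystal_chain`.
#' @param scene a `scene`.
#' @param id_prefix prefix for the generated object ids (`<prefix>1`, ...).
#' @param source mesh provenance recorded on each copy, see
#'   [scene_add_object()].
#' @return The updated scene.
#' @export
chain_to_scene <- function(chain, scene, id_prefix = "copy",
                           source = list(type = "inline")) {
  for (i in seq_len(chain$n)) {
    scene <- scene_add_object(scene, chain$base_mesh,
                              id = paste0(id_prefix, i),
                              pose = chain$copy_poses[[i]], source = source)
  }
  scene
}
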