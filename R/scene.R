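# The scene: a table of rigid mesh instances with poses, colors and group
# membership, plus chains, connectors, a timeline and physics parameters.
# Everything downstream (collision queries, physics, layout, animation,
# serialization) operates on this container.

SCENE_FORMAT_VERSION <- "1.0"

#' Create an empty scene
#'
#' @param physics a list of physics parameters, see [physics_params()].
#' @return An object of class `scene`.
#' @export
scene_new <- function(physics = physics_params()) {
  structure(list(version = SCENE_FORMAT_VERSION,
                 objects = list(),
                 groups = list(),
                 chains = list(),
                 connectors = list(),
                 timeline = timeline_new(),
                 physics = physics,
                 next_id = 1L),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d object(s), %d group(s), %d chain(s), %d connector(s)\n",
              length(x$objects), length(x$groups), length(x$chains),
              length(x$connectors)))
  invisible(x)
}

fresh_id <- function(scene, prefix) {
  repeat {
    id <- paste0(prefix, scene$next_id)
    scene$next_id <- scene$next_id + 1L
    if (is.null(scene$objects[[id]]) && is.null(scene$groups[[id]]) &&
        is.null(scene$chains[[id]]) && is.null(scene$connectors[[id]]))
      break
  }
  list(scene = scene, id = id)
}

#' Add a rigid object to a scene
#'
#' @param scene a `scene`.
#' @param mesh a `triangle_mesh` (the object's surface, in its local frame).
#' @param id object identifier; generated when `NULL`.
#' @param pose a `rigid_transform` placing the object in the world.
#' @param color RGB triple in `[0, 1]` or a character data-coloring label
#'   (e.g. `"charge"`).
#' @param group id of the group the object belongs to, or `NA`.
#' @param source how to rebuild the mesh when the scene is re-loaded: a list
#'   with `type = "fixture"` (plus `kind`, `params`, `seed`) or
#'   `type = "obj"` (plus `path`); `type = "inline"` objects cannot be
#'   serialized.
#' @return The updated scene.
#' @export
scene_add_object <- function(scene, mesh, id = NULL, pose = rt_identity(),
                             color = c(1, 1, 1), group = NA_character_,
                             source = list(type = "inline")) {
  stopifnot(inherits(scene, "scene"), inherits(mesh, "triangle_mesh"))
  rt_validate(pose)
  if (is.null(id)) {
    fr <- fresh_id(scene, "obj")
    scene <- fr$scene; id <- fr$id
  } else if (!is.null(scene$objects[[id]])) {
    stop("object id already in use: ", id, call. = FALSE)
  }
  scene$objects[[id]] <- list(id = id, mesh = mesh, bvh = build_bvh(mesh),
                              pose = pose, color = color, group = group,
                              source = source)
  scene
}

#' Set the pose of a scene object
#' @param scene a `scene`.
#' @param id object id.
#' @param pose a `rigid_transform`.
#' @return The updated scene.
#' @export
scene_set_pose <- function(scene, id, pose) {
  if (is.null(scene$objects[[id]])) stop("unknown object id: ", id, call. = FALSE)
  rt_validate(pose)
  scene$objects[[id]]$pose <- pose
  scene
}

#' Object ids in a scene
#' @param scene a `scene`.
#' @return Character vector of ids.
#' @export
scene_object_ids <- function(scene) names(scene$objects)

scene_object <- function(scene, id) {
  obj <- scene$objects[[id]]
  if (is.null(obj)) stop("unknown object id: ", id, call. = FALSE)
  obj
}

#' Create a group of objects
#'
#' Groups let a set of molecules be moved, copied and keyframed as a unit.
#'
#' @param scene a `scene`.
#' @param member_ids object ids to place in the group.
#' @param id group identifier; generated when `NULL`.
#' @return The updated scene.
#' @export
scene_add_group <- function(scene, member_ids, id = NULL) {
  missing <- setdiff(member_ids, names(scene$objects))
  if (length(missing)) stop("unknown object id(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(id)) {
    fr <- fresh_id(scene, "grp")
    scene <- fr$scene; id <- fr$id
  }
  scene$groups[[id]] <- list(id = id, members = member_ids)
  for (m in member_ids) scene$objects[[m]]$group <- id
  scene
}

#' Move every object of a group by a rigid transform
#' @param scene a `scene`.
#' @param group_id group id.
#' @param T a `rigid_transform` applied on the left (in world frame).
#' @return The updated scene.
#' @export
scene_move_group <- function(scene, group_id, T) {
  grp <- scene$groups[[group_id]]
  if (is.null(grp)) stop("unknown group id: ", group_id, call. = FALSE)
  for (m in grp$members)
    scene$objects[[m]]$pose <- rt_compose(T, scene$objects[[m]]$pose)
  scene
}
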