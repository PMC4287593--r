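# Scene persistence: a human-diffable JSON project format.  Poses are 4x4
# row-major matrices; meshes are referenced by provenance (fixture spec or
# OBJ path), never inlined.  Unknown keys and dangling id references are
# rejected with named errors so a mistyped project file fails loudly.

OBJECT_KEYS <- c("id", "source", "pose", "color", "group")
SCENE_KEYS <- c("version", "objects", "groups", "chains", "connectors",
                "timeline", "physics")
CONNECTOR_KEYS <- c("id_a", "id_b", "point_a", "point_b", "stiffness",
                    "rest_length", "mode")
CHAIN_KEYS <- c("id", "base", "T_AB", "n")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
}

pose_to_json <- function(T) as.numeric(t(rt_to_matrix(T)))  # row-major

pose_from_json <- function(v) {
  if (length(v) != 16) stop("pose must be a 16-element row-major 4x4 matrix",
                            call. = FALSE)
  rt_from_matrix(matrix(as.numeric(v), 4, 4, byrow = TRUE))
}

scene_to_document <- function(scene) {
  objects <- lapply(scene$objects, function(o) {
    if (identical(o$source$type, "inline"))
      stop("object ", o$id, " has an inline mesh and cannot be serialized; ",
           "give it a fixture or obj source", call. = FALSE)
    list(id = o$id, source = o$source, pose = pose_to_json(o$pose),
         color = o$color, group = o$group)
  })
  chains <- lapply(scene$chains, function(ch)
    list(id = ch$id, base = ch$base, T_AB = pose_to_json(ch$T_AB), n = ch$n))
  tracks <- lapply(scene$timeline$tracks, function(track)
    lapply(track, function(k)
      list(time = k$time, pose = pose_to_json(k$pose), color = k$color,
           group = k$group, visible = k$visible)))
  list(version = scene$version,
       objects = unname(objects),
       groups = unname(lapply(scene$groups, function(g)
         list(id = g$id, members = g$members))),
       chains = unname(chains),
       connectors = unname(lapply(scene$connectors, function(cn)
         cn[CONNECTOR_KEYS])),
       timeline = list(duration = scene$timeline$duration, tracks = tracks),
       physics = unclass(scene$physics))
}

#' Save / load a scene as a JSON project file
#'
#' The file stores object provenance (fixture spec or OBJ path), poses,
#' colors, groups, chains, connectors, the animation timeline and physics
#' parameters. Loading rebuilds every mesh from its source, validates all id
#' references, and rejects unknown keys by name. OBJ paths are resolved
#' relative to the scene file's directory.
#'
#' @param scene a `scene` whose objects all have serializable sources.
#' @param path file path.
#' @return `save_scene`: `path` invisibly; `load_scene`: a `scene`.
#' @export
save_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  doc <- scene_to_document(scene)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

mesh_from_source <- function(source, base_dir) {
  if (identical(source$type, "fixture")) {
    args <- c(list(kind = source$kind), source$params)
    if (!is.null(source$seed)) args$seed <- source$seed
    do.call(make_fixture, args)
  } else if (identical(source$type, "obj")) {
    p <- source$path
    if (!file.exists(p) && !is.null(base_dir)) p <- file.path(base_dir, source$path)
    read_obj(p)
  } else {
    stop("unknown mesh source type: ", source$type, call. = FALSE)
  }
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  document_to_scene(doc, base_dir = dirname(path))
}

document_to_scene <- function(doc, base_dir = NULL) {
  check_keys(doc, SCENE_KEYS, "scene document")
  if (is.null(doc$version) || !identical(doc$version, SCENE_FORMAT_VERSION))
    stop("unrecognized scene format version: ",
         if (is.null(doc$version)) "<missing>" else doc$version, call. = FALSE)
  scene <- scene_new(physics = do.call(physics_params, doc$physics %||% list()))

  for (o in doc$objects %||% list()) {
    check_keys(o, OBJECT_KEYS, paste0("object '", o$id %||% "?", "'"))
    mesh <- mesh_from_source(o$source, base_dir)
    color <- if (is.character(o$color)) o$color else as.numeric(unlist(o$color))
    scene <- scene_add_object(scene, mesh, id = o$id,
                              pose = pose_from_json(unlist(o$pose)),
                              color = color,
                              group = o$group %||% NA_character_,
                              source = o$source)
  }
  ids <- scene_object_ids(scene)

  for (g in doc$groups %||% list()) {
    members <- as.character(unlist(g$members))
    dangling <- setdiff(members, ids)
    if (length(dangling))
      stop("validation error: group ", g$id, " references unknown object(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    scene <- scene_add_group(scene, members, id = g$id)
  }
  for (ch in doc$chains %||% list()) {
    check_keys(ch, CHAIN_KEYS, paste0("chain '", ch$id %||% "?", "'"))
    if (!(ch$base %in% ids))
      stop("validation error: chain ", ch$id, " references unknown object: ",
           ch$base, call. = FALSE)
    scene$chains[[ch$id]] <- list(id = ch$id, base = ch$base,
                                  T_AB = pose_from_json(unlist(ch$T_AB)),
                                  n = as.integer(ch$n))
  }
  for (cn in doc$connectors %||% list()) {
    check_keys(cn, CONNECTOR_KEYS, "connector")
    dangling <- setdiff(c(cn$id_a, cn$id_b), ids)
    if (length(dangling))
      stop("validation error: connector references unknown object(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    scene$connectors[[length(scene$connectors) + 1L]] <-
      spring_connector(cn$id_a, cn$id_b, as.numeric(unlist(cn$point_a)),
                       as.numeric(unlist(cn$point_b)), cn$stiffness,
                       cn$rest_length, cn$mode)
  }
  tl <- doc$timeline %||% list(duration = 0, tracks = list())
  check_keys(tl, c("duration", "tracks"), "timeline")
  scene$timeline <- timeline_new(tl$duration %||% 0)
  for (oid in names(tl$tracks %||% list())) {
    if (!(oid %in% ids))
      stop("validation error: timeline track for unknown object: ", oid,
           call. = FALSE)
    for (k in tl$tracks[[oid]]) {
      color <- if (is.character(k$color)) k$color else as.numeric(unlist(k$color))
      scene$timeline <- set_keyframe(scene$timeline, oid,
        keyframe(k$time, pose_from_json(unlist(k$pose)), color,
                 k$group %||% NA_character_, isTRUE(k$visible)))
    }
  }
  scene
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate a scene's chain record as a crystal chain
#'
#' @param scene a `scene`.
#' @param chain_id id of a chain record in the scene.
#' @return A `crystal_chain` built from the base object's mesh and pose.
#' @export
scene_chain <- function(scene, chain_id) {
  ch <- scene$chains[[chain_id]]
  if (is.null(ch)) stop("unknown chain id: ", chain_id, call. = FALSE)
  base <- scene_object(scene, ch$base)
  chain <- chain_from_pair(base$mesh, base$pose,
                           rt_compose(base$pose, ch$T_AB), ch$n)
  chain$bvh <- base$bvh
  chain
}

# ---- copy / paste ---------------------------------------------------------

#' Duplicate an object or a group
#'
#' Deep copy with fresh ids: poses, colors and keyframe tracks are copied;
#' duplicating a group copies every member and creates a new group. The
#' copies are fully independent of the originals.
#'
#' @param scene a `scene`.
#' @param id an object or group id.
#' @return The updated scene; the new ids can be read off
#'   `scene_object_ids()` / `names(scene$groups)`.
#' @export
duplicate <- function(scene, id) {
  if (!is.null(scene$objects[[id]])) {
    copy_object(scene, id)$scene
  } else if (!is.null(scene$groups[[id]])) {
    grp <- scene$groups[[id]]
    new_members <- character(0)
    for (m in grp$members) {
      cp <- copy_object(scene, m)
      scene <- cp$scene
      new_members <- c(new_members, cp$id)
    }
    scene_add_group(scene, new_members)
  } else {
    stop("unknown object or group id: ", id, call. = FALSE)
  }
}

copy_object <- function(scene, id) {
  obj <- scene_object(scene, id)
  fr <- fresh_id(scene, "obj")
  scene <- fr$scene; new_id <- fr$id
  obj$id <- new_id
  obj$group <- NA_character_
  scene$objects[[new_id]] <- obj
  track <- scene$timeline$tracks[[id]]
  if (!is.null(track)) scene$timeline$tracks[[new_id]] <- track
  list(scene = scene, id = new_id)
}

#' Export a group to a reusable fragment file / import it elsewhere
#'
#' The fragment is itself a valid scene document containing the group and
#' its member objects, so a structure built once (a filament, a complex) can
#' be re-imported into any project. Importing assigns fresh ids throughout —
#' collisions with existing ids are resolved by remapping, never by
#' overwriting — and returns both the scene and the id mapping.
#'
#' @param scene a `scene`.
#' @param group_id group to export.
#' @param path fragment file path.
#' @return `export_group`: `path` invisibly. `import_group`: list with the
#'   updated `scene`, the new `group_id`, and `id_map` (old id -> new id).
#' @export
export_group <- function(scene, group_id, path) {
  grp <- scene$groups[[group_id]]
  if (is.null(grp)) stop("unknown group id: ", group_id, call. = FALSE)
  sub <- scene_new(physics = scene$physics)
  for (m in grp$members) {
    o <- scene_object(scene, m)
    sub <- scene_add_object(sub, o$mesh, id = o$id, pose = o$pose,
                            color = o$color, source = o$source)
  }
  sub <- scene_add_group(sub, grp$members, id = grp$id)
  save_scene(sub, path)
}

#' @rdname export_group
#' @export
import_group <- function(scene, path) {
  frag <- load_scene(path)
  id_map <- character(0)
  for (oid in scene_object_ids(frag)) {
    o <- frag$objects[[oid]]
    fr <- fresh_id(scene, "obj")
    scene <- fr$scene
    o$id <- fr$id
    o$group <- NA_character_
    scene$objects[[fr$id]] <- o
    id_map[oid] <- fr$id
  }
  new_group <- NULL
  for (g in frag$groups) {
    fr <- fresh_id(scene, "grp")
    scene <- fr$scene
    scene <- scene_add_group(scene, unname(id_map[g$members]), id = fr$id)
    new_group <- fr$id
  }
  list(scene = scene, group_id = new_group, id_map = id_map)
}
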