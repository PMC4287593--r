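# Pose-mode physics.  Manipulated objects are pulled toward target poses by
# a spring-damper wrench; collision response forces act only on the
# manipulated objects, so everything else in the scene is immovable by
# construction.  Penalty forces along contact normals let a manipulated
# object slide along a static one without interpenetrating.  A rejection
# variant (move only when the candidate pose is collision-free) is kept as a
# comparison mode; it is prone to sticking, which is why the response-force
# scheme is the default.

#' Physics parameters
#'
#' Unit mass and unit inertia are used for every object: the integrator is a
#' pose controller, not a dynamics simulator, so only the ratios of these
#' constants matter.
#'
#' @param k_translate pull force per Angstrom of position error.
#' @param k_rotate pull torque per radian of orientation error.
#' @param damping per-step velocity retention factor in (0, 1]; lower is
#'   more damped. The default 0.8 with `dt = 0.1` is close to critical
#'   damping for unit stiffness, so free motion settles in a few hundred
#'   steps without oscillating.
#' @param response_gain penalty force per contact normal.
#' @param dt integration time step (arbitrary time unit).
#' @param penetration_tolerance acceptable residual overlap (Angstrom).
#' @param max_iterations step limit for convergence loops.
#' @param convergence_tol wrench norm below which motion is converged.
#' @param max_speed cap on linear speed (Angstrom per time unit) and angular
#'   speed (radian per time unit). Penalty contact forces scale with the
#'   number of contact triangles, so an uncapped impulse can eject a barely
#'   touching object; the cap bounds per-step motion to `dt * max_speed`
#'   (0.05 Angstrom at the defaults), which also bounds how deep a moving
#'   object can tunnel before contact is noticed.
#' @return A list of class `physics_params`.
#' @export
physics_params <- function(k_translate = 1, k_rotate = 1, damping = 0.8,
                           response_gain = 10, dt = 0.1,
                           penetration_tolerance = 0.1,
                           max_iterations = 2000, convergence_tol = 1e-4,
                           max_speed = 0.5) {
  p <- list(k_translate = k_translate, k_rotate = k_rotate, damping = damping,
            response_gain = response_gain, dt = dt,
            penetration_tolerance = penetration_tolerance,
            max_iterations = as.integer(max_iterations),
            convergence_tol = convergence_tol, max_speed = max_speed)
  if (any(unlist(p) <= 0)) stop("all physics parameters must be positive", call. = FALSE)
  if (damping > 1) stop("damping must be in (0, 1]", call. = FALSE)
  class(p) <- "physics_params"
  p
}

#' Manipulation state for pose-mode physics
#'
#' @param manipulated character vector of object ids being moved.
#' @param targets named list of `rigid_transform` target poses (one per
#'   manipulated id); may be `NULL` when motion is driven by springs only.
#' @return A list of class `manipulation_state` holding per-object linear
#'   and angular velocities (initially zero).
#' @export
manipulation_state <- function(manipulated, targets = NULL) {
  manipulated <- as.character(manipulated)
  if (!is.null(targets)) {
    if (!all(manipulated %in% names(targets)))
      stop("every manipulated id needs a target pose (or pass targets = NULL)",
           call. = FALSE)
    for (T in targets) rt_validate(T)
  }
  vel <- stats::setNames(rep(list(c(0, 0, 0)), length(manipulated)), manipulated)
  structure(list(manipulated = manipulated, targets = targets,
                 velocity = vel, angular_velocity = vel),
            class = "manipulation_state")
}

# axis-angle vector (rotation log) of a rotation matrix
rotation_log <- function(R) {
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (pi - theta < 1e-7) {
    M <- R + diag(3)
    cn <- sqrt(colSums(M^2))
    a <- M[, which.max(cn)]
    a <- a / sqrt(sum(a^2))
    nz <- which(abs(a) > 1e-9)[1]
    if (a[nz] < 0) a <- -a
    return(theta * a)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  theta * v / (2 * sin(theta))
}

#' Tracker wrench pulling a pose toward a target
#'
#' Force proportional to the position error and torque proportional to the
#' axis-angle orientation error; both vanish exactly when the poses
#' coincide.
#'
#' @param current,target `rigid_transform` poses.
#' @param params a `physics_params` list.
#' @return List with `force` and `torque` 3-vectors.
#' @export
tracker_wrench <- function(current, target, params = physics_params()) {
  force <- params$k_translate * (target$t - current$t)
  R_err <- target$R %*% t(current$R)
  torque <- params$k_rotate * rotation_log(R_err)
  list(force = force, torque = as.numeric(torque))
}

# world-space unit normal and centroid of triangle `tri` of a posed mesh
triangle_normal_world <- function(mesh, pose, tri) {
  idx <- mesh$faces[tri, ]
  p <- rt_apply(pose, mesh$vertices[idx, , drop = FALSE])
  n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
  nn <- sqrt(sum(n^2))
  list(normal = if (nn > 0) n / nn else c(0, 0, 0), centroid = colMeans(p))
}

#' Collision-response wrench on manipulated objects
#'
#' For every contact, the responding force on a manipulated object points
#' along the contact-triangle normal of the *other* body (oriented away from
#' that body), scaled by `response_gain`; the torque is the contact offset
#' crossed with the force. Objects that are not manipulated receive nothing.
#'
#' @param report a `collision_report` from [scene_collisions()].
#' @param scene the `scene` the report refers to.
#' @param manipulated character vector of manipulated object ids.
#' @param params a `physics_params` list.
#' @return Named list (per manipulated id) of `force` / `torque` pairs.
#' @export
collision_response <- function(report, scene, manipulated,
                               params = physics_params()) {
  out <- stats::setNames(
    rep(list(list(force = c(0, 0, 0), torque = c(0, 0, 0))), length(manipulated)),
    manipulated)
  np <- nrow(report$colliding_pairs)
  if (np == 0) return(out)
  for (i in seq_len(np)) {
    id1 <- report$colliding_pairs$id1[i]
    id2 <- report$colliding_pairs$id2[i]
    cts <- report$contacts[[i]]
    for (side in 1:2) {
      manip <- if (side == 1) id1 else id2
      other <- if (side == 1) id2 else id1
      if (!(manip %in% manipulated)) next
      om <- scene_object(scene, manip)
      oo <- scene_object(scene, other)
      other_col <- if (side == 1) 2L else 1L
      center_m <- om$pose$t
      center_o <- rt_apply(oo$pose, colMeans(oo$mesh$vertices))
      for (r in seq_len(nrow(cts))) {
        tn <- triangle_normal_world(oo$mesh, oo$pose, cts[r, other_col])
        n <- tn$normal
        # orient away from the other body
        if (sum(n * (tn$centroid - center_o)) < 0) n <- -n
        f <- params$response_gain * n
        out[[manip]]$force <- out[[manip]]$force + f
        out[[manip]]$torque <- out[[manip]]$torque +
          pracma_cross(tn$centroid - center_m, f)
      }
    }
  }
  out
}

clamp_norm <- function(v, cap) {
  n <- sqrt(sum(v^2))
  if (n > cap) v * (cap / n) else v
}

integrate_object <- function(pose, vel, ang, force, torque, params) {
  vel <- clamp_norm(params$damping * (vel + params$dt * force), params$max_speed)
  ang <- clamp_norm(params$damping * (ang + params$dt * torque), params$max_speed)
  t_new <- pose$t + params$dt * vel
  w <- params$dt * ang
  wn <- sqrt(sum(w^2))
  R_new <- if (wn > 0) axis_angle_matrix(w / wn, wn) %*% pose$R else pose$R
  list(pose = rt_new(R_new, t_new), vel = vel, ang = ang)
}

#' One pose-physics step
#'
#' Integrates the manipulated objects under tracker pull plus collision
#' response (semi-implicit Euler with velocity damping). Poses of all other
#' objects are returned bitwise unchanged — that is the defining property of
#' pose mode.
#'
#' @param scene a `scene`.
#' @param state a `manipulation_state`.
#' @param params a `physics_params` list.
#' @return List with updated `scene`, `state`, the step's `report`
#'   (collision report) and `wrench_norm` (largest combined force/torque
#'   norm over manipulated objects, before response).
#' @export
physics_step <- function(scene, state, params = physics_params()) {
  report <- scene_collisions(scene, state$manipulated)
  resp <- collision_response(report, scene, state$manipulated, params)
  wmax <- 0
  for (id in state$manipulated) {
    obj <- scene_object(scene, id)
    if (!is.null(state$targets) && !is.null(state$targets[[id]])) {
      tw <- tracker_wrench(obj$pose, state$targets[[id]], params)
    } else {
      tw <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
    }
    wmax <- max(wmax, sqrt(sum(tw$force^2) + sum(tw$torque^2)))
    force <- tw$force + resp[[id]]$force
    torque <- tw$torque + resp[[id]]$torque
    if (!all(is.finite(c(force, torque))))
      stop("numeric failure: non-finite wrench on object ", id, call. = FALSE)
    upd <- integrate_object(obj$pose, state$velocity[[id]],
                            state$angular_velocity[[id]], force, torque, params)
    scene$objects[[id]]$pose <- upd$pose
    state$velocity[[id]] <- upd$vel
    state$angular_velocity[[id]] <- upd$ang
  }
  list(scene = scene, state = state, report = report, wrench_norm = wmax)
}

#' One step of the rejection variant
#'
#' The candidate pose comes from the tracker wrench alone and is applied
#' only when it is collision-free; otherwise the object stays put (and its
#' velocity is cleared). Kept as a comparison mode: near contact it tends to
#' lock objects in place, which is precisely why response forces replaced
#' it.
#'
#' @inheritParams physics_step
#' @return As [physics_step()].
#' @export
physics_step_reject <- function(scene, state, params = physics_params()) {
  wmax <- 0
  for (id in state$manipulated) {
    obj <- scene_object(scene, id)
    if (!is.null(state$targets) && !is.null(state$targets[[id]])) {
      tw <- tracker_wrench(obj$pose, state$targets[[id]], params)
    } else {
      tw <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
    }
    wmax <- max(wmax, sqrt(sum(tw$force^2) + sum(tw$torque^2)))
    upd <- integrate_object(obj$pose, state$velocity[[id]],
                            state$angular_velocity[[id]],
                            tw$force, tw$torque, params)
    trial <- scene
    trial$objects[[id]]$pose <- upd$pose
    rep_trial <- scene_collisions(trial, id)
    if (nrow(rep_trial$colliding_pairs) == 0) {
      scene <- trial
      state$velocity[[id]] <- upd$vel
      state$angular_velocity[[id]] <- upd$ang
    } else {
      state$velocity[[id]] <- c(0, 0, 0)
      state$angular_velocity[[id]] <- c(0, 0, 0)
    }
  }
  report <- scene_collisions(scene, state$manipulated)
  list(scene = scene, state = state, report = report, wrench_norm = wmax)
}

#' Run pose physics to convergence
#'
#' Repeats [physics_step()] (or [physics_step_reject()]) until the tracker
#' wrench norm drops below `convergence_tol` or `max_iterations` is reached.
#' In sustained contact the wrench cannot vanish (pull balances response),
#' so the iteration cap is the intended stop there.
#'
#' @inheritParams physics_step
#' @param mode `"response"` (default) or `"reject"`.
#' @return List with final `scene`, `state`, `iterations`, `converged`, and
#'   `max_penetration` (Angstrom, estimated from the final contact set).
#' @export
physics_run <- function(scene, state, params = physics_params(),
                        mode = c("response", "reject")) {
  mode <- match.arg(mode)
  stepper <- if (mode == "response") physics_step else physics_step_reject
  iterations <- 0L
  converged <- FALSE
  report <- NULL
  while (iterations < params$max_iterations) {
    st <- stepper(scene, state, params)
    scene <- st$scene; state <- st$state; report <- st$report
    iterations <- iterations + 1L
    if (st$wrench_norm < params$convergence_tol) { converged <- TRUE; break }
  }
  pen <- if (is.null(report)) 0 else penetration_depth(report, scene)
  list(scene = scene, state = state, iterations = iterations,
       converged = converged, max_penetration = pen)
}

#' Estimated penetration depth of a contact set
#'
#' For every contact, measures how far the deepest vertex of one contact
#' triangle sits behind the plane of the other, along that plane's outward
#' normal. An inexpensive diagnostic bound on overlap, not an exact minimum
#' translation distance.
#'
#' @param report a `collision_report`.
#' @param scene the `scene` it refers to.
#' @return Maximum penetration over all contacts (Angstrom); 0 when the
#'   report is empty.
#' @export
penetration_depth <- function(report, scene) {
  np <- nrow(report$colliding_pairs)
  if (np == 0) return(0)
  worst <- 0
  for (i in seq_len(np)) {
    o1 <- scene_object(scene, report$colliding_pairs$id1[i])
    o2 <- scene_object(scene, report$colliding_pairs$id2[i])
    cts <- report$contacts[[i]]
    c1 <- rt_apply(o1$pose, colMeans(o1$mesh$vertices))
    c2 <- rt_apply(o2$pose, colMeans(o2$mesh$vertices))
    for (r in seq_len(nrow(cts))) {
      tn2 <- triangle_normal_world(o2$mesh, o2$pose, cts[r, 2])
      n <- tn2$normal
      if (sum(n * (tn2$centroid - c2)) < 0) n <- -n
      idx <- o1$mesh$faces[cts[r, 1], ]
      p1 <- rt_apply(o1$pose, o1$mesh$vertices[idx, , drop = FALSE])
      d <- min(as.numeric((p1 - matrix(tn2$centroid, 3, 3, byrow = TRUE)) %*% n))
      worst <- max(worst, max(0, -d))
    }
  }
  worst
}
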