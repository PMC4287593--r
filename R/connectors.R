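# Spring connectors.  A connector ties an attachment point on one object to
# an attachment point on another; in force mode it is a Hookean spring with
# rest length L0 (encoding an experimentally known separation), in visual
# mode it only marks that the objects are linked (e.g. a disordered linker
# with no crystal structure).  Layout relaxation integrates the spring
# wrenches with the pose-physics stepper until the network settles.

#' Create a spring connector
#'
#' @param id_a,id_b object ids of the two endpoints.
#' @param point_a,point_b attachment points in each object's local frame
#'   (Angstrom).
#' @param stiffness Hookean spring constant (force per Angstrom).
#' @param rest_length rest length L0 >= 0 (Angstrom); the spring is relaxed
#'   exactly when the world-space attachment distance equals L0.
#' @param mode `"force"` (acts on layout) or `"visual"` (marker only).
#' @return A list of class `spring_connector`.
#' @export
spring_connector <- function(id_a, id_b, point_a = c(0, 0, 0),
                             point_b = c(0, 0, 0), stiffness = 1,
                             rest_length = 0, mode = c("force", "visual")) {
  mode <- match.arg(mode)
  point_a <- as.numeric(point_a); point_b <- as.numeric(point_b)
  if (rest_length < 0) stop("rest_length must be >= 0", call. = FALSE)
  if (mode == "force" && stiffness <= 0)
    stop("stiffness must be positive for force-mode connectors", call. = FALSE)
  if (!all(is.finite(c(point_a, point_b))))
    stop("attachment points must be finite", call. = FALSE)
  structure(list(id_a = id_a, id_b = id_b, point_a = point_a,
                 point_b = point_b, stiffness = stiffness,
                 rest_length = rest_length, mode = mode),
            class = "spring_connector")
}

#' @export
print.spring_connector <- function(x, ...) {
  cat(sprintf("<%s connector> %s -- %s, k = %g, L0 = %g A\n",
              x$mode, x$id_a, x$id_b, x$stiffness, x$rest_length))
  invisible(x)
}

#' Spring wrench on a connector's endpoint objects
#'
#' With `d` the vector from A's to B's world attachment point, A is pulled
#' by `k (|d| - L0) d/|d|` and B by its negation (Newton's third law);
#' torques come from the attachment offsets. Visual-mode connectors produce
#' a zero wrench. Coincident endpoints with positive rest length have no
#' defined direction; a fixed +x direction is used to break the tie so the
#' pair can separate.
#'
#' @param conn a `spring_connector`.
#' @param scene the `scene` holding the endpoint objects.
#' @return List with per-endpoint `force` / `torque` and the current
#'   attachment `distance`.
#' @export
spring_wrench <- function(conn, scene) {
  oa <- scene_object(scene, conn$id_a)
  ob <- scene_object(scene, conn$id_b)
  wa <- rt_apply(oa$pose, conn$point_a)
  wb <- rt_apply(ob$pose, conn$point_b)
  zero <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
  if (conn$mode == "visual")
    return(list(a = zero, b = zero, distance = sqrt(sum((wb - wa)^2))))
  d <- wb - wa
  len <- sqrt(sum(d^2))
  dir <- if (len > 1e-12) d / len else c(1, 0, 0)  # tie-break, documented
  fmag <- conn$stiffness * (len - conn$rest_length)
  fa <- fmag * dir
  fb <- -fa
  list(a = list(force = fa, torque = pracma_cross(wa - oa$pose$t, fa)),
       b = list(force = fb, torque = pracma_cross(wb - ob$pose$t, fb)),
       distance = len)
}

#' Snap a connector end to a protein terminus
#'
#' Sets the local attachment point of one end to the first (N) or last (C)
#' alpha-carbon of a chain, sparing the user precise hand placement. The CA
#' coordinate is taken in the structure's frame, which is assumed to be the
#' scene object's local frame (the surface generated from the same PDB file
#' shares it).
#'
#' @param conn a `spring_connector`.
#' @param end `"a"` or `"b"`: which end to snap.
#' @param structure an `atomic_structure` from [read_pdb()].
#' @param chain chain identifier within the structure.
#' @param terminus `"N"` or `"C"`.
#' @return The updated connector.
#' @export
snap_to_terminus <- function(conn, end = c("a", "b"), structure, chain,
                             terminus = c("N", "C")) {
  end <- match.arg(end)
  terminus <- match.arg(terminus)
  p <- terminus_position(structure, chain, terminus)
  if (end == "a") conn$point_a <- p else conn$point_b <- p
  conn
}

#' Relax a scene under its spring connectors
#'
#' Treats every spring-connected object as manipulated (no tracker targets)
#' and integrates spring wrenches plus collision response until the total
#' spring force norm falls below the convergence tolerance. Soft
#' constraints: an infeasible network does not error, it settles into a
#' force-balance compromise and the residuals report how far each spring is
#' from its rest length.
#'
#' @param scene a `scene` with at least one force-mode connector among
#'   `connectors`.
#' @param connectors list of `spring_connector` objects; defaults to the
#'   scene's own connector table.
#' @param params a `physics_params` list.
#' @param free_ids additional object ids allowed to move even without a
#'   spring (by default, spring-less objects stay fixed).
#' @return List with the relaxed `scene`, `residuals` (per force-mode
#'   connector, `| |d| - L0 |`), `iterations` and `converged`.
#' @export
relax_layout <- function(scene, connectors = scene$connectors,
                         params = physics_params(), free_ids = character(0)) {
  force_conns <- Filter(function(cn) cn$mode == "force", connectors)
  if (length(force_conns) == 0)
    stop("need at least one force-mode connector", call. = FALSE)
  for (cn in force_conns) {
    scene_object(scene, cn$id_a); scene_object(scene, cn$id_b)
  }
  movable <- unique(c(unlist(lapply(force_conns, function(cn) c(cn$id_a, cn$id_b))),
                      free_ids))
  state <- manipulation_state(movable, targets = NULL)

  iterations <- 0L
  converged <- FALSE
  while (iterations < params$max_iterations) {
    report <- scene_collisions(scene, movable)
    resp <- collision_response(report, scene, movable, params)
    forces <- stats::setNames(rep(list(c(0, 0, 0)), length(movable)), movable)
    torques <- forces
    for (cn in force_conns) {
      w <- spring_wrench(cn, scene)
      forces[[cn$id_a]] <- forces[[cn$id_a]] + w$a$force
      torques[[cn$id_a]] <- torques[[cn$id_a]] + w$a$torque
      forces[[cn$id_b]] <- forces[[cn$id_b]] + w$b$force
      torques[[cn$id_b]] <- torques[[cn$id_b]] + w$b$torque
    }
    # equilibrium = zero *net* spring wrench on every object (an infeasible
    # network balances with taut springs, which still counts as settled)
    total <- sum(vapply(movable, function(id)
      sum(forces[[id]]^2) + sum(torques[[id]]^2), numeric(1)))
    if (sqrt(total) < params$convergence_tol) { converged <- TRUE; break }
    for (id in movable) {
      upd <- integrate_object(scene$objects[[id]]$pose, state$velocity[[id]],
                              state$angular_velocity[[id]],
                              forces[[id]] + resp[[id]]$force,
                              torques[[id]] + resp[[id]]$torque, params)
      scene$objects[[id]]$pose <- upd$pose
      state$velocity[[id]] <- upd$vel
      state$angular_velocity[[id]] <- upd$ang
    }
    iterations <- iterations + 1L
  }

  residuals <- vapply(force_conns, function(cn) {
    abs(spring_wrench(cn, scene)$distance - cn$rest_length)
  }, numeric(1))
  list(scene = scene, residuals = residuals, iterations = iterations,
       converged = converged)
}

#' Total spring energy of a connector set
#'
#' `sum 0.5 k (|d| - L0)^2` over force-mode connectors; non-increasing over
#' a contact-free relaxation with the default damping.
#'
#' @param connectors list of `spring_connector` objects.
#' @param scene the `scene` they refer to.
#' @return Energy (force times Angstrom).
#' @export
spring_energy <- function(connectors, scene) {
  sum(vapply(Filter(function(cn) cn$mode == "force", connectors), function(cn) {
    d <- spring_wrench(cn, scene)$distance
    0.5 * cn$stiffness * (d - cn$rest_length)^2
  }, numeric(1)))
}
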