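# Pose-mode physics: tracker wrench, collision response, immobility of
# non-manipulated objects, wall equilibrium and sliding contact.

wall_scene <- function(ball_pose = rt_identity()) {
  # flat wall (thin wide ellipsoid) with its inner face at x = 3,
  # plus a unit sphere
  wall <- make_fixture("ellipsoid", semi_axes = c(0.5, 6, 6), subdivisions = 3)
  ball <- make_fixture("sphere", radius = 1, subdivisions = 1)
  scene <- scene_new()
  scene <- scene_add_object(scene, wall, id = "wall", pose = rt_translation(3.5, 0, 0))
  scene <- scene_add_object(scene, ball, id = "ball", pose = ball_pose)
  scene
}

test_that("tracker wrench is proportional to pose error and vanishes at it", {
  p <- physics_params()
  same <- tracker_wrench(rt_translation(1, 2, 3), rt_translation(1, 2, 3), p)
  expect_equal(same$force, c(0, 0, 0))
  expect_equal(same$torque, c(0, 0, 0))

  pull <- tracker_wrench(rt_identity(), rt_translation(2, 0, 0),
                         physics_params(k_translate = 1))
  expect_equal(pull$force, c(2, 0, 0))
  expect_equal(pull$torque, c(0, 0, 0))

  turn <- tracker_wrench(rt_identity(), rt_rotation(c(0, 0, 1), pi / 2),
                         physics_params(k_rotate = 1))
  expect_equal(turn$force, c(0, 0, 0))
  expect_equal(turn$torque, c(0, 0, pi / 2), tolerance = 1e-12)
})

test_that("collision response pushes along the other body's outward normals", {
  scene <- wall_scene(rt_translation(2.2, 0, 0))  # overlapping the wall face
  rep <- scene_collisions(scene, "ball")
  expect_gt(nrow(rep$colliding_pairs), 0)
  resp <- collision_response(rep, scene, "ball", physics_params())
  f <- resp$ball$force
  # net response within 5 degrees of the -x face normal
  ang <- acos(sum(f * c(-1, 0, 0)) / sqrt(sum(f^2)))
  expect_lt(ang * 180 / pi, 5)

  # empty contact set: zero wrench
  scene0 <- wall_scene(rt_translation(0, 0, 0))
  rep0 <- scene_collisions(scene0, "ball")
  resp0 <- collision_response(rep0, scene0, "ball", physics_params())
  expect_equal(resp0$ball$force, c(0, 0, 0))
})

test_that("a symmetric pinch produces a balanced response", {
  wall <- make_fixture("ellipsoid", semi_axes = c(0.5, 6, 6), subdivisions = 3)
  ball <- make_fixture("sphere", radius = 1, subdivisions = 2)
  pinch <- scene_new()
  pinch <- scene_add_object(pinch, wall, id = "left", pose = rt_translation(-1.4, 0, 0))
  pinch <- scene_add_object(pinch, wall, id = "right", pose = rt_translation(1.4, 0, 0))
  pinch <- scene_add_object(pinch, ball, id = "ball")
  rep2 <- scene_collisions(pinch, "ball")
  expect_equal(nrow(rep2$colliding_pairs), 2)
  resp2 <- collision_response(rep2, pinch, "ball", physics_params())

  one <- scene_new()
  one <- scene_add_object(one, wall, id = "right", pose = rt_translation(1.4, 0, 0))
  one <- scene_add_object(one, ball, id = "ball")
  rep1 <- scene_collisions(one, "ball")
  resp1 <- collision_response(rep1, one, "ball", physics_params())
  expect_lt(sqrt(sum(resp2$ball$force^2)), 0.01 * sqrt(sum(resp1$ball$force^2)))
})

test_that("an unobstructed object converges to its target pose", {
  ball <- make_fixture("sphere", radius = 1, subdivisions = 1)
  scene <- scene_new()
  scene <- scene_add_object(scene, ball, id = "ball")
  target <- rt_compose(rt_translation(5, 2, -1), rt_rotation(c(0, 1, 0), 0.8))
  st <- manipulation_state("ball", list(ball = target))
  res <- physics_run(scene, st)
  expect_true(res$converged)
  final <- res$scene$objects[["ball"]]$pose
  expect_lt(sqrt(sum((final$t - target$t)^2)), 1e-3)
  expect_lt(max(abs(final$R - target$R)), 1e-3)
})

test_that("non-manipulated poses are bitwise unchanged across stepping", {
  scene <- wall_scene()
  wall0 <- scene$objects[["wall"]]$pose
  st <- manipulation_state("ball", list(ball = rt_translation(5, 0, 0)))
  for (i in 1:25) {
    out <- physics_step(scene, st, physics_params())
    scene <- out$scene; st <- out$state
    expect_identical(scene$objects[["wall"]]$pose, wall0)
  }
  out <- physics_run(scene, st)
  expect_identical(out$scene$objects[["wall"]]$pose, wall0)
})

test_that("pushing into a wall reaches equilibrium short of it", {
  scene <- wall_scene()
  st <- manipulation_state("ball", list(ball = rt_translation(5, 0, 0)))
  p <- physics_params()
  res <- physics_run(scene, st, p)
  x <- res$scene$objects[["ball"]]$pose$t[1]
  # stops near the contact point (wall face at 3, sphere radius 1)
  expect_gt(x, 1.5)
  expect_lt(x, 2.0 + p$penetration_tolerance)
  expect_lte(res$max_penetration, p$penetration_tolerance)
})

test_that("sliding along a wall reaches the tangential target; rejection sticks", {
  # ball starts pressed against the wall with a slight overlap
  start <- rt_translation(2.05, 0, 0)
  target <- rt_new(diag(3), c(2.05, 4, 0))
  p <- physics_params()

  slide <- physics_run(wall_scene(start),
                       manipulation_state("ball", list(ball = target)), p)
  y_slide <- slide$scene$objects[["ball"]]$pose$t[2]
  expect_gte(y_slide, 0.9 * 4)
  expect_lte(slide$max_penetration, p$penetration_tolerance)

  reject <- physics_run(wall_scene(start),
                        manipulation_state("ball", list(ball = target)), p,
                        mode = "reject")
  y_reject <- reject$scene$objects[["ball"]]$pose$t[2]
  expect_lt(y_reject, 0.1 * y_slide + 1e-9)
})

test_that("rejection mode reproduces the stuck-together failure", {
  # an ellipsoid lodged into the wall; the target pulls away while rotating,
  # so every bounded candidate step still collides and is refused
  probe <- make_fixture("ellipsoid", semi_axes = c(1.4, 0.8, 0.8), subdivisions = 1)
  wall <- make_fixture("ellipsoid", semi_axes = c(0.5, 6, 6), subdivisions = 3)
  scene <- scene_new()
  scene <- scene_add_object(scene, wall, id = "wall", pose = rt_translation(3.5, 0, 0))
  scene <- scene_add_object(scene, probe, id = "probe", pose = rt_translation(1.9, 0, 0))
  start_pose <- scene$objects[["probe"]]$pose
  target <- rt_compose(rt_translation(-2, 0, 0), rt_rotation(c(0, 0, 1), pi / 2))
  st <- manipulation_state("probe", list(probe = target))
  p <- physics_params(max_iterations = 60)
  res <- physics_run(scene, st, p, mode = "reject")
  expect_identical(res$scene$objects[["probe"]]$pose, start_pose)
  # response mode frees the same fixture
  res2 <- physics_run(scene, st, physics_params(max_iterations = 600))
  moved <- res2$scene$objects[["probe"]]$pose$t
  expect_lt(moved[1], 0)  # pulled clear of the wall
})

test_that("rejection mode equals response mode in free space", {
  ball <- make_fixture("sphere", radius = 1, subdivisions = 1)
  scene <- scene_new()
  scene <- scene_add_object(scene, ball, id = "ball")
  target <- rt_translation(4, 1, 0)
  p <- physics_params(max_iterations = 500)
  a <- physics_run(scene, manipulation_state("ball", list(ball = target)), p)
  b <- physics_run(scene, manipulation_state("ball", list(ball = target)), p,
                   mode = "reject")
  expect_lt(max_transform_diff(a$scene$objects[["ball"]]$pose,
                               b$scene$objects[["ball"]]$pose), 1e-9)
})

test_that("velocities decay once the pull is released", {
  ball <- make_fixture("sphere", radius = 1, subdivisions = 1)
  scene <- scene_new()
  scene <- scene_add_object(scene, ball, id = "ball")
  st <- manipulation_state("ball", list(ball = rt_translation(3, 0, 0)))
  p <- physics_params()
  # spin up, then drop the target: kinetic energy must not increase
  for (i in 1:20) {
    out <- physics_step(scene, st, p)
    scene <- out$scene; st <- out$state
  }
  st$targets <- NULL
  energy <- function(s) sum(s$velocity$ball^2) + sum(s$angular_velocity$ball^2)
  prev <- energy(st)
  for (i in 1:30) {
    out <- physics_step(scene, st, p)
    scene <- out$scene; st <- out$state
    e <- energy(st)
    expect_lte(e, prev + 1e-12)
    prev <- e
  }
})
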