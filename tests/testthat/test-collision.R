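# BVH construction, pairwise queries against the exhaustive oracle, and the
# pose-mode / chain test-count guarantees.

test_that("BVH construction partitions faces and stays balanced", {
  tri <- mesh_new(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  b <- build_bvh(tri)
  expect_equal(b$tree$n_faces, 1)
  expect_equal(length(b$tree$left), 1)   # single leaf
  expect_equal(b$tree$left[1], 0)

  m <- make_fixture("sphere", subdivisions = 1)  # 80 faces
  b2 <- build_bvh(m)
  # each face in exactly one leaf
  expect_identical(sort(b2$tree$order), seq_len(nrow(m$faces)))
  # median split keeps the tree near log depth
  expect_lte(molassembly:::bvh_depth(b2), 2 * ceiling(log2(nrow(m$faces))) + 1)
  # parent boxes contain children
  tr <- b2$tree
  for (i in seq_along(tr$left)) {
    for (child in c(tr$left[i], tr$right[i])) {
      if (child > 0) {
        expect_true(all(tr$node_min[child, ] >= tr$node_min[i, ] - 1e-12))
        expect_true(all(tr$node_max[child, ] <= tr$node_max[i, ] + 1e-12))
      }
    }
  }
})

test_that("pair queries separate and detect unit spheres correctly", {
  m <- make_fixture("sphere", subdivisions = 1)
  b <- build_bvh(m)
  expect_equal(nrow(collide_pair(b, rt_identity(), b, rt_translation(3, 0, 0))), 0)
  touching <- collide_pair(b, rt_identity(), b, rt_translation(1.5, 0, 0))
  expect_gt(nrow(touching), 0)
  first <- collide_pair(b, rt_identity(), b, rt_translation(1.5, 0, 0), mode = "first")
  expect_equal(nrow(first), 1)
  none <- collide_pair(b, rt_identity(), b, rt_translation(3, 0, 0), mode = "first")
  expect_equal(nrow(none), 0)
})

sort_contacts <- function(x) unname(x[order(x[, 1], x[, 2]), , drop = FALSE])

test_that("tree-accelerated contacts equal the exhaustive oracle", {
  set.seed(2024)
  mA <- make_fixture("blob", seed = 1, subdivisions = 1)
  mB <- make_fixture("ellipsoid", semi_axes = c(1.6, 1, 0.7), subdivisions = 1)
  bA <- build_bvh(mA); bB <- build_bvh(mB)
  hits <- 0
  for (i in 1:100) {
    pA <- rt_new(random_rotation(), runif(3, -1, 1))
    pB <- rt_new(random_rotation(), runif(3, -1, 1))
    fast <- collide_pair(bA, pA, bB, pB)
    slow <- collide_pair_brute(mA, pA, mB, pB)
    expect_identical(sort_contacts(fast), sort_contacts(slow))
    if (nrow(slow) > 0) hits <- hits + 1
    # symmetry: swapping the roles mirrors the contact set
    swapped <- collide_pair(bB, pB, bA, pA)
    expect_identical(sort_contacts(swapped[, c(2, 1), drop = FALSE]),
                     sort_contacts(fast))
  }
  expect_gt(hits, 10)  # the fixture actually exercises colliding cases
})

test_that("pose-mode filtering tests only pairs involving moving objects", {
  set.seed(5)
  scene <- random_scene(10, box = 10)
  none <- scene_collisions(scene, character(0))
  expect_equal(none$tests_performed, 0)
  expect_equal(nrow(none$colliding_pairs), 0)

  one <- scene_collisions(scene, "o01")
  expect_equal(one$tests_performed, 9)

  two <- scene_collisions(scene, c("o01", "o02"))
  expect_lte(two$tests_performed, 2 * 10)

  expect_error(scene_collisions(scene, "nope"), "unknown object")
})

test_that("pose-mode collision sets equal brute force on moving-involved pairs", {
  for (seed in 1:50) {
    set.seed(seed)
    scene <- random_scene(8, box = 5)
    moving <- sample(scene_object_ids(scene), 2)
    rep <- scene_collisions(scene, moving)
    expect_identical(report_pair_keys(rep), brute_scene_pairs(scene, moving))
    expect_lte(rep$tests_performed, 2 * 8)
  }
})

test_that("chain internal collisions need exactly n-1 tests", {
  m <- make_fixture("sphere", subdivisions = 1)
  wide <- chain_from_pair(m, rt_identity(), rt_translation(0, 0, 2.5), n = 6)
  r <- chain_internal_collisions(wide)
  expect_equal(r$tests_performed, 5)
  expect_equal(nrow(r$colliding_pairs), 0)

  tight <- set_internal_transform(wide, rt_translation(0, 0, 1.5))
  r2 <- chain_internal_collisions(tight)
  expect_equal(r2$tests_performed, 5)
  expect_identical(report_pair_keys(r2),
                   sort(paste(1:5, 2:6, sep = "|")))
  expect_identical(report_pair_keys(r2), brute_chain_pairs(tight))

  expect_error(chain_from_pair(m, rt_identity(), rt_translation(0, 0, 1), n = 1),
               ">= 2")
})

test_that("implied pairs of a tight helix match brute force at all offsets", {
  m <- make_fixture("sphere", subdivisions = 1)
  # helix around the z axis: consecutive copies touch, and so do copies two
  # apart, but not three apart
  T_AB <- screw_transform(list(axis_direction = c(0, 0, 1),
                               axis_point = c(2, 0, 0),
                               angle = 25 * pi / 180, rise = 0.2))
  helix <- chain_from_pair(m, rt_identity(), T_AB, n = 6)
  r <- chain_internal_collisions(helix)
  expect_equal(r$tests_performed, 5)
  keys <- report_pair_keys(r)
  expect_true(all(paste(1:5, 2:6, sep = "|") %in% keys))  # offset 1
  expect_true(all(paste(1:4, 3:6, sep = "|") %in% keys))  # offset 2
  expect_identical(keys, brute_chain_pairs(helix))
  # implied pairs share the representative pair's contact topology
  off1 <- which(r$colliding_pairs$id1 == "2" & r$colliding_pairs$id2 == "3")
  base1 <- which(r$colliding_pairs$id1 == "1" & r$colliding_pairs$id2 == "2")
  expect_identical(r$contacts[[off1]], r$contacts[[base1]])
})

test_that("chain-external collisions match brute force over chain copies", {
  m <- make_fixture("sphere", subdivisions = 1)
  chain <- chain_from_pair(m, rt_identity(), rt_translation(0, 0, 3), n = 5)

  empty <- chain_external_collisions(chain, scene_new())
  expect_equal(nrow(empty$colliding_pairs), 0)

  scene <- scene_new()
  # a sphere overlapping copy 3 (at z = 6) only
  scene <- scene_add_object(scene, m, id = "ext", pose = rt_translation(1.2, 0, 6))
  r <- chain_external_collisions(chain, scene)
  expect_equal(nrow(r$colliding_pairs), 1)
  expect_equal(r$colliding_pairs$id1, "copy:3")
  expect_equal(r$tests_performed, 5)

  far <- move_chain(chain, rt_translation(100, 0, 0))
  expect_equal(nrow(chain_external_collisions(far, scene)$colliding_pairs), 0)
})
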