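# Scene JSON round trips, validation, duplication and group export/import.

fixture_source <- function(kind = "sphere", seed = 1, ...) {
  list(type = "fixture", kind = kind, params = list(...), seed = seed)
}

demo_scene <- function() {
  scene <- scene_new()
  scene <- scene_add_object(scene, make_fixture("sphere", radius = 2, subdivisions = 1),
                            id = "s1", pose = rt_translation(1, 2, 3),
                            color = c(1, 0, 0),
                            source = fixture_source(radius = 2, subdivisions = 1))
  scene <- scene_add_object(scene, make_fixture("blob", seed = 7), id = "s2",
                            pose = rt_compose(rt_rotation(c(0, 0, 1), 0.3),
                                              rt_translation(8, 0, 0)),
                            source = fixture_source("blob", seed = 7))
  scene$connectors[[1]] <- spring_connector("s1", "s2", rest_length = 5)
  scene$chains[["ch1"]] <- list(id = "ch1", base = "s1",
                                T_AB = rt_translation(0, 0, 5), n = 4L)
  scene <- scene_add_group(scene, c("s1", "s2"), id = "g1")
  scene$timeline <- set_keyframe(scene$timeline, "s1",
                                 keyframe(0, rt_translation(1, 2, 3)))
  scene$timeline <- set_keyframe(scene$timeline, "s1",
                                 keyframe(2, rt_translation(1, 6, 3), c(0, 1, 0)))
  scene
}

test_that("an empty scene and a populated scene round trip through JSON", {
  tf <- tempfile(fileext = ".json")
  empty <- scene_new()
  save_scene(empty, tf)
  expect_equal(molassembly:::scene_to_document(load_scene(tf)),
               molassembly:::scene_to_document(empty))

  scene <- demo_scene()
  save_scene(scene, tf)
  back <- load_scene(tf)
  expect_equal(molassembly:::scene_to_document(back),
               molassembly:::scene_to_document(scene))
  # meshes rebuilt from the recorded sources are bit-identical
  expect_identical(back$objects[["s2"]]$mesh, scene$objects[["s2"]]$mesh)
  # relative pose of the two objects survives within 1e-9
  rel0 <- rt_relative(scene$objects[["s1"]]$pose, scene$objects[["s2"]]$pose)
  rel1 <- rt_relative(back$objects[["s1"]]$pose, back$objects[["s2"]]$pose)
  expect_lt(max_transform_diff(rel0, rel1), 1e-9)
})

test_that("scene chains re-instantiate as crystal chains", {
  tf <- tempfile(fileext = ".json")
  save_scene(demo_scene(), tf)
  ch <- scene_chain(load_scene(tf), "ch1")
  expect_s3_class(ch, "crystal_chain")
  expect_equal(ch$n, 4)
  expect_equal(ch$copy_poses[[4]]$t, c(1, 2, 18))
})

test_that("validation rejects unknown keys and dangling references by name", {
  tf <- tempfile(fileext = ".json")
  scene <- demo_scene()
  save_scene(scene, tf)
  doc <- jsonlite::read_json(tf, simplifyVector = FALSE)

  bad <- doc; bad$surprise <- 1
  tf2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, tf2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_scene(tf2), "surprise")

  bad2 <- doc; bad2$connectors[[1]]$id_b <- "ghost"
  jsonlite::write_json(bad2, tf2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_scene(tf2), "ghost")

  bad3 <- doc; bad3$version <- "99"
  jsonlite::write_json(bad3, tf2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_scene(tf2), "version")

  bad4 <- doc; bad4$objects[[1]]$flavour <- "x"
  jsonlite::write_json(bad4, tf2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_scene(tf2), "flavour")

  # inline meshes cannot be saved
  inline <- scene_add_object(scene_new(), make_fixture("sphere", subdivisions = 0))
  expect_error(save_scene(inline, tf2), "inline")
})

test_that("duplicating an object copies state and keeps copies independent", {
  scene <- demo_scene()
  n0 <- length(scene$objects)
  scene2 <- duplicate(scene, "s1")
  expect_equal(length(scene2$objects), n0 + 1)
  new_id <- setdiff(scene_object_ids(scene2), scene_object_ids(scene))
  expect_identical(scene2$objects[[new_id]]$mesh, scene$objects[["s1"]]$mesh)
  expect_identical(scene2$objects[[new_id]]$pose, scene$objects[["s1"]]$pose)
  # keyframes came along
  expect_equal(length(scene2$timeline$tracks[[new_id]]), 2)
  # moving the copy leaves the original untouched
  moved <- scene_set_pose(scene2, new_id, rt_translation(50, 0, 0))
  expect_identical(moved$objects[["s1"]]$pose, scene$objects[["s1"]]$pose)
})

test_that("duplicating a group copies every member plus the group", {
  scene <- demo_scene()
  scene <- scene_add_object(scene, make_fixture("sphere", subdivisions = 0), id = "s3",
                            source = fixture_source(subdivisions = 0))
  scene <- scene_add_group(scene, "s3", id = "g2")
  out <- duplicate(scene, "g1")
  expect_equal(length(out$objects), 3 + 2)
  expect_equal(length(out$groups), 2 + 1)
  new_grp <- setdiff(names(out$groups), names(scene$groups))
  expect_equal(length(out$groups[[new_grp]]$members), 2)
})

test_that("group export/import preserves members and relative poses", {
  scene <- demo_scene()
  tf <- tempfile(fileext = ".json")
  export_group(scene, "g1", tf)

  # the fragment is itself a loadable scene document
  frag <- load_scene(tf)
  expect_equal(length(frag$objects), 2)

  target <- scene_new()
  target <- scene_add_object(target, make_fixture("sphere", subdivisions = 0),
                             id = "s1",  # id collision with the fragment
                             source = fixture_source(subdivisions = 0))
  once <- import_group(target, tf)
  expect_equal(length(once$scene$objects), 3)
  expect_false("s1" %in% once$id_map)  # collision resolved by remapping
  expect_identical(once$scene$objects[["s1"]]$source$params$subdivisions, 0)

  twice <- import_group(once$scene, tf)
  expect_equal(length(twice$scene$objects), 5)
  expect_equal(length(intersect(unname(once$id_map), unname(twice$id_map))), 0)

  # relative pose of the imported pair matches the original group
  rel0 <- rt_relative(scene$objects[["s1"]]$pose, scene$objects[["s2"]]$pose)
  a <- once$id_map[["s1"]]; b <- once$id_map[["s2"]]
  rel1 <- rt_relative(once$scene$objects[[a]]$pose, once$scene$objects[[b]]$pose)
  expect_lt(max_transform_diff(rel0, rel1), 1e-9)
})

test_that("the command-line interface drives fixtures, chains and export", {
  dir <- tempfile(); dir.create(dir)
  obj <- file.path(dir, "monomer.obj")
  expect_equal(cli_main(c("fixture", "--kind", "sphere", "--radius", "2",
                          "--subdivisions", "1", "--out", obj)), 0L)
  expect_true(file.exists(obj))

  chain_obj <- file.path(dir, "chain.obj")
  expect_equal(cli_main(c("build-chain", "--mesh", obj, "--n", "4",
                          "--twist", "-166.7", "--rise", "27.5",
                          "--out", chain_obj)), 0L)
  built <- read_obj(chain_obj)
  expect_equal(nrow(built$vertices), 4 * nrow(read_obj(obj)$vertices))
  expect_true(file.exists(file.path(dir, "chain_poses.json")))

  # scene-driven subcommands
  sc <- scene_new()
  sc <- scene_add_object(sc, make_fixture("sphere", radius = 1, subdivisions = 1),
                         id = "a", source = fixture_source(radius = 1, subdivisions = 1))
  sc$timeline <- set_keyframe(sc$timeline, "a", keyframe(0, rt_identity()))
  sc$timeline <- set_keyframe(sc$timeline, "a", keyframe(1, rt_translation(4, 0, 0)))
  scene_file <- file.path(dir, "scene.json")
  save_scene(sc, scene_file)
  frames <- file.path(dir, "frames.jsonl")
  expect_equal(cli_main(c("animate-export", "--scene", scene_file,
                          "--out", frames, "--fps", "10", "--t1", "1")), 0L)
  expect_equal(length(readLines(frames)), 11)
  expect_equal(cli_main(c("collide-check", "--scene", scene_file)), 0L)
  # unknown command and missing file map to the validation exit code
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(cli_main(c("info", "--scene", "/nope.json"))), 2L)
})
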