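# Phantom generator: tree construction, ground truth, rasterization,
# artifact injection.

test_that("complete trees have 2^g - 1 branches and per-generation 2^(g-1)", {
  tree <- build_tree(tree_spec(generations = 6, prune_prob = 0, seed = 2))
  expect_equal(length(tree$branches), 63)
  gt <- tree$ground_truth
  for (g in 1:6) {
    expect_equal(sum(gt$generation == g), 2^(g - 1))
  }
  expect_tree_labels(gt, 6)
})

test_that("a single-generation tree is one branch labeled 1", {
  tree <- build_tree(tree_spec(generations = 1, seed = 5))
  expect_equal(length(tree$branches), 1)
  expect_equal(tree$ground_truth$label, "1")
  expect_error(tree_spec(generations = 0), "generations")
})

test_that("pruned tree matches an independent recursive enumeration", {
  spec <- tree_spec(generations = 6, prune_prob = 0.2, seed = 31)
  tree <- build_tree(spec)
  # oracle: replay the per-label pruning decisions directly from the
  # deterministic substream, without touching the generator's recursion
  oracle_labels <- character(0)
  enumerate <- function(label) {
    if (nchar(label) > 1) {
      u <- airwaymorph:::label_rng(spec$seed, paste0(label, ":prune"), 1)
      if (nchar(label) >= 3 && u < spec$prune_prob) return(invisible())
    }
    oracle_labels <<- c(oracle_labels, label)
    if (nchar(label) < spec$generations) {
      enumerate(paste0(label, "1"))
      enumerate(paste0(label, "2"))
    }
  }
  enumerate("1")
  expect_setequal(names(tree$branches), oracle_labels)
  expect_lt(length(tree$branches), 63)
})

test_that("identical spec (incl. seed) gives bit-identical output", {
  spec <- tree_spec(generations = 4, prune_prob = 0.1, curvature = 0.05,
                    seed = 9)
  t1 <- build_tree(spec)
  t2 <- build_tree(spec)
  expect_identical(t1$ground_truth, t2$ground_truth)
  v1 <- rasterize_tree(t1, 50)
  v2 <- rasterize_tree(t2, 50)
  expect_identical(v1$values, v2$values)
})

test_that("ground truth is self-consistent", {
  tree <- build_tree(tree_spec(generations = 5, seed = 13))
  gt <- tree$ground_truth
  d <- sqrt((gt$x2 - gt$x1)^2 + (gt$y2 - gt$y1)^2 + (gt$z2 - gt$z1)^2)
  expect_lt(max(abs(d - gt$length_mm)), 1e-9)
  # every non-root label's prefix exists
  expect_tree_labels(gt, 5)
  # trachea at 90 degrees to the constructed gravity
  expect_equal(gt$gravity_angle_deg[gt$label == "1"], 90, tolerance = 1e-9)
})

test_that("rasterized capsule volume matches the analytic value", {
  tree <- build_tree(tree_spec(generations = 1, seed = 1))
  b <- tree$branches[["1"]]
  vox <- 1.2 / 20 * 1000  # trachea diameter = 20 voxels
  vol <- rasterize_tree(tree, vox)
  analytic_mm3 <- pi * (b$diameter / 2)^2 * b$length +
    4 / 3 * pi * (b$diameter / 2)^3
  measured_mm3 <- sum(vol$values) * (vol$spacing / 1000)^3
  expect_lt(abs(measured_mm3 / analytic_mm3 - 1), 0.05)
})

test_that("an empty tree rasterizes to an empty volume", {
  tree <- structure(list(spec = tree_spec(seed = 1), branches = list()),
                    class = "airway_tree")
  vol <- rasterize_tree(tree, 10)
  expect_false(any(vol$values))
})

test_that("full mouse-scale tree rasterizes to one 26-connected component", {
  vol <- cached("vol6", rasterize_tree(
    cached("tree6", build_tree(tree_spec(generations = 6, seed = 1))), 35))
  lab <- airwaymorph:::cpp_label_components(as.logical(vol$values),
                                            dim(vol$values), 26L)
  expect_equal(max(lab), 1)
})

test_that("sub-4-voxel diameters trigger the accuracy warning", {
  tree <- build_tree(tree_spec(generations = 4, seed = 1))
  expect_warning(rasterize_tree(tree, 200), "accuracy")
})

test_that("artifact injection: identity, validation, and nub terminal", {
  tree <- small_tree()
  vol <- small_volume()
  expect_identical(inject_artifacts(vol, tree, list())$values, vol$values)
  expect_error(inject_artifacts(vol, tree,
                                list(list(kind = "wormhole", location = "1",
                                          magnitude = 10))), "unknown")
  v1 <- inject_artifacts(vol, tree, list(list(kind = "spur_nub",
                                              location = "1",
                                              magnitude = 250, radius = 100)))
  expect_gt(sum(v1$values), sum(vol$values))
  net0 <- small_network()
  net1 <- build_network(skeletonize(largest_component(v1)), v1)
  n_term0 <- sum(net0$nodes$kind == "terminal")
  n_term1 <- sum(net1$nodes$kind == "terminal")
  expect_equal(n_term1, n_term0 + 1)
})

test_that("thin touching bridge is removed by opening; thick bridge loops", {
  tree <- small_tree()
  vol <- small_volume()
  thin <- inject_artifacts(vol, tree, list(list(
    kind = "touching_branches", location = c("111", "121"), magnitude = 80)))
  net_raw <- build_network(skeletonize(largest_component(thin)), thin)
  expect_equal(sum(detect_exceptions(net_raw)$kind == "closed_loop"), 1)
  opened <- open_volume(thin, 2)
  net_open <- build_network(skeletonize(largest_component(opened)), opened)
  expect_equal(sum(detect_exceptions(net_open)$kind == "closed_loop"), 0)

  thick <- inject_artifacts(vol, tree, list(list(
    kind = "closed_loop", location = c("111", "121"), magnitude = 350)))
  op2 <- open_volume(thick, 2)
  net_thick <- build_network(skeletonize(largest_component(op2)), op2)
  expect_equal(sum(detect_exceptions(net_thick)$kind == "closed_loop"), 1)
})

test_that("ground truth CSV round-trips", {
  tree <- build_tree(tree_spec(generations = 3, seed = 4))
  path <- tempfile(fileext = ".csv")
  write_ground_truth(tree$ground_truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$label, tree$ground_truth$label)
  expect_equal(back$length_mm, tree$ground_truth$length_mm, tolerance = 1e-9)
  unlink(path)
})
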