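# Per-branch measurements, gravity construction, Raabe labeling and
# generation summaries.

fake_branch <- function(p0, p1) list(polyline = rbind(p0, p1))

test_that("branch vector and airway length basics", {
  b <- fake_branch(c(0, 0, 0), c(0, 0, 2))
  expect_equal(branch_vector(b), c(0, 0, 2))
  expect_equal(airway_length(b), 2)
  rev_b <- fake_branch(c(0, 0, 2), c(0, 0, 0))
  expect_equal(branch_vector(rev_b), -branch_vector(b))
  b3 <- fake_branch(c(1, 1, 1), c(1, 4, 1))
  expect_equal(airway_length(b3), 3)
  degen <- fake_branch(c(1, 1, 1), c(1, 1, 1))
  expect_true(isTRUE(attr(branch_vector(degen), "degenerate")))
})

test_that("length is the chord, not the arc, for curved branches", {
  t <- seq(0, 1, length.out = 21)
  arc_pts <- cbind(sin(pi * t) * 0.3, t * 2, 0)
  b <- list(polyline = arc_pts)
  chord <- airway_length(b)
  arc <- airwaymorph:::polyline_length(arc_pts)
  expect_equal(chord, 2)
  expect_gt(arc, chord)
  # the generator records chords too
  tree <- build_tree(tree_spec(generations = 2, curvature = 0.2, seed = 3))
  gt <- tree$ground_truth
  d <- sqrt((gt$x2 - gt$x1)^2 + (gt$y2 - gt$y1)^2 + (gt$z2 - gt$z1)^2)
  expect_equal(gt$length_mm, d, tolerance = 1e-12)
})

test_that("branch angle: collinear 0, perpendicular 90, zero flagged", {
  expect_equal(branch_angle(c(0, 1, 0), c(0, 2, 0)), 0)
  expect_equal(branch_angle(c(0, 1, 0), c(1, 0, 0)), 90)
  expect_equal(branch_angle(c(0, 1, 0), c(0, -1, 0)), 180)
  expect_true(is.na(branch_angle(c(0, 0, 0), c(1, 0, 0))))
})

test_that("gravity vector matches the hand Gram-Schmidt construction", {
  # trachea along +y, bronchi averaging to (0, 1, -1)/sqrt(2)
  nodes <- rbind(c(0, -2, 0), c(0, 0, 0),
                 c(1, 1, -1), c(-1, 1, -1))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L))
  net <- manual_network(nodes, edges)
  g <- gravity_vector(net)
  expect_equal(g, c(0, 0, -1), tolerance = 1e-12)
  # orthogonal to the trachea by construction
  expect_equal(sum(g * c(0, 1, 0)), 0, tolerance = 1e-12)
  expect_equal(gravity_angle(c(0, 1, 0), g), 90)
  expect_equal(gravity_angle(g, g), 0)
  expect_equal(gravity_angle(-g, g), 180)
})

test_that("gravity construction is covariant under rigid rotation", {
  spec <- tree_spec(generations = 3, seed = 21)
  tree <- build_tree(spec)
  R <- airwaymorph:::rotation_matrix(c(1, 2, 0.5), 63)
  rtree <- transform_tree(tree, R, c(0.3, -0.2, 0.15))
  expect_equal(rtree$gravity, as.numeric(R %*% tree$gravity),
               tolerance = 1e-9)
  expect_equal(rtree$ground_truth$gravity_angle_deg,
               tree$ground_truth$gravity_angle_deg, tolerance = 1e-9)
  expect_equal(rtree$ground_truth$branch_angle_deg,
               tree$ground_truth$branch_angle_deg, tolerance = 1e-9)
})

test_that("hydraulic diameter closed forms: circle and square sections", {
  th <- seq(0, 2 * pi, length.out = 721)
  r <- 0.37
  circ <- airwaymorph:::polygon_area_perimeter(r * cos(th), r * sin(th))
  expect_equal(4 * circ$area / circ$perimeter, 2 * r, tolerance = 1e-4)
  s <- 0.8
  sq <- airwaymorph:::polygon_area_perimeter(c(0, s, s, 0), c(0, 0, s, s))
  expect_equal(4 * sq$area / sq$perimeter, s, tolerance = 1e-12)
})

test_that("hydraulic diameter of a rasterized cylinder is within 5%", {
  vol <- capsule_volume(10, 50, spacing = 10)
  net <- build_network(skeletonize(vol), vol)
  hd <- hydraulic_diameter(net$branches[[1]], vol, net, step = 2)
  expect_true(hd$valid)
  expect_lt(abs(hd$diameter_mm / 0.2 - 1), 0.05)
})

test_that("a branch shorter than its diameter gets a zero/invalid flag", {
  vol <- capsule_volume(10, 50, spacing = 10)
  net <- build_network(skeletonize(vol), vol)
  b <- net$branches[[1]]
  # truncate the polyline to a stub shorter than the tube diameter
  keep <- b$polyline[, 2] - b$polyline[1, 2] < 0.1
  b$polyline <- b$polyline[keep, , drop = FALSE]
  b$radius_mm <- b$radius_mm[seq_len(max(0, nrow(b$polyline) - 2))]
  hd <- hydraulic_diameter(b, vol, net, step = 2)
  expect_false(hd$valid)
  expect_equal(hd$diameter_mm, 0)
})

test_that("Raabe labels follow the daughter-diameter convention", {
  net <- qc_network(small_network())$network
  tab <- measure_network(net, small_volume())
  # the larger-diameter daughter of the trachea is 11, the smaller 12
  d11 <- tab$diameter_mm[tab$label == "11"]
  d12 <- tab$diameter_mm[tab$label == "12"]
  expect_gt(d11, d12)
  # all labels prefix-closed, unique, generation = digits
  expect_tree_labels(tab, 3)
  # complete enumeration for the phantom
  expect_setequal(tab$label, small_tree()$ground_truth$label)
})

test_that("tie-breaking in labeling is deterministic", {
  nodes <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 2, 0), c(-1, 2, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L))
  net <- manual_network(nodes, edges)
  l1 <- assign_labels(net, c(1, 0.5, 0.5))
  l2 <- assign_labels(net, c(1, 0.5, 0.5))
  expect_identical(vapply(l1$branches, `[[`, "", "label"),
                   vapply(l2$branches, `[[`, "", "label"))
})

test_that("generation counts and averages match hand arithmetic", {
  tab <- data.frame(
    label = c("1", "11", "12", "111", "112"),
    generation = c(1, 2, 2, 3, 3),
    length_mm = c(2, 1.5, 1.2, 1.0, 0.8),
    diameter_mm = c(1.2, 0.9, 0.8, 0, 0.6),
    diameter_valid = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    branch_angle_deg = c(NA, 20, 40, 30, 35),
    gravity_angle_deg = c(90, 70, 50, 60, 80),
    stringsAsFactors = FALSE
  )
  counts <- generation_counts(tab)
  expect_equal(counts$n, c(1, 2, 2))
  av <- generation_averages(tab)
  expect_equal(av$length_mean, c(2, 1.35, 0.9))
  # invalid diameter of 111 contributes its parent 11's diameter
  expect_equal(av$diameter_mean[3], mean(c(0.9, 0.6)))
  expect_equal(av$diameter_sd[2], sd(c(0.9, 0.8)))
  expect_equal(av$length_se[2], sd(c(1.5, 1.2)) / sqrt(2))
  expect_equal(av$branch_angle_mean[1], NA_real_)
  # single branch -> count [1]
  expect_equal(generation_counts(tab[1, ])$n, 1)
})

test_that("measurements are invariant under rigid motion of the cast", {
  spec <- tree_spec(generations = 3, seed = 7)
  tree <- build_tree(spec)
  R <- airwaymorph:::rotation_matrix(c(0.3, 1, 0.2), 37)
  rtree <- transform_tree(tree, R, c(0.5, 0.1, -0.3))
  cfg <- pipeline_config(voxel_size = 40, resample_factor = 1,
                         opening_radius_px = 0)
  run_vol <- function(tr) {
    v <- rasterize_tree(tr, cfg$voxel_size)
    run_pipeline(v, cfg)$table
  }
  t0 <- run_vol(tree)
  t1 <- run_vol(rtree)
  m <- merge(t0, t1, by = "label", suffixes = c("_a", "_b"))
  expect_equal(nrow(m), 7)
  expect_lt(max(abs(m$length_mm_a - m$length_mm_b)), 2 * 0.04)
  expect_lt(max(abs(m$diameter_mm_a / m$diameter_mm_b - 1)), 0.05)
  expect_lt(max(abs(m$branch_angle_deg_a - m$branch_angle_deg_b),
                na.rm = TRUE), 5)
  expect_lt(max(abs(m$gravity_angle_deg_a - m$gravity_angle_deg_b),
                na.rm = TRUE), 5)
})

test_that("morphometry table round-trips through CSV", {
  net <- qc_network(small_network())$network
  tab <- measure_network(net, small_volume())
  path <- tempfile(fileext = ".csv")
  write_morphometry(tab, path)
  back <- read_morphometry(path)
  expect_equal(back$label, tab$label)
  expect_equal(back$diameter_mm, tab$diameter_mm, tolerance = 1e-12)
  unlink(path)
})
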