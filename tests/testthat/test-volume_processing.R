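# Pre-processing: threshold, resampling, opening, component selection,
# accuracy estimate.

test_that("threshold is identity on binary input and empty on zeros", {
  vol <- capsule_volume(6, 20)
  gray <- voxel_volume(array(as.numeric(vol$values), dim(vol$values)),
                       vol$spacing)
  expect_identical(threshold_volume(gray, 0.5)$values, vol$values)
  zeros <- voxel_volume(array(0, c(4, 4, 4)), 10)
  expect_false(any(threshold_volume(zeros, 0.5)$values))
  expect_error(threshold_volume(gray, NaN), "finite")
})

test_that("thresholding a graded tube recovers the analytic radius", {
  # intensity decreases with distance to the tube axis; the level chosen
  # at radius r must give a mask of radius r (within a voxel)
  n <- 41
  ctr <- 21
  r_target <- 8
  dist_ax <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  slice <- 20 - dist_ax
  arr <- array(rep(slice, 10), c(n, n, 10))
  arr <- aperm(arr, c(1, 3, 2))
  vol <- voxel_volume(arr, 10)
  mask <- threshold_volume(vol, 20 - r_target)
  expect_lte(max(dist_ax[mask$values[, 5, ]]), r_target + 1)
  expect_gte(max(dist_ax[mask$values[, 5, ]]), r_target - 1)
})

test_that("threshold is monotone in the level", {
  set.seed(42)
  vol <- voxel_volume(array(runif(27 * 64), c(48, 6, 6)), 5)
  lo <- threshold_volume(vol, 0.3)
  hi <- threshold_volume(vol, 0.7)
  expect_true(all(vol$values[hi$values] >= 0.7))
  expect_true(all(hi$values <= lo$values))
})

test_that("resampling: identity, block vote and spacing bookkeeping", {
  vol <- capsule_volume(6, 20)
  expect_identical(resample_volume(vol, 1)$values, vol$values)
  block <- voxel_volume(array(TRUE, c(2, 2, 2)), 10)
  down <- resample_volume(block, 2)
  expect_equal(dim(down$values), c(1, 1, 1))
  expect_true(down$values[1, 1, 1])
  expect_equal(down$spacing, 20)
  expect_error(resample_volume(vol, 0), "factor")
})

test_that("resampling a cylinder conserves foreground volume within 10%", {
  vol <- capsule_volume(10, 60, spacing = 10)
  down <- resample_volume(vol, 2)
  v0 <- sum(vol$values) * (vol$spacing / 1000)^3
  v1 <- sum(down$values) * (down$spacing / 1000)^3
  expect_lt(abs(v1 / v0 - 1), 0.10)
})

test_that("majority vote ties go to foreground", {
  half <- array(FALSE, c(2, 2, 2))
  half[1, , ] <- TRUE  # 4 of 8 voxels
  down <- resample_volume(voxel_volume(half, 10), 2)
  expect_true(down$values[1, 1, 1])
})

test_that("opening: identity at radius 0, anti-extensive, idempotent", {
  vol <- capsule_volume(8, 30)
  expect_identical(open_volume(vol, 0)$values, vol$values)
  o1 <- open_volume(vol, 2)
  expect_true(all(o1$values <= vol$values))       # anti-extensive
  o2 <- open_volume(o1, 2)
  expect_identical(o2$values, o1$values)          # idempotent
})

test_that("opening removes a 2-voxel bridge between thick tubes", {
  d <- c(30, 70, 30)
  segs <- rbind(c(15, 5, 15, 15, 25, 15, 8),
                c(15, 45, 15, 15, 65, 15, 8))
  arr <- cpp_capsules(d, segs)
  arr[15:16, 26:44, 15:16] <- TRUE  # 2x2 bridge
  vol <- voxel_volume(arr, 10)
  n0 <- max(airwaymorph:::cpp_label_components(as.logical(arr), d, 26L))
  expect_equal(n0, 1)
  opened <- open_volume(vol, 2)
  n1 <- max(airwaymorph:::cpp_label_components(as.logical(opened$values),
                                               d, 26L))
  expect_equal(n1, 2)
  # the tubes themselves survive
  expect_gt(sum(opened$values), 0.8 * sum(cpp_capsules(d, segs)))
})

test_that("largest_component keeps the cast and drops debris", {
  vol <- capsule_volume(6, 30)
  expect_identical(largest_component(vol)$values, vol$values)
  arr <- vol$values
  arr[1, 1, 1] <- TRUE  # distant speck
  kept <- largest_component(voxel_volume(arr, 10))
  expect_identical(kept$values, vol$values)
  expect_error(largest_component(voxel_volume(array(FALSE, c(3, 3, 3)), 10)),
               "empty")
})

test_that("largest_component agrees with a brute-force flood fill", {
  set.seed(7)
  arr <- array(runif(12^3) < 0.25, c(12, 12, 12))
  arr[1, 1, 1] <- TRUE
  # oracle: plain R BFS flood fill over 26-neighborhoods
  comp_sizes <- local({
    seen <- array(FALSE, dim(arr))
    sizes <- integer(0)
    idx <- which(arr, arr.ind = TRUE)
    for (s in seq_len(nrow(idx))) {
      p <- idx[s, ]
      if (seen[p[1], p[2], p[3]]) next
      size <- 0
      queue <- list(p)
      seen[p[1], p[2], p[3]] <- TRUE
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        size <- size + 1
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          r <- q + c(dx, dy, dz)
          if (any(r < 1) || any(r > dim(arr))) next
          if (arr[r[1], r[2], r[3]] && !seen[r[1], r[2], r[3]]) {
            seen[r[1], r[2], r[3]] <- TRUE
            queue[[length(queue) + 1]] <- r
          }
        }
      }
      sizes <- c(sizes, size)
    }
    sizes
  })
  kept <- largest_component(voxel_volume(arr, 10))
  expect_equal(sum(kept$values), max(comp_sizes))
})

test_that("workflow accuracy estimate follows 2 x bandwidth x voxel", {
  ref <- accuracy_estimate(6.6, 2, 2)
  expect_equal(ref$bandwidth_voxels, 4)
  expect_equal(ref$exact_um, 52.8)
  expect_equal(ref$about_um, 50)
  expect_equal(accuracy_estimate(1, 1, 1)$exact_um, 2)
  expect_equal(accuracy_estimate(10, 2, 3)$exact_um, 120)
})

test_that("provenance records every pre-processing step in order", {
  vol <- capsule_volume(8, 30)
  out <- preprocess_volume(vol, pipeline_config(resample_factor = 2,
                                                opening_radius_px = 1))
  ops <- vapply(provenance(out), `[[`, "", "op")
  expect_equal(ops, c("resample", "opening", "largest_component"))
})
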