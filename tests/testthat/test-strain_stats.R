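# Comparison statistics: branch matching, through-origin regression,
# ANOVA across strains, paired t with Bonferroni.

fake_table <- function(labels, seed = 1) {
  set.seed(seed)
  data.frame(
    label = labels,
    generation = nchar(labels),
    length_mm = runif(length(labels), 0.5, 3),
    diameter_mm = runif(length(labels), 0.2, 1.2),
    branch_angle_deg = runif(length(labels), 5, 90),
    gravity_angle_deg = runif(length(labels), 0, 180),
    stringsAsFactors = FALSE
  )
}

complete_labels <- function(gmax) {
  labs <- "1"
  out <- labs
  for (g in 2:gmax) {
    labs <- c(paste0(labs, "1"), paste0(labs, "2"))
    out <- c(out, labs)
  }
  out
}

test_that("branch matching is an inner join on labels", {
  labs <- complete_labels(6)
  a <- fake_table(labs, 1)
  b <- fake_table(labs, 2)
  mp <- match_branches(a, b)
  expect_equal(nrow(mp$pairs), 63)
  expect_length(mp$only_a, 0)
  # disjoint tables pair nothing
  mp0 <- match_branches(a[1:3, ], b[10:20, ])
  expect_equal(nrow(mp0$pairs), 0)
  # a table missing two generation-6 airways pairs 61 of 63
  b61 <- b[!(b$label %in% tail(labs, 2)), ]
  mp61 <- match_branches(a, b61)
  expect_equal(nrow(mp61$pairs), 61)
  expect_length(mp61$only_a, 2)
  expect_error(match_branches(rbind(a, a[1, ]), b), "duplicate")
})

test_that("through-origin regression matches closed forms", {
  x <- c(1, 2, 3, 4)
  fit <- regression_through_origin(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  fit2 <- regression_through_origin(x, -x)
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$r, -1)
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "zero")
})

test_that("through-origin slope equals the numeric minimizer", {
  set.seed(11)
  x <- runif(50, 0, 5)
  y <- 1.7 * x + rnorm(50, 0, 0.4)
  fit <- regression_through_origin(x, y)
  # oracle: grid refinement of argmin sum((y - b x)^2)
  obj <- function(b) sum((y - b * x)^2)
  lo <- -5; hi <- 5
  for (pass in 1:30) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, obj, 0)
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(41, i + 1)]
  }
  expect_equal(fit$slope, (lo + hi) / 2, tolerance = 1e-6)
  # r matches the covariance formula
  expect_equal(fit$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
})

test_that("regression is scale-equivariant in y", {
  set.seed(3)
  x <- runif(20, 1, 4)
  y <- 0.8 * x + rnorm(20, 0, 0.2)
  f1 <- regression_through_origin(x, y)
  f2 <- regression_through_origin(x, 3 * y)
  expect_equal(f2$slope, 3 * f1$slope, tolerance = 1e-12)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
})

test_that("slope on paired noisy diameters concentrates near 1", {
  set.seed(5)
  d <- rep(1.2 * 0.75^(0:5), times = 2^(0:5))
  for (noise in c(0.05, 0.01)) {
    a <- d * (1 + rnorm(length(d), 0, noise))
    b <- d * (1 + rnorm(length(d), 0, noise))
    fit <- regression_through_origin(a, b)
    expect_lt(abs(fit$slope - 1), 4 * noise)
  }
})

test_that("ANOVA across strains: degenerate and textbook cases", {
  tabs <- list(fake_table("1", 1), fake_table("1", 2),
               fake_table("1", 3), fake_table("1", 4))
  for (i in seq_along(tabs)) tabs[[i]]$length_mm <- 2  # identical groups
  res <- anova_by_strain(tabs, c("A", "A", "B", "B"),
                         measures = "length_mm")
  expect_equal(res$F[1], 0)
  expect_equal(res$p[1], 1)

  # textbook 3 + 3: groups (1,2,3) and (5,6,7)
  mk <- function(v) {
    t <- fake_table("1")
    t$length_mm <- v
    t
  }
  tabs2 <- list(mk(1), mk(2), mk(3), mk(5), mk(6), mk(7))
  res2 <- anova_by_strain(tabs2, c(rep("A", 3), rep("B", 3)),
                          measures = "length_mm")
  # hand arithmetic: MSbetween = 24, MSwithin = 1 -> F = 24
  expect_equal(res2$F[1], 24, tolerance = 1e-12)
  expect_equal(res2$p[1], 1 - pf(24, 1, 4), tolerance = 1e-12)
  expect_true(res2$sig_05[1])

  # insufficient groups reported, not fabricated
  res3 <- anova_by_strain(list(mk(1), mk(2)), c("A", "B"),
                          measures = "length_mm")
  expect_true(is.na(res3$p[1]))
  expect_match(res3$reason[1], "insufficient")
})

test_that("ANOVA p-values live in [0, 1] for random inputs", {
  set.seed(9)
  for (rep in 1:5) {
    tabs <- lapply(1:6, function(i) {
      t <- fake_table("1", i + rep * 10)
      t
    })
    res <- anova_by_strain(tabs, rep(c("A", "B", "C"), each = 2),
                           measures = c("length_mm", "diameter_mm"))
    expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  }
})

test_that("paired t with Bonferroni handles degenerate and shifted pairs", {
  same <- list(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  r <- paired_t_bonferroni(same)
  expect_equal(r$t, 0)
  expect_true(r$degenerate)
  const <- list(list(x = c(2, 3, 4, 5, 6), y = c(1, 2, 3, 4, 5)))
  r2 <- paired_t_bonferroni(const)
  expect_true(is.infinite(r2$t))
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)
  # threshold is alpha / m and adjusted p = min(1, m p)
  set.seed(2)
  cmps <- lapply(1:4, function(i)
    list(x = rnorm(8, 0.5), y = rnorm(8)))
  r3 <- paired_t_bonferroni(cmps, alpha = 0.01)
  expect_equal(unique(r3$threshold), 0.01 / 4)
  expect_equal(r3$p_adjusted, pmin(1, 4 * r3$p))
})

test_that("paired t p-value agrees with a permutation oracle", {
  set.seed(17)
  x <- rnorm(9, 0.8, 1)
  y <- rnorm(9, 0, 1)
  r <- paired_t_bonferroni(list(list(x = x, y = y)), m = 1)
  d <- x - y
  tobs <- abs(mean(d) / (sd(d) / sqrt(length(d))))
  # exact sign-flip permutation distribution (2^9 = 512 flips)
  flips <- expand.grid(rep(list(c(-1, 1)), 9))
  tperm <- apply(flips, 1, function(s) {
    ds <- d * as.numeric(s)
    abs(mean(ds) / (sd(ds) / sqrt(length(ds))))
  })
  p_perm <- mean(tperm >= tobs - 1e-12)
  expect_lt(abs(r$p - p_perm), 0.06)
})

test_that("compare_tables reports slope/r per measure", {
  labs <- complete_labels(4)
  a <- fake_table(labs, 4)
  b <- a
  b$length_mm <- a$length_mm * 1.05
  b$diameter_mm <- a$diameter_mm
  res <- compare_tables(a, b)
  expect_equal(res$slope[res$measure == "length_mm"], 1.05,
               tolerance = 1e-12)
  expect_equal(res$r[res$measure == "diameter_mm"], 1)
  expect_equal(unique(res$n), nrow(a))
})
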