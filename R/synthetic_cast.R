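#' Specification of a synthetic airway-tree phantom
#'
#' Parametric description of a bifurcating airway tree used to generate
#' voxel phantoms with analytic ground truth. Defaults emulate a mouse
#' tracheobronchial tree: tracheal diameter 1.2 mm, per-generation diameter
#' ratio 0.75, length/diameter ratio 2. The trachea runs along +y and the
#' lungs extend toward -z, so the anatomical gravity construction (see
#' [gravity_vector()]) is non-trivial.
#'
#' @param generations Number of airway generations (trachea = generation 1).
#' @param length_scale Per-generation mean branch length, mm. A vector of
#'   length `generations` (recycled from the default geometric series when a
#'   single ratio-based default is wanted).
#' @param diameter_scale Per-generation mean branch diameter, mm.
#' @param branch_angle_mean,branch_angle_sd Daughter departure angle
#'   distribution, degrees.
#' @param daughter_asymmetry Ratio of minor/major daughter diameter in (0,1].
#' @param curvature Maximum centerline bow (sagitta) as a fraction of branch
#'   length; 0 gives straight branches.
#' @param prune_prob Per-branch probability that a subtree (generation >= 3)
#'   is absent.
#' @param seed Integer seed; identical specs give identical phantoms.
#' @return A `tree_spec` object.
#' @export
tree_spec <- function(generations = 6,
                      length_scale = NULL,
                      diameter_scale = NULL,
                      branch_angle_mean = 35,
                      branch_angle_sd = 8,
                      daughter_asymmetry = 0.8,
                      curvature = 0,
                      prune_prob = 0,
                      seed = 1L) {
  if (!is.numeric(generations) || generations < 1) {
    stop("`generations` must be >= 1")
  }
  generations <- as.integer(generations)
  if (is.null(diameter_scale)) diameter_scale <- 1.2 * 0.75^(0:(generations - 1))
  if (is.null(length_scale)) length_scale <- 2 * diameter_scale
  stopifnot(length(length_scale) == generations,
            length(diameter_scale) == generations,
            all(length_scale > 0), all(diameter_scale > 0))
  if (daughter_asymmetry <= 0 || daughter_asymmetry > 1) {
    stop("`daughter_asymmetry` must be in (0, 1]")
  }
  if (prune_prob < 0 || prune_prob >= 1) stop("`prune_prob` must be in [0,1)")
  structure(list(
    generations = generations,
    length_scale = as.numeric(length_scale),
    diameter_scale = as.numeric(diameter_scale),
    branch_angle_mean = branch_angle_mean,
    branch_angle_sd = branch_angle_sd,
    daughter_asymmetry = daughter_asymmetry,
    curvature = curvature,
    prune_prob = prune_prob,
    seed = as.integer(seed)
  ), class = "tree_spec")
}

# Deterministic per-branch random substream: draws for one branch depend only
# on (seed, label), so pruning one subtree never perturbs its siblings.
label_rng <- function(seed, label, n) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  h <- (h + as.numeric(seed) * 7919) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(h))
  stats::runif(n)
}

# Gaussian draw from uniform substream values (Box-Muller).
substream_normal <- function(u1, u2) {
  sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
}

#' Build the resolved geometry and ground truth of a phantom tree
#'
#' Recursively constructs a bifurcating tree in 3D from a [tree_spec()].
#' Branch geometry is analytic (capsules; optional circular-arc bows), and
#' the ground-truth morphometry table (lengths, diameters, branch angles,
#' gravity angles, Raabe labels) is computed in closed form from the
#' generated node coordinates. The two main bronchi are never pruned, so
#' the anatomical gravity vector is always defined for `generations >= 2`.
#'
#' @param spec A [tree_spec()].
#' @return An `airway_tree`: list with `spec`, `branches` (per-branch
#'   geometry), `ground_truth` (data frame; see [write_ground_truth()]) and
#'   `gravity` (unit 3-vector, or NULL for a single-generation tree).
#' @export
build_tree <- function(spec) {
  if (!inherits(spec, "tree_spec")) stop("`spec` must be a tree_spec")
  branches <- list()

  grow <- function(label, p0, dir, normal) {
    g <- nchar(label)
    u <- label_rng(spec$seed, label, 8)
    L <- spec$length_scale[g]
    D <- spec$diameter_scale[g]
    if (label == "1") {
      len <- L
      diam <- D
    } else {
      # scale stored on the parent's dispatch; passed via attr on dir
      len <- attr(dir, "length")
      diam <- attr(dir, "diameter")
    }
    d <- unit(as.numeric(dir))
    p1 <- p0 + d * len
    sag <- spec$curvature * len * u[7]
    branches[[label]] <<- list(
      label = label, generation = g, p0 = p0, p1 = p1,
      dir = d, length = len, diameter = diam, normal = normal,
      sagitta = sag
    )
    if (g >= spec$generations) return(invisible())

    # daughter departure angles and bifurcation-plane rotation
    th1 <- min(80, max(10, spec$branch_angle_mean +
                         spec$branch_angle_sd * substream_normal(u[1], u[2])))
    th2 <- min(80, max(10, spec$branch_angle_mean +
                         spec$branch_angle_sd * substream_normal(u[3], u[4])))
    a <- spec$daughter_asymmetry
    base_d <- spec$diameter_scale[g + 1]
    base_l <- spec$length_scale[g + 1]
    d_major <- base_d * 2 / (1 + a)
    d_minor <- a * d_major
    l_major <- base_l * d_major / base_d
    l_minor <- base_l * d_minor / base_d

    dir1 <- rotate_about(d, normal, th1)
    dir2 <- rotate_about(d, normal, -th2)
    if (label == "1") {
      # tilt the main bronchi toward -z so the lungs hang below the trachea
      dir1 <- unit(dir1 + c(0, 0, -0.35))
      dir2 <- unit(dir2 + c(0, 0, -0.35))
    }
    # major daughter on a random side
    swap <- u[5] < 0.5
    dmaj <- if (swap) dir2 else dir1
    dmin <- if (swap) dir1 else dir2

    # next bifurcation plane: rotate ~90 deg about the daughter axis
    phi <- 90 + 20 * (u[6] - 0.5)
    for (side in c("1", "2")) {
      dd <- if (side == "1") dmaj else dmin
      child <- paste0(label, side)
      # prune subtrees (but never the main bronchi)
      uc <- label_rng(spec$seed, paste0(child, ":prune"), 1)
      if (nchar(child) >= 3 && spec$prune_prob > 0 && uc < spec$prune_prob) {
        next
      }
      nrm <- unit(rotate_about(normal, dd, phi) -
                    sum(rotate_about(normal, dd, phi) * dd) * dd)
      dd2 <- dd
      attr(dd2, "length") <- if (side == "1") l_major else l_minor
      attr(dd2, "diameter") <- if (side == "1") d_major else d_minor
      grow(child, p1, dd2, nrm)
    }
    invisible()
  }

  root_dir <- c(0, 1, 0)
  attr(root_dir, "length") <- spec$length_scale[1]
  attr(root_dir, "diameter") <- spec$diameter_scale[1]
  grow("1", c(0, 0, 0), root_dir, c(1, 0, 0))

  tree <- structure(list(spec = spec, branches = branches), class = "airway_tree")
  tree$gravity <- tree_gravity(tree)
  tree$ground_truth <- tree_ground_truth(tree)
  tree
}

# Anatomical gravity vector from the true geometry: perpendicular to the
# trachea, in the plane of the trachea and the mean main-bronchus direction.
tree_gravity <- function(tree) {
  br <- tree$branches
  if (is.null(br[["11"]]) || is.null(br[["12"]])) return(NULL)
  t_vec <- unit(br[["1"]]$p1 - br[["1"]]$p0)
  b1 <- unit(br[["11"]]$p1 - br[["11"]]$p0)
  b2 <- unit(br[["12"]]$p1 - br[["12"]]$p0)
  b <- unit(b1 + b2)
  g <- b - sum(b * t_vec) * t_vec
  if (vnorm(g) < 1e-12) return(NULL)
  g <- unit(g)
  if (sum(g * b) < 0) g <- -g
  g
}

tree_ground_truth <- function(tree) {
  br <- tree$branches
  g <- tree$gravity
  labs <- names(br)
  labs <- labs[order(nchar(labs), labs)]
  rows <- lapply(labs, function(lab) {
    b <- br[[lab]]
    parent <- if (nchar(lab) > 1) br[[substr(lab, 1, nchar(lab) - 1)]] else NULL
    chord <- b$p1 - b$p0
    ba <- if (is.null(parent)) NA_real_ else
      vec_angle_deg(parent$p1 - parent$p0, chord)
    ga <- if (is.null(g)) NA_real_ else vec_angle_deg(chord, g)
    data.frame(
      label = lab, generation = b$generation,
      x1 = b$p0[1], y1 = b$p0[2], z1 = b$p0[3],
      x2 = b$p1[1], y2 = b$p1[2], z2 = b$p1[3],
      length_mm = vnorm(chord), diameter_mm = b$diameter,
      branch_angle_deg = ba, gravity_angle_deg = ga,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("<airway_tree> %d branches, %d generations, seed %d\n",
              length(x$branches), x$spec$generations, x$spec$seed))
  invisible(x)
}

# Centerline polyline of one branch in mm: straight chord or circular-arc bow
# (sagitta = curvature * length, bowed along the bifurcation-plane normal).
branch_polyline <- function(branch, step_mm = NULL) {
  p0 <- branch$p0
  p1 <- branch$p1
  if (is.null(step_mm)) step_mm <- branch$length / 16
  n <- max(2, ceiling(branch$length / step_mm) + 1)
  t <- seq(0, 1, length.out = n)
  pts <- outer(1 - t, p0) + outer(t, p1)
  if (branch$sagitta > 0) {
    bow <- branch$normal * branch$sagitta
    pts <- pts + outer(sin(pi * t), bow)
  }
  pts
}

#' Rasterize a phantom tree into a binary voxel volume
#'
#' Each branch is swept as a capsule (hemispherically capped tube) along its
#' centerline; the volume is the union over branches. The grid is sized to
#' the tree's bounding box plus padding, and positions are recoverable via
#' the recorded origin/spacing.
#'
#' @param tree An `airway_tree` from [build_tree()].
#' @param voxel_size Isotropic voxel edge length, micrometers.
#' @param pad_voxels Padding around the bounding box, voxels.
#' @return A binary `voxel_volume`. Warns if the smallest branch diameter
#'   falls below 4 voxels (below the workflow's resolving accuracy).
#' @export
rasterize_tree <- function(tree, voxel_size, pad_voxels = 4) {
  if (!inherits(tree, "airway_tree")) stop("`tree` must be an airway_tree")
  vs_mm <- voxel_size / 1000
  if (length(tree$branches) == 0) {
    return(voxel_volume(array(FALSE, c(1, 1, 1)), voxel_size))
  }
  min_d <- min(vapply(tree$branches, `[[`, 0, "diameter"))
  if (min_d / vs_mm < 4) {
    warning(sprintf(paste0("smallest branch diameter is %.1f voxels ",
                           "(< 4): measurements fall below the workflow ",
                           "accuracy"), min_d / vs_mm))
  }
  polys <- lapply(tree$branches, branch_polyline, step_mm = vs_mm * 4)
  allpts <- do.call(rbind, polys)
  radii <- vapply(tree$branches, function(b) b$diameter / 2, 0)
  rmax <- max(radii)
  lo <- apply(allpts, 2, min) - rmax - pad_voxels * vs_mm
  hi <- apply(allpts, 2, max) + rmax + pad_voxels * vs_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / vs_mm)) + 1L)
  origin_um <- lo * 1000
  vol <- logical(prod(dims))
  segs <- list()
  for (lab in names(tree$branches)) {
    pts <- polys[[lab]]
    vox <- world_to_voxel(pts, voxel_size, origin_um) - 1  # 0-based for C++
    r_vox <- tree$branches[[lab]]$diameter / 2 / vs_mm
    n <- nrow(vox)
    segs[[lab]] <- cbind(vox[-n, , drop = FALSE], vox[-1, , drop = FALSE],
                         rep(r_vox, n - 1))
  }
  segmat <- do.call(rbind, segs)
  vol <- cpp_rasterize_capsules(vol, dims, segmat)
  out <- voxel_volume(array(vol, dims), voxel_size, origin_um)
  add_provenance(out, "rasterize_tree",
                 list(voxel_size = voxel_size, seed = tree$spec$seed))
}

#' Inject scan-artifact classes into a phantom volume
#'
#' Emulates the defects real cast scans exhibit: thin artificial contacts
#' between branches (removable by morphological opening), annular-ligament
#' spur nubs, thick bridges that close loops, and trifurcations.
#'
#' @param volume Binary `voxel_volume` from [rasterize_tree()].
#' @param tree The `airway_tree` the volume was rasterized from.
#' @param artifacts List of artifact specs, each a list with `kind` (one of
#'   `"touching_branches"`, `"spur_nub"`, `"closed_loop"`,
#'   `"trifurcation"`), `location` (a branch label, or two labels for
#'   bridges) and `magnitude` (micrometers; bridge/nub thickness or length).
#' @return The modified binary volume (provenance records each artifact).
#' @export
inject_artifacts <- function(volume, tree, artifacts) {
  if (length(artifacts) == 0) return(volume)
  dims <- dim(volume$values)
  vs_mm <- volume$spacing / 1000
  vol <- as.logical(volume$values)
  segs <- NULL
  for (a in artifacts) {
    kind <- a$kind
    if (!kind %in% c("touching_branches", "spur_nub", "closed_loop",
                     "trifurcation")) {
      stop("unknown artifact kind: ", kind)
    }
    mag_mm <- a$magnitude / 1000
    if (kind %in% c("touching_branches", "closed_loop")) {
      labs <- a$location
      if (length(labs) != 2 || !all(labs %in% names(tree$branches))) {
        stop("bridge artifacts need two existing branch labels")
      }
      b1 <- tree$branches[[labs[1]]]
      b2 <- tree$branches[[labs[2]]]
      # bridge between genuinely separated surface patches: the closest
      # centerline pair whose surface gap is at least 3 voxels (points
      # nearer a shared node are already fused in the cast), crossing
      # empty space rather than a third branch
      others <- setdiff(names(tree$branches), labs)
      obst <- do.call(rbind, lapply(tree$branches[others], branch_polyline))
      obst_r <- rep(
        vapply(tree$branches[others], function(bb) bb$diameter / 2, 0),
        vapply(tree$branches[others],
               function(bb) nrow(branch_polyline(bb)), 0L))
      pq <- closest_separated(branch_polyline(b1), branch_polyline(b2),
                              b1$diameter / 2, b2$diameter / 2,
                              min_gap = max(3 * vs_mm, 1.5 * mag_mm),
                              obstacles = obst, obstacle_r = obst_r,
                              clearance = mag_mm / 2 + vs_mm)
      if (is.null(pq)) {
        stop("branches ", labs[1], " and ", labs[2],
             " have no separated surfaces to bridge")
      }
      segs <- rbind(segs, c(pq$p, pq$q, mag_mm / 2))
    } else if (kind == "spur_nub") {
      lab <- a$location
      if (!lab %in% names(tree$branches)) stop("no such branch: ", lab)
      b <- tree$branches[[lab]]
      mid <- (b$p0 + b$p1) / 2
      # protrude in the perpendicular direction with the most clearance
      # from the rest of the tree, so the nub touches nothing else
      binormal <- unit(pracma_cross(b$dir, b$normal))
      cands <- list(unit(b$normal), -unit(b$normal), binormal, -binormal)
      other_pts <- do.call(rbind, lapply(
        tree$branches[setdiff(names(tree$branches), lab)],
        branch_polyline))
      other_r <- rep(vapply(tree$branches[setdiff(names(tree$branches), lab)],
                            function(bb) bb$diameter / 2, 0),
                     vapply(tree$branches[setdiff(names(tree$branches), lab)],
                            function(bb) nrow(branch_polyline(bb)), 0L))
      clearance <- vapply(cands, function(dd) {
        tip <- mid + dd * (b$diameter / 2 + mag_mm)
        min(sqrt(rowSums(sweep(other_pts, 2, tip)^2)) - other_r)
      }, 0)
      dd <- cands[[which.max(clearance)]]
      tip <- mid + dd * (b$diameter / 2 + mag_mm)
      r <- if (!is.null(a$radius)) a$radius / 1000 else mag_mm / 2
      segs <- rbind(segs, c(mid, tip, r))
    } else if (kind == "trifurcation") {
      lab <- a$location
      if (!lab %in% names(tree$branches)) stop("no such branch: ", lab)
      b <- tree$branches[[lab]]
      c1 <- tree$branches[[paste0(lab, "1")]]
      c2 <- tree$branches[[paste0(lab, "2")]]
      if (is.null(c1) || is.null(c2)) {
        stop("trifurcation needs a branch with two daughters: ", lab)
      }
      g <- b$generation
      spec <- tree$spec
      d_extra <- if (g < spec$generations) spec$diameter_scale[g + 1] else
        b$diameter * 0.75
      l_extra <- if (g < spec$generations) spec$length_scale[g + 1] else
        b$length * 0.75
      # third daughter leaves the existing daughters' plane, pointing away
      # from the rest of the tree so it does not collide with other subtrees
      nrm <- unit(pracma_cross(c1$dir, c2$dir))
      centroid <- colMeans(do.call(rbind, lapply(tree$branches,
                                                 function(bb) bb$p1)))
      if (sum(nrm * (b$p1 - centroid)) < 0) nrm <- -nrm
      bis <- unit(c1$dir + c2$dir)
      dir3 <- unit(bis * cos(50 * pi / 180) + nrm * sin(50 * pi / 180))
      segs <- rbind(segs, c(b$p1, b$p1 + dir3 * l_extra, d_extra / 2))
    }
  }
  if (!is.null(segs)) {
    v1 <- world_to_voxel(segs[, 1:3, drop = FALSE], volume$spacing,
                         volume$origin) - 1
    v2 <- world_to_voxel(segs[, 4:6, drop = FALSE], volume$spacing,
                         volume$origin) - 1
    segmat <- cbind(v1, v2, segs[, 7] / vs_mm)
    vol <- cpp_rasterize_capsules(vol, dims, segmat)
  }
  out <- voxel_volume(array(vol, dims), volume$spacing, volume$origin,
                      provenance(volume))
  for (a in artifacts) {
    out <- add_provenance(out, "inject_artifact",
                          list(kind = a$kind,
                               location = paste(a$location, collapse = "+"),
                               magnitude = a$magnitude))
  }
  out
}

# closest pair of centerline points whose capsule surfaces are separated by
# at least `min_gap` and whose connecting segment stays clear of every other
# branch (so the bridge actually crosses empty space); NULL when impossible
closest_separated <- function(pts1, pts2, r1, r2, min_gap,
                              obstacles = NULL, obstacle_r = NULL,
                              clearance = 0) {
  d2 <- outer(rowSums(pts1^2), rowSums(pts2^2), "+") - 2 * pts1 %*% t(pts2)
  d <- sqrt(pmax(d2, 0))
  d[d - r1 - r2 < min_gap] <- Inf
  # prefer mid-branch contact points: near a shared node the cast is a
  # fused web (a bridge there fills a disk instead of closing a handle),
  # while a contact at the very tip leaves no resolvable distal stub
  fr1 <- (seq_len(nrow(pts1)) - 1) / max(1, nrow(pts1) - 1)
  fr2 <- (seq_len(nrow(pts2)) - 1) / max(1, nrow(pts2) - 1)
  score <- -outer((fr1 - 0.6)^2, (fr2 - 0.6)^2, "+") -
    d / (100 * max(d[is.finite(d)], 1))
  score[!is.finite(d)] <- -Inf
  ord <- order(score, decreasing = TRUE)
  for (idx in ord[seq_len(min(400, length(ord)))]) {
    if (!is.finite(d[idx])) break
    i <- (idx - 1) %% nrow(pts1) + 1
    j <- (idx - 1) %/% nrow(pts1) + 1
    p <- pts1[i, ]
    q <- pts2[j, ]
    ok <- TRUE
    if (!is.null(obstacles) && nrow(obstacles)) {
      tt <- seq(0.1, 0.9, length.out = 9)
      seg <- outer(1 - tt, p) + outer(tt, q)
      for (s in seq_len(nrow(seg))) {
        gap <- sqrt(rowSums(sweep(obstacles, 2, seg[s, ])^2)) - obstacle_r
        if (any(gap < clearance)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(list(p = p, q = q, dist = d[idx]))
  }
  NULL
}

# Closest pair of points between two polylines (vertex-to-vertex; adequate
# for artifact placement).
closest_points <- function(pts1, pts2) {
  d2 <- outer(rowSums(pts1^2), rowSums(pts2^2), "+") -
    2 * pts1 %*% t(pts2)
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(p = pts1[ij[1], ], q = pts2[ij[2], ], dist = sqrt(max(0, min(d2))))
}

#' Rigidly transform a phantom tree
#'
#' Applies a rotation matrix and translation to every branch. Ground truth
#' (including gravity, which is anatomy-defined) is recomputed, so all true
#' angles are unchanged: useful for testing that measurements are invariant
#' under rigid motion of the scanned cast.
#'
#' @param tree An `airway_tree`.
#' @param R 3x3 rotation matrix.
#' @param translation Length-3 shift, mm.
#' @return The transformed `airway_tree`.
#' @export
transform_tree <- function(tree, R = diag(3), translation = c(0, 0, 0)) {
  for (lab in names(tree$branches)) {
    b <- tree$branches[[lab]]
    b$p0 <- as.numeric(R %*% b$p0 + translation)
    b$p1 <- as.numeric(R %*% b$p1 + translation)
    b$dir <- as.numeric(R %*% b$dir)
    b$normal <- as.numeric(R %*% b$normal)
    tree$branches[[lab]] <- b
  }
  tree$gravity <- tree_gravity(tree)
  tree$ground_truth <- tree_ground_truth(tree)
  tree
}

#' Write / read a ground-truth (or measured) morphometry table as CSV
#'
#' Column schema: label, generation, x1,y1,z1,x2,y2,z2 (mm), length_mm,
#' diameter_mm, branch_angle_deg, gravity_angle_deg.
#'
#' @param truth Data frame (e.g. `tree$ground_truth`).
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  df
}
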