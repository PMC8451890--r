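# Per-branch morphometry: node-to-node length, averaged hydraulic diameter
# from perpendicular cross-sections, branch angle, inclination to gravity,
# Raabe binary labels and airway generations.

#' Branch vector (proximal to distal node)
#'
#' @param branch A branch from a `centerline_network` (list with `polyline`).
#' @return Length-3 numeric, mm. A zero vector (coincident nodes) carries
#'   attribute `degenerate = TRUE`.
#' @export
branch_vector <- function(branch) {
  v <- branch$polyline[nrow(branch$polyline), ] - branch$polyline[1, ]
  if (vnorm(v) == 0) attr(v, "degenerate") <- TRUE
  v
}

#' Airway length: linear distance between the two bifurcation nodes
#'
#' The chord, not the arc length of the centerline.
#'
#' @param branch A branch (list with `polyline`).
#' @return Length in mm.
#' @export
airway_length <- function(branch) {
  vnorm(branch_vector(branch))
}

#' Branch angle between parent and daughter airway vectors
#'
#' Angle (degrees, in \[0, 180\]) between the proximal-to-distal vectors of
#' parent and daughter; a straight continuation scores 0.
#'
#' @param parent_vector,daughter_vector Length-3 numeric vectors, mm.
#' @return Degrees, or NA (flagged) for a zero vector.
#' @export
branch_angle <- function(parent_vector, daughter_vector) {
  vec_angle_deg(parent_vector, daughter_vector)
}

#' Anatomical gravity vector of a cast
#'
#' Gravity is assumed perpendicular to the trachea and lying in the plane
#' of the trachea and the average of the two main-bronchus vectors:
#' `g = normalize(b - (b.t) t)` with the sign chosen so `g.b >= 0`. By
#' construction the trachea's inclination to gravity is exactly 90 degrees.
#'
#' @param network A rooted `centerline_network` whose root branch has two
#'   daughters.
#' @return Unit 3-vector.
#' @export
gravity_vector <- function(network) {
  rb <- root_branch(network)
  if (is.na(rb)) stop("network has no root branch")
  kids <- branch_children(network, rb)
  if (length(kids) < 2) stop("root branch must have two daughters")
  t_vec <- unit(branch_vector(network$branches[[rb]]))
  b1 <- unit(branch_vector(network$branches[[kids[1]]]))
  b2 <- unit(branch_vector(network$branches[[kids[2]]]))
  b <- unit(b1 + b2)
  g <- b - sum(b * t_vec) * t_vec
  if (vnorm(g) < 1e-9) stop("main-bronchi average is parallel to the trachea")
  g <- unit(g)
  if (sum(g * b) < 0) g <- -g
  g
}

root_branch <- function(network) {
  for (k in seq_along(network$branches)) {
    if (is.na(network$branches[[k]]$parent)) return(k)
  }
  NA_integer_
}

#' Inclination to gravity of one airway
#'
#' @param branch_vector Length-3 airway vector, mm.
#' @param g Unit gravity vector.
#' @return Degrees in \[0, 180\]; NA for a zero branch vector.
#' @export
gravity_angle <- function(branch_vector, g) {
  vec_angle_deg(branch_vector, g)
}

# --- hydraulic diameter ------------------------------------------------

# vectorized trilinear interpolation of a 3D array at continuous 1-based
# voxel coordinates (n x 3); outside the grid -> 0
trilinear_interp <- function(arr, pts) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (dx * fx + (1 - dx) * (1 - fx)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (dz * fz + (1 - dz) * (1 - fz))
    ok <- xi >= 1 & yi >= 1 & zi >= 1 & xi <= d[1] & yi <= d[2] & zi <= d[3]
    v <- numeric(nrow(pts))
    if (any(ok)) {
      v[ok] <- arr[cbind(xi[ok], yi[ok], zi[ok])]
    }
    val <- val + w * v
  }
  val
}

# separable Gaussian blur of a matrix (zero-padded edges); suppresses the
# staircase jaggedness of the 0.5-level contour of interpolated binary data,
# which otherwise inflates perimeters by several percent
gauss_blur_2d <- function(M, sd_px = 1) {
  k <- stats::dnorm(-3:3, sd = sd_px)
  k <- k / sum(k)
  M1 <- apply(M, 2, function(col) {
    v <- stats::filter(col, k, sides = 2)
    v[is.na(v)] <- 0
    as.numeric(v)
  })
  t(apply(t(M1), 2, function(col) {
    v <- stats::filter(col, k, sides = 2)
    v[is.na(v)] <- 0
    as.numeric(v)
  }))
}

# 4-connected flood fill of a logical matrix from (i0, j0)
flood_fill_2d <- function(B, i0, j0) {
  filled <- matrix(FALSE, nrow(B), ncol(B))
  if (!B[i0, j0]) return(filled)
  frontier <- filled
  frontier[i0, j0] <- TRUE
  filled[i0, j0] <- TRUE
  nr <- nrow(B); nc <- ncol(B)
  repeat {
    grown <- matrix(FALSE, nr, nc)
    grown[-1, ] <- grown[-1, ] | frontier[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | frontier[-1, ]
    grown[, -1] <- grown[, -1] | frontier[, -nc]
    grown[, -nc] <- grown[, -nc] | frontier[, -1]
    frontier <- grown & B & !filled
    if (!any(frontier)) break
    filled <- filled | frontier
  }
  filled
}

polygon_area_perimeter <- function(xs, ys) {
  n <- length(xs)
  if (xs[1] != xs[n] || ys[1] != ys[n]) {
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
    n <- n + 1
  }
  area <- abs(sum(xs[-n] * ys[-1] - xs[-1] * ys[-n])) / 2
  per <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  list(area = area, perimeter = per)
}

point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# resample a polyline at equal arclength stations; returns positions,
# tangents and interpolated per-point auxiliary values
polyline_stations <- function(pts, aux, step_mm, exclude0 = 0,
                              exclude1 = 0) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  lo <- exclude0
  hi <- total - exclude1
  if (hi <= lo) return(NULL)
  st <- seq(lo, hi, by = step_mm)
  if (!length(st)) st <- (lo + hi) / 2
  interp_row <- function(t) {
    i <- findInterval(t, s, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(pts) - 1)
    f <- if (seglen[i] > 0) (t - s[i]) / seglen[i] else 0
    pts[i, ] * (1 - f) + pts[i + 1, ] * f
  }
  pos <- t(vapply(st, interp_row, numeric(3)))
  # tangents by central differences on the stations
  tangent <- pos
  eps <- max(step_mm / 2, 1e-6)
  for (i in seq_along(st)) {
    a <- interp_row(max(lo, st[i] - eps))
    b <- interp_row(min(hi, st[i] + eps))
    v <- b - a
    tangent[i, ] <- if (vnorm(v) > 0) unit(v) else c(NA, NA, NA)
  }
  auxv <- NULL
  if (!is.null(aux)) {
    auxv <- vapply(st, function(t) {
      i <- findInterval(t, s, rightmost.closed = TRUE)
      i <- min(max(i, 1), length(aux) - 1)
      f <- if (seglen[i] > 0) (t - s[i]) / seglen[i] else 0
      aux[i] * (1 - f) + aux[i + 1] * f
    }, 0)
  }
  list(s = st, pos = pos, tangent = tangent, aux = auxv, total = total)
}

#' Averaged hydraulic diameter of one branch
#'
#' Cross-section planes perpendicular to the local centerline tangent are
#' sampled every `step` voxels along the branch (excluding one local
#' radius nearest each node, to avoid bifurcation flare). On each plane the
#' foreground region containing the centerline point is extracted and its
#' hydraulic diameter computed as `4 * Area / Perimeter` from the 0.5-level
#' contour of the trilinearly interpolated mask. A plane is discharged when
#' it crosses another branch's centerline (within the plane half-width
#' laterally and half a step axially) or when the region touches the plane
#' boundary. The branch diameter is the mean over retained planes; when no
#' plane is retained (branch shorter than its diameter, or highly bent) the
#' diameter is 0 with the validity flag unset.
#'
#' @param branch Branch from a `centerline_network` (with `polyline`,
#'   `radius_mm`).
#' @param mask Binary `voxel_volume` the network came from.
#' @param network The full network (for the discharge test against other
#'   branches' centerlines).
#' @param step Plane spacing in voxels (default 2).
#' @param edt Optional precomputed Euclidean distance map of `mask`
#'   (voxels), to avoid recomputation across branches.
#' @return List with `diameter_mm` and `valid`.
#' @export
hydraulic_diameter <- function(branch, mask, network, step = 2, edt = NULL) {
  vox_mm <- mask$spacing / 1000
  pts <- branch$polyline
  if (is.null(edt)) {
    edt <- sqrt(cpp_edt_sq(as.logical(mask$values), dim(mask$values)))
  }
  vox_pts <- world_to_voxel(pts, mask$spacing, mask$origin)
  r_mm <- trilinear_interp(array(edt, dim(mask$values)), vox_pts) * vox_mm
  r_mm[r_mm <= 0] <- vox_mm  # guard: polyline point grazing the surface
  r0 <- r_mm[1]
  r1 <- r_mm[length(r_mm)]
  stations <- polyline_stations(pts, r_mm, step * vox_mm,
                                exclude0 = r0, exclude1 = r1)
  if (is.null(stations)) return(list(diameter_mm = 0, valid = FALSE))

  # other branches' centerline points for the discharge test
  others <- lapply(network$branches, function(b2) {
    if (identical(b2$id, branch$id)) NULL else b2$polyline
  })
  others <- do.call(rbind, others)

  arr <- mask$values
  storage.mode(arr) <- "double"
  dh <- numeric(0)
  for (i in seq_len(nrow(stations$pos))) {
    tg <- stations$tangent[i, ]
    if (any(is.na(tg))) next
    center <- stations$pos[i, ]
    r_loc <- max(stations$aux[i], vox_mm)
    hw <- 2 * r_loc
    # discharge if another centerline comes near this plane
    if (!is.null(others) && nrow(others)) {
      dvec <- sweep(others, 2, center)
      ax <- as.numeric(dvec %*% tg)
      lat2 <- rowSums(dvec^2) - ax^2
      if (any(abs(ax) <= step * vox_mm / 2 & lat2 <= hw^2)) next
    }
    u <- perpendicular_to(tg)
    v <- pracma_cross(tg, u)
    px <- vox_mm * 0.75
    m <- ceiling(hw / px)
    g1 <- seq(-m, m) * px
    grid_uv <- as.matrix(expand.grid(a = g1, b = g1))
    pts3 <- matrix(center, nrow(grid_uv), 3, byrow = TRUE) +
      grid_uv[, 1] %o% u + grid_uv[, 2] %o% v
    vox3 <- world_to_voxel(pts3, mask$spacing, mask$origin)
    f <- trilinear_interp(arr, vox3)
    Fm <- gauss_blur_2d(matrix(f, length(g1), length(g1)))
    ci <- m + 1L
    if (Fm[ci, ci] < 0.5) next  # centerline outside foreground: discharge
    comp <- flood_fill_2d(Fm >= 0.5, ci, ci)
    # region touching the plane boundary: cross-section not fully captured
    if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
        any(comp[, 1]) || any(comp[, ncol(comp)])) next
    Fmask <- Fm
    Fmask[!comp & Fm >= 0.5] <- 0  # suppress other regions in the plane
    cl <- grDevices::contourLines(g1, g1, Fmask, levels = 0.5)
    if (!length(cl)) next
    picked <- NULL
    for (cc in cl) {
      if (point_in_polygon(0, 0, cc$x, cc$y)) {
        picked <- cc
        break
      }
    }
    if (is.null(picked)) next
    ap <- polygon_area_perimeter(picked$x, picked$y)
    if (ap$perimeter <= 0) next
    dh <- c(dh, 4 * ap$area / ap$perimeter)
  }
  if (!length(dh)) return(list(diameter_mm = 0, valid = FALSE))
  list(diameter_mm = mean(dh), valid = TRUE)
}

# --- labeling and tables ----------------------------------------------

subtree_count <- function(net, k) {
  kids <- branch_children(net, k)
  1L + sum(vapply(kids, function(j) subtree_count(net, j), 0L))
}

#' Assign Raabe binary airway labels
#'
#' The trachea (root branch) is labeled "1". At each bifurcation the
#' larger-diameter daughter appends "1" (major daughter) and the smaller
#' appends "2" (minor daughter) to the parent's label. Daughters with an
#' invalid (zero) measured diameter inherit the parent's diameter for the
#' comparison. Ties break by larger subtree branch count, then by a
#' deterministic spatial rule (lexicographically larger chord direction).
#'
#' @param network Strictly bifurcating rooted `centerline_network`.
#' @param diameters Numeric vector of per-branch diameters (mm), indexed
#'   like `network$branches`; 0 marks an invalid measurement.
#' @return The network with `label` set on each branch.
#' @export
assign_labels <- function(network, diameters) {
  outd <- node_out_degree(network)
  if (any(outd > 2)) stop("network is not strictly bifurcating; run QC first")
  rb <- root_branch(network)
  eff <- diameters
  assign1 <- function(k, label, parent_eff) {
    if (is.na(eff[k]) || eff[k] <= 0) eff[k] <<- parent_eff
    network$branches[[k]]$label <<- label
    kids <- branch_children(network, k)
    if (length(kids) == 2) {
      d1 <- if (!is.na(eff[kids[1]]) && eff[kids[1]] > 0) eff[kids[1]] else eff[k]
      d2 <- if (!is.na(eff[kids[2]]) && eff[kids[2]] > 0) eff[kids[2]] else eff[k]
      major <- if (d1 > d2) 1L else if (d2 > d1) 2L else {
        s1 <- subtree_count(network, kids[1])
        s2 <- subtree_count(network, kids[2])
        if (s1 > s2) 1L else if (s2 > s1) 2L else {
          v1 <- branch_vector(network$branches[[kids[1]]])
          v2 <- branch_vector(network$branches[[kids[2]]])
          cmp <- sign(v1 - v2)
          nz <- which(cmp != 0)
          if (length(nz) && cmp[nz[1]] > 0) 1L else 2L
        }
      }
      minor <- 3L - major
      assign1(kids[major], paste0(label, "1"), eff[k])
      assign1(kids[minor], paste0(label, "2"), eff[k])
    } else if (length(kids) == 1) {
      # degree-2 remnant (should have been merged); pass the label through
      assign1(kids[1], paste0(label, "1"), eff[k])
    }
  }
  assign1(rb, "1", if (!is.na(diameters[rb]) && diameters[rb] > 0)
    diameters[rb] else 1)
  network
}

#' Measure a post-QC network into a morphometry table
#'
#' Computes every branch's length (node-to-node), averaged hydraulic
#' diameter (with discharge/zero-flag rules), branch angle, inclination to
#' gravity, Raabe label and generation. Trifurcation-intermediate airways
#' are recorded with length 0.1 mm, branch angle 0, and the parent's
#' diameter. The root branch (tracheal stub) is measured but flagged
#' `root-stub`.
#'
#' @param network Post-QC `centerline_network`.
#' @param mask Binary `voxel_volume`.
#' @param step Cross-section plane spacing, voxels.
#' @param fold_gravity Fold gravity angles into \[0, 90\] (default FALSE).
#' @return A `morphometry_table` data frame: label, generation, length_mm,
#'   diameter_mm, diameter_valid, branch_angle_deg, gravity_angle_deg,
#'   flags.
#' @export
measure_network <- function(network, mask, step = 2, fold_gravity = FALSE) {
  nb <- length(network$branches)
  if (!nb) stop("network has no branches")
  edt <- sqrt(cpp_edt_sq(as.logical(mask$values), dim(mask$values)))
  lens <- vapply(seq_len(nb), function(k)
    airway_length(network$branches[[k]]), 0)
  hd <- lapply(seq_len(nb), function(k) {
    b <- network$branches[[k]]
    if ("intermediate" %in% b$flags) return(list(diameter_mm = 0, valid = FALSE))
    hydraulic_diameter(b, mask, network, step = step, edt = edt)
  })
  diam <- vapply(hd, `[[`, 0, "diameter_mm")
  valid <- vapply(hd, `[[`, TRUE, "valid")

  network <- assign_labels(network, diam)
  labels <- vapply(network$branches, function(b) b$label, "")

  # trifurcation-intermediate overrides: parent's diameter, 0.1 mm, 0 deg
  for (k in seq_len(nb)) {
    b <- network$branches[[k]]
    if ("intermediate" %in% b$flags && !is.na(b$parent)) {
      diam[k] <- diam[b$parent]
      valid[k] <- valid[b$parent]
      lens[k] <- 0.1
    }
  }

  g <- tryCatch(gravity_vector(network), error = function(e) NULL)
  rb <- root_branch(network)
  rows <- lapply(seq_len(nb), function(k) {
    b <- network$branches[[k]]
    intermediate <- "intermediate" %in% b$flags
    bv <- branch_vector(b)
    ba <- if (intermediate) 0 else if (is.na(b$parent)) NA_real_ else
      branch_angle(branch_vector(network$branches[[b$parent]]), bv)
    ga <- if (is.null(g)) NA_real_ else gravity_angle(bv, g)
    if (fold_gravity && !is.na(ga) && ga > 90) ga <- 180 - ga
    flags <- b$flags
    if (k == rb) flags <- union(flags, "root-stub")
    data.frame(
      label = b$label, generation = nchar(b$label),
      length_mm = lens[k], diameter_mm = diam[k],
      diameter_valid = valid[k],
      branch_angle_deg = ba, gravity_angle_deg = ga,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$generation, tab$label), ]
  rownames(tab) <- NULL
  class(tab) <- c("morphometry_table", "data.frame")
  tab
}

#' Count airways per generation
#'
#' @param table A `morphometry_table` (or any data frame with `label`).
#' @return Data frame: generation, n.
#' @export
generation_counts <- function(table) {
  gen <- nchar(table$label)
  tab <- base::table(factor(gen, levels = seq_len(max(gen))))
  data.frame(generation = as.integer(names(tab)), n = as.integer(tab))
}

#' Per-generation averages of the four morphometric measures
#'
#' Means, SD and SE (SD/sqrt(n)) per generation. A branch whose diameter
#' measurement is invalid (zero) contributes its parent's diameter to the
#' diameter average; the other measures use recorded values.
#'
#' @param table A `morphometry_table`.
#' @return Data frame keyed by generation with n, mean/sd/se per measure.
#' @export
generation_averages <- function(table) {
  gen <- nchar(table$label)
  # substitute the parent's diameter for invalid measurements
  diam <- table$diameter_mm
  if (!is.null(table$diameter_valid)) {
    for (i in which(!table$diameter_valid)) {
      lab <- table$label[i]
      while (nchar(lab) > 1) {
        lab <- substr(lab, 1, nchar(lab) - 1)
        j <- which(table$label == lab)
        if (length(j) && table$diameter_valid[j[1]]) {
          diam[i] <- table$diameter_mm[j[1]]
          break
        }
      }
    }
  }
  measures <- list(length = table$length_mm, diameter = diam,
                   branch_angle = table$branch_angle_deg,
                   gravity_angle = table$gravity_angle_deg)
  gens <- sort(unique(gen))
  rows <- lapply(gens, function(gg) {
    sel <- gen == gg
    out <- data.frame(generation = gg, n = sum(sel))
    for (m in names(measures)) {
      x <- measures[[m]][sel]
      x <- x[!is.na(x)]
      out[[paste0(m, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(m, "_sd")]] <- if (length(x) > 1) stats::sd(x) else NA_real_
      out[[paste0(m, "_se")]] <- if (length(x) > 1)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Write / read a morphometry table CSV
#'
#' Schema: label, generation, length_mm, diameter_mm, diameter_valid,
#' branch_angle_deg, gravity_angle_deg, flags — the same schema accepted
#' for manual-morphometry tables.
#'
#' @param table A `morphometry_table` data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_morphometry <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphometry
#' @export
read_morphometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  class(df) <- c("morphometry_table", "data.frame")
  df
}
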