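#' Curve-skeletonize a binary mask
#'
#' Topology-preserving 3D thinning: simple points are deleted in order of
#' the Euclidean distance map (surface inward), keeping curve endpoints, so
#' the object shrinks to a one-voxel-wide, medially centered curve skeleton
#' with the same number of connected components as the input.
#'
#' @param mask Binary `voxel_volume`, typically single-component.
#' @return Binary `voxel_volume` containing the skeleton.
#' @export
skeletonize <- function(mask) {
  if (!is_binary_volume(mask)) stop("`mask` must be binary")
  if (!any(mask$values)) stop("mask is empty")
  d <- dim(mask$values)
  sk <- cpp_skeletonize(as.logical(mask$values), d)
  sk <- prune_skeleton_twigs(array(sk, d),
                             sqrt(cpp_edt_sq(as.logical(mask$values), d)))
  out <- voxel_volume(sk, mask$spacing, mask$origin, provenance(mask))
  add_provenance(out, "skeletonize", list(method = "distance-ordered thinning"))
}

# Thinning leaves short side twigs inside thick tubes (a twig runs from the
# axis to just inside the surface, so its length is at most the local
# radius). Remove terminal chains shorter than the local radius plus a
# small margin; genuine anatomy (including artifact nubs that protrude
# beyond the surface) is longer and survives.
prune_skeleton_twigs <- function(skel_arr, edt, margin_vox = 1.5) {
  edt <- array(edt, dim(skel_arr))
  repeat {
    coords <- which(skel_arr, arr.ind = TRUE)
    if (nrow(coords) < 3) return(skel_arr)
    storage.mode(coords) <- "integer"
    edges <- skeleton_adjacency(skel_arr, coords)
    if (is.null(edges)) return(skel_arr)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(coords) - igraph::vcount(g)))
    deg <- igraph::degree(g)
    junction <- deg >= 3
    if (!any(junction)) return(skel_arr)
    removed_any <- FALSE
    for (t in which(deg == 1)) {
      chain <- t
      cur <- t
      prev <- -1L
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        nb <- nb[!nb %in% chain]
        if (length(nb) == 0) {
          attach_j <- NA_integer_
          break
        }
        if (any(junction[nb])) {
          jj <- nb[junction[nb]]
          attach_j <- jj[which.max(edt[coords[jj, , drop = FALSE]])]
          break
        }
        if (length(nb) != 1) {
          attach_j <- NA_integer_
          break
        }
        prev <- cur
        cur <- nb[1]
        chain <- c(chain, cur)
      }
      if (is.na(attach_j)) next
      # chain arc length in voxels
      cl <- sum(sqrt(rowSums((coords[chain[-1], , drop = FALSE] -
                                coords[chain[-length(chain)], ,
                                       drop = FALSE])^2))) +
        sqrt(sum((coords[attach_j, ] - coords[chain[length(chain)], ])^2))
      r_loc <- edt[coords[attach_j, , drop = FALSE]]
      if (cl < r_loc + margin_vox) {
        skel_arr[coords[chain, , drop = FALSE]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(skel_arr)
  }
}

# 26-neighbor adjacency among skeleton voxels: returns edge list of row
# indices into `coords` (n x 3 voxel indices).
skeleton_adjacency <- function(skel_arr, coords) {
  d <- dim(skel_arr)
  idx_arr <- array(0L, d)
  lin <- coords[, 1] + (coords[, 2] - 1L) * d[1] +
    (coords[, 3] - 1L) * d[1] * d[2]
  idx_arr[lin] <- seq_len(nrow(coords))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  # keep only lexicographically positive half to avoid duplicate edges
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
                (offs$dy == 0 & offs$dx > 0))), ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(as.integer(offs[k, ]), nrow(coords), 3,
                          byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin_nb <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    j <- idx_arr[lin_nb]
    i <- which(ok)[j > 0]
    j <- j[j > 0]
    if (length(i)) edges <- rbind(edges, cbind(i, j))
  }
  edges
}

#' Build a centerline network from a voxel skeleton
#'
#' Skeleton voxels with three or more neighbors are clustered (within 2
#' voxels) into bifurcation nodes; degree-1 voxels become terminals. The
#' root is the terminal nearest `root_hint` when given, otherwise the
#' terminal with the largest local cast radius (the trachea is the widest
#' airway). Branches are oriented proximal-to-distal from the root and
#' carried as ordered polylines in millimeters. When `mask` is supplied,
#' the Euclidean distance map provides a local cast radius along every
#' polyline (used by QC thresholds, cross-section sizing and root
#' selection).
#'
#' @param skeleton Binary `voxel_volume` from [skeletonize()].
#' @param mask Optional binary `voxel_volume` the skeleton came from.
#' @param root_hint Optional world position (mm, length 3) near the root.
#' @return A `centerline_network`: list with `nodes` (data frame: id, x, y,
#'   z in mm, kind), `branches` (list: id, proximal, distal, parent,
#'   points, radius_mm, flags), `spacing` (um).
#' @export
build_network <- function(skeleton, mask = NULL, root_hint = NULL) {
  skel_arr <- skeleton$values
  if (!any(skel_arr)) stop("skeleton is empty")
  coords <- which(skel_arr, arr.ind = TRUE)
  storage.mode(coords) <- "integer"
  n <- nrow(coords)
  spacing <- skeleton$spacing

  radius_vox <- NULL
  if (!is.null(mask)) {
    edt <- sqrt(cpp_edt_sq(as.logical(mask$values), dim(mask$values)))
    lin <- coords[, 1] + (coords[, 2] - 1L) * dim(mask$values)[1] +
      (coords[, 3] - 1L) * dim(mask$values)[1] * dim(mask$values)[2]
    radius_vox <- edt[lin]
  }

  edges <- skeleton_adjacency(skel_arr, coords)
  g <- igraph::graph_from_edgelist(if (is.null(edges))
    matrix(integer(0), 0, 2) else edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  deg <- igraph::degree(g)

  if (n == 1) {
    # degenerate single-voxel skeleton
    pos <- voxel_to_world(coords, spacing, skeleton$origin)
    nodes <- data.frame(id = 1L, x = pos[1], y = pos[2], z = pos[3],
                        kind = "root", stringsAsFactors = FALSE)
    return(new_network(nodes, list(), spacing))
  }
  if (!any(deg == 1)) stop("skeleton has no terminal voxel (closed structure)")

  junction <- which(deg >= 3)
  terminal <- which(deg == 1)

  # cluster junction voxels within a 2-voxel Chebyshev radius
  cluster_id <- integer(n)
  clusters <- list()
  if (length(junction)) {
    jc <- coords[junction, , drop = FALSE]
    dmat <- as.matrix(stats::dist(jc, method = "maximum"))
    adj <- dmat <= 2
    gj <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(gj)$membership
    for (ci in seq_len(max(comp))) {
      members <- junction[comp == ci]
      clusters[[ci]] <- members
      cluster_id[members] <- ci
    }
  }
  ncl <- length(clusters)

  # node table: one per junction cluster, one per terminal voxel
  node_pos <- matrix(0, ncl + length(terminal), 3)
  node_kind <- character(ncl + length(terminal))
  node_radius <- numeric(ncl + length(terminal))
  if (ncl) {
    for (ci in seq_len(ncl)) {
      node_pos[ci, ] <- colMeans(coords[clusters[[ci]], , drop = FALSE])
      node_kind[ci] <- "bifurcation"
      if (!is.null(radius_vox))
        node_radius[ci] <- max(radius_vox[clusters[[ci]]])
    }
  }
  term_node <- integer(n)
  for (k in seq_along(terminal)) {
    node_pos[ncl + k, ] <- coords[terminal[k], ]
    node_kind[ncl + k] <- "terminal"
    if (!is.null(radius_vox)) node_radius[ncl + k] <- radius_vox[terminal[k]]
    term_node[terminal[k]] <- ncl + k
  }

  # voxel -> node map (0 = chain voxel)
  vox_node <- integer(n)
  vox_node[junction] <- cluster_id[junction]
  vox_node[terminal] <- term_node[terminal]
  # a terminal that is also inside a junction cluster cannot happen (deg 1)

  # remove junction-cluster voxels; remaining components are branch chains
  nodevox <- which(vox_node > 0 & deg >= 3)
  keep <- setdiff(seq_len(n), nodevox)
  gsub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(gsub)
  raw_branches <- list()
  for (ci in seq_len(comp$no)) {
    members <- keep[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, members)
    dsub <- igraph::degree(sub)
    ends <- members[dsub <= 1]
    if (length(members) == 1) {
      chain <- members
    } else if (length(ends) >= 2) {
      sp <- igraph::shortest_paths(sub, from = which(members == ends[1]),
                                   to = which(members == ends[2]))$vpath[[1]]
      chain <- members[as.integer(sp)]
    } else {
      # chain is a cycle not passing through any junction: break arbitrarily
      chain <- members[as.integer(igraph::dfs(sub, root = 1)$order)]
    }
    # attach node endpoints: terminal nodes at the voxel itself, or junction
    # clusters adjacent to the chain ends
    adjacent_clusters <- function(v) {
      nbrs <- as.integer(igraph::neighbors(g, v))
      unique(vox_node[nbrs][vox_node[nbrs] > 0 & deg[nbrs] >= 3])
    }
    if (length(chain) == 1) {
      v <- chain[1]
      cl <- adjacent_clusters(v)
      if (vox_node[v] > 0) {       # lone terminal voxel next to a junction
        from <- vox_node[v]
        to <- if (length(cl)) cl[1] else NA_integer_
      } else {                     # lone chain voxel linking two clusters
        from <- if (length(cl) >= 1) cl[1] else NA_integer_
        to <- if (length(cl) >= 2) cl[2] else NA_integer_
      }
    } else {
      e1 <- chain[1]; e2 <- chain[length(chain)]
      from <- if (vox_node[e1] > 0) vox_node[e1] else {
        cl <- adjacent_clusters(e1); if (length(cl)) cl[1] else NA_integer_
      }
      to <- if (vox_node[e2] > 0) vox_node[e2] else {
        cl <- adjacent_clusters(e2); if (length(cl)) cl[1] else NA_integer_
      }
    }
    raw_branches[[length(raw_branches) + 1]] <-
      list(chain = chain, from = from, to = to)
  }
  # direct cluster-cluster adjacencies with no chain voxels between them
  if (ncl > 1) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      ca <- if (deg[a] >= 3) cluster_id[a] else 0L
      cb <- if (deg[b] >= 3) cluster_id[b] else 0L
      if (ca > 0 && cb > 0 && ca != cb) {
        already <- any(vapply(raw_branches, function(br)
          length(br$chain) == 0 && ((br$from == ca & br$to == cb) |
                                      (br$from == cb & br$to == ca)), TRUE))
        if (!already) {
          raw_branches[[length(raw_branches) + 1]] <-
            list(chain = integer(0), from = ca, to = cb)
        }
      }
    }
  }

  nodes <- data.frame(
    id = seq_len(nrow(node_pos)),
    x = 0, y = 0, z = 0,
    kind = node_kind, stringsAsFactors = FALSE
  )
  pos_mm <- voxel_to_world(node_pos, spacing, skeleton$origin)
  nodes$x <- pos_mm[, 1]; nodes$y <- pos_mm[, 2]; nodes$z <- pos_mm[, 3]
  nodes$radius_mm <- node_radius * spacing / 1000

  # choose root terminal
  termidx <- which(nodes$kind == "terminal")
  if (!is.null(root_hint)) {
    dd <- sqrt((nodes$x[termidx] - root_hint[1])^2 +
                 (nodes$y[termidx] - root_hint[2])^2 +
                 (nodes$z[termidx] - root_hint[3])^2)
    root_node <- termidx[which.min(dd)]
  } else if (!is.null(radius_vox)) {
    root_node <- termidx[which.max(nodes$radius_mm[termidx])]
  } else {
    root_node <- termidx[1]
  }
  nodes$kind[root_node] <- "root"

  # fix up chains with unattached ends (isolated skeleton cycles or
  # degenerate junction geometry): give them their own terminal nodes so the
  # graph stays well-formed and QC can resolve them
  for (k in seq_along(raw_branches)) {
    rb <- raw_branches[[k]]
    if (!is.na(rb$from) && !is.na(rb$to)) next
    pure_cycle <- is.na(rb$from) && is.na(rb$to) && length(rb$chain) > 1
    for (side in c("from", "to")) {
      if (!is.na(rb[[side]])) next
      if (pure_cycle && side == "to") {
        rb$to <- rb$from  # close the isolated cycle onto its own node
        next
      }
      v <- if (side == "from") rb$chain[1] else rb$chain[length(rb$chain)]
      newn <- nrow(nodes) + 1L
      vp <- voxel_to_world(matrix(coords[v, ], 1), spacing, skeleton$origin)
      nodes <- rbind(nodes, data.frame(
        id = newn, x = vp[1], y = vp[2], z = vp[3], kind = "terminal",
        radius_mm = if (!is.null(radius_vox)) radius_vox[v] * spacing / 1000
          else 0, stringsAsFactors = FALSE))
      rb[[side]] <- newn
    }
    raw_branches[[k]] <- rb
  }

  branches <- list()
  for (k in seq_along(raw_branches)) {
    rb <- raw_branches[[k]]
    chain_mm <- if (length(rb$chain))
      voxel_to_world(coords[rb$chain, , drop = FALSE], spacing,
                     skeleton$origin)
    else matrix(0, 0, 3)
    r_mm <- if (!is.null(radius_vox) && length(rb$chain))
      radius_vox[rb$chain] * spacing / 1000 else numeric(0)
    branches[[k]] <- list(
      id = k, proximal = rb$from, distal = rb$to, parent = NA_integer_,
      points = chain_mm, radius_mm = r_mm, flags = character(0)
    )
  }

  net <- new_network(nodes, branches, spacing)
  net <- orient_network(net, root_node)
  net <- refine_bifurcation_nodes(net)
  if (!is.null(mask)) {
    edt_arr <- array(edt, dim(mask$values))
    net <- extend_terminal_tips(net, edt_arr, spacing, skeleton$origin)
  }
  net
}

# Thinning can retract a terminal endpoint a few voxels short of the true
# branch end (the endpoint lock is order-dependent while the end cap is
# eaten). Recover the tip by marching from each terminal endpoint along the
# end tangent while the local cast radius (distance map) stays at the
# endpoint's level: the true end is the furthest point before the radius
# starts dropping toward the surface.
extend_terminal_tips <- function(net, edt_arr, spacing, origin) {
  vox_mm <- spacing / 1000
  edt_at <- function(p_mm) {
    trilinear_interp(edt_arr, world_to_voxel(matrix(p_mm, 1), spacing, origin))
  }
  for (nd in which(net$nodes$kind %in% c("terminal", "root"))) {
    inc <- which(vapply(net$branches, function(b)
      b$proximal == nd || b$distal == nd, TRUE))
    if (length(inc) != 1) next
    b <- net$branches[[inc]]
    pts <- b$polyline
    at_end <- b$distal == nd
    e <- if (at_end) pts[nrow(pts), ] else pts[1, ]
    # direction from ~2 local radii back along the polyline
    r0 <- edt_at(e) * vox_mm
    if (!is.finite(r0) || r0 <= 0) next
    seg <- if (at_end) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
    s <- c(0, cumsum(sqrt(rowSums((seg[-1, , drop = FALSE] -
                                     seg[-nrow(seg), , drop = FALSE])^2))))
    back <- which(s >= min(2 * r0, s[length(s)] * 0.8))
    ref <- if (length(back)) seg[back[1], ] else seg[nrow(seg), ]
    if (vnorm(e - ref) == 0) next
    dirv <- unit(e - ref)
    step <- 0.25 * vox_mm
    tol <- 0.75 * vox_mm
    smax <- 3 * r0
    sbest <- 0
    sq <- step
    while (sq <= smax) {
      if (edt_at(e + sq * dirv) * vox_mm >= r0 - tol) sbest <- sq else break
      sq <- sq + step
    }
    if (sbest > 0) {
      tip <- e + sbest * dirv
      if (at_end) {
        b$polyline <- rbind(b$polyline, tip)
      } else {
        b$polyline <- rbind(tip, b$polyline)
      }
      rownames(b$polyline) <- NULL
      net$branches[[inc]] <- b
      net$nodes$x[nd] <- tip[1]
      net$nodes$y[nd] <- tip[2]
      net$nodes$z[nd] <- tip[3]
    }
  }
  net
}

# Thinning merges daughter centerlines slightly inside the parent, so the
# raw junction-cluster centroid sits displaced along the bifurcation flare.
# Re-estimate each bifurcation node as the least-squares intersection of
# lines fitted to the incident branch centerlines just beyond the flare
# (arclength window [r, 3r] from the node, r = local cast radius).
refine_bifurcation_nodes <- function(net) {
  vox_mm <- net$spacing / 1000
  for (nd in which(net$nodes$kind == "bifurcation")) {
    inc <- which(vapply(net$branches, function(b)
      b$proximal == nd || b$distal == nd, TRUE))
    if (length(inc) < 3) next
    r <- net$nodes$radius_mm[nd]
    if (!is.finite(r) || r <= 0) r <- 2 * vox_mm
    p_old <- as.numeric(net$nodes[nd, c("x", "y", "z")])
    A <- matrix(0, 3, 3)
    rhs <- numeric(3)
    nlines <- 0
    for (k in inc) {
      b <- net$branches[[k]]
      pts <- b$polyline
      if (b$distal == nd) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      # arclength from the node
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
      s <- c(0, cumsum(seg))
      sel <- which(s >= r & s <= 3 * r)
      if (length(sel) < 3) sel <- which(s <= 3 * r)
      if (length(sel) < 3) next
      P <- pts[sel, , drop = FALSE]
      ctr <- colMeans(P)
      dvec <- svd(sweep(P, 2, ctr))$v[, 1]
      Pr <- diag(3) - dvec %o% dvec
      A <- A + Pr
      rhs <- rhs + Pr %*% ctr
      nlines <- nlines + 1
    }
    if (nlines < 2) next
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    sol <- as.numeric(sol)
    # accept only local refinements (within the junction's radius)
    if (vnorm(sol - p_old) > 1.5 * r) next
    net$nodes$x[nd] <- sol[1]
    net$nodes$y[nd] <- sol[2]
    net$nodes$z[nd] <- sol[3]
    for (k in inc) {
      b <- net$branches[[k]]
      if (b$proximal == nd) b$polyline[1, ] <- sol
      if (b$distal == nd) b$polyline[nrow(b$polyline), ] <- sol
      net$branches[[k]] <- b
    }
  }
  net
}

new_network <- function(nodes, branches, spacing) {
  structure(list(nodes = nodes, branches = branches, spacing = spacing),
            class = "centerline_network")
}

#' @export
print.centerline_network <- function(x, ...) {
  cat(sprintf(
    "<centerline_network> %d nodes (%d bifurcation, %d terminal), %d branches\n",
    nrow(x$nodes), sum(x$nodes$kind == "bifurcation"),
    sum(x$nodes$kind == "terminal"), length(x$branches)))
  invisible(x)
}

node_pos <- function(net, id) {
  as.numeric(net$nodes[net$nodes$id == id, c("x", "y", "z")])
}

# Orient all branches proximal->distal by BFS from the root node, set
# parent branch ids, and prepend/append node positions to each polyline.
orient_network <- function(net, root_node = NULL) {
  nodes <- net$nodes
  if (is.null(root_node)) root_node <- nodes$id[nodes$kind == "root"][1]
  nb <- length(net$branches)
  if (nb == 0) return(net)
  # node -> incident branch index
  inc <- vector("list", nrow(nodes))
  for (k in seq_len(nb)) {
    b <- net$branches[[k]]
    inc[[b$proximal]] <- c(inc[[b$proximal]], k)
    inc[[b$distal]] <- c(inc[[b$distal]], k)
  }
  visited_b <- logical(nb)
  visited_n <- logical(nrow(nodes))
  queue <- list(list(node = root_node, via = NA_integer_))
  visited_n[root_node] <- TRUE
  ordered <- list()
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (k in inc[[cur$node]]) {
      if (visited_b[k]) next
      visited_b[k] <- TRUE
      b <- net$branches[[k]]
      if (b$distal == cur$node && b$proximal != cur$node) {
        # flip orientation
        tmp <- b$proximal; b$proximal <- b$distal; b$distal <- tmp
        b$points <- b$points[rev(seq_len(nrow(b$points))), , drop = FALSE]
        b$radius_mm <- rev(b$radius_mm)
      }
      b$parent <- cur$via
      net$branches[[k]] <- b
      ordered[[length(ordered) + 1]] <- k
      if (!visited_n[b$distal]) {
        visited_n[b$distal] <- TRUE
        queue[[length(queue) + 1]] <- list(node = b$distal, via = k)
      }
    }
  }
  # polylines run node-to-node
  for (k in seq_len(nb)) {
    b <- net$branches[[k]]
    p0 <- node_pos(net, b$proximal)
    p1 <- node_pos(net, b$distal)
    pts <- rbind(p0, b$points, p1)
    rownames(pts) <- NULL
    b$polyline <- pts
    net$branches[[k]] <- b
  }
  net$root_node <- root_node
  net
}

#' Smooth branch centerlines
#'
#' Moving-average smoothing of each branch polyline's interior points with a
#' window of `window` points; the endpoints stay pinned to the node
#' positions and topology is unchanged. `window = 1` is the identity.
#'
#' @param network A `centerline_network`.
#' @param window Odd window size in points (>= 1).
#' @return The smoothed network.
#' @export
smooth_centerlines <- function(network, window = 5) {
  if (window < 1) stop("`window` must be >= 1")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(network)
  half <- window %/% 2L
  for (k in seq_along(network$branches)) {
    b <- network$branches[[k]]
    pts <- b$polyline
    np <- nrow(pts)
    if (np <= 2) next
    sm <- pts
    for (i in 2:(np - 1)) {
      lo <- max(1, i - half)
      hi <- min(np, i + half)
      sm[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
    }
    sm[1, ] <- pts[1, ]
    sm[np, ] <- pts[np, ]
    b$polyline <- sm
    network$branches[[k]] <- b
  }
  network
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Serialize a centerline network to JSON (and back)
#'
#' @param network A `centerline_network`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_network <- function(network, path) {
  obj <- list(
    spacing_um = network$spacing,
    root_node = network$root_node,
    nodes = network$nodes,
    branches = lapply(network$branches, function(b) list(
      id = b$id, proximal = b$proximal, distal = b$distal,
      parent = b$parent, flags = as.list(b$flags),
      polyline = b$polyline, radius_mm = b$radius_mm
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  branches <- lapply(seq_len(nrow(obj$branches %||% data.frame())), identity)
  # jsonlite simplifies the branch list to a data frame of lists; rebuild
  brs <- obj$branches
  branches <- lapply(seq_along(brs$id), function(i) list(
    id = brs$id[i], proximal = brs$proximal[i], distal = brs$distal[i],
    parent = brs$parent[i],
    flags = unlist(brs$flags[[i]]) %||% character(0),
    polyline = matrix(unlist(brs$polyline[[i]]), ncol = 3),
    radius_mm = unlist(brs$radius_mm[[i]]) %||% numeric(0)
  ))
  net <- new_network(nodes, branches, obj$spacing_um)
  net$root_node <- obj$root_node
  net
}
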