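# Exception detection and resolution: loops, trifurcations, spurious
# nodes, spurs.

test_that("a clean bifurcating network yields no exceptions", {
  net <- qc_network(small_network())$network
  ex <- detect_exceptions(net)
  expect_equal(nrow(ex), 0)
})

test_that("an injected closed loop is reported and resolved", {
  tree <- small_tree()
  vol <- small_volume()
  v <- inject_artifacts(vol, tree, list(list(kind = "closed_loop",
                                             location = c("111", "121"),
                                             magnitude = 350)))
  net <- build_network(skeletonize(largest_component(v)), v)
  ex <- detect_exceptions(net)
  expect_equal(sum(ex$kind == "closed_loop"), 1)
  qc <- qc_network(net)
  expect_equal(sum(qc$reports$kind == "closed_loop"), 1)
  # tree restored: acyclic, correct branch count, all true branches present
  expect_equal(nrow(detect_exceptions(qc$network)), 0)
  tab <- measure_network(qc$network, v)
  expect_setequal(tab$label, tree$ground_truth$label)
})

test_that("an injected trifurcation is reported and split per convention", {
  tree <- small_tree()
  vol <- small_volume()
  v <- inject_artifacts(vol, tree, list(list(kind = "trifurcation",
                                             location = "12",
                                             magnitude = 0)))
  net <- build_network(skeletonize(largest_component(v)), v)
  ex <- detect_exceptions(net)
  expect_gte(sum(ex$kind == "trifurcation"), 1)
  qc <- qc_network(net)
  outd <- airwaymorph:::node_out_degree(qc$network)
  expect_true(all(outd <= 2))
  tab <- measure_network(qc$network, v)
  inter <- tab[grepl("intermediate", tab$flags), ]
  expect_equal(nrow(inter), 1)
  expect_equal(inter$length_mm, 0.1)
  expect_equal(inter$branch_angle_deg, 0)
  # diameter of the airway created equals the parent's
  parent_lab <- substr(inter$label, 1, nchar(inter$label) - 1)
  expect_equal(inter$diameter_mm, tab$diameter_mm[tab$label == parent_lab])
})

test_that("resolve_trifurcation on hand-built network groups closest pair", {
  # parent below, three daughters: two nearly parallel (+y tilted x), one
  # off to the side
  nodes <- rbind(c(0, 0, 0), c(0, 1, 0), c(0.1, 2, 0), c(-0.1, 2, 0),
                 c(1, 1.5, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(2L, 5L))
  net <- manual_network(nodes, edges)
  for (k in seq_along(net$branches)) {
    b <- net$branches[[k]]
    b$polyline <- rbind(as.numeric(net$nodes[b$proximal, c("x", "y", "z")]),
                        as.numeric(net$nodes[b$distal, c("x", "y", "z")]))
    net$branches[[k]] <- b
  }
  expect_error(resolve_trifurcation(net, 1), "not a trifurcation")
  out <- resolve_trifurcation(net, 2)
  outd <- airwaymorph:::node_out_degree(out)
  expect_true(all(outd <= 2))
  nb <- out$branches[[length(out$branches)]]
  expect_true("intermediate" %in% nb$flags)
  # the two near-parallel daughters (to nodes 3 and 4) share the new node
  grouped <- vapply(out$branches, function(b)
    b$distal %in% c(3, 4) && b$proximal == nb$distal, TRUE)
  expect_equal(sum(grouped), 2)
})

test_that("spur pruning removes only the nub and is idempotent", {
  tree <- small_tree()
  vol <- small_volume()
  v <- inject_artifacts(vol, tree, list(list(kind = "spur_nub",
                                             location = "1",
                                             magnitude = 250, radius = 100)))
  net <- build_network(skeletonize(largest_component(v)), v)
  ex <- detect_exceptions(net)
  expect_gte(sum(ex$kind == "spur"), 1)
  qc <- qc_network(net)
  tab <- measure_network(qc$network, v)
  expect_setequal(tab$label, tree$ground_truth$label)
  # fixed point: a second pass removes nothing
  again <- prune_spurs(qc$network)
  expect_null(again$reports)
  expect_equal(length(again$network$branches), length(qc$network$branches))
})

test_that("merging degree-2 nodes concatenates and conserves length", {
  # chain of 3 collinear segments root -> a -> b -> tip
  nodes <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2.5, 0), c(0, 4, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  net <- manual_network(nodes, edges)
  for (k in seq_along(net$branches)) {
    b <- net$branches[[k]]
    b$polyline <- rbind(as.numeric(net$nodes[b$proximal, c("x", "y", "z")]),
                        as.numeric(net$nodes[b$distal, c("x", "y", "z")]))
    net$branches[[k]] <- b
  }
  total0 <- sum(vapply(net$branches, function(b)
    airwaymorph:::polyline_length(b$polyline), 0))
  merged <- merge_spurious_nodes(net)
  expect_equal(length(merged$branches), 1)
  total1 <- airwaymorph:::polyline_length(merged$branches[[1]]$polyline)
  expect_lt(abs(total1 - total0), 1e-9)
  expect_equal(airway_length(merged$branches[[1]]), 4)
  # no degree-2 nodes -> identity
  expect_equal(length(merge_spurious_nodes(merged)$branches), 1)
})

test_that("resolve_loop keeps the thicker path and is identity when acyclic", {
  net <- small_network()
  expect_equal(length(resolve_loop(net, integer(0))$branches),
               length(net$branches))
  tree <- small_tree()
  vol <- small_volume()
  v <- inject_artifacts(vol, tree, list(list(kind = "closed_loop",
                                             location = c("111", "121"),
                                             magnitude = 350)))
  netl <- build_network(skeletonize(largest_component(v)), v)
  cyc <- airwaymorph:::cycle_edges(netl)
  expect_equal(length(cyc), 1)
  resolved <- resolve_loop(netl, cyc[[1]])
  expect_equal(length(airwaymorph:::cycle_edges(resolved)), 0)
  expect_equal(length(resolved$branches), length(netl$branches) - 1)
})

test_that("QC is deterministic", {
  tree <- small_tree()
  vol <- small_volume()
  v <- inject_artifacts(vol, tree, list(
    list(kind = "trifurcation", location = "12", magnitude = 0),
    list(kind = "spur_nub", location = "1", magnitude = 250, radius = 100)))
  net <- build_network(skeletonize(largest_component(v)), v)
  qc1 <- qc_network(net)
  qc2 <- qc_network(net)
  expect_identical(qc1$reports, qc2$reports)
  expect_equal(length(qc1$network$branches), length(qc2$network$branches))
})
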