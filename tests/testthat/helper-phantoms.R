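# Shared fixture builders. Everything is generated in code; expensive
# phantoms are memoized for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# axis-aligned capsule (hemispherically capped cylinder) along +y
capsule_volume <- function(radius_vox = 10, length_vox = 50, spacing = 10,
                           margin = 5) {
  r <- radius_vox
  d <- c(2 * (r + margin) + 1, length_vox + 2 * (r + margin) + 1,
         2 * (r + margin) + 1)
  c0 <- r + margin  # 0-based center in x/z
  y0 <- r + margin
  segs <- matrix(c(c0, y0, c0, c0, y0 + length_vox, c0, r), 1)
  vol <- cpp_capsules(d, segs)
  voxel_volume(vol, spacing)
}

# access to the internal rasterizer for fixture construction
cpp_capsules <- function(d, segs) {
  v <- airwaymorph:::cpp_rasterize_capsules(logical(prod(d)), d, segs)
  array(v, d)
}

# Y-shaped tube: stem plus two diverging arms
y_tube_volume <- function(spacing = 10) {
  d <- c(80, 90, 60)
  segs <- rbind(c(40, 10, 30, 40, 45, 30, 8),
                c(40, 45, 30, 65, 75, 30, 7),
                c(40, 45, 30, 15, 75, 30, 7))
  voxel_volume(cpp_capsules(d, segs), spacing)
}

# small 3-generation phantom reused across the artifact tests
small_tree <- function() cached("tree3", build_tree(tree_spec(generations = 3,
                                                              seed = 7)))
small_volume <- function() cached("vol3", rasterize_tree(small_tree(), 40))
small_network <- function() cached("net3", {
  v <- small_volume()
  build_network(skeletonize(largest_component(v)), v)
})

# hand-built centerline network (no voxels involved): a rooted tree from an
# edge table; positions in mm
manual_network <- function(nodes, edges, root = 1L, spacing = 40) {
  nd <- data.frame(id = seq_len(nrow(nodes)), x = nodes[, 1], y = nodes[, 2],
                   z = nodes[, 3],
                   kind = "bifurcation", radius_mm = 0.3,
                   stringsAsFactors = FALSE)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(nodes))
  nd$kind[deg == 1] <- "terminal"
  nd$kind[root] <- "root"
  brs <- lapply(seq_len(nrow(edges)), function(k) {
    list(id = k, proximal = edges[k, 1], distal = edges[k, 2],
         parent = NA_integer_, points = matrix(0, 0, 3),
         radius_mm = numeric(0), flags = character(0))
  })
  net <- airwaymorph:::new_network(nd, brs, spacing)
  airwaymorph:::orient_network(net, root)
}

expect_tree_labels <- function(table, n_generations) {
  labs <- table$label
  expect_false(anyDuplicated(labs) > 0)
  expect_equal(nchar(labs), table$generation)
  non_root <- labs[nchar(labs) > 1]
  prefixes <- substr(non_root, 1, nchar(non_root) - 1)
  expect_true(all(prefixes %in% labs))
  expect_true(all(grepl("^[12]+$", labs)))
}
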