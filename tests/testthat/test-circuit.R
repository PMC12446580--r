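test_that("buffers pad by the right width and resample the core distribution", {
  core <- uniform_raster(10, 10, 7)
  buf <- add_buffer(core, 0.2, seed = 1)
  expect_identical(dim(buf), c(14L, 14L))
  expect_true(all(raster_values(buf) == 7))
  expect_equal(attr(buf, "buffer_width"), 2L)

  core100 <- uniform_raster(100, 100, 5)
  expect_identical(dim(add_buffer(core100, 0.2, seed = 1)), c(140L, 140L))

  set.seed(8)
  bimodal <- cs_raster(matrix(sample(c(1, 100), 100 * 100, TRUE), 100, 100))
  b <- add_buffer(bimodal, 0.2, seed = 3)
  ring <- raster_values(b)
  ring[21:120, 21:120] <- NA          # mask out the core
  ring <- ring[!is.na(ring)]
  expect_gt(length(ring), 9000)   # 140^2 - 100^2 = 9600 buffer cells
  expect_lt(abs(mean(ring == 1) - 0.5), 0.03)
  expect_error(add_buffer(cs_raster(matrix(NA_real_, 2, 2)), 0.2), "empty")
})

test_that("buffer crop restores the core exactly", {
  set.seed(5)
  core <- cs_raster(matrix(runif(60, 1, 9), 6, 10), cell_size = 30,
                    origin = c(100, 200))
  buf <- add_buffer(core, 0.25, seed = 2)
  back <- crop_buffer(buf, attr(buf, "buffer_width"))
  expect_true(same_geometry(core, back))
  expect_equal(raster_values(back), raster_values(core))
  expect_identical(crop_buffer(core, 0), core)
  big <- crop_buffer(cs_raster(matrix(0, 140, 140)), 20)
  expect_identical(dim(big), c(100L, 100L))
  expect_error(crop_buffer(cs_raster(matrix(0, 5, 5)), 3), "does not match")
})

test_that("perimeter nodes are distinct, evenly spaced and pair up correctly", {
  r <- uniform_raster(30, 30)
  n25 <- place_nodes(r, 25, seed = 1)
  expect_length(unique(n25), 25)
  expect_equal(n_node_pairs(n25), 300)    # 25 terminals -> 300 pairs
  rc <- attr(n25, "rc")
  expect_true(all(rc[, 1] %in% c(1, 30) | rc[, 2] %in% c(1, 30)))

  two <- attr(place_nodes(r, 2, seed = 4), "rc")
  arc <- function(rc) abs(rc[1, 1] - rc[2, 1]) + abs(rc[1, 2] - rc[2, 2])
  expect_gt(arc(two), 20)  # roughly half the perimeter apart

  four <- attr(place_nodes(uniform_raster(21, 21), 4, seed = 2), "rc")
  sides <- apply(four, 1, function(p) {
    if (p[1] == 1) "N" else if (p[1] == 21) "S"
    else if (p[2] == 1) "W" else "E"
  })
  expect_length(unique(sides), 4)         # one terminal per side
  expect_error(place_nodes(uniform_raster(2, 2), 25), "perimeter")
})

test_that("lattice edges follow the mean-conductance convention", {
  g <- build_lattice(cs_raster(matrix(c(1, 1), 1, 2)))
  expect_equal(g$edges$conductance, 1)
  g2 <- build_lattice(cs_raster(matrix(c(1, 3), 1, 2)))
  expect_equal(g2$edges$conductance, (1 + 1 / 3) / 2)
  g3 <- build_lattice(cs_raster(matrix(c(1, NA, NA, 1), 2, 2)))
  # two diagonal cells, others nodata: single diagonal edge at 1/sqrt(2)
  expect_equal(nrow(g3$edges), 1)
  expect_equal(g3$edges$conductance, 1 / sqrt(2))
  expect_error(build_lattice(cs_raster(matrix(c(0, 1), 1, 2))), "positive")
})

test_that("series chains read the injected current everywhere", {
  chain <- build_lattice(cs_raster(matrix(1, 1, 3)))
  sol <- solve_pair(chain, 1, 3)
  expect_equal(sol$effective_resistance, 2, tolerance = 1e-10)
  expect_equal(as.vector(raster_values(sol$current)), c(1, 1, 1),
               tolerance = 1e-10)
  two <- solve_pair(build_lattice(cs_raster(matrix(1, 1, 2))), 1, 2)
  expect_equal(two$effective_resistance, 1, tolerance = 1e-10)
})

test_that("per-cell currents match the dense pseudo-inverse oracle", {
  fixtures <- list(
    uniform_raster(3, 3),
    random_resistance(5, 4, seed = 1),
    random_resistance(8, 8, seed = 2),
    random_resistance(12, 12, seed = 3))
  for (r in fixtures) {
    g <- build_lattice(r)
    s <- 1; t <- g$n_nodes
    sol <- solve_pair(g, s, t)
    oracle <- dense_current_oracle(g, s, t)
    got <- as.vector(t(raster_values(sol$current)))
    expect_lt(max(abs(got - oracle$currents)), 1e-8)
    expect_equal(sol$effective_resistance, oracle$effective_resistance,
                 tolerance = 1e-8)
  }
})

test_that("Kirchhoff current conservation holds at non-terminal nodes", {
  g <- build_lattice(random_resistance(9, 9, seed = 6))
  s <- 5; t <- g$n_nodes - 3
  sol <- solve_pair(g, s, t)
  L <- circuitshift:::lattice_laplacian(g)
  net <- as.numeric(L %*% sol$voltages)   # net injected current per node
  non_term <- setdiff(seq_len(g$n_nodes), c(s, t))
  expect_lt(max(abs(net[non_term])), 1e-8)
  expect_equal(net[s], 1, tolerance = 1e-8)
  expect_equal(net[t], -1, tolerance = 1e-8)
})

test_that("solves are reciprocal and invariant to resistance scaling", {
  r <- random_resistance(6, 7, seed = 11)
  g <- build_lattice(r)
  ab <- solve_pair(g, 2, 30)
  ba <- solve_pair(g, 30, 2)
  expect_equal(raster_values(ab$current), raster_values(ba$current),
               tolerance = 1e-9)
  scaled <- build_lattice(raster_like(r, raster_values(r) * 7))
  ab7 <- solve_pair(scaled, 2, 30)
  expect_equal(ab7$effective_resistance, 7 * ab$effective_resistance,
               tolerance = 1e-8)
  expect_equal(raster_values(ab7$current), raster_values(ab$current),
               tolerance = 1e-8)
})

test_that("raising any one cell's resistance cannot lower effective resistance", {
  r <- random_resistance(5, 5, seed = 21, lo = 1, hi = 10)
  g <- build_lattice(r)
  base <- solve_pair(g, 1, 25)$effective_resistance
  set.seed(22)
  for (cell in sample(25, 6)) {
    v <- raster_values(r)
    v[(cell - 1) %/% 5 + 1, (cell - 1) %% 5 + 1] <-
      v[(cell - 1) %/% 5 + 1, (cell - 1) %% 5 + 1] * 5
    up <- solve_pair(build_lattice(raster_like(r, v)), 1, 25)
    expect_gte(up$effective_resistance, base - 1e-10)
  }
})

test_that("cumulative omnidirectional current is symmetric and counts solves", {
  r <- uniform_raster(15, 15)
  nodes <- place_nodes(r, 4, seed = 99)
  g <- build_lattice(r)
  cur <- cumulative_current(g, nodes)
  expect_equal(attr(cur, "n_solves"), 6)
  expect_true(all(raster_values(cur) >= 0))

  # 2 terminals: cumulative equals the single pair solve
  n2 <- place_nodes(r, 2, seed = 1)
  cur2 <- cumulative_current(g, n2)
  single <- solve_pair(g, g$node_of[n2[1]], g$node_of[n2[2]])
  expect_equal(raster_values(cur2), raster_values(single$current),
               tolerance = 1e-9)

  # uniform raster with terminals at the 4 corners: map invariant under
  # the grid's symmetry group
  nr <- 13
  corners <- structure(c(1L, nr, (nr - 1L) * nr + 1L, nr * nr),
                       class = "cs_nodes")
  cc <- raster_values(cumulative_current(build_lattice(uniform_raster(nr, nr)),
                                         corners))
  expect_lt(max(abs(cc - t(cc))), 1e-6)
  expect_lt(max(abs(cc - cc[nr:1, ])), 1e-6)
  expect_lt(max(abs(cc - cc[, nr:1])), 1e-6)
})

test_that("disconnected terminals raise an informative error", {
  m <- matrix(1, 5, 5); m[, 3] <- NA    # wall of nodata
  g <- build_lattice(cs_raster(m))
  expect_error(cumulative_current(
    g, structure(c(1L, 25L), class = "cs_nodes")), "component")
  expect_error(solve_pair(g, 1, g$n_nodes), "components")
})

test_that("null normalisation removes uniform-resistance geometry effects", {
  r2 <- uniform_raster(20, 20, 2)
  nodes <- place_nodes(r2, 8, seed = 5)
  g <- build_lattice(r2)
  cur <- cumulative_current(g, nodes)
  norm <- null_normalise(cur, g, nodes)
  # currents under fixed unit injection do not depend on the uniform level
  expect_lt(max(abs(raster_values(norm) - 1)), 1e-9)

  ones <- uniform_raster(20, 20, 1)
  g1 <- build_lattice(ones)
  norm1 <- null_normalise(cumulative_current(g1, nodes), g1, nodes)
  expect_lt(max(abs(raster_values(norm1) - 1)), 1e-9)
})

test_that("planted corridors carry more normalised current than background", {
  fix <- gen_corridor_fixture(24, 24, 4, 100, 1, cell_size = 1)
  buf <- add_buffer(fix, 0.2, seed = 7)
  nodes <- place_nodes(buf, 12, seed = 7)
  g <- build_lattice(buf)
  norm <- crop_buffer(null_normalise(cumulative_current(g, nodes), g, nodes),
                      attr(buf, "buffer_width"))
  v <- raster_values(norm)
  corridor <- raster_values(fix) == 1
  expect_gt(median(v[corridor]), median(v[!corridor]))
})
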