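test_that("the network solver honours series and parallel circuit laws", {
  # 3-node series chain, resistances r1 = 2, r2 = 5: Reff = 7, unit current
  sol <- solve_network(rbind(c(1, 2), c(2, 3)), g = c(1 / 2, 1 / 5),
                       n = 3, a = 1, b = 3)
  expect_equal(sol$reff, 7)
  expect_equal(abs(sol$edge_currents), c(1, 1))
  # two disjoint equal paths: each carries half the current
  edges <- rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4))
  sol2 <- solve_network(edges, g = rep(1, 4), n = 4, a = 1, b = 4)
  expect_equal(abs(sol2$edge_currents), rep(0.5, 4))
  # unit-resistance square, opposite corners: Reff = (2*2)/(2+2) = 1
  expect_equal(sol2$reff, 1.0)
  # disconnected terminals are flagged with infinite resistance
  sol3 <- solve_network(rbind(c(1, 2), c(3, 4)), g = c(1, 1), n = 4, a = 1, b = 3)
  expect_false(sol3$connected)
  expect_equal(sol3$reff, Inf)
  expect_true(all(sol3$node_current == 0))
})

test_that("effective resistance matches the dense pseudo-inverse oracle", {
  set.seed(17)
  for (rep in 1:25) {
    nw <- random_network(sample(4:30, 1))
    ab <- sample(nw$n, 2)
    sol <- solve_network(nw$edges, nw$g, nw$n, ab[1], ab[2])
    expect_equal(sol$reff,
                 reff_pinv_oracle(nw$edges, nw$g, nw$n, ab[1], ab[2]),
                 tolerance = 1e-8)
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("lattice conductances follow the shared cost kernel", {
  # two adjacent cells with resistances 2 and 4 at 30 m: g = 1/90
  r <- eco_grid(matrix(c(2, 4), 1, 2), cell_size = 30)
  lcg <- eco_grid(matrix(c(1, 0), 1, 2), cell_size = 30, band_kind = "categorical")
  src <- label_patches(lcg, 1, 8)
  circ <- build_lattice(r, src, connectivity = 4)
  expect_equal(circ$g, 1 / 90)
  # supernode collapse: a 2-cell patch becomes one node and preserves its
  # total outside conductance
  r3 <- eco_grid(matrix(1, 1, 3), cell_size = 30)
  lc3 <- eco_grid(matrix(c(1, 1, 0), 1, 3), cell_size = 30, band_kind = "categorical")
  src3 <- label_patches(lc3, 1, 8)
  circ3 <- build_lattice(r3, src3, connectivity = 4)
  expect_equal(circ3$n_nodes, 2)          # supernode + 1 free cell
  expect_equal(sum(circ3$g), 1 / 30)      # only the boundary edge remains
})

test_that("pair solves conserve current and are reciprocal", {
  ts <- two_source_strip(nr = 6, nc = 12)
  circ <- build_lattice(ts$resistance, ts$sources, connectivity = 4)
  s12 <- solve_pair(circ, 1, 2)
  s21 <- solve_pair(circ, 2, 1)
  expect_lt(s12$residual, 1e-8)
  expect_equal(s12$current$values, s21$current$values, tolerance = 1e-10)
  expect_equal(s12$reff, s21$reff, tolerance = 1e-12)
  # terminals carry the injected unit current
  expect_true(all(s12$current$values[, 1] == 1))
  expect_true(all(s12$current$values[, 12] == 1))
  # effective resistance cannot exceed the best single path's resistance
  net <- cost_network(ts$resistance, ts$sources, connectivity = 4)
  lcd <- build_corridors(net, cost_fields(net),
                         matrix(c(1, 2), 1), cutoff = 0)[[1]]$lcd
  expect_lte(s12$reff, lcd + 1e-9)
})

test_that("a uniform slab matches the analytic series/parallel resistance", {
  # 6 independent rows of 11 edges each between the end columns: for unit
  # resistance at 30 m cells under rook connectivity, each row has
  # resistance 11 * 30 and the 6 rows are in parallel... but rung edges
  # between rows make the lattice slightly better connected; the analytic
  # parallel bound still brackets the answer from above
  ts <- two_source_strip(nr = 6, nc = 12)
  circ <- build_lattice(ts$resistance, ts$sources, connectivity = 4)
  s <- solve_pair(circ, 1, 2)
  expect_lte(s$reff, 11 * 30 / 6 + 1e-9)
  expect_gte(s$reff, 11 * 30 / 6 - 1e-9)  # symmetric slab: rungs carry none
})

test_that("cumulative current is additive and order-invariant", {
  r <- eco_grid(matrix(1, 5, 21), cell_size = 30)
  lab <- eco_grid((matrix(0L, 5, 21) + (col(matrix(0, 5, 21)) %in% c(1, 11, 21))) * 1,
                  cell_size = 30, band_kind = "categorical")
  src <- label_patches(lab, 1, 8)
  circ <- build_lattice(r, src, connectivity = 4)
  prs <- rbind(c(1, 2), c(2, 3))
  cm <- cumulative_current(circ, prs)
  cm_rev <- cumulative_current(circ, prs[2:1, , drop = FALSE])
  expect_equal(cm$cumulative$values, cm_rev$cumulative$values, tolerance = 1e-12)
  # a duplicated pair doubles its contribution
  cm_dup <- cumulative_current(circ, rbind(c(1, 2), c(1, 2)))
  one <- cumulative_current(circ, matrix(c(1, 2), 1))
  expect_equal(cm_dup$cumulative$values, 2 * one$cumulative$values,
               tolerance = 1e-12)
})

test_that("pinch points sit in the neck of an hourglass landscape", {
  # passable band wide at the ends, one-cell-wide in the middle
  nr <- 11; nc <- 21
  r <- matrix(1000, nr, nc)
  r[, c(1:5, 17:21)] <- 1
  r[6, ] <- 1                      # the neck row
  rg <- eco_grid(r, cell_size = 30)
  lab <- matrix(0L, nr, nc); lab[, 1] <- 1L; lab[, nc] <- 2L
  src <- label_patches(eco_grid((lab > 0) * 1, cell_size = 30,
                                band_kind = "categorical"), 1, 8)
  circ <- build_lattice(rg, src, connectivity = 4)
  cm <- cumulative_current(circ, matrix(c(1, 2), 1))
  mask <- matrix(TRUE, nr, nc)
  pp <- find_pinch_points(cm$cumulative, mask, src, percentile = 0.95)
  expect_gte(length(pp$areas), 1)
  # the hottest non-source cell lies on the neck row in the narrow section
  cur <- cm$cumulative$values
  cur[, c(1, nc)] <- -Inf
  hot <- which(cur == max(cur), arr.ind = TRUE)
  expect_true(all(hot[, 1] == 6))
  expect_true(all(hot[, 2] >= 6 & hot[, 2] <= 16))
  # percentile 0 returns the whole (non-source) mask
  pp0 <- find_pinch_points(cm$cumulative, mask, src, percentile = 0)
  expect_equal(sum(pp0$labels$values > 0, na.rm = TRUE), nr * nc - 2 * nr)
})
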