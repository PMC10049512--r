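# A minimal hand-built stack: one settlement cell in the corner of a
# uniform forest landscape.
point_threat_stack <- function(nr = 9, nc = 9, cell = 100) {
  cls <- landcover_classes()
  lc <- matrix(cls[["forest"]], nr, nc)
  g <- function(v, kind) eco_grid(v, cell_size = cell, band_kind = kind)
  thr <- matrix(0, nr, nc); thr[1, 1] <- 1
  structure(list(
    landcover = g(lc, "categorical"),
    threats = list(settlement = g(thr, "categorical"))
  ), class = "landscape_stack")
}

test_that("degradation follows the distance-decay kernels", {
  st <- point_threat_stack()
  # single linear threat, w = 1, S = 1: D at exactly d_max/2 is 0.5
  threats <- data.frame(name = "settlement", weight = 1,
                        max_dist = 800, decay = "linear")
  sens <- default_sensitivity()
  sens$settlement[] <- 1
  D <- habitat_degradation(st, threats, sens)
  expect_equal(D$values[1, 1], 1)              # on the threat
  expect_equal(D$values[1, 5], 0.5)            # 400 m = d_max / 2
  expect_equal(D$values[1, 9], 0)              # 800 m: past the range
  expect_true(all(D$values >= 0))
  # exponential decay: exp(-2.99 d / dmax), clipped beyond dmax
  threats$decay <- "exponential"
  De <- habitat_degradation(st, threats, sens)
  expect_equal(De$values[1, 5], exp(-2.99 * 400 / 800))
  expect_equal(De$values[1, 9], 0)
  # two threats with weights 1 and 3, both at full impact, S = 1: D = 1
  st$threats$mining <- st$threats$settlement
  th2 <- data.frame(name = c("settlement", "mining"), weight = c(1, 3),
                    max_dist = c(1e6, 1e6), decay = "exponential")
  sens$mining[] <- 1
  D2 <- habitat_degradation(st, th2, sens)
  expect_equal(D2$values[1, 1], 1)             # 0.25 + 0.75
  # a threat named in the table but missing from the stack is a config error
  th3 <- data.frame(name = "railway", weight = 1, max_dist = 1e3, decay = "linear")
  sens$railway <- 1
  expect_error(habitat_degradation(st, th3, sens), "configuration error")
})

test_that("the quality model satisfies its closed-form identities", {
  cls <- landcover_classes()
  lc <- eco_grid(matrix(cls[["forest"]], 3, 3), cell_size = 30,
                 band_kind = "categorical")
  sens <- default_sensitivity()
  mkD <- function(x) eco_grid(matrix(x, 3, 3), cell_size = 30)
  # D = 0 gives Q = H_j
  expect_equal(habitat_quality(mkD(0), lc, sens)$values[1, 1], 1.0)
  # D = k with H = 1 gives the half-saturation value 0.5
  expect_equal(habitat_quality(mkD(0.5), lc, sens, k = 0.5, z = 2.5)$values[1, 1], 0.5)
  # H = 0 forces Q = 0 regardless of D
  lc0 <- eco_grid(matrix(cls[["artificial"]], 3, 3), cell_size = 30,
                  band_kind = "categorical")
  expect_equal(habitat_quality(mkD(3), lc0, sens)$values[1, 1], 0)
  # Q antitone in D over a lattice of D values
  Ds <- seq(0, 3, by = 0.05)
  Qs <- vapply(Ds, function(d) habitat_quality(mkD(d), lc, sens)$values[1, 1], 0)
  expect_true(all(diff(Qs) <= 1e-12))
  # large z approaches a step at D = k
  q_lo <- habitat_quality(mkD(0.4), lc, sens, k = 0.5, z = 50)$values[1, 1]
  q_hi <- habitat_quality(mkD(0.6), lc, sens, k = 0.5, z = 50)$values[1, 1]
  expect_gt(q_lo, 0.999)
  expect_lt(q_hi, 0.001)
})

test_that("quality classification partitions the landscape", {
  st <- worked_toy()
  Q <- habitat_quality(habitat_degradation(st), st$landcover)
  lv <- classify_quality(Q, 5)
  expect_setequal(unique(as.vector(lv$values)), 1:5)
  expect_equal(sum(!is.na(lv$values)), sum(!is.na(Q$values)))
  # levels are ordered: mean quality increases with level
  mq <- tapply(as.vector(Q$values), as.vector(lv$values), mean)
  expect_true(all(diff(mq) > 0))
})

test_that("source extraction applies a strict area threshold, ranked by area", {
  # build a level grid with two top-level patches: 3 cells and 30 cells at
  # 1 km cells (areas 3 and 30 km^2)
  lv <- matrix(1, 10, 10)
  lv[1, 1:3] <- 5
  lv[5:10, 1:5] <- 5
  g <- eco_grid(lv, cell_size = 1000, band_kind = "categorical")
  src <- extract_sources(g, min_area_km2 = 3)   # strict: 3 km^2 excluded
  expect_length(src$areas, 1)
  expect_equal(unname(src$areas), 30)
  src0 <- extract_sources(g, min_area_km2 = 0)
  expect_length(src0$areas, 2)
  expect_equal(unname(src0$areas), c(30, 3))    # ranked descending
  # an exact-threshold patch is excluded ("greater than")
  src3 <- extract_sources(g, min_area_km2 = 30)
  expect_length(src3$areas, 0)
})

test_that("the toy's two constructed cores are extracted as sources", {
  st <- worked_toy()
  Q <- habitat_quality(habitat_degradation(st), st$landcover)
  src <- extract_sources(classify_quality(Q, 5), min_area_km2 = 2)
  expect_equal(length(src$areas), 2)
  expect_true(all(src$areas > 2))
  # one source overlaps the west water core, the other the east forest core
  lab <- src$labels$values
  cls <- landcover_classes()
  west <- unique(lab[st$landcover$values == cls[["water"]] & lab > 0])
  east <- unique(lab[st$landcover$values == cls[["forest"]] & lab > 0])
  expect_length(west, 1)
  expect_length(east, 1)
  expect_false(west == east)
})
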