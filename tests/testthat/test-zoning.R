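# Minimal layer kit: one source block on a habitat/cultivated landscape.
zoning_fixture <- function() {
  cls <- landcover_classes()
  nr <- 30; nc <- 30; cell <- 100
  lc <- matrix(cls[["cultivated"]], nr, nc)
  lc[10:20, 1:15] <- cls[["forest"]]
  landcover <- eco_grid(lc, cell_size = cell, band_kind = "categorical")
  srcmask <- matrix(0, nr, nc); srcmask[13:17, 3:7] <- 1
  sources <- label_patches(grid_like(landcover, srcmask), 1, 8)
  empty <- grid_like(landcover, matrix(0, nr, nc))
  list(landcover = landcover,
       layers = list(sources = sources, pinch_regions = empty,
                     key_corridors = empty, potential_corridors = empty,
                     barrier_regions = empty, is_grid = empty))
}

test_that("default rules: sources are PPZ, their habitat ring SPZ, rest LPZ", {
  fx <- zoning_fixture()
  z <- apply_zoning(fx$layers, fx$landcover)
  zc <- zone_codes()
  src <- fx$layers$sources$labels$values > 0
  expect_true(all(z$zones$values[src] == zc[["PPZ"]]))
  # a forest cell within 2 km of the source block is SPZ
  expect_equal(z$zones$values[13, 10], zc[["SPZ"]])
  # cultivated cells in the ring are filtered out of SPZ
  expect_equal(z$zones$values[5, 5], zc[["LPZ"]])
  expect_false(any(z$zones$values == zc[["ERZ"]]))
  # zones partition the non-nodata cells
  expect_equal(sum(!is.na(z$zones$values)), length(z$zones$values))
})

test_that("precedence resolves overlapping prescriptions toward PPZ", {
  fx <- zoning_fixture()
  m <- matrix(0, 30, 30); m[25, 25] <- 1
  fx$layers$pinch_regions <- grid_like(fx$landcover, m)
  fx$layers$barrier_regions <- grid_like(fx$landcover, m)
  z <- apply_zoning(fx$layers, fx$landcover)
  # the cell sits in both the pinch (PPZ) and barrier (ERZ) 1 km buffers
  expect_equal(z$zones$values[25, 25], zone_codes()[["PPZ"]])
  # a referenced layer that is absent entirely is a configuration error
  fx$layers$pinch_regions <- NULL
  expect_error(apply_zoning(fx$layers, fx$landcover), "configuration error")
})

test_that("the IS-band variant zones by improvement score", {
  fx <- zoning_fixture()
  isv <- matrix(0, 30, 30)
  isv[1, 1] <- 0.03   # ERZ band (0, 0.05]
  isv[1, 2] <- 0.10   # SPZ band (0.05, 0.15]
  fx$layers$is_grid <- grid_like(fx$landcover, isv)
  z <- apply_zoning(fx$layers, fx$landcover,
                    default_zoning_rules(variant = "is_bands"))
  zc <- zone_codes()
  expect_equal(z$zones$values[1, 1], zc[["ERZ"]])
  expect_equal(z$zones$values[1, 2], zc[["SPZ"]])
})

test_that("area accounting is exactly consistent", {
  fx <- zoning_fixture()
  z <- apply_zoning(fx$layers, fx$landcover)
  d <- voronoi_districts(fx$landcover, k = 3, seed = 2)
  tab <- area_report(z$zones, d)
  n <- nrow(tab)
  body <- tab[-n, c("PPZ", "ERZ", "SPZ", "LPZ")]
  # row sums equal district totals, column sums equal the Total row
  expect_equal(unname(rowSums(body)), tab$Total[-n])
  expect_equal(unname(colSums(body)), unname(unlist(tab[n, c("PPZ", "ERZ", "SPZ", "LPZ")])))
  expect_equal(tab$Total[n], sum(tab$Total[-n]))
  # grand total is the full landscape area; every entry a multiple of the
  # cell area
  expect_equal(tab$Total[n], 900 * 0.01)
  expect_true(all(abs(round(as.matrix(body) / 0.01) * 0.01 - as.matrix(body)) < 1e-9))
})

test_that("printed-table accounting identities hold for count and area reports", {
  # the zone-area table style: four zone entries summing to the total row
  zone_totals <- c(PPZ = 42175.81, SPZ = 201054.59, ERZ = 9164.25,
                   LPZ = 707508.00)
  expect_equal(sum(zone_totals), 959902.65)
  # count tables: district counts summing to the reported totals
  pinch_by_district <- c(13, 2, 2, 4, 1, 2, 2, 6)
  barrier_by_district <- c(7, 5, 2, 2, 2, 1, 0, 2)
  expect_equal(sum(pinch_by_district), 32)
  expect_equal(sum(barrier_by_district), 21)
})

test_that("count report assigns regions to districts by centroid", {
  fx <- zoning_fixture()
  d <- voronoi_districts(fx$landcover, k = 2, seed = 5)
  m1 <- matrix(0, 30, 30); m1[2:4, 2:4] <- 1; m1[20:22, 20:22] <- 1
  pinch <- label_patches(grid_like(fx$landcover, m1), 1, 8)
  m2 <- matrix(0, 30, 30)
  barrier <- label_patches(grid_like(fx$landcover, m2), 1, 8)
  tab <- count_report(pinch, barrier, d)
  n <- nrow(tab)
  expect_equal(tab$pinch_points[n], 2)
  expect_equal(tab$barrier_points[n], 0)
  expect_equal(sum(tab$pinch_points[-n]), tab$pinch_points[n])
})

test_that("zoning is monotone in buffer size", {
  fx <- zoning_fixture()
  m <- matrix(0, 30, 30); m[25, 25] <- 1
  fx$layers$pinch_regions <- grid_like(fx$landcover, m)
  rules_big <- default_zoning_rules()
  rules_small <- default_zoning_rules()
  rules_small$zones$PPZ$parts$buffer_m[2] <- 300   # shrink the pinch buffer
  z_big <- apply_zoning(fx$layers, fx$landcover, rules_big)
  z_small <- apply_zoning(fx$layers, fx$landcover, rules_small)
  zc <- zone_codes()
  ppz_small <- z_small$zones$values == zc[["PPZ"]]
  ppz_big <- z_big$zones$values == zc[["PPZ"]]
  expect_true(all(ppz_big[ppz_small]))
})
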