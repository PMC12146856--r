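test_that("point-to-segment distances match closed forms", {
  rn <- road_network(data.frame(x0 = -10, y0 = 0, x1 = 10, y1 = 0))
  pts <- data.frame(x = c(0, 0, 15), y = c(0, 3, 3))
  d <- nearest_road_distance(pts, rn)
  expect_equal(d, c(0, 3, sqrt(5^2 + 3^2)), tolerance = 1e-12)
  expect_true(all(d >= 0))

  multi <- road_network(data.frame(x0 = c(-10, 0), y0 = c(0, -5),
                                   x1 = c(10, 0), y1 = c(0, 5)))
  expect_equal(nearest_road_distance(data.frame(x = 2, y = 1), multi), 1)

  empty <- road_network(data.frame(x0 = numeric(0), y0 = numeric(0),
                                   x1 = numeric(0), y1 = numeric(0)))
  expect_error(nearest_road_distance(pts, empty), "no roads")
})

test_that("buffer union area matches the stadium closed form and is idempotent", {
  rn <- road_network(data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 0))
  z <- buffer_union(rn, 1)
  expect_equal(z$area, 2 * 10 * 1 + pi, tolerance = 5e-3)

  tilted <- road_network(data.frame(x0 = 0, y0 = 0, x1 = 7, y1 = 7))
  expect_equal(buffer_union(tilted, 2)$area, 2 * sqrt(98) * 2 + pi * 4,
               tolerance = 5e-3)

  twice <- road_network(data.frame(x0 = c(0, 0), y0 = c(0, 0),
                                   x1 = c(10, 10), y1 = c(0, 0)))
  expect_equal(buffer_union(twice, 1)$area, z$area, tolerance = 1e-3)

  # union never exceeds the sum of per-segment stadium areas
  net <- small_network()$roads
  segs <- net$segments
  stadiums <- sum(2 * sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2) * 5 +
                    pi * 25)
  expect_lt(buffer_union(net, 5)$area, stadiums * (1 + 1e-3))

  expect_error(buffer_union(rn, 0), "positive")
  expect_error(buffer_union(rn, -2), "positive")
})

test_that("buffer membership agrees exactly with the distance predicate", {
  fx <- small_network()
  z <- buffer_union(fx$roads, 5)
  pts <- uniform_points_in(fx$region, 1000, seed = 99)
  d <- nearest_road_distance(pts, fx$roads)
  expect_identical(in_buffer(z, pts), d <= 5)
})

test_that("buffer union area grows monotonically with radius", {
  net <- small_network()$roads
  areas <- vapply(c(1, 2, 5, 10), function(d) buffer_union(net, d)$area,
                  numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("buffer fraction covers the degenerate and constructed cases", {
  reg <- make_region(10, 10)
  # a road far away: zone disjoint from the region
  far <- road_network(data.frame(x0 = 1000, y0 = 0, x1 = 1010, y1 = 0))
  expect_equal(buffer_fraction(buffer_union(far, 1), reg), 0)
  # a giant buffer swallowing the region entirely
  mid <- road_network(data.frame(x0 = -10, y0 = 5, x1 = 20, y1 = 5))
  expect_equal(buffer_fraction(buffer_union(mid, 50), reg), 1)
  # left-edge road with d = 5 covers exactly the left half of the 10 km square
  left <- road_network(data.frame(x0 = 0, y0 = -50, x1 = 0, y1 = 60))
  expect_equal(buffer_fraction(buffer_union(left, 5), reg), 0.5,
               tolerance = 2e-3)
})

test_that("buffer fraction is invariant under a joint rigid motion", {
  fx <- small_network()
  p0 <- buffer_fraction(buffer_union(fx$roads, 5), fx$region)
  th <- pi / 7
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 13,
                             y = sin(th) * x + cos(th) * y - 4)
  s <- fx$roads$segments
  a <- rot(s$x0, s$y0); b <- rot(s$x1, s$y1)
  roads_r <- road_network(data.frame(x0 = a$x, y0 = a$y, x1 = b$x, y1 = b$y))
  br <- rot(fx$region$boundary$x, fx$region$boundary$y)
  reg_r <- region(data.frame(x = br$x, y = br$y))
  p1 <- buffer_fraction(buffer_union(roads_r, 5), reg_r)
  expect_equal(p1, p0, tolerance = 2e-3)
})

test_that("road density matches the diameter closed form and is linear in length", {
  rn <- road_network(data.frame(x0 = -20, y0 = 0, x1 = 20, y1 = 0))
  pt <- data.frame(x = 0, y = 0)
  expect_equal(road_density_around(pt, rn, 5), 2 * 5 / (pi * 25),
               tolerance = 1e-12)
  doubled <- road_network(data.frame(x0 = c(-20, -20), y0 = c(0, 0.1),
                                     x1 = c(20, 20), y1 = c(0, 0.1)))
  expect_equal(road_density_around(pt, doubled, 5),
               2 * road_density_around(pt, rn, 5), tolerance = 1e-3)
  none <- road_network(data.frame(x0 = 100, y0 = 100, x1 = 120, y1 = 100))
  expect_equal(road_density_around(pt, none, 5), 0)
  # disc clipped to the region at a corner point
  reg <- make_region(100, 100)
  corner <- data.frame(x = 0, y = 0)
  rn2 <- road_network(data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 0))
  len <- 5 # road leaves the disc at x = 5
  expect_equal(road_density_around(corner, rn2, 5, reg),
               len / (pi * 25 / 4), tolerance = 1e-3)
})

test_that("uniform sampling is uniform, in-region and reproducible", {
  reg <- make_region(1, 1)
  pts <- uniform_points_in(reg, 10000, seed = 5)
  expect_true(all(points_in_polygon(pts, reg)))
  expect_identical(uniform_points_in(reg, 10000, seed = 5), pts)
  # CLT bound on the mean of U(0,1): 3 sigma / sqrt(n)
  expect_lt(abs(mean(pts$x) - 0.5), 3 * sqrt(1 / 12) / sqrt(10000))
  # chi-square uniformity on a 4x4 grid at alpha = 0.01 (seed fixed)
  cell <- paste(pmin(floor(pts$x * 4), 3), pmin(floor(pts$y * 4), 3))
  chi <- chisq.test(table(cell))
  expect_gt(chi$p.value, 0.01)
  expect_error(region(data.frame(x = c(0, 1, 2), y = c(0, 0, 0))),
               "degenerate")
})
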