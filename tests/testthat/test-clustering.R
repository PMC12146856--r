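test_that("p_clustering reproduces hand-enumerated binomial sums", {
  expect_equal(p_clustering(10, 2, 0.5), 56 / 1024, tolerance = 1e-12)
  expect_equal(p_clustering(10, 7, 0.3), 0.98941, tolerance = 1e-5)
  expect_identical(p_clustering(100, 20, 0.2), 0.5)
  expect_error(p_clustering(10, 2, 0), "degenerate")
  expect_error(p_clustering(10, 2, 1), "degenerate")
})

test_that("p_clustering is nondecreasing in n_d across the 0.50 transition", {
  # integer expectation: N * p = 5
  v1 <- p_clustering(20, 0:20, 0.25)
  expect_true(all(diff(v1) >= 0))
  expect_identical(v1[6], 0.5) # n_d = 5 hits the expectation exactly
  # non-integer expectation: no sentinel on the path
  v2 <- p_clustering(20, 0:20, 0.33)
  expect_true(all(diff(v2) >= 0))
  expect_false(any(v2 == 0.5))
  expect_true(all(v2 > 0 & v2 < 1))
})

test_that("the deficit branch satisfies the binomial complement identity", {
  for (N in c(15, 40)) {
    for (p in c(0.2, 0.6)) {
      nd <- 0:floor(N * p - 1e-9)
      lhs <- p_clustering(N, nd, p)
      rhs <- 1 - pbinom(N - nd - 1, N, 1 - p)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("categories map onto the five-class legend", {
  cl <- function(p) as.character(classify_clustering(p))
  expect_equal(cl(0.0546875), "fewer than expected (n.s.)")
  expect_equal(cl(0.98941), "significant clustering")
  expect_equal(cl(0.5), "as expected")
  expect_equal(cl(0.049), "significantly away")
  expect_equal(cl(0.95), "more than expected (n.s.)")
  expect_equal(cl(0.950001), "significant clustering")
  expect_true(is.ordered(classify_clustering(0.3)))
})

test_that("national clustering flags fully-buffered record sets", {
  reg <- make_region(10, 10)
  left <- road_network(data.frame(x0 = 0, y0 = -50, x1 = 0, y1 = 60))
  pts <- data.frame(x = runif(50, 0, 4.9), y = runif(50, 0, 10))
  res <- national_clustering(pts, left, reg, d = 5)
  expect_equal(res$N, 50)
  expect_equal(res$n_d, 50)
  expect_equal(res$p_d, 0.5, tolerance = 2e-3)
  expect_gt(res$p_clustering, 0.999)
  expect_equal(res$category, "significant clustering")
})

test_that("national clustering is calibrated under uniform sampling", {
  fx <- small_network()
  zone <- buffer_union(fx$roads, 5)
  cats <- vapply(1:50, function(s) {
    pts <- uniform_points_in(fx$region, 1000, seed = 500 + s)
    national_clustering(pts, fx$roads, fx$region, 5, zone)$category
  }, character(1))
  expect_lte(sum(cats == "significant clustering"), 6)
  expect_lte(sum(cats == "significantly away"), 6)
})

test_that("county clustering conserves counts and flags degenerate counties", {
  sim <- std_sim
  zone <- buffer_union(sim$roads, 5)
  nat <- national_clustering(sim$occurrences, sim$roads, sim$region, 5, zone)
  cty <- county_clustering(sim$occurrences, sim$roads, sim$region, 5, zone)
  expect_equal(nrow(cty), 16)
  expect_equal(sum(cty$N), nat$N)
  expect_equal(sum(cty$n_d), nat$n_d)

  # a county wholly inside the buffer is reported untestable, not dropped
  reg <- make_region(20, 20, grid = 2)
  mid <- road_network(data.frame(x0 = 5, y0 = -10, x1 = 5, y1 = 30))
  pts <- data.frame(x = runif(40, 0, 20), y = runif(40, 0, 20))
  out <- county_clustering(pts, mid, reg, d = 8)
  deg <- out[!is.na(out$note) & grepl("degenerate", out$note), ]
  expect_gte(nrow(deg), 1)
  expect_true(all(is.na(deg$p_clustering)))
})

test_that("counties carrying roads cluster more than roadless counties", {
  # biased collection = roadside (offset-mode) effort on top of a uniform
  # background; roadside counties inflate their in-buffer counts while
  # roadless counties see only the calibrated background
  reg <- make_region(100, 100, grid = 4)
  roads <- make_roads(reg, 4, seed = 3)
  zone <- buffer_union(roads, 10)
  # classify counties by whether a road passes through them
  s <- roads$segments
  tt <- seq(0, 1, length.out = 200)
  on_road <- purrr::map(seq_len(nrow(s)), function(i) {
    data.frame(x = s$x0[i] + tt * (s$x1[i] - s$x0[i]),
               y = s$y0[i] + tt * (s$y1[i] - s$y0[i]))
  }) |> purrr::list_rbind()
  labs <- unique(reg$counties$county)
  has_road <- vapply(labs, function(lab) {
    any(points_in_polygon(on_road, reg$counties[reg$counties$county == lab, ]))
  }, logical(1))
  expect_gt(sum(has_road), 0)
  expect_gt(sum(!has_road), 0)

  per_seed <- purrr::map(1:20, function(s) {
    roadside <- sample_biased_occurrences(roads, reg, 1000, mode = "offset",
                                          shape = 0.4, scale = 2,
                                          seed = 700 + s)
    background <- sample_biased_occurrences(roads, reg, 500,
                                            mode = "uniform", seed = 900 + s)
    county_clustering(dplyr::bind_rows(roadside, background), roads, reg,
                      10, zone)
  }) |> purrr::list_rbind()
  med <- per_seed |>
    dplyr::filter(!is.na(p_clustering)) |>
    dplyr::group_by(unit) |>
    dplyr::summarise(p = stats::median(p_clustering))
  med$has_road <- has_road[med$unit]
  w <- stats::wilcox.test(p ~ has_road, data = med, exact = FALSE)
  expect_lt(w$p.value, 0.05)
  expect_gt(stats::median(med$p[med$has_road]),
            stats::median(med$p[!med$has_road]))
})
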