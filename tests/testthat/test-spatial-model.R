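test_that("distance truncation preserves short pairs and substitutes long ones", {
  co <- data.frame(x = c(0, 150, 500), y = c(0, 0, 0))
  D <- truncated_distance_matrix(co, truncation = 300)
  expect_equal(D[1, 2], 150)
  expect_equal(D[1, 3], 1200)
  expect_equal(D[2, 3], 1200)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("PCNM filters are orthogonal, sign-fixed and scale-ordered", {
  co <- data.frame(x = seq(0, 90, by = 10), y = rep(0, 10))
  f <- pcnm_filters(truncated_distance_matrix(co, truncation = 1000))
  # with no effective truncation the first axis is the line coordinate
  expect_true(all(diff(f$vectors[, 1]) > 0) || all(diff(f$vectors[, 1]) < 0))
  expect_true(all(diff(f$values) <= 0))

  set.seed(8)
  co2 <- data.frame(x = runif(40) * 100, y = runif(40) * 100)
  f2 <- pcnm_filters(truncated_distance_matrix(co2, truncation = 25))
  V <- f2$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_lt(max(abs(colMeans(V))), 1e-8)
  # label equivariance: permuting the points permutes the rows (up to sign)
  perm <- sample(40)
  f3 <- pcnm_filters(truncated_distance_matrix(co2[perm, ], truncation = 25))
  for (j in seq_len(ncol(V))) {
    expect_equal(abs(f3$vectors[, j]), abs(V[perm, j]), tolerance = 1e-6)
  }
})

test_that("PCNM filters agree with the vegan reference implementation", {
  set.seed(9)
  co <- data.frame(x = runif(30) * 100, y = runif(30) * 100)
  D <- truncated_distance_matrix(co, truncation = 20)
  mine <- pcnm_filters(D)
  ref <- vegan::pcnm(stats::as.dist(D))
  expect_equal(ncol(mine$vectors), ncol(ref$vectors))
  for (j in seq_len(min(5, ncol(ref$vectors)))) {
    expect_equal(abs(cor(mine$vectors[, j], ref$vectors[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("Moran's I matches its permutation null and flags smooth surfaces", {
  set.seed(14)
  co <- data.frame(x = runif(100) * 100, y = runif(100) * 100)
  v <- rnorm(100)
  perms <- vapply(1:200, function(i) {
    morans_i(sample(v), co, radius = 15)$I
  }, numeric(1))
  expect_lt(abs(mean(perms) - (-1 / 99)), 3 * sd(perms) / sqrt(200))

  smooth <- sin(co$x / 15) + cos(co$y / 15) + rnorm(100, 0, 0.1)
  m <- morans_i(smooth, co, radius = 15)
  expect_gt(m$I, 0)
  expect_lt(m$p_value, 0.01)
  expect_equal(m$expected, -1 / 99)

  expect_error(morans_i(rep(1, 100), co, radius = 15), "zero variance")
  expect_error(morans_i(v, co, radius = 1e-6), "no neighbor pairs")
})

test_that("correlograms decay with distance for smooth surfaces", {
  set.seed(15)
  co <- data.frame(x = runif(300) * 100, y = runif(300) * 100)
  noise <- rnorm(300)
  cg0 <- moran_correlogram(noise, co, breaks = c(0, 10, 20, 40, 80))
  expect_true(all(cg0$p_value > 0.01, na.rm = TRUE))

  surf <- make_covariates(co, effects = c(a = 1), spatial_sd = 0,
                          noise_sd = 0.05, covariate_range = 40,
                          seed = 16)$data$response
  cg1 <- moran_correlogram(surf, co, breaks = c(0, 10, 20, 40, 80))
  expect_equal(which.max(cg1$I), 1)
  expect_true(all(cg1$I[-1] < cg1$I[1]))
  expect_s3_class(autoplot(cg1), "ggplot")
})

test_that("forest fits recover signal, reject noise, and reproduce by seed", {
  set.seed(17)
  df <- tibble::tibble(x1 = rnorm(1000), x2 = rnorm(1000))
  noise <- dplyr::mutate(df, y = rnorm(1000))
  f0 <- rf_fit(noise, "y", ntree = 300, seed = 1)
  expect_lte(f0$r2, 0.05)
  signal <- dplyr::mutate(df, y = x1)
  f1 <- rf_fit(signal, "y", ntree = 300, seed = 1)
  expect_gte(f1$r2, 0.9)
  f1b <- rf_fit(signal, "y", ntree = 300, seed = 1)
  expect_identical(f1$r2, f1b$r2)
})

test_that("permutation importance is normalized and ranks a dominant effect first", {
  set.seed(18)
  df <- tibble::tibble(big = rnorm(800), small = rnorm(800),
                       junk = rnorm(800))
  df$y <- 2 * df$big + 0.5 * df$small + rnorm(800, 0, 0.5)
  fit <- rf_fit(df, "y", ntree = 400, seed = 2)
  imp <- rf_importance(fit)
  expect_equal(sum(imp$importance_pct), 100, tolerance = 0.1)
  expect_true(all(imp$importance_pct >= 0))
  expect_equal(imp$term[which.max(imp$importance_pct)], "big")
  expect_lt(imp$importance_pct[imp$term == "junk"], 5)
})

test_that("backward pseudo-AIC selection keeps signal and sheds noise", {
  hits_all <- 0; dropped2 <- 0
  for (s in 1:6) {
    df <- withr::with_seed(20 + s, {
      d <- tibble::tibble(
        s1 = rnorm(400), s2 = rnorm(400), s3 = rnorm(400),
        n1 = rnorm(400), n2 = rnorm(400), n3 = rnorm(400)
      )
      dplyr::mutate(d, y = s1 + 0.8 * s2 + 0.6 * s3 + rnorm(400, 0, 0.5))
    })
    sel <- backward_select_aic(df, "y", ntree = 300, seed = s)$selected
    if (all(c("s1", "s2", "s3") %in% sel)) hits_all <- hits_all + 1
    if (sum(c("n1", "n2", "n3") %in% sel) <= 1) dropped2 <- dropped2 + 1
  }
  expect_gte(hits_all, 5)
  expect_gte(dropped2, 5)

  single <- tibble::tibble(x = rnorm(100), y = rnorm(100))
  expect_identical(backward_select_aic(single, "y", ntree = 100,
                                       seed = 1)$selected, "x")
  # invariance to predictor column order
  df2 <- withr::with_seed(30, tibble::tibble(
    a = rnorm(300), b = rnorm(300), y = rnorm(300) + 2 * rnorm(300)
  ))
  s1 <- backward_select_aic(df2[c("y", "a", "b")], "y", 200, seed = 3)
  s2 <- backward_select_aic(df2[c("b", "y", "a")], "y", 200, seed = 3)
  expect_identical(sort(s1$selected), sort(s2$selected))
})

test_that("greedy filter inclusion absorbs constructed spatial noise", {
  reg <- make_region(100, 100)
  pts <- uniform_points_in(reg, 500, seed = 80)
  filters <- pcnm_filters(truncated_distance_matrix(pts, mst_max_edge(pts)))
  spatial <- make_covariates(pts, effects = c(a = 1, b = 0.5),
                             covariate_range = 50, spatial_sd = 0.8,
                             noise_sd = 0.5, noise_range = 50, seed = 81)
  # without filters the residuals are autocorrelated
  base <- rf_fit(dplyr::select(spatial$data, -x, -y), "response",
                 ntree = 300, seed = 82, importance = "none")
  expect_lt(morans_i(base$residuals, pts, 10)$p_value, 0.05)
  res <- add_spatial_filters(
    dplyr::select(spatial$data, -x, -y), "response", filters, pts,
    ntree = 300, seed = 82, moran_radius = 10, max_candidates = 10
  )
  expect_gte(res$n_filters, 1)
  expect_gte(res$moran$p_value, 0.05)
  expect_false(res$unresolved)

  # white-noise response: the loop never starts
  white <- dplyr::mutate(dplyr::select(spatial$data, -x, -y, -response),
                         response = withr::with_seed(83, rnorm(500)))
  res0 <- add_spatial_filters(white, "response", filters, pts,
                              ntree = 300, seed = 84, moran_radius = 10,
                              max_candidates = 10)
  expect_identical(res0$n_filters, 0L)

  # overwhelming fine-scale structure with one candidate: flag raised
  hard <- make_covariates(pts, effects = c(a = 1, b = 0.5),
                          covariate_range = 50, spatial_sd = 2,
                          noise_sd = 0.2, noise_range = 50, seed = 85)
  res1 <- add_spatial_filters(
    dplyr::select(hard$data, -x, -y), "response", filters, pts,
    ntree = 100, seed = 86, moran_radius = 10, max_candidates = 1
  )
  expect_true(res1$unresolved)
  expect_identical(res1$n_filters, 1L)
})

test_that("pearson_r matches hand calculation and rejects zero variance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_equal(pearson_r(x, -x + 7), -1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_r(x, y), 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")
})

test_that("the full spatial model recovers the generating structure", {
  sim <- std_sim
  cdat <- sim$covariates$data
  mdl <- roadbias_rf(dplyr::select(cdat, -x, -y), "response",
                     dplyr::select(cdat, x, y), ntree = 400, seed = 90)
  expect_true(all(c("cov1", "cov2") %in% mdl$selected))
  expect_gt(mdl$pearson[["cov1"]], 0)
  expect_gt(mdl$pearson[["cov2"]], 0)
  expect_gte(mdl$moran$p_value, 0.05)
  td <- tidy(mdl)
  expect_equal(sum(td$importance_pct), 100, tolerance = 0.1)
  gl <- glance(mdl)
  expect_lte(gl$r2, 1)
  expect_equal(gl$n, 1000)
  expect_s3_class(autoplot(mdl), "ggplot")
})
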