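#' Mean nearest-road distance of observed records (km)
#'
#' @param points Data frame of records with columns `x`, `y`.
#' @param roads A [road_network()].
#' @return Arithmetic mean of the per-record nearest-road distances.
#' @export
observed_mean_distance <- function(points, roads) {
  if (is.null(points) || nrow(points) == 0) {
    stop("no records: cannot compute a mean distance", call. = FALSE)
  }
  mean(nearest_road_distance(points, roads))
}

#' Monte-Carlo null distribution of mean nearest-road distance
#'
#' Draws `reps` uniform random patterns of `n_points` points over the region
#' (the same number as the observed records, following the null-model
#' construction) and records each pattern's mean nearest-road distance.
#'
#' @param region A [region()].
#' @param roads A [road_network()].
#' @param n_points Points per replicate pattern.
#' @param reps Number of replicates (field default 1000).
#' @param seed Optional integer seed.
#' @return A `null_distribution` object: replicate means, side (`"lower"`)
#'   and the seed used.
#' @export
null_mean_distance <- function(region, roads, n_points, reps = 1000,
                               seed = NULL) {
  stopifnot(n_points >= 1, reps >= 1)
  draw <- function() {
    vapply(seq_len(reps), function(i) {
      observed_mean_distance(uniform_points_in(region, n_points), roads)
    }, numeric(1))
  }
  values <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(values = values, reps = reps, side = "lower", seed = seed,
         n_points = n_points),
    class = "null_distribution"
  )
}

#' Percentile of a null distribution
#'
#' Linear interpolation on the sorted replicate values.
#'
#' @param null A `null_distribution`.
#' @param probs Probabilities in `[0, 1]`.
#' @export
null_percentile <- function(null, probs) {
  unname(quantile(null$values, probs, type = 7))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d replicate means (%s side), mean %.3f, p5 %.3f\n",
    x$reps, x$side, mean(x$values), null_percentile(x, 0.05)
  ))
  invisible(x)
}

#' Gamma maximum-likelihood fit to nearest-road distances
#'
#' Fits a two-parameter gamma distribution to the observed distances by
#' maximum likelihood (scale unconstrained). The shape parameter `k` indexes
#' the distance decay of collection effort: smaller `k` means record numbers
#' fall off faster with distance from roads, i.e. a stronger roadside bias.
#' Exact zeros (records lying on a road) make the gamma log-likelihood
#' unbounded for `k < 1`, so they are replaced by half the smallest positive
#' distance before fitting.
#'
#' @param distances Numeric vector of nearest-road distances (km).
#' @return A `gamma_fit` list with `shape` (k), `scale` (theta, km),
#'   `loglik` and `n`.
#' @export
fit_gamma_shape <- function(distances) {
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  pos <- distances[distances > 0]
  if (length(pos) == 0) stop("all distances are zero", call. = FALSE)
  x <- distances
  x[x == 0] <- min(pos) / 2
  if (length(x) < 10) stop("need at least 10 distances", call. = FALSE)
  m <- mean(x)
  xs <- x / m  # scale-normalized: shape invariant, scale multiplies back
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(xs, "gamma")),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    shape <- unname(fit$estimate["shape"])
    scale <- m / unname(fit$estimate["rate"])
  } else {
    # direct likelihood maximization in log-parameters
    nll <- function(p) -sum(stats::dgamma(xs, exp(p[1]), rate = exp(p[2]),
                                          log = TRUE))
    s0 <- mean(xs)^2 / var(xs)
    opt <- optim(log(c(s0, s0)), nll)
    shape <- exp(opt$par[1])
    scale <- m / exp(opt$par[2])
  }
  structure(
    list(shape = shape, scale = scale,
         loglik = sum(stats::dgamma(x, shape, scale = scale, log = TRUE)),
         n = length(x)),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> k = %.4f, theta = %.4f km (n = %d)\n",
              x$shape, x$scale, x$n))
  invisible(x)
}

#' Road-map effect test on nearest-road distances
#'
#' Compares the observed mean nearest-road distance against a Monte-Carlo
#' null of uniform random patterns of equal size. A significant road-map
#' effect is declared when the observed mean falls below the 5th percentile
#' of the replicate means. Also reported: the ratio of the observed mean to
#' the null mean (closer to 0 = stronger deviation from randomness), an
#' add-one Monte-Carlo p-value `(1 + #\{null <= observed\}) / (reps + 1)`,
#' and the gamma decay index fitted to the observed distances.
#'
#' @param points Data frame of records with columns `x`, `y`.
#' @param region A [region()].
#' @param roads A [road_network()].
#' @param reps Monte-Carlo replicates (field default 1000).
#' @param seed Optional integer seed.
#' @param fit_gamma Fit the gamma decay index as part of the summary?
#' @return A `roadmap_distance_test` object; see [tidy()] for the one-row
#'   summary.
#' @examples
#' reg <- make_region(50, 50)
#' rn <- make_roads(reg, 6, seed = 1)
#' occ <- sample_biased_occurrences(rn, reg, 200, mode = "offset",
#'                                  shape = 0.4, scale = 2, seed = 2)
#' roadmap_distance_test(occ, reg, rn, reps = 99, seed = 3)
#' @export
roadmap_distance_test <- function(points, region, roads, reps = 1000,
                                  seed = NULL, fit_gamma = TRUE) {
  d_obs <- nearest_road_distance(points, roads)
  observed <- mean(d_obs)
  null <- null_mean_distance(region, roads, nrow(points), reps, seed)
  p5 <- null_percentile(null, 0.05)
  gam <- if (fit_gamma) fit_gamma_shape(d_obs) else NULL
  structure(
    list(
      observed_mean = observed,
      null = null,
      null_p5 = p5,
      null_mean = mean(null$values),
      ratio = observed / mean(null$values),
      p_value = (1 + sum(null$values <= observed)) / (reps + 1),
      significant = observed < p5,
      gamma = gam,
      n_records = nrow(points),
      reps = reps
    ),
    class = "roadmap_distance_test"
  )
}

#' @export
print.roadmap_distance_test <- function(x, ...) {
  cat("Road-map effect: nearest-road distance null-model test\n")
  cat(sprintf("  observed mean distance: %.3f km (n = %d)\n",
              x$observed_mean, x$n_records))
  cat(sprintf("  null mean: %.3f km, 5th percentile: %.3f km (%d reps)\n",
              x$null_mean, x$null_p5, x$reps))
  cat(sprintf("  ratio observed/null: %.3f, p = %.4g%s\n", x$ratio, x$p_value,
              if (x$significant) "  [significant road-map effect]" else ""))
  if (!is.null(x$gamma)) {
    cat(sprintf("  gamma decay index: k = %.3f, theta = %.3f km\n",
                x$gamma$shape, x$gamma$scale))
  }
  invisible(x)
}

#' @rdname roadmap_distance_test
#' @param x A `roadmap_distance_test`.
#' @param ... Unused.
#' @export
tidy.roadmap_distance_test <- function(x, ...) {
  tibble::tibble(
    observed_mean = x$observed_mean,
    null_mean = x$null_mean,
    null_p5 = x$null_p5,
    ratio = x$ratio,
    p_value = x$p_value,
    significant = x$significant,
    gamma_shape = if (is.null(x$gamma)) NA_real_ else x$gamma$shape,
    gamma_scale = if (is.null(x$gamma)) NA_real_ else x$gamma$scale,
    n_records = x$n_records,
    reps = x$reps
  )
}

#' @export
glance.roadmap_distance_test <- function(x, ...) tidy(x, ...)

#' @export
autoplot.roadmap_distance_test <- function(object, ...) {
  df <- tibble::tibble(null_mean = object$null$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        colour = "goldenrod", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$null_p5, colour = "steelblue4",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "mean nearest-road distance of random pattern (km)",
      y = "replicates",
      title = "Observed mean distance (solid) vs Monte-Carlo null",
      subtitle = sprintf("ratio = %.2f, p = %.3g", object$ratio,
                         object$p_value)
    )
}

#' Road-map effect test on road density around records
#'
#' Compares the mean road density within a disc of the given radius around
#' each observed record against the same quantity for uniform random
#' patterns. Significant when the observed mean exceeds the 95th percentile
#' of the replicate means; the add-one p-value counts null replicates at
#' least as dense as observed.
#'
#' @inheritParams roadmap_distance_test
#' @param radius Disc radius in km (field convention: 5, 10, 20, 30, 50, 60).
#' @return A `roadmap_density_test` object.
#' @export
roadmap_density_test <- function(points, region, roads, radius = 5,
                                 reps = 1000, seed = NULL) {
  stopifnot(radius > 0, nrow(points) >= 1)
  observed <- mean(road_density_around(points, roads, radius, region))
  draw <- function() {
    vapply(seq_len(reps), function(i) {
      mean(road_density_around(uniform_points_in(region, nrow(points)),
                               roads, radius, region))
    }, numeric(1))
  }
  values <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  null <- structure(
    list(values = values, reps = reps, side = "upper", seed = seed,
         n_points = nrow(points)),
    class = "null_distribution"
  )
  p95 <- null_percentile(null, 0.95)
  structure(
    list(
      radius = radius,
      observed_mean_density = observed,
      null = null,
      null_p95 = p95,
      null_mean = mean(values),
      p_value = (1 + sum(values >= observed)) / (reps + 1),
      significant = observed > p95,
      n_records = nrow(points),
      reps = reps
    ),
    class = "roadmap_density_test"
  )
}

#' @export
print.roadmap_density_test <- function(x, ...) {
  cat("Road-map effect: road-density null-model test\n")
  cat(sprintf("  radius %g km; observed mean density %.4f km/km^2 (n = %d)\n",
              x$radius, x$observed_mean_density, x$n_records))
  cat(sprintf("  null mean %.4f, 95th percentile %.4f (%d reps)\n",
              x$null_mean, x$null_p95, x$reps))
  cat(sprintf("  p = %.4g%s\n", x$p_value,
              if (x$significant) "  [records sit in denser road areas]" else ""))
  invisible(x)
}

#' @rdname roadmap_density_test
#' @param x A `roadmap_density_test`.
#' @param ... Unused.
#' @export
tidy.roadmap_density_test <- function(x, ...) {
  tibble::tibble(
    radius = x$radius,
    observed_mean_density = x$observed_mean_density,
    null_mean = x$null_mean,
    null_p95 = x$null_p95,
    p_value = x$p_value,
    significant = x$significant,
    n_records = x$n_records,
    reps = x$reps
  )
}

#' @export
glance.roadmap_density_test <- function(x, ...) tidy(x, ...)

#' @export
autoplot.roadmap_density_test <- function(object, ...) {
  df <- tibble::tibble(null_density = object$null$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_density)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_mean_density,
                        colour = "goldenrod", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$null_p95, colour = "steelblue4",
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("mean road density within %g km (km/km^2)", object$radius),
      y = "replicates",
      title = "Observed road density (solid) vs Monte-Carlo null",
      subtitle = sprintf("p = %.3g", object$p_value)
    )
}
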