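#' Binomial buffer-clustering statistic
#'
#' Measures how strongly records cluster inside road buffer zones, under the
#' null that records are uniform over the region. With `N` records in the
#' region, of which `n_d` fall inside the buffer, and a buffer-area fraction
#' `p_d`, the in-buffer count is Binomial(`N`, `p_d`) under the null and
#' \describe{
#'   \item{more than expected (`n_d > N p_d`)}{`P = P(X <= n_d - 1)`, the
#'     left cumulative just below the observation, so `1 - P` is the
#'     right-tail p-value;}
#'   \item{fewer than expected (`n_d < N p_d`)}{`P = P(X <= n_d)`, itself
#'     the left-tail p-value;}
#'   \item{exactly as expected (`n_d = N p_d`, integer)}{`P = 0.50`.}
#' }
#' Values above 0.95 indicate significant clustering inside the buffers,
#' values below 0.05 significant avoidance. The cumulative probabilities are
#' evaluated with the regularized incomplete beta function (via
#' [stats::pbinom()]), numerically stable up to national-scale `N`.
#'
#' @param N Total records in the unit (>= 1).
#' @param n_d Records inside the buffer zone (0 <= `n_d` <= `N`).
#' @param p_d Buffer-area fraction, strictly inside (0, 1).
#' @return A value strictly inside (0, 1). Vectorized over `N`, `n_d`, `p_d`.
#' @examples
#' p_clustering(100, 20, 0.2) # expectation met exactly -> 0.5
#' p_clustering(10, 7, 0.3)   # clustering, but is it significant?
#' @export
p_clustering <- function(N, n_d, p_d) {
  k <- max(length(N), length(n_d), length(p_d))
  N <- rep_len(N, k); n_d <- rep_len(n_d, k); p_d <- rep_len(p_d, k)
  if (any(p_d <= 0 | p_d >= 1)) {
    stop("degenerate buffer fraction: p_d must lie strictly in (0, 1)",
         call. = FALSE)
  }
  stopifnot(all(N >= 1), all(n_d >= 0), all(n_d <= N))
  expected <- N * p_d
  out <- numeric(k)
  eq <- abs(n_d - expected) <= 1e-9 * pmax(1, expected)
  above <- !eq & n_d > expected
  below <- !eq & n_d < expected
  out[eq] <- 0.5
  out[above] <- pbinom(n_d[above] - 1, N[above], p_d[above])
  out[below] <- pbinom(n_d[below], N[below], p_d[below])
  out
}

#' Five-category interpretation of a P_clustering value
#'
#' @param p P_clustering values in (0, 1) (0.50 is the exact-expectation
#'   sentinel).
#' @return An ordered factor with levels from significant avoidance of the
#'   buffers to significant clustering inside them.
#' @export
classify_clustering <- function(p) {
  lv <- c("significantly away", "fewer than expected (n.s.)", "as expected",
          "more than expected (n.s.)", "significant clustering")
  out <- dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.05 ~ lv[1],
    p < 0.5 ~ lv[2],
    p == 0.5 ~ lv[3],
    p <= 0.95 ~ lv[4],
    TRUE ~ lv[5]
  )
  factor(out, levels = lv, ordered = TRUE)
}

#' Buffer clustering of records at the regional (national) scale
#'
#' Builds the dissolved buffer zone around all roads, takes `p_d` as its
#' area fraction of the whole region, counts the records within distance `d`
#' of a road, and evaluates [p_clustering()].
#'
#' @param points Data frame of records with columns `x`, `y`.
#' @param roads A [road_network()].
#' @param region A [region()].
#' @param d Buffer radius in km (field convention: 5 or 10).
#' @param zone Optional precomputed [buffer_union()] for `roads` at `d`.
#' @return A one-row tibble: `scale`, `unit`, `N`, `n_d`, `p_d`, `d`,
#'   `p_clustering`, `category`.
#' @export
national_clustering <- function(points, roads, region, d = 5, zone = NULL) {
  if (is.null(zone)) zone <- buffer_union(roads, d)
  p_d <- buffer_fraction(zone, region)
  N <- nrow(points)
  n_d <- sum(in_buffer(zone, points))
  P <- p_clustering(N, n_d, p_d)
  tibble::tibble(
    scale = "national", unit = "all",
    N = N, n_d = n_d, p_d = p_d, d = d,
    p_clustering = P,
    category = as.character(classify_clustering(P))
  )
}

#' Buffer clustering of records county by county
#'
#' The buffer zone is built once around all roads of the region and then
#' clipped to each county: each county's `p_d` is the buffered share of that
#' county's own area, and its records are scored against
#' Binomial(`N_county`, `p_d`). Counties without records are emitted with
#' `N = 0` and a `"no data"` note; counties whose area is entirely inside
#' (or entirely outside) the buffer have a degenerate `p_d` and are flagged
#' untestable rather than dropped.
#'
#' @inheritParams national_clustering
#' @return A tibble with one row per county: `scale`, `unit`, `N`, `n_d`,
#'   `p_d`, `d`, `p_clustering`, `category`, `note`.
#' @export
county_clustering <- function(points, roads, region, d = 5, zone = NULL) {
  if (is.null(region$counties)) stop("region has no county partition")
  if (is.null(zone)) zone <- buffer_union(roads, d)
  dist <- nearest_road_distance(points, roads)
  labels <- unique(region$counties$county)
  purrr::map(labels, function(lab) {
    ring <- county_ring(region, lab)
    inside <- points_in_polygon(points, ring)
    N <- sum(inside)
    n_d <- sum(inside & dist <= d)
    p_d <- buffer_fraction(zone, ring)
    row <- tibble::tibble(
      scale = "county", unit = lab, N = N, n_d = n_d, p_d = p_d, d = d,
      p_clustering = NA_real_, category = NA_character_, note = NA_character_
    )
    if (p_d <= 0 || p_d >= 1) {
      row$note <- sprintf("untestable: degenerate p_d = %g", p_d)
    } else if (N == 0) {
      row$note <- "no data"
    } else {
      row$p_clustering <- p_clustering(N, n_d, p_d)
      row$category <- as.character(classify_clustering(row$p_clustering))
    }
    row
  }) |>
    purrr::list_rbind()
}

#' Map of county-level P_clustering categories
#'
#' Joins a [county_clustering()] table back to the county polygons and draws
#' the five-category choropleth, with the road network overlaid.
#'
#' @param county_table Output of [county_clustering()].
#' @param region The [region()] the table was computed on.
#' @param roads Optional [road_network()] to overlay.
#' @return A ggplot object.
#' @export
plot_clustering_map <- function(county_table, region, roads = NULL) {
  lv <- levels(classify_clustering(0.5))
  polys <- region$counties |>
    dplyr::left_join(
      dplyr::select(county_table, "unit", "category", "note"),
      by = c(county = "unit")
    ) |>
    dplyr::mutate(category = factor(
      dplyr::coalesce(.data$category, .data$note), levels = c(lv, "no data")
    ))
  pal <- setNames(
    c("#2166ac", "#92c5de", "#f7f7f7", "#f4a582", "#b2182b", "grey70"),
    c(lv, "no data")
  )
  p <- ggplot2::ggplot(polys,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$county,
                                    fill = .data$category)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                               name = "P_clustering") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)")
  if (!is.null(roads)) {
    p <- p + ggplot2::geom_segment(
      data = roads$segments,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      inherit.aes = FALSE, colour = "black", linewidth = 0.3
    )
  }
  p
}
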