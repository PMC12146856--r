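#' Rectangular synthetic region with a county grid
#'
#' @param width_km,height_km Region dimensions (km, > 0).
#' @param grid Counties per side; the region is partitioned into
#'   `grid * grid` equal rectangles labelled `c01`, `c02`, ...
#' @return A [region()].
#' @examples
#' make_region(100, 100, grid = 4)
#' @export
make_region <- function(width_km, height_km, grid = 1L) {
  stopifnot(width_km > 0, height_km > 0, grid >= 1)
  boundary <- tibble::tibble(
    x = c(0, width_km, width_km, 0),
    y = c(0, 0, height_km, height_km)
  )
  wx <- width_km / grid; wy <- height_km / grid
  counties <- tidyr::expand_grid(i = seq_len(grid) - 1L, j = seq_len(grid) - 1L) |>
    dplyr::mutate(county = sprintf("c%02d", dplyr::row_number())) |>
    purrr::pmap(function(i, j, county) {
      tibble::tibble(
        county = county,
        x = c(i * wx, (i + 1) * wx, (i + 1) * wx, i * wx),
        y = c(j * wy, j * wy, (j + 1) * wy, (j + 1) * wy)
      )
    }) |>
    purrr::list_rbind()
  region(boundary, counties)
}

# point at curvilinear position t (0 <= t < perimeter) along a ring
perimeter_point <- function(ring, t) {
  x <- c(ring$x, ring$x[1]); y <- c(ring$y, ring$y[1])
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  ends <- cumsum(seg_len)
  i <- findInterval(t, c(0, ends), rightmost.closed = TRUE)
  i <- pmin(i, length(seg_len))
  f <- (t - c(0, ends)[i]) / seg_len[i]
  cbind(x[i] + f * (x[i + 1] - x[i]), y[i] + f * (y[i + 1] - y[i]))
}

#' Random-chord synthetic road network
#'
#' Draws `n_lines` random chords of the region (each connecting two
#' perimeter-uniform boundary points). `densify = k` appends a further
#' `(k - 1) * n_lines` chords from the continuation of the same seed stream,
#' so the network for a sparser period is a strict subset of any denser
#' period generated with the same seed -- emulating decade-to-decade road
#' network growth.
#'
#' @param region A [region()].
#' @param n_lines Base number of chords (>= 1).
#' @param seed Optional integer seed.
#' @param densify Integer densification factor (>= 1).
#' @param period_label,map_year Passed to [road_network()].
#' @return A [road_network()].
#' @export
make_roads <- function(region, n_lines, seed = NULL, densify = 1L,
                       period_label = "all", map_year = NA_integer_) {
  stopifnot(n_lines >= 1, densify >= 1)
  draw <- function() {
    ring <- region$boundary
    per <- {
      x <- c(ring$x, ring$x[1]); y <- c(ring$y, ring$y[1])
      sum(sqrt(diff(x)^2 + diff(y)^2))
    }
    total <- n_lines * densify
    segs <- vector("list", total)
    for (i in seq_len(total)) {
      repeat {
        p <- perimeter_point(ring, runif(2, 0, per))
        if (sqrt(sum((p[1, ] - p[2, ])^2)) > 1e-6) break
      }
      segs[[i]] <- tibble::tibble(x0 = p[1, 1], y0 = p[1, 2],
                                  x1 = p[2, 1], y1 = p[2, 2])
    }
    road_network(purrr::list_rbind(segs), period_label, map_year)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Synthetic occurrence records with a controllable roadside bias
#'
#' Three sampling modes emulate collection behaviour relative to roads:
#' \describe{
#'   \item{`"uniform"`}{no bias; delegates to [uniform_points_in()].}
#'   \item{`"offset"`}{a record sits at a perpendicular gamma-distributed
#'     offset from a length-weighted random point on a random road (shape
#'     `shape`, scale `scale`, km). Draws landing outside the region are
#'     re-drawn, not clipped, so the offset law stays exactly gamma. For a
#'     single straight road the nearest-road distance equals the drawn
#'     offset, which makes gamma-shape recovery testable.}
#'   \item{`"thinning"`}{uniform proposals are accepted with probability
#'     `exp(-d / lambda)` where `d` is the nearest-road distance: an
#'     exponential distance-decay of sampling effort.}
#' }
#'
#' @param roads A [road_network()].
#' @param region A [region()].
#' @param n Number of records.
#' @param mode `"uniform"`, `"offset"` or `"thinning"`.
#' @param shape,scale Gamma offset parameters (offset mode), km.
#' @param lambda Exponential decay scale (thinning mode), km.
#' @param year,species Attached to every generated record.
#' @param seed Optional integer seed.
#' @param max_tries Proposal budget per record before giving up.
#' @return A tibble with columns `record_id`, `species`, `x`, `y`, `year`.
#' @export
sample_biased_occurrences <- function(roads, region, n,
                                      mode = c("uniform", "offset", "thinning"),
                                      shape = 0.4, scale = 9, lambda = 5,
                                      year = NA_integer_, species = "sp",
                                      seed = NULL, max_tries = 1000) {
  mode <- match.arg(mode)
  stopifnot(n > 0)
  finish <- function(px, py) {
    tibble::tibble(
      record_id = sprintf("o%06d", seq_len(n)),
      species = species, x = px, y = py, year = as.integer(year)
    )
  }
  draw <- function() {
    if (mode == "uniform") {
      u <- uniform_points_in(region, n)
      return(finish(u$x, u$y))
    }
    ring <- region$boundary
    s <- roads$segments
    px <- numeric(0); py <- numeric(0)
    proposed <- 0
    while (length(px) < n) {
      m <- max(2L * (n - length(px)), 200L)
      proposed <- proposed + m
      if (proposed > max_tries * n) {
        stop("unable to place occurrences: acceptance rate too low",
             call. = FALSE)
      }
      if (mode == "offset") {
        len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
        i <- sample.int(nrow(s), m, replace = TRUE, prob = len)
        t <- runif(m)
        bx <- s$x0[i] + t * (s$x1[i] - s$x0[i])
        by <- s$y0[i] + t * (s$y1[i] - s$y0[i])
        nx <- -(s$y1[i] - s$y0[i]) / len[i]
        ny <- (s$x1[i] - s$x0[i]) / len[i]
        side <- sample(c(-1, 1), m, replace = TRUE)
        off <- rgamma(m, shape = shape, scale = scale)
        cx <- bx + side * off * nx
        cy <- by + side * off * ny
        keep <- cpp_points_in_polygon(cx, cy, ring$x, ring$y)
      } else {
        u <- uniform_points_in(region, m)
        cx <- u$x; cy <- u$y
        d <- nearest_road_distance(u, roads)
        keep <- runif(m) < exp(-d / lambda)
      }
      px <- c(px, cx[keep]); py <- c(py, cy[keep])
    }
    finish(px[seq_len(n)], py[seq_len(n)])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# random-Fourier-feature surface generator: approximates a unit-variance
# Gaussian-process surface with squared-exponential lengthscale `range / 2`
make_surface <- function(range, n_basis = 64) {
  ell <- range / 2
  wx <- rnorm(n_basis, 0, 1 / ell)
  wy <- rnorm(n_basis, 0, 1 / ell)
  phi <- runif(n_basis, 0, 2 * pi)
  function(x, y) {
    out <- numeric(length(x))
    for (j in seq_len(n_basis)) {
      out <- out + cos(wx[j] * x + wy[j] * y + phi[j])
    }
    out * sqrt(2 / n_basis)
  }
}

#' Spatially autocorrelated covariates with known effects
#'
#' Each covariate is a smooth random surface (sum of `n_basis` random cosine
#' bases approximating a unit-variance Gaussian process with correlation
#' range `covariate_range` km) evaluated at the record coordinates. The
#' response is the linear combination of the covariates under `effects`,
#' plus a spatially correlated noise surface (same mechanism, range
#' `noise_range`, standard deviation `spatial_sd`) and white noise of
#' standard deviation `noise_sd`. The generating truth is returned alongside
#' the table so recovery can be scored.
#'
#' The covariate range is kept well below the noise range by default:
#' independent smooth fields whose range approaches the region extent are
#' strongly mutually correlated by chance, which would make "independent
#' covariates with known effects" unrecoverable by any method.
#'
#' @param points Data frame with columns `x`, `y` (km).
#' @param effects Named numeric vector of true linear effects; the names
#'   become the covariate columns.
#' @param covariate_range Correlation range of the covariate surfaces (km).
#' @param noise_range Correlation range of the spatial noise surface (km).
#' @param spatial_sd Standard deviation of the spatially correlated noise
#'   component (0 disables it).
#' @param noise_sd Standard deviation of the white-noise component.
#' @param n_basis Number of cosine basis terms per surface.
#' @param seed Optional integer seed.
#' @return A list with `data` (tibble: `x`, `y`, covariates, `response`) and
#'   `truth` (list of the generating parameters).
#' @export
make_covariates <- function(points, effects = c(cov1 = 1, cov2 = 0.5,
                                                cov3 = 0, cov4 = 0),
                            covariate_range = 25, noise_range = 50,
                            spatial_sd = 0.5, noise_sd = 0.5, n_basis = 64,
                            seed = NULL) {
  stopifnot(length(effects) >= 1, covariate_range >= 0, noise_range >= 0,
            !is.null(names(effects)))
  draw <- function() {
    n <- nrow(points)
    covs <- purrr::map(names(effects), function(nm) {
      f <- make_surface(covariate_range, n_basis)
      f(points$x, points$y)
    })
    names(covs) <- names(effects)
    response <- Reduce(`+`, purrr::map2(covs, effects, `*`))
    if (spatial_sd > 0) {
      g <- make_surface(noise_range, n_basis)
      response <- response + spatial_sd * g(points$x, points$y)
    }
    response <- response + rnorm(n, 0, noise_sd)
    data <- tibble::tibble(x = points$x, y = points$y, !!!covs,
                           response = response)
    list(
      data = data,
      truth = list(effects = effects, covariate_range = covariate_range,
                   noise_range = noise_range, spatial_sd = spatial_sd,
                   noise_sd = noise_sd)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Default synthetic scenario
#'
#' The study conditions used throughout the package's tests and examples: a
#' 100 x 100 km region with a 4 x 4 county grid, 12 random-chord roads, 1000
#' occurrence records placed by perpendicular gamma offsets (shape 0.4, mean
#' 3.6 km -- a strong roadside bias), and four covariate surfaces with true
#' effects (1, 0.5, 0, 0) and 25 km correlation range, plus spatial noise of
#' sd 0.5 with 50 km range and white noise of sd 0.5.
#'
#' @return A nested list of generator parameters accepted by
#'   [simulate_scenario()].
#' @export
default_scenario <- function() {
  list(
    region = list(width_km = 100, height_km = 100, grid = 4L),
    roads = list(n_lines = 12L, densify = 1L,
                 period_label = "2010s", map_year = 2012L),
    occurrences = list(n = 1000L, mode = "offset", shape = 0.4, scale = 9,
                       lambda = 5, year = 2012L),
    covariates = list(effects = c(cov1 = 1, cov2 = 0.5, cov3 = 0, cov4 = 0),
                      covariate_range = 25, noise_range = 50,
                      spatial_sd = 0.5, noise_sd = 0.5)
  )
}

#' Generate a full synthetic scenario
#'
#' Runs the region, road, occurrence and covariate generators under one seed
#' stream. Pure: the same `(scenario, seed)` pair always yields identical
#' output.
#'
#' @param scenario A scenario list as produced by [default_scenario()];
#'   individual elements may be overridden.
#' @param seed Integer seed.
#' @return A list with elements `region`, `roads`, `occurrences`,
#'   `covariates` (see [make_covariates()]) and `seed`.
#' @export
simulate_scenario <- function(scenario = default_scenario(), seed = 1) {
  withr::with_seed(seed, {
    reg <- do.call(make_region, scenario$region)
    roads <- do.call(make_roads, c(list(region = reg), scenario$roads))
    occ <- do.call(sample_biased_occurrences,
                   c(list(roads = roads, region = reg), scenario$occurrences))
    cov <- do.call(make_covariates,
                   c(list(points = occ), scenario$covariates))
    list(region = reg, roads = roads, occurrences = occ, covariates = cov,
         seed = seed)
  })
}
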