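#' Truncated pairwise distance matrix for PCNM
#'
#' Euclidean distances between record coordinates, with every distance above
#' the truncation threshold replaced by four times that threshold. The
#' substitution keeps the matrix finite while down-weighting long-range
#' relationships, so the subsequent eigen-decomposition concentrates on
#' neighbourhood structure.
#'
#' @param coords Data frame or matrix with columns `x`, `y` (km).
#' @param truncation Threshold distance in km (default 300, the scale below
#'   which residual spatial autocorrelation is typically concentrated for a
#'   continental analysis; pick it from a correlogram for other extents).
#' @return A symmetric matrix with zero diagonal; entries are either the
#'   original distance (<= truncation) or `4 * truncation`.
#' @examples
#' truncated_distance_matrix(data.frame(x = c(0, 500), y = c(0, 0)), 300)
#' @export
truncated_distance_matrix <- function(coords, truncation = 300) {
  coords <- as.data.frame(coords)
  stopifnot(nrow(coords) >= 3, truncation > 0)
  D <- as.matrix(dist(cbind(coords$x, coords$y)))
  D[D > truncation] <- 4 * truncation
  diag(D) <- 0
  attr(D, "truncation") <- truncation
  D
}

# longest edge of the minimum spanning tree (Prim), the classical default
# PCNM truncation: the smallest threshold keeping all points connected
mst_max_edge <- function(coords) {
  D <- as.matrix(dist(cbind(coords$x, coords$y)))
  n <- nrow(D)
  used <- rep(FALSE, n); used[1] <- TRUE
  best <- D[1, ]
  maxedge <- 0
  for (k in seq_len(n - 1)) {
    best[used] <- Inf
    j <- which.min(best)
    maxedge <- max(maxedge, best[j])
    used[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  maxedge
}

#' PCNM spatial filters from a truncated distance matrix
#'
#' Principal coordinates of neighbour matrices: the truncated distance
#' matrix is double-centered as \eqn{-\frac12 H D^2 H} and
#' eigen-decomposed; the eigenvectors with positive eigenvalues are the
#' spatial filters, ordered from broadest to finest spatial scale. Vectors
#' are unit-norm, centered, mutually orthogonal, and sign-fixed so each
#' vector's first nonzero loading is positive.
#'
#' @param D A matrix from [truncated_distance_matrix()].
#' @return A `spatial_filters` object: `vectors` (n x k matrix, columns
#'   `PCNM1`, `PCNM2`, ...), `values` (positive eigenvalues, descending) and
#'   the truncation used.
#' @export
pcnm_filters <- function(D) {
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  keep <- e$values > tol
  if (!any(keep)) stop("no spatial structure: no positive eigenvalues",
                       call. = FALSE)
  V <- e$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PCNM", seq_len(ncol(V)))
  structure(
    list(vectors = V, values = e$values[keep],
         truncation = attr(D, "truncation")),
    class = "spatial_filters"
  )
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("<spatial_filters> %d positive-eigenvalue PCNM vectors (n = %d)\n",
              ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

# binary distance-band weights (no self-neighbours)
band_weights <- function(coords, lower, upper) {
  D <- as.matrix(dist(cbind(coords$x, coords$y)))
  W <- (D >= lower & D <= upper) * 1
  diag(W) <- 0
  W
}

#' Global Moran's I with distance-band weights
#'
#' Binary neighbour weights (pairs within `radius` km), row-standardized;
#' significance from the normal approximation with the analytic null
#' expectation `-1/(n-1)`.
#'
#' @param values Numeric vector.
#' @param coords Data frame with columns `x`, `y`, one row per value.
#' @param radius Neighbourhood radius in km.
#' @return A `moran_test` list: `I`, `expected`, `sd`, `z`, `p_value`, `n`.
#' @export
morans_i <- function(values, coords, radius) {
  stopifnot(length(values) == nrow(coords), length(values) >= 10)
  if (var(values) == 0) stop("zero variance", call. = FALSE)
  W <- band_weights(coords, 0, radius)
  if (sum(W) == 0) stop("no neighbor pairs within radius", call. = FALSE)
  m <- ape::Moran.I(values, W, scaled = FALSE, alternative = "two.sided")
  structure(
    list(I = m$observed, expected = m$expected, sd = m$sd,
         z = (m$observed - m$expected) / m$sd, p_value = m$p.value,
         n = length(values), radius = radius),
    class = "moran_test"
  )
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (expected %.4f, sd %.4f), z = %.2f, p = %.4g [n = %d, radius %g km]\n",
    x$I, x$expected, x$sd, x$z, x$p_value, x$n, x$radius
  ))
  invisible(x)
}

#' @rdname morans_i
#' @param x A `moran_test`.
#' @param ... Unused.
#' @export
tidy.moran_test <- function(x, ...) {
  tibble::tibble(I = x$I, expected = x$expected, sd = x$sd, z = x$z,
                 p_value = x$p_value, n = x$n, radius = x$radius)
}

#' Moran correlogram over distance classes
#'
#' Moran's I computed per distance class with band weights; empty classes
#' are flagged missing. Used to choose the PCNM truncation distance: take
#' the class beyond which autocorrelation becomes negligible.
#'
#' @param values Numeric vector.
#' @param coords Data frame with columns `x`, `y`.
#' @param breaks Increasing vector of class boundaries (km), at least 3
#'   values (2 classes).
#' @return A tibble of class `moran_correlogram`: `lower`, `upper`,
#'   `n_pairs`, `I`, `p_value`.
#' @export
moran_correlogram <- function(values, coords, breaks) {
  stopifnot(length(breaks) >= 3, !is.unsorted(breaks))
  D <- as.matrix(dist(cbind(coords$x, coords$y)))
  rows <- purrr::map(seq_len(length(breaks) - 1), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    W <- (D > lo & D <= hi) * 1
    diag(W) <- 0
    if (sum(W) == 0 || var(values) == 0) {
      return(tibble::tibble(lower = lo, upper = hi, n_pairs = sum(W) / 2,
                            I = NA_real_, p_value = NA_real_))
    }
    m <- ape::Moran.I(values, W, scaled = FALSE, alternative = "two.sided")
    tibble::tibble(lower = lo, upper = hi, n_pairs = sum(W) / 2,
                   I = m$observed, p_value = m$p.value)
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("moran_correlogram", class(out))
  out
}

#' @export
autoplot.moran_correlogram <- function(object, ...) {
  df <- dplyr::mutate(object, mid = (.data$lower + .data$upper) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$I)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$p_value < 0.01), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "p < 0.01") +
    ggplot2::labs(x = "distance class midpoint (km)", y = "Moran's I")
}

#' Pearson correlation with validity checks
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return The product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  cor(x, y)
}

#' Random-forest regression fit with out-of-bag R-squared
#'
#' Thin seeded wrapper around [ranger::ranger()] (single-threaded, so the
#' same seed always reproduces the same forest). Predictor columns are
#' sorted by name before fitting, making results invariant to the column
#' order of `data`. The out-of-bag R-squared, `1 - MSE_oob / var(y)`, is the
#' forest's variance explained, the analogue of R-squared in a linear
#' regression.
#'
#' @param data Data frame holding the response column and predictor columns
#'   (nothing else).
#' @param response Name of the response column.
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @param importance `"permutation"` (increase in OOB MSE when the predictor
#'   is permuted) or `"none"` (faster; selection loops use this).
#' @return An `rf_fit` list: `model`, `r2`, `mse`, `residuals` (OOB),
#'   `predictors`, `response`, `ntree`, `seed`.
#' @export
rf_fit <- function(data, response, ntree = 500, seed = 1,
                   importance = c("permutation", "none")) {
  importance <- match.arg(importance)
  stopifnot(response %in% names(data))
  y <- data[[response]]
  x <- data[sort(setdiff(names(data), response))]
  stopifnot(ncol(x) >= 1, nrow(x) >= 2)
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y, num.trees = ntree, seed = seed,
    num.threads = 1, importance = importance, oob.error = TRUE
  )
  pred <- fit$predictions
  pred[is.nan(pred)] <- mean(y)
  structure(
    list(model = fit, r2 = 1 - fit$prediction.error / var(y),
         mse = fit$prediction.error, residuals = y - pred,
         predictors = names(x), response = response,
         ntree = ntree, seed = seed),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %s ~ %s | ntree = %d, OOB R^2 = %.3f\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$ntree, x$r2))
  invisible(x)
}

#' Normalized permutation importance of a fitted forest
#'
#' Raw importance is the increase in out-of-bag MSE when each predictor is
#' permuted; negative values (pure noise) are floored at zero and the rest
#' rescaled to sum to 100, giving relative importance shares.
#'
#' @param fit An [rf_fit()] trained with `importance = "permutation"`.
#' @return A tibble: `term`, `raw` (increase in OOB MSE),
#'   `importance_pct`.
#' @export
rf_importance <- function(fit) {
  raw <- fit$model$variable.importance
  if (is.null(raw)) stop("fit was trained without permutation importance")
  floored <- pmax(raw, 0)
  total <- sum(floored)
  pct <- if (total > 0) 100 * floored / total else
    rep(100 / length(floored), length(floored))
  tibble::tibble(term = names(raw), raw = unname(raw),
                 importance_pct = unname(pct))
}

# pseudo-AIC for a forest: n log(OOB MSE) + 2 (p + 1). Monotone in OOB fit,
# penalizes predictor count; used only to rank nested candidate models.
pseudo_aic <- function(fit, n) n * log(fit$mse) + 2 * (length(fit$predictors) + 1)

#' Stepwise backward predictor selection by pseudo-AIC
#'
#' Starting from the full predictor set, repeatedly refits the forest with
#' each predictor removed and drops the one whose removal most decreases the
#' pseudo-AIC `n log(MSE_oob) + 2 (p + 1)`; stops when no removal decreases
#' it. Deterministic for a fixed seed, and invariant to predictor column
#' order (fits sort columns internally).
#'
#' @inheritParams rf_fit
#' @return A list: `selected` (character vector of retained predictors) and
#'   `trace` (tibble of steps: predictor dropped, resulting pseudo-AIC).
#' @export
backward_select_aic <- function(data, response, ntree = 500, seed = 1) {
  preds <- sort(setdiff(names(data), response))
  stopifnot(length(preds) >= 1)
  n <- nrow(data)
  fit_subset <- function(keep) {
    rf_fit(data[c(response, keep)], response, ntree, seed,
           importance = "none")
  }
  current <- preds
  aic <- pseudo_aic(fit_subset(current), n)
  trace <- list(tibble::tibble(step = 0L, dropped = NA_character_, aic = aic))
  step <- 0L
  while (length(current) > 1) {
    cand <- purrr::map_dbl(current, function(p) {
      pseudo_aic(fit_subset(setdiff(current, p)), n)
    })
    if (min(cand) >= aic) break
    step <- step + 1L
    drop <- current[which.min(cand)]
    aic <- min(cand)
    current <- setdiff(current, drop)
    trace <- c(trace, list(tibble::tibble(step = step, dropped = drop,
                                          aic = aic)))
  }
  list(selected = current, trace = purrr::list_rbind(trace))
}

#' Greedy inclusion of PCNM filters until residuals are non-autocorrelated
#'
#' Starting from the forest on the selected predictors, tests the OOB
#' residuals for spatial autocorrelation (global Moran's I at
#' `moran_radius`). While significant (p < `alpha`), each remaining
#' candidate filter is tried in turn and the one with the largest marginal
#' gain in OOB R-squared is added; the loop stops when residual
#' autocorrelation becomes insignificant or candidates are exhausted (then
#' flagged unresolved).
#'
#' @inheritParams rf_fit
#' @param filters A [pcnm_filters()] result aligned with `data` rows.
#' @param coords Data frame with columns `x`, `y` for the residual test.
#' @param moran_radius Neighbourhood radius (km) for the residual Moran
#'   test.
#' @param alpha Significance level declaring residuals autocorrelated.
#' @param max_candidates Consider only the first `max_candidates` filters
#'   (broadest spatial scales); `NULL` for all.
#' @return A list: `fit` (final [rf_fit()] with permutation importance),
#'   `n_filters`, `filters_used`, `moran` (final residual test),
#'   `unresolved` (logical).
#' @export
add_spatial_filters <- function(data, response, filters, coords,
                                ntree = 500, seed = 1, alpha = 0.05,
                                moran_radius = 10, max_candidates = NULL) {
  V <- filters$vectors
  if (!is.null(max_candidates)) {
    V <- V[, seq_len(min(max_candidates, ncol(V))), drop = FALSE]
  }
  stopifnot(nrow(V) == nrow(data))
  fit_with <- function(cols, importance = "none") {
    df <- dplyr::bind_cols(data, tibble::as_tibble(V[, cols, drop = FALSE]))
    rf_fit(df, response, ntree, seed, importance)
  }
  used <- character(0)
  fit <- rf_fit(data, response, ntree, seed, importance = "none")
  moran <- morans_i(fit$residuals, coords, moran_radius)
  remaining <- colnames(V)
  while (moran$p_value < alpha && length(remaining) > 0) {
    gains <- purrr::map_dbl(remaining, function(f) {
      fit_with(c(used, f))$r2 - fit$r2
    })
    best <- remaining[which.max(gains)]
    used <- c(used, best)
    remaining <- setdiff(remaining, best)
    fit <- fit_with(used)
    moran <- morans_i(fit$residuals, coords, moran_radius)
  }
  final <- if (length(used) > 0) fit_with(used, importance = "permutation")
           else rf_fit(data, response, ntree, seed,
                       importance = "permutation")
  list(fit = final, n_filters = length(used), filters_used = used,
       moran = morans_i(final$residuals, coords, moran_radius),
       unresolved = moran$p_value < alpha)
}

#' Spatially explicit random-forest covariate analysis
#'
#' The full modelling pipeline for one road-map-effect response (nearest-road
#' distance, P_clustering or road density) against environmental /
#' socio-economic covariates:
#' \enumerate{
#'   \item stepwise backward predictor selection by pseudo-AIC
#'     ([backward_select_aic()]);
#'   \item PCNM spatial filters from the truncated distance matrix of the
#'     record coordinates ([truncated_distance_matrix()], [pcnm_filters()]);
#'   \item greedy filter inclusion until residual Moran's I is insignificant
#'     ([add_spatial_filters()]);
#'   \item permutation importance normalized to 100 across predictors and
#'     filters, plus Pearson correlations giving effect directions.
#' }
#'
#' @param data Data frame with the response column and candidate predictor
#'   columns (coordinates passed separately).
#' @param response Name of the response column.
#' @param coords Data frame with columns `x`, `y` (km), one row per record.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @param truncation PCNM truncation distance (km); `NULL` uses the longest
#'   minimum-spanning-tree edge (the classical PCNM default), appropriate
#'   when the extent is far below the continental 300 km convention.
#' @param moran_radius Residual Moran neighbourhood radius (km).
#' @param alpha Residual-autocorrelation significance level.
#' @param max_filter_candidates Candidate pool size for greedy filter
#'   inclusion (broadest scales first).
#' @param select Run backward selection first? `FALSE` keeps all predictors.
#' @return A `roadbias_rf` object; `tidy()` gives the per-term table
#'   (Pearson r and relative importance), `glance()` the model-level row.
#' @export
roadbias_rf <- function(data, response, coords, ntree = 500, seed = 1,
                        truncation = NULL, moran_radius = 10, alpha = 0.05,
                        max_filter_candidates = 10, select = TRUE) {
  stopifnot(nrow(data) == nrow(coords), nrow(data) >= 50)
  sel <- if (select) backward_select_aic(data, response, ntree, seed)
         else list(selected = sort(setdiff(names(data), response)),
                   trace = NULL)
  if (is.null(truncation)) truncation <- mst_max_edge(coords)
  filters <- pcnm_filters(truncated_distance_matrix(coords, truncation))
  step <- add_spatial_filters(data[c(response, sel$selected)], response,
                              filters, coords, ntree, seed, alpha,
                              moran_radius, max_filter_candidates)
  imp <- rf_importance(step$fit)
  pr <- purrr::map_dbl(sel$selected, function(p) {
    pearson_r(data[[p]], data[[response]])
  })
  structure(
    list(
      response = response,
      selected = sel$selected,
      selection_trace = sel$trace,
      n_filters = step$n_filters,
      filters_used = step$filters_used,
      r2 = step$fit$r2,
      importance = imp,
      pearson = setNames(pr, sel$selected),
      moran = step$moran,
      unresolved = step$unresolved,
      truncation = truncation,
      ntree = ntree,
      seed = seed,
      n = nrow(data),
      fit = step$fit
    ),
    class = "roadbias_rf"
  )
}

#' @export
print.roadbias_rf <- function(x, ...) {
  cat(sprintf("Spatial random-forest model for '%s' (n = %d, ntree = %d)\n",
              x$response, x$n, x$ntree))
  cat(sprintf("  variance explained (OOB R^2): %.4f\n", x$r2))
  cat(sprintf("  predictors: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("  spatial filters included: %d%s\n", x$n_filters,
              if (x$unresolved) " (residual autocorrelation unresolved)" else ""))
  cat(sprintf("  residual Moran's I: %.4f (p = %.3g)\n",
              x$moran$I, x$moran$p_value))
  print(tidy(x))
  invisible(x)
}

#' @rdname roadbias_rf
#' @param x A `roadbias_rf` object.
#' @param ... Unused.
#' @export
tidy.roadbias_rf <- function(x, ...) {
  imp <- x$importance
  pred_rows <- imp |>
    dplyr::filter(.data$term %in% x$selected) |>
    dplyr::mutate(pearson_r = unname(x$pearson[.data$term])) |>
    dplyr::select("term", "pearson_r", "importance_pct") |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
  filt <- imp |> dplyr::filter(!.data$term %in% x$selected)
  if (nrow(filt) > 0) {
    pred_rows <- dplyr::bind_rows(
      pred_rows,
      tibble::tibble(term = sprintf("%d spatial filters", nrow(filt)),
                     pearson_r = NA_real_,
                     importance_pct = sum(filt$importance_pct))
    )
  }
  pred_rows
}

#' @export
glance.roadbias_rf <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    r2 = x$r2,
    n_predictors = length(x$selected),
    n_filters = x$n_filters,
    residual_moran_i = x$moran$I,
    residual_moran_p = x$moran$p_value,
    unresolved_autocorrelation = x$unresolved,
    ntree = x$ntree,
    n = x$n
  )
}

#' @export
autoplot.roadbias_rf <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)),
                  direction = dplyr::case_when(
                    is.na(.data$pearson_r) ~ "spatial filters",
                    .data$pearson_r >= 0 ~ "positive",
                    TRUE ~ "negative"
                  ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance_pct, y = .data$term,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "#b2182b",
                                          negative = "#2166ac",
                                          `spatial filters` = "grey60")) +
    ggplot2::labs(
      x = "relative importance (%)", y = NULL,
      title = sprintf("Variance explained: %.1f%%", 100 * object$r2)
    )
}
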