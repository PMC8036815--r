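#' Cross-type Ripley K function
#'
#' Estimates the cross-type Ripley K statistic between two cell
#' populations: the expected number of type-y points within distance
#' `r` of a type-x point, scaled by the intensity of y over the
#' observation window,
#' \deqn{\hat K_{xy}(r) = \frac{A}{n_x n_y} \sum_i \sum_j 1(d_{ij} \le r).}
#' No edge correction is applied by default: the radii used for
#' whole-slide immune-contexture features (20-250 um) are small relative
#' to slide extent, so boundary bias is negligible there.  A translation
#' correction is available via `correction = "translation"` for
#' rectangular windows.
#'
#' @param points_x data frame or matrix with columns `x`, `y` (um);
#'   reference population.
#' @param points_y same layout; counted population.
#' @param window observation window: either a single number (area in
#'   um^2) or a list with `xrange`, `yrange` (um).
#' @param r numeric vector of radii (um), strictly increasing, all > 0.
#' @param correction `"none"` (default) or `"translation"` (requires a
#'   rectangular window).
#' @return numeric vector of K values (um^2), one per radius.  If either
#'   population is empty, a vector of `NA` with attribute
#'   `empty_population = TRUE` is returned; downstream feature assembly
#'   imputes the CSR-neutral value.
#' @seealso [l_curve()], [cross_k_oracle()]
#' @export
cross_k <- function(points_x, points_y, window, r, correction = c("none", "translation")) {
  correction <- match.arg(correction)
  r <- as.numeric(r)
  if (length(r) < 1 || any(!is.finite(r)) || any(r <= 0) || is.unsorted(r, strictly = TRUE))
    stop("radii must be strictly increasing and positive")
  px <- .as_points(points_x)
  py <- .as_points(points_y)
  A <- .window_area(window)
  if (!is.finite(A) || A <= 0) stop("window area must be finite and positive")
  nx <- nrow(px); ny <- nrow(py)
  if (nx == 0L || ny == 0L) {
    out <- rep(NA_real_, length(r))
    attr(out, "empty_population") <- TRUE
    return(out)
  }
  if (correction == "none") {
    cnt <- .pair_count_within(px$x, px$y, py$x, py$y, r)
    K <- A * cnt / (nx * ny)
  } else {
    if (!is.list(window)) stop("translation correction requires a rectangular window")
    K <- .cross_k_translation(px, py, window, r)
  }
  as.numeric(K)
}

#' Brute-force cross-K oracle
#'
#' Direct double loop over all (x, y) pairs; intended as an independent
#' check of [cross_k()] on small inputs.
#'
#' @inheritParams cross_k
#' @return numeric vector of K values, one per radius.
#' @export
cross_k_oracle <- function(points_x, points_y, window, r) {
  px <- .as_points(points_x)
  py <- .as_points(points_y)
  A <- .window_area(window)
  nx <- nrow(px); ny <- nrow(py)
  if (nx == 0L || ny == 0L) {
    out <- rep(NA_real_, length(r))
    attr(out, "empty_population") <- TRUE
    return(out)
  }
  vapply(as.numeric(r), function(ri) {
    cnt <- 0L
    for (i in seq_len(nx)) {
      d <- sqrt((py$x - px$x[i])^2 + (py$y - px$y[i])^2)
      cnt <- cnt + sum(d <= ri)
    }
    A * cnt / (nx * ny)
  }, numeric(1))
}

#' Cross-type L function curve
#'
#' The variance-stabilised transform \eqn{L_{xy}(r) = \sqrt{K_{xy}(r)/\pi}},
#' so that complete spatial randomness gives \eqn{L(r) = r}: values above
#' `r` indicate clustering of y around x, values below indicate
#' dispersion.  Each radius is carried as a separate feature downstream
#' rather than summarised (e.g. by area under the curve).
#'
#' @inheritParams cross_k
#' @param radii radii (um), default the six whole-slide feature radii
#'   `c(20, 50, 100, 150, 200, 250)`.
#' @return object of class `l_curve`: a data frame with columns `r`,
#'   `K`, `L`, plus attributes `n_x`, `n_y`, `area`, `lambda_y`,
#'   `empty_population`.
#' @export
l_curve <- function(points_x, points_y, window, radii = c(20, 50, 100, 150, 200, 250),
                    correction = c("none", "translation")) {
  K <- cross_k(points_x, points_y, window, radii, correction = match.arg(correction))
  empty <- isTRUE(attr(K, "empty_population"))
  A <- .window_area(window)
  nx <- nrow(.as_points(points_x)); ny <- nrow(.as_points(points_y))
  out <- data.frame(r = as.numeric(radii), K = as.numeric(K),
                    L = sqrt(pmax(as.numeric(K), 0) / pi))
  if (empty) out$L <- NA_real_
  structure(out, class = c("l_curve", "data.frame"),
            n_x = nx, n_y = ny, area = A,
            lambda_y = if (ny > 0) ny / A else NA_real_,
            empty_population = empty)
}

# translation edge correction for a rectangular window: weight each pair
# by the reciprocal overlap fraction of the window with itself shifted
# by the pair separation
.cross_k_translation <- function(px, py, window, r) {
  a <- diff(range(window$xrange)); b <- diff(range(window$yrange))
  A <- a * b
  nx <- nrow(px); ny <- nrow(py)
  K <- numeric(length(r))
  for (i in seq_len(nx)) {
    dx <- abs(py$x - px$x[i]); dy <- abs(py$y - px$y[i])
    d <- sqrt(dx^2 + dy^2)
    w <- A / ((a - dx) * (b - dy))
    w[dx >= a | dy >= b] <- 0
    for (k in seq_along(r)) K[k] <- K[k] + sum(w[d <= r[k]])
  }
  A * K / (nx * ny)
}

.as_points <- function(p) {
  if (is.matrix(p)) p <- as.data.frame(p)
  if (is.null(p) || nrow(p) == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  if (!all(c("x", "y") %in% names(p))) {
    if (ncol(p) >= 2) { p <- p[, 1:2]; names(p) <- c("x", "y") }
    else stop("points need columns x and y")
  }
  if (any(!is.finite(p$x)) || any(!is.finite(p$y))) stop("non-finite coordinates")
  p[, c("x", "y")]
}

.window_area <- function(window) {
  if (is.numeric(window) && length(window) == 1L) return(as.numeric(window))
  if (is.list(window) && all(c("xrange", "yrange") %in% names(window)))
    return(diff(range(window$xrange)) * diff(range(window$yrange)))
  stop("window must be an area (um^2) or list(xrange=, yrange=)")
}
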