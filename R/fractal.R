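#' Box counting on a normalised curve
#'
#' Counts the distinct cells of the `g x g` uniform grid on `[0,1]^2` that
#' are touched by the piecewise-linear curve through `points`. Segments are
#' rasterised at arc-length step `1/(10 g)` so that no crossed cell is
#' skipped; the boundary convention is `cell = min(floor(coord * g), g-1)`.
#'
#' @param points data.frame or matrix with columns x, y; coordinates are
#'   clipped to `[0, 1]`.
#' @param g grid subdivision, >= 1.
#' @return number of occupied cells (between 1 and `g^2`).
#' @examples
#' box_count(data.frame(x = c(0, 1), y = c(0, 1)), 7)  # 7: one cell per row
#' @export
box_count <- function(points, g) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L)
    stop_petkin("at least one point is required", "petkin_invalid_input")
  g <- as.integer(g)
  if (g < 1L) stop_petkin("g must be >= 1", "petkin_invalid_input")
  x <- pmin(pmax(pts[, 1], 0), 1)
  y <- pmin(pmax(pts[, 2], 0), 1)
  n <- length(x)
  if (n > 1L) {
    step <- 1 / (10 * g)
    xs <- list(); ys <- list()
    for (i in seq_len(n - 1L)) {
      len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
      m <- max(1L, ceiling(len / step))
      tt <- seq(0, 1, length.out = m + 1L)
      xs[[i]] <- x[i] + tt * (x[i + 1] - x[i])
      ys[[i]] <- y[i] + tt * (y[i + 1] - y[i])
    }
    x <- unlist(xs); y <- unlist(ys)
  }
  ix <- pmin(floor(x * g), g - 1L)
  iy <- pmin(floor(y * g), g - 1L)
  length(unique(ix * g + iy))
}

#' Box-counting fractal dimension of a time--SUV curve
#'
#' A non-compartmental heterogeneity index: the time axis is normalised to
#' `[0, 1]` over the schedule span and the SUV axis by a fixed `max_suv`
#' (values above it are clipped), the piecewise-linear curve through the
#' frame midpoints is box-counted on grids `g = 1..max_grid`, and the
#' fractal dimension is the least-squares slope of `ln(boxes)` versus
#' `ln(g)`, clipped to `[0, 2]`. Smooth monotone uptake curves give values
#' near 1; a single point gives 0. The conventional settings are a 7 x 7
#' subdivision and a maximal SUV of 20.
#'
#' @param tac_suv a [tac()], normally in SUV units.
#' @param max_suv normalisation ceiling for the SUV axis (default 20).
#' @param max_grid finest grid level (default 7).
#' @return object of class `fd_result`: list with `fd`, `box_counts`
#'   (data.frame `g`, `boxes`), `regression_r2`.
#' @examples
#' sched <- default_schedule()
#' ramp <- tac(sched, seq(0, 20, length.out = 28), units = "SUV")
#' fractal_dimension(ramp)$fd  # ~1 for a straight ramp
#' @export
fractal_dimension <- function(tac_suv, max_suv = 20, max_grid = 7) {
  stopifnot(inherits(tac_suv, "tac"))
  assert_scalar_num(max_suv, "max_suv", lower = 0, strict_lower = TRUE)
  max_grid <- as.integer(max_grid)
  if (max_grid < 1L)
    stop_petkin("max_grid must be >= 1", "petkin_invalid_input")

  s <- tac_suv$schedule
  n <- nrow(s)
  span0 <- s$frame_start_s[1]
  span1 <- s$frame_start_s[n] + s$frame_duration_s[n]
  if (span1 - span0 <= 0 && n > 1L)
    stop_petkin("degenerate schedule: zero time span", "petkin_invalid_input")
  if (n == 1L) {
    pts <- data.frame(x = 0.5, y = min(max(tac_suv$values / max_suv, 0), 1))
  } else {
    pts <- data.frame(
      x = (frame_mid_s(s) - span0) / (span1 - span0),
      y = pmin(pmax(tac_suv$values, 0), max_suv) / max_suv
    )
  }
  gs <- seq_len(max_grid)
  boxes <- vapply(gs, function(g) box_count(pts, g), numeric(1))
  lg <- log(gs); lb <- log(boxes)
  if (stats::var(lg) == 0 || stats::var(lb) == 0) {
    slope <- 0
    r2 <- if (stats::var(lb) == 0) 1 else 0
  } else {
    fitl <- stats::lm(lb ~ lg)
    slope <- unname(stats::coef(fitl)[2])
    r2 <- 1 - sum(stats::residuals(fitl)^2) / sum((lb - mean(lb))^2)
  }
  structure(list(fd = min(max(slope, 0), 2),
                 box_counts = data.frame(g = gs, boxes = boxes),
                 regression_r2 = r2),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fractal dimension> fd = %.4f (r2 = %.3f)\n",
              x$fd, x$regression_r2))
  invisible(x)
}
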