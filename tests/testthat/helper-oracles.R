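# Independent numerical oracles used by the tests. These deliberately
# avoid the package's analytic code paths: the compartment system is
# integrated by classical RK4, frame means by trapezoidal quadrature on
# the integration grid, and box counts by brute-force rasterisation at a
# fixed fine step.

# Impulse response oracle: homogeneous two-compartment system started at
# (K1, 0); h(t) = C1(t) + C2(t). Vectorised across parameter sets (each a
# list with K1..k4). Returns a matrix [set, time].
ode_irf <- function(params_list, t_out, h = 0.002) {
  n <- length(params_list)
  K1 <- vapply(params_list, `[[`, 0, "K1")
  k2 <- vapply(params_list, `[[`, 0, "k2")
  k3 <- vapply(params_list, `[[`, 0, "k3")
  k4 <- vapply(params_list, `[[`, 0, "k4")
  C1 <- K1; C2 <- numeric(n)
  t_end <- max(t_out)
  nstep <- ceiling(t_end / h); h <- t_end / nstep
  out <- matrix(NA_real_, n, length(t_out))
  out[, t_out == 0] <- K1
  targets <- round(t_out / h)
  d1 <- function(C1, C2) -(k2 + k3) * C1 + k4 * C2
  d2 <- function(C1, C2) k3 * C1 - k4 * C2
  for (s in seq_len(nstep)) {
    a1 <- d1(C1, C2); a2 <- d2(C1, C2)
    b1 <- d1(C1 + h / 2 * a1, C2 + h / 2 * a2)
    b2 <- d2(C1 + h / 2 * a1, C2 + h / 2 * a2)
    c1 <- d1(C1 + h / 2 * b1, C2 + h / 2 * b2)
    c2 <- d2(C1 + h / 2 * b1, C2 + h / 2 * b2)
    e1 <- d1(C1 + h * c1, C2 + h * c2)
    e2 <- d2(C1 + h * c1, C2 + h * c2)
    C1 <- C1 + h / 6 * (a1 + 2 * b1 + 2 * c1 + e1)
    C2 <- C2 + h / 6 * (a2 + 2 * b2 + 2 * c2 + e2)
    hit <- which(targets == s)
    if (length(hit)) out[, hit] <- C1 + C2
  }
  out
}

# Driven-system oracle: C_PET frame means for one input model and many
# parameter sets. RK4 on a grid that subdivides every frame; frame means
# accumulated by trapezoid on the same grid. Returns [set, frame].
ode_tac_frame_means <- function(params_list, input_model, schedule,
                                h = 5e-4) {
  n <- length(params_list)
  K1 <- vapply(params_list, `[[`, 0, "K1")
  k2 <- vapply(params_list, `[[`, 0, "k2")
  k3 <- vapply(params_list, `[[`, 0, "k3")
  k4 <- vapply(params_list, `[[`, 0, "k4")
  VB <- vapply(params_list, `[[`, 0, "VB")
  cp <- function(t) evaluate_input(input_model, t)
  a <- schedule$frame_start_s / 60
  b <- (schedule$frame_start_s + schedule$frame_duration_s) / 60
  nf <- length(a)
  out <- matrix(0, n, nf)
  C1 <- numeric(n); C2 <- numeric(n)
  t <- 0
  d1 <- function(C1, C2, cpv) K1 * cpv - (k2 + k3) * C1 + k4 * C2
  d2 <- function(C1, C2) k3 * C1 - k4 * C2
  cpet <- function(C1, C2, cpv) (1 - VB) * (C1 + C2) + VB * cpv
  frame_of <- function(t) which(t >= a - 1e-12 & t <= b + 1e-12)
  prev_val <- cpet(C1, C2, cp(0))
  for (f in seq_len(nf)) {
    # integrate from frame start to frame end (assumes contiguous frames)
    nstep <- ceiling((b[f] - a[f]) / h)
    hh <- (b[f] - a[f]) / nstep
    acc <- numeric(n)
    for (s in seq_len(nstep)) {
      tcur <- a[f] + (s - 1) * hh
      cpv0 <- cp(tcur); cpv1 <- cp(tcur + hh / 2); cpv2 <- cp(tcur + hh)
      a1 <- d1(C1, C2, cpv0); a2 <- d2(C1, C2)
      b1 <- d1(C1 + hh / 2 * a1, C2 + hh / 2 * a2, cpv1)
      b2 <- d2(C1 + hh / 2 * a1, C2 + hh / 2 * a2)
      c1 <- d1(C1 + hh / 2 * b1, C2 + hh / 2 * b2, cpv1)
      c2 <- d2(C1 + hh / 2 * b1, C2 + hh / 2 * b2)
      e1 <- d1(C1 + hh * c1, C2 + hh * c2, cpv2)
      e2 <- d2(C1 + hh * c1, C2 + hh * c2)
      C1 <- C1 + hh / 6 * (a1 + 2 * b1 + 2 * c1 + e1)
      C2 <- C2 + hh / 6 * (a2 + 2 * b2 + 2 * c2 + e2)
      val <- cpet(C1, C2, cpv2)
      acc <- acc + hh * (prev_val + val) / 2
      prev_val <- val
    }
    out[, f] <- acc / (b[f] - a[f])
  }
  out
}

# Brute-force box count: rasterise every segment at a fixed fine step
# independent of g. Upper bound / cross-check for box_count().
brute_box_count <- function(points, g, step = 2e-4) {
  x <- pmin(pmax(points$x, 0), 1)
  y <- pmin(pmax(points$y, 0), 1)
  xs <- list(); ys <- list()
  n <- length(x)
  if (n == 1L) { xs <- list(x); ys <- list(y) }
  for (i in seq_len(n - 1L)) {
    len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    m <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = m + 1L)
    xs[[i]] <- x[i] + tt * (x[i + 1] - x[i])
    ys[[i]] <- y[i] + tt * (y[i + 1] - y[i])
  }
  xx <- unlist(xs); yy <- unlist(ys)
  ix <- pmin(floor(xx * g), g - 1L)
  iy <- pmin(floor(yy * g), g - 1L)
  length(unique(ix * g + iy))
}

# Random valid kinetic parameter sets within the published min-max ranges
# (plus VB), optionally including hand-picked near-degenerate sets.
random_params <- function(n, seed = 42L, include_degenerate = FALSE) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    list(K1 = runif(1, 0.23, 0.49), k2 = runif(1, 0.27, 0.62),
         k3 = runif(1, 0.058, 0.2), k4 = runif(1, 0.038, 0.175),
         VB = runif(1, 0.046, 0.165))
  })
  if (include_degenerate) {
    out <- c(out, list(
      list(K1 = 0.3, k2 = 0.25, k3 = 1e-9, k4 = 0.25, VB = 0.08),
      list(K1 = 0.3, k2 = 0.25, k3 = 0, k4 = 0.25, VB = 0.08),
      list(K1 = 0.3, k2 = 0.3, k3 = 1e-7, k4 = 0.3, VB = 0.08)
    ))
  }
  out
}

as_kp <- function(p) structure(p, class = "kinetic_params")

# Small synthetic parameter table for the statistics tests: two groups
# drawn from (optionally different) log-normal distributions.
random_param_table <- function(n_b = 5, n_r = 4,
                               center_b = NULL, center_r = NULL,
                               cv = 0.25) {
  base <- c(VB = 0.08, K1 = 0.3, k2 = 0.5, k3 = 0.12, k4 = 0.08,
            RBP = 0.06, SUV = 1.1, FD = 1.05)
  cb <- if (is.null(center_b)) base else center_b
  cr <- if (is.null(center_r)) base else center_r
  draw <- function(center, n, g) {
    cols <- lapply(names(base), function(p)
      stats::rlnorm(n, log(center[[p]]), sqrt(log(1 + cv^2))))
    names(cols) <- names(base)
    data.frame(group = g, cols)
  }
  rbind(draw(cb, n_b, "B"), draw(cr, n_r, "R"))
}
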