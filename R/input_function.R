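#' Exponential model of the image-derived blood input function
#'
#' The arterial/whole-blood activity concentration driving the tissue model
#' is represented as a delayed sum of 1--3 decaying exponentials,
#' `Cp(t) = sum_i A_i exp(-lambda_i (t - t0))` for `t >= t0` and 0 before.
#' This mirrors the preprocessing used for heart-VOI input curves in
#' dynamic small-animal studies.
#'
#' @param amplitudes numeric vector (1--3), term amplitudes `A_i` >= 0, in
#'   activity-concentration units.
#' @param rates numeric vector, decay rates `lambda_i` >= 0 in 1/min.
#' @param delay_t0 onset delay in minutes (default 0).
#' @return Object of class `if_model`.
#' @examples
#' m <- input_function_model(c(10, 1), c(2, 0.05))
#' evaluate_input(m, c(0, 1, 10))
#' @export
input_function_model <- function(amplitudes, rates, delay_t0 = 0) {
  if (length(amplitudes) != length(rates))
    stop_petkin("amplitudes and rates must have equal length",
                "petkin_invalid_input")
  if (length(amplitudes) < 1L || length(amplitudes) > 3L)
    stop_petkin("between 1 and 3 exponential terms are supported",
                "petkin_invalid_input")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop_petkin("amplitudes must be finite and >= 0", "petkin_invalid_input")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_petkin("decay rates must be finite and >= 0", "petkin_invalid_input")
  assert_scalar_num(delay_t0, "delay_t0", lower = 0)
  structure(list(amplitudes = as.numeric(amplitudes),
                 rates = as.numeric(rates),
                 delay_t0 = as.numeric(delay_t0)),
            class = "if_model")
}

#' Evaluate a blood input model at arbitrary times
#'
#' @param model an [input_function_model()] (or the fit object returned by
#'   [fit_input_exponentials()], which interpolates the measured pre-peak
#'   frames before the fitted window).
#' @param t_min times in minutes; may be a vector.
#' @return activity-concentration values, 0 before the model onset.
#' @export
evaluate_input <- function(model, t_min) {
  UseMethod("evaluate_input")
}

#' @export
evaluate_input.if_model <- function(model, t_min) {
  s <- t_min - model$delay_t0
  out <- numeric(length(s))
  on <- s >= 0
  if (any(on)) {
    acc <- 0
    for (k in seq_along(model$amplitudes))
      acc <- acc + model$amplitudes[k] * exp(-model$rates[k] * s[on])
    out[on] <- acc
  }
  out
}

#' @export
evaluate_input.if_fit <- function(model, t_min) {
  out <- NextMethod()  # exponential part (t0 = fit-window start)
  pre <- t_min < model$fit_start_min
  if (any(pre) && nrow(model$prepeak) > 0) {
    # linear interpolation through the measured pre-peak frame means,
    # anchored at the model value at the window start
    xs <- c(model$prepeak$t_min, model$fit_start_min)
    ys <- c(model$prepeak$value,
            sum(model$amplitudes))
    out[pre] <- stats::approx(xs, ys, xout = t_min[pre], rule = 2)$y
  }
  out
}

#' @export
print.if_model <- function(x, ...) {
  cat(sprintf("<input function> %d exponential term(s), t0 = %.3g min\n",
              length(x$amplitudes), x$delay_t0))
  for (k in seq_along(x$amplitudes))
    cat(sprintf("  A = %.6g, lambda = %.6g /min\n",
                x$amplitudes[k], x$rates[k]))
  invisible(x)
}

# Frame-averaged model prediction: mean of Cp over each frame, with frames
# given by their [start, end] in minutes relative to the model onset.
if_frame_means <- function(amplitudes, rates, t0_min, start_min, end_min) {
  u1 <- pmax(start_min - t0_min, 0)
  u2 <- end_min - t0_min
  acc <- numeric(length(u1))
  for (k in seq_along(amplitudes))
    acc <- acc + amplitudes[k] * int_exp0(rates[k], u1, u2)
  acc / (end_min - start_min)
}

#' Fit a sum of decaying exponentials to a blood curve
#'
#' Post-peak frames of the measured blood TAC are fitted by weighted
#' nonlinear least squares with a frame-averaged model (the model
#' prediction for a frame is the mean of `Cp(t)` over the frame, matching
#' what a reconstructed frame reports). The number of terms (1 to
#' `max_terms`) is chosen by small-sample AIC (AICc); an extra term is kept
#' only when it strictly lowers AICc. Frames before the peak are retained:
#' when the returned model is evaluated there it linearly interpolates the
#' measured pre-peak values.
#'
#' Rates are constrained to be >= 0; if the unconstrained optimum would
#' need a growing exponential the rate is clamped at 0 and a warning is
#' issued.
#'
#' @param blood_tac a [tac()] with the heart/blood curve.
#' @param max_terms maximum number of exponential terms, 1--3.
#' @return An object of classes `if_fit` and `if_model` with extra fields
#'   `fit_start_min`, `prepeak` (measured pre-peak frame means),
#'   `aicc_table` and `wrss`.
#' @export
fit_input_exponentials <- function(blood_tac, max_terms = 3) {
  stopifnot(inherits(blood_tac, "tac"))
  max_terms <- as.integer(max_terms)
  if (max_terms < 1L || max_terms > 3L)
    stop_petkin("max_terms must be 1, 2 or 3", "petkin_invalid_input")

  sched <- blood_tac$schedule
  y <- blood_tac$values
  peak <- which.max(y)
  idx <- peak:length(y)
  n <- length(idx)
  if (n < 3L)
    stop_petkin("need at least 3 frames from the peak onward",
                "petkin_if_too_few_frames")
  m_allow <- min(max_terms, (n - 1L) %/% 2L)
  if (m_allow < 1L)
    stop_petkin("too few post-peak frames for even one exponential term",
                "petkin_if_too_few_frames")

  t0 <- sched$frame_start_s[peak] / 60
  a_min <- sched$frame_start_s[idx] / 60
  b_min <- (sched$frame_start_s[idx] + sched$frame_duration_s[idx]) / 60
  yy <- y[idx]
  w <- sched$frame_duration_s[idx] / sum(sched$frame_duration_s[idx])
  scale <- max(yy, 1e-12)

  fits <- vector("list", m_allow)
  aicc <- rep(NA_real_, m_allow)
  wrss_floor <- 1e-12 * sum(w * yy^2) + 1e-300
  for (m in seq_len(m_allow)) {
    fits[[m]] <- if_fit_varpro(yy, w, a_min, b_min, t0, m, scale)
    p <- 2 * m
    wrss <- max(fits[[m]]$wrss, wrss_floor)
    pen <- if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
    aicc[m] <- n * log(wrss / n) + 2 * p + pen
  }
  best_m <- 1L
  for (m in seq_len(m_allow)[-1L])
    if (is.finite(aicc[m]) && aicc[m] < aicc[best_m] - 1e-9) best_m <- m

  amps <- fits[[best_m]]$amplitudes
  lams <- fits[[best_m]]$rates
  if (any(lams < 1e-12) && best_m == m_allow && any(diff(yy) > 0) &&
      stats::cor(seq_along(yy), yy) > 0.5)
    warning("blood curve does not decay after its peak; rate(s) clamped at 0")
  ord <- order(lams, decreasing = TRUE)
  amps <- amps[ord]; lams <- lams[ord]

  keep <- amps > 0
  if (!any(keep)) keep <- which.max(amps)
  amps <- amps[keep]; lams <- lams[keep]

  prepeak <- data.frame(
    t_min = frame_mid_s(sched)[seq_len(peak - 1L)] / 60,
    value = y[seq_len(peak - 1L)]
  )
  out <- input_function_model(amps, lams, delay_t0 = t0)
  out$fit_start_min <- t0
  out$prepeak <- prepeak
  out$wrss <- fits[[best_m]]$wrss
  out$aicc_table <- data.frame(n_terms = seq_len(m_allow), aicc = aicc)
  class(out) <- c("if_fit", class(out))
  out
}

# Variable-projection fit of m exponential terms to post-peak frame means:
# for fixed rates the amplitudes solve a nonnegative weighted linear
# least-squares problem (simple active-set: drop the most negative
# coefficient and re-solve), so the nonlinear search runs only over the m
# rates. Multi-start over geometric rate ladders anchored at the tail
# slope, polished with bounded L-BFGS-B (rates >= 0 so the fitted curve
# never grows).
if_fit_varpro <- function(y, w, a_min, b_min, t0, m, scale) {
  u1 <- a_min - t0
  u2 <- b_min - t0
  dur <- b_min - a_min
  sw <- sqrt(w)

  design <- function(lams) {
    vapply(lams, function(l) int_exp0(l, u1, u2) / dur, numeric(length(u1)))
  }
  solve_amps <- function(M) {
    active <- seq_len(ncol(M))
    amps <- numeric(ncol(M))
    repeat {
      fitc <- tryCatch(
        stats::lm.fit(sw * M[, active, drop = FALSE], sw * y)$coefficients,
        error = function(e) NULL)
      if (is.null(fitc)) return(NULL)
      fitc[is.na(fitc)] <- 0
      if (all(fitc >= 0) || length(active) == 1L) {
        amps[active] <- pmax(fitc, 0)
        return(amps)
      }
      active <- active[-which.min(fitc)]
    }
  }
  obj <- function(lams) {
    M <- design(lams)
    amps <- solve_amps(M)
    if (is.null(amps)) return(Inf)
    sum(w * (drop(M %*% amps) - y)^2)
  }

  # tail-slope anchor for the slowest rate
  ntail <- max(3L, ceiling(length(y) / 3))
  seg <- seq(length(y) - ntail + 1L, length(y))
  tm <- (u1 + u2) / 2
  ypos <- pmax(y[seg], scale * 1e-9)
  lam_tail <- max(-stats::coef(stats::lm(log(ypos) ~ tm[seg]))[[2]], 1e-3)
  lam_tail <- min(lam_tail, 20)

  ladder <- function(base, ratio) base * ratio^(seq_len(m) - 1L)
  starts <- list(ladder(lam_tail, 12), ladder(lam_tail, 25),
                 ladder(lam_tail / 2, 12), ladder(lam_tail * 2, 12),
                 ladder(0.02, 15), ladder(0.05, 10))
  starts <- lapply(starts, function(s) rev(pmin(s, 45)))

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = rep(0, m), upper = rep(50, m),
                   control = list(maxit = 400, factr = 1e2,
                                  ndeps = pmax(1e-6, s * 1e-4))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop_petkin("input-function fit failed for all starts", "petkin_fit_failure")
  lams <- best$par
  amps <- solve_amps(design(lams))
  list(amplitudes = amps, rates = lams, wrss = best$value)
}
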