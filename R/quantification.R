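#' Standardized uptake value
#'
#' `SUV = tissue concentration (Bq/g) / (injected dose (Bq) / body weight (g))`,
#' i.e. `concentration * weight / dose`. Unitless under the convention that
#' 1 mL of tissue weighs 1 g.
#'
#' @param concentration activity concentration in Bq/g (vectorised).
#' @param dose injected dose in Bq, > 0.
#' @param weight body weight in g, > 0.
#' @return SUV value(s).
#' @examples
#' suv(1000, 3e7, 300)  # 0.01
#' @export
suv <- function(concentration, dose, weight) {
  assert_scalar_num(dose, "dose", lower = 0, strict_lower = TRUE)
  assert_scalar_num(weight, "weight", lower = 0, strict_lower = TRUE)
  if (any(concentration < 0))
    stop_petkin("concentration must be >= 0", "petkin_invalid_input")
  concentration * weight / dose
}

#' Convert an activity TAC to SUV units
#'
#' @param x a [tac()] in Bq/g.
#' @inheritParams suv
#' @return a [tac()] with `units = "SUV"`.
#' @export
suv_curve <- function(x, dose, weight) {
  stopifnot(inherits(x, "tac"))
  tac(x$schedule, suv(x$values, dose, weight), units = "SUV")
}

#' Late (55--60 min) SUV
#'
#' The standard late-uptake reading: the duration-weighted mean of all
#' frames fully inside the `[3300, 3600]` s window. On the default 28-frame
#' schedule that is exactly the final 300 s frame.
#'
#' @param suv_tac a [tac()] (usually in SUV units) whose schedule covers
#'   `[3300, 3600]` s.
#' @param window start/end of the late window in seconds.
#' @return scalar late SUV.
#' @export
late_suv <- function(suv_tac, window = c(3300, 3600)) {
  stopifnot(inherits(suv_tac, "tac"))
  s <- suv_tac$schedule
  ends <- s$frame_start_s + s$frame_duration_s
  inside <- s$frame_start_s >= window[1] - 1e-9 & ends <= window[2] + 1e-9
  if (!any(inside) || max(ends) < window[2] - 1e-9)
    stop_petkin(sprintf("schedule does not cover the %g-%g s window",
                        window[1], window[2]),
                "petkin_window_uncovered")
  sum(suv_tac$values[inside] * s$frame_duration_s[inside]) /
    sum(s$frame_duration_s[inside])
}

#' Recovery-coefficient model for partial-volume correction
#'
#' Small objects recover only a fraction of their true activity because of
#' finite scanner resolution. The model is a set of phantom-measured
#' anchors (diameter, recovery coefficient); coefficients between anchors
#' are linearly interpolated, outside them linearly extrapolated, floored
#' at 0.01 and capped at 1. The default anchors are RC = 0.32 at 3 mm and
#' RC = 0.85 at 8 mm.
#'
#' @param anchors data.frame with columns `diameter_mm` (> 0) and
#'   `recovery` (in (0, 1]), coefficients nondecreasing with diameter.
#' @return object of class `recovery_model`.
#' @examples
#' rc <- recovery_model()
#' recovery_coefficient(rc, 8)    # 0.85
#' recovery_coefficient(rc, 5.5)  # 0.585
#' @export
recovery_model <- function(anchors = data.frame(diameter_mm = c(3, 8),
                                                recovery = c(0.32, 0.85))) {
  if (!all(c("diameter_mm", "recovery") %in% names(anchors)) ||
      nrow(anchors) < 1L)
    stop_petkin("anchors must have >= 1 row with diameter_mm and recovery",
                "petkin_invalid_input")
  if (any(anchors$diameter_mm <= 0))
    stop_petkin("anchor diameters must be > 0", "petkin_invalid_input")
  if (any(anchors$recovery <= 0 | anchors$recovery > 1))
    stop_petkin("recovery coefficients must be in (0, 1]", "petkin_invalid_input")
  anchors <- anchors[order(anchors$diameter_mm), , drop = FALSE]
  if (is.unsorted(anchors$recovery))
    stop_petkin("recovery must be nondecreasing with diameter",
                "petkin_invalid_input")
  structure(list(anchors = anchors), class = "recovery_model")
}

#' @rdname recovery_model
#' @param model a `recovery_model`.
#' @param diameter_mm object diameter in mm, > 0.
#' @export
recovery_coefficient <- function(model, diameter_mm) {
  stopifnot(inherits(model, "recovery_model"))
  assert_scalar_num(diameter_mm, "diameter_mm", lower = 0, strict_lower = TRUE)
  a <- model$anchors
  if (nrow(a) == 1L) return(min(max(a$recovery, 0.01), 1))
  rc <- stats::approx(a$diameter_mm, a$recovery, xout = diameter_mm,
                      rule = 1)$y
  if (is.na(rc)) {
    # linear extrapolation from the nearest pair of anchors
    if (diameter_mm < a$diameter_mm[1]) i <- 1:2 else i <- (nrow(a) - 1):nrow(a)
    slope <- diff(a$recovery[i]) / diff(a$diameter_mm[i])
    rc <- a$recovery[i[1]] + slope * (diameter_mm - a$diameter_mm[i[1]])
  }
  min(max(rc, 0.01), 1)
}

#' Partial-volume correction of a measured value
#'
#' Divides a VOI-mean value by the recovery coefficient for the object
#' diameter, restoring the activity lost to spill-out. A warning is
#' attached when the coefficient sits at its 0.01 floor (extreme, likely
#' unphysical extrapolation).
#'
#' @param value measured value(s), >= 0 (activity concentration or SUV).
#' @inheritParams recovery_coefficient
#' @return corrected value(s).
#' @examples
#' pvc_correct(1, recovery_model(), 8)  # 1 / 0.85
#' @export
pvc_correct <- function(value, model, diameter_mm) {
  if (any(value < 0))
    stop_petkin("value must be >= 0", "petkin_invalid_input")
  rc <- recovery_coefficient(model, diameter_mm)
  if (rc <= 0.01 + 1e-12)
    warning("recovery coefficient at its 0.01 floor; correction is extreme")
  value / rc
}

#' @rdname pvc_correct
#' @param x a [tac()] to correct frame-wise.
#' @export
pvc_correct_tac <- function(x, model, diameter_mm) {
  stopifnot(inherits(x, "tac"))
  tac(x$schedule, pvc_correct(x$values, model, diameter_mm), units = x$units)
}
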