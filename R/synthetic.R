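# Seeded synthetic cohorts emulating a two-tracer small-animal study:
# group B (bombesin analog, n = 5) and group R (RGD tetramer, n = 4),
# blood input curves shaped as three decaying exponentials, tumor TACs
# simulated from the two-tissue model around the published group medians.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(code)
}

#' Default blood input template (SUV units)
#'
#' Three decaying exponentials emulating an image-derived heart curve of a
#' ⁶⁸Ga-labelled peptide in the rat: a fast distribution term
#' (6 /min), an intermediate clearance term (0.4 /min) and a slow terminal
#' term (0.02 /min), with relative amplitudes 12 : 2.5 : 0.9. Amplitudes
#' are in SUV units and are converted to Bq/g by dose/weight when activity
#' curves are generated. `scale` multiplies all amplitudes; the per-group
#' defaults (2.394891 for B, 1.454849 for R) were calibrated once so that
#' a tumor curve simulated from each group's median kinetic parameters
#' lands exactly on that group's published median late SUV (1.1865 and
#' 0.9886) -- the two tracers clear from blood differently, which is what
#' a group-specific input scale emulates.
#'
#' @param scale overall amplitude multiplier (default 1).
#' @return an [input_function_model()].
#' @export
default_input_spec <- function(scale = 1) {
  input_function_model(amplitudes = c(12, 2.5, 0.9) * scale,
                       rates = c(6, 0.4, 0.02),
                       delay_t0 = 0)
}

.petkin_input_scale <- c(B = 2.394891, R = 1.454849)

#' Specification of one synthetic tracer group
#'
#' @param group_label `"B"` or `"R"`.
#' @param n_animals number of animals, >= 1.
#' @param param_center [kinetic_params()] giving the group median of each
#'   kinetic parameter (sampling is median-preserving log-normal).
#' @param param_spread named numeric vector of relative SDs
#'   (coefficients of variation) for `K1, k2, k3, k4, VB`.
#' @param input_spec an [input_function_model()] in SUV units.
#' @param noise_level proportional noise fraction at the 30 s reference
#'   frame duration (default 0.05); frame SD is
#'   `noise_level * value * sqrt(30 / duration_s)`.
#' @param dose_range injected-dose range in Bq (uniform sampling).
#' @param weight_range body-weight range in g (uniform sampling).
#' @param seed integer seed making the group reproducible.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label, n_animals, param_center, param_spread,
                        input_spec = default_input_spec(),
                        noise_level = 0.05,
                        dose_range = c(20e6, 40e6),
                        weight_range = c(250, 350),
                        seed = 1L) {
  if (!group_label %in% c("B", "R"))
    stop_petkin("group_label must be 'B' or 'R'", "petkin_invalid_input")
  if (n_animals < 1L)
    stop_petkin("n_animals must be >= 1", "petkin_invalid_input")
  assert_scalar_num(noise_level, "noise_level", lower = 0)
  if (!params_accepted(param_center))
    stop_petkin("param_center must satisfy the acceptance constraints",
                "petkin_invalid_input")
  need <- c("K1", "k2", "k3", "k4", "VB")
  if (!all(need %in% names(param_spread)))
    stop_petkin("param_spread needs entries K1, k2, k3, k4, VB",
                "petkin_invalid_input")
  structure(list(group_label = group_label,
                 n_animals = as.integer(n_animals),
                 param_center = param_center,
                 param_spread = param_spread[need],
                 input_spec = input_spec,
                 noise_level = noise_level,
                 dose_range = dose_range,
                 weight_range = weight_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default group specifications
#'
#' Group centers are the published per-group medians and the relative SDs
#' are the published SD/mean ratios of the two tracer groups (bombesin
#' analog B, n = 5; RGD tetramer R, n = 4). Injected-dose ranges follow
#' the study protocol: 20--40 MBq for B, 10--30 MBq for R.
#'
#' @param seed integer seed (group R uses `seed + 1`).
#' @param noise_level proportional noise fraction (default 0.05).
#' @return a [cohort_spec()].
#' @export
default_spec_b <- function(seed = 1L, noise_level = 0.05) {
  cohort_spec(
    "B", 5L,
    kinetic_params(K1 = 0.3506, k2 = 0.5216, k3 = 0.1177, k4 = 0.1005,
                   VB = 0.0903),
    c(K1 = 0.0718 / 0.3717, k2 = 0.1312 / 0.4808, k3 = 0.0534 / 0.1235,
      k4 = 0.0524 / 0.0986, VB = 0.0443 / 0.1037),
    input_spec = default_input_spec(scale = .petkin_input_scale[["B"]]),
    noise_level = noise_level,
    dose_range = c(20e6, 40e6),
    seed = seed
  )
}

#' @rdname default_spec_b
#' @export
default_spec_r <- function(seed = 1L, noise_level = 0.05) {
  cohort_spec(
    "R", 4L,
    kinetic_params(K1 = 0.2728, k2 = 0.5721, k3 = 0.1180, k4 = 0.0442,
                   VB = 0.0574),
    c(K1 = 0.0479 / 0.2739, k2 = 0.0985 / 0.5386, k3 = 0.0298 / 0.1097,
      k4 = 0.0052 / 0.0443, VB = 0.0102 / 0.0582),
    input_spec = default_input_spec(scale = .petkin_input_scale[["R"]]),
    noise_level = noise_level,
    dose_range = c(10e6, 30e6),
    seed = seed + 1L
  )
}

# Zero-mean proportional Gaussian noise, SD scaled by sqrt(30 s / frame
# duration) so that longer frames are less noisy; clipped at 0.
add_frame_noise <- function(values, durations_s, noise_level) {
  if (noise_level == 0) return(values)
  sd <- noise_level * values * sqrt(30 / durations_s)
  pmax(values + stats::rnorm(length(values), 0, sd), 0)
}

#' Generate a noisy frame-averaged blood input curve
#'
#' Frame values are the analytic frame means of the continuous model
#' `Cp(t)` with zero-mean proportional Gaussian noise added
#' (`SD = noise_level * value * sqrt(30 s / duration)`), clipped at 0.
#'
#' @param input_spec an [input_function_model()].
#' @param schedule a [frame_schedule()].
#' @param noise_level proportional noise fraction, >= 0.
#' @param seed integer seed.
#' @return a [tac()] in the units of the model amplitudes.
#' @export
generate_input_curve <- function(input_spec, schedule, noise_level = 0.05,
                                 seed = 1L) {
  stopifnot(inherits(schedule, "frame_schedule"))
  assert_scalar_num(noise_level, "noise_level", lower = 0)
  a <- schedule$frame_start_s / 60
  b <- (schedule$frame_start_s + schedule$frame_duration_s) / 60
  mu <- if_frame_means(input_spec$amplitudes, input_spec$rates,
                       input_spec$delay_t0, a, b)
  vals <- local_seed(seed,
                     add_frame_noise(mu, schedule$frame_duration_s, noise_level))
  tac(schedule, vals)
}

#' Apply or undo physical decay of Gallium-68
#'
#' Reconstructed PET activities are normally decay-corrected to injection
#' time; these helpers apply (or undo) the physical decay factor
#' `exp(-ln(2) t / T_half)` at the frame midpoints, for testing the
#' correction path. The ⁶⁸Ga half-life is 67.71 min.
#'
#' @param x a [tac()].
#' @param half_life_min isotope half-life in minutes.
#' @return a [tac()].
#' @export
apply_physical_decay <- function(x, half_life_min = 67.71) {
  stopifnot(inherits(x, "tac"))
  f <- exp(-log(2) * frame_mid_s(x$schedule) / 60 / half_life_min)
  tac(x$schedule, x$values * f, units = x$units)
}

#' @rdname apply_physical_decay
#' @export
decay_correct <- function(x, half_life_min = 67.71) {
  stopifnot(inherits(x, "tac"))
  f <- exp(-log(2) * frame_mid_s(x$schedule) / 60 / half_life_min)
  tac(x$schedule, x$values / f, units = x$units)
}

draw_params <- function(center, spread, max_resample = 100L) {
  nm <- c("K1", "k2", "k3", "k4", "VB")
  for (i in seq_len(max_resample)) {
    vals <- vapply(nm, function(p) {
      cv <- spread[[p]]
      if (cv <= 0) return(center[[p]])
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(1, meanlog = log(center[[p]]), sdlog = sdlog)
    }, numeric(1))
    p <- structure(as.list(vals), class = "kinetic_params")
    if (params_accepted(p)) return(p)
  }
  stop_petkin(sprintf("no admissible parameter draw in %d resamples",
                      max_resample),
              "petkin_resample_exhausted")
}

#' One synthetic (or real) animal record
#'
#' @param animal_id identifier string.
#' @param group `"B"` or `"R"`.
#' @param injected_dose_bq injected dose in Bq, > 0.
#' @param body_weight_g body weight in g, > 0.
#' @param blood_tac,tumor_tac [tac()] objects on a shared schedule.
#' @param true_params generating [kinetic_params()], or NULL for real data.
#' @return list of class `study_record`.
#' @export
study_record <- function(animal_id, group, injected_dose_bq, body_weight_g,
                         blood_tac, tumor_tac, true_params = NULL) {
  assert_scalar_num(injected_dose_bq, "injected_dose_bq", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(body_weight_g, "body_weight_g", lower = 0,
                    strict_lower = TRUE)
  stopifnot(inherits(blood_tac, "tac"), inherits(tumor_tac, "tac"))
  if (!same_schedule(blood_tac$schedule, tumor_tac$schedule))
    stop_petkin("blood and tumor TACs must share one schedule",
                "petkin_invalid_input")
  structure(list(animal_id = as.character(animal_id), group = group,
                 injected_dose_bq = injected_dose_bq,
                 body_weight_g = body_weight_g,
                 blood_tac = blood_tac, tumor_tac = tumor_tac,
                 true_params = true_params),
            class = "study_record")
}

#' Generate a two-group synthetic cohort
#'
#' For each animal: kinetic parameters are drawn median-preserving
#' log-normally around the group center (resampling, at most 100 times,
#' until the acceptance constraints hold), dose and weight uniformly
#' within their ranges, the blood curve is the frame-averaged input model
#' scaled from SUV to Bq/g by dose/weight, and the tumor curve is the
#' two-tissue model forward simulation driven by the continuous input.
#' Proportional frame noise is added to both curves. When `pv_effect` is
#' TRUE (default) the observed curves are multiplied by the recovery
#' coefficients of the configured object diameters, emulating
#' partial-volume loss so that the pipeline's correction step is exercised
#' end to end.
#'
#' @param spec_b,spec_r [cohort_spec()] objects for the two groups.
#' @param schedule a [frame_schedule()] (default [default_schedule()]).
#' @param pv_effect simulate partial-volume loss (default TRUE).
#' @param recovery a [recovery_model()].
#' @param tumor_diameter_mm,input_diameter_mm object diameters used for
#'   the partial-volume effect (defaults 8 and 10 mm).
#' @return list of [study_record()]s (class `cohort`), group B first.
#' @export
generate_cohort <- function(spec_b, spec_r, schedule = default_schedule(),
                            pv_effect = TRUE,
                            recovery = recovery_model(),
                            tumor_diameter_mm = 8,
                            input_diameter_mm = 10) {
  stopifnot(inherits(spec_b, "cohort_spec"), inherits(spec_r, "cohort_spec"))
  rc_t <- if (pv_effect) recovery_coefficient(recovery, tumor_diameter_mm) else 1
  rc_i <- if (pv_effect) recovery_coefficient(recovery, input_diameter_mm) else 1

  gen_group <- function(spec) {
    local_seed(spec$seed, {
      lapply(seq_len(spec$n_animals), function(i) {
        p <- draw_params(spec$param_center, spec$param_spread)
        dose <- stats::runif(1, spec$dose_range[1], spec$dose_range[2])
        wt <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
        sf <- dose / wt  # SUV -> Bq/g
        input_bq <- input_function_model(spec$input_spec$amplitudes * sf,
                                         spec$input_spec$rates,
                                         spec$input_spec$delay_t0)
        a <- schedule$frame_start_s / 60
        b <- (schedule$frame_start_s + schedule$frame_duration_s) / 60
        blood_mu <- if_frame_means(input_bq$amplitudes, input_bq$rates,
                                   input_bq$delay_t0, a, b)
        tumor_mu <- simulate_tac(p, input_bq, schedule)$values
        blood <- add_frame_noise(blood_mu * rc_i, schedule$frame_duration_s,
                                 spec$noise_level)
        tumor <- add_frame_noise(tumor_mu * rc_t, schedule$frame_duration_s,
                                 spec$noise_level)
        study_record(sprintf("%s%02d", spec$group_label, i),
                     spec$group_label, dose, wt,
                     tac(schedule, blood), tac(schedule, tumor),
                     true_params = p)
      })
    })
  }
  structure(c(gen_group(spec_b), gen_group(spec_r)), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  gl <- vapply(x, function(r) r$group, character(1))
  cat(sprintf("<cohort> %d animals (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(gl)), table(gl)),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a cohort as TAC CSVs plus a JSON manifest
#'
#' One `<animal>_blood.csv` and `<animal>_tumor.csv` per animal (format of
#' [write_tac_csv()]) and a `manifest.json` listing animal metadata, file
#' paths and -- for synthetic animals -- the generating parameters.
#'
#' @param cohort a list of [study_record()]s.
#' @param dir output directory (created if missing).
#' @return `write_cohort()`: the manifest path, invisibly.
#'   `read_cohort()`: a `cohort` list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(r) {
    bf <- file.path(dir, paste0(r$animal_id, "_blood.csv"))
    tf <- file.path(dir, paste0(r$animal_id, "_tumor.csv"))
    write_tac_csv(r$blood_tac, bf)
    write_tac_csv(r$tumor_tac, tf)
    list(animal_id = r$animal_id, group = r$group,
         dose_bq = r$injected_dose_bq, weight_g = r$body_weight_g,
         blood_tac = basename(bf), tumor_tac = basename(tf),
         true_params = if (!is.null(r$true_params)) unclass(r$true_params))
  })
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mf)
}

#' @rdname write_cohort
#' @param manifest_path path to a `manifest.json`.
#' @export
read_cohort <- function(manifest_path) {
  entries <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  recs <- lapply(entries, function(e) {
    tp <- if (!is.null(e$true_params))
      structure(lapply(e$true_params, as.numeric), class = "kinetic_params")
    study_record(e$animal_id, e$group, e$dose_bq, e$weight_g,
                 read_tac_csv(file.path(dir, e$blood_tac)),
                 read_tac_csv(file.path(dir, e$tumor_tac)),
                 true_params = tp)
  })
  structure(recs, class = "cohort")
}
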