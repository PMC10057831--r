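#' A single timed infusion segment
#'
#' Boluses are represented as short finite infusions at their clinically
#' stated durations rather than instantaneous impulses.
#'
#' @param t_start Segment start time, s.
#' @param duration Segment duration, s (> 0).
#' @param mass Drug mass delivered over the segment, mg (>= 0).
#' @return A list of class `"infusion_segment"`.
#' @export
infusion_segment <- function(t_start, duration, mass) {
  if (t_start < 0) stop("t_start must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (mass < 0) stop("mass must be >= 0")
  structure(list(t_start = t_start, duration = duration, mass = mass),
            class = c("infusion_segment", "list"))
}

#' An intravenous dose regimen
#'
#' @param drug Drug name (one of [drug_names()], or any label for custom
#'   regimens).
#' @param segments List of [infusion_segment()]s, time-ordered and
#'   non-overlapping.
#' @param weight_based Whether the total dose was resolved from a per-kg
#'   prescription.
#' @param dose_per_kg Prescribed dose per body weight, mg/kg (if
#'   `weight_based`).
#' @return A list of class `"regimen"`.
#' @export
regimen <- function(drug, segments, weight_based = FALSE,
                    dose_per_kg = NA_real_) {
  if (!length(segments)) stop("a regimen needs at least one segment")
  starts <- vapply(segments, `[[`, 0, "t_start")
  ends <- starts + vapply(segments, `[[`, 0, "duration")
  ord <- order(starts)
  segments <- segments[ord]
  starts <- starts[ord]; ends <- ends[ord]
  if (length(segments) > 1L &&
      any(starts[-1L] < ends[-length(ends)] - 1e-12)) {
    stop("infusion segments overlap")
  }
  total <- sum(vapply(segments, `[[`, 0, "mass"))
  if (total <= 0) stop("total regimen mass must be positive")
  structure(list(drug = drug, segments = segments,
                 weight_based = weight_based, dose_per_kg = dose_per_kg),
            class = c("regimen", "list"))
}

#' Built-in dose regimen for a drug
#'
#' The standard intravenous regimens: alteplase 0.9 mg/kg with 10% as a
#' 1-min loading bolus and 90% infused over 60 min; tenecteplase 0.25 mg/kg
#' as a single 5-s bolus; reteplase two 17.4 mg boluses of 2 min each
#' separated by a 30-min interval (end of first to start of second);
#' urokinase 1,500,000 U (11.3 mg) infused over 30 min.
#'
#' @param name Drug name.
#' @param patient A [patient()] (needed for weight-based regimens).
#' @param config Scenario configuration (unused for the built-ins; present
#'   for interface symmetry).
#' @return A [regimen()].
#' @export
builtin_regimen <- function(name, patient = thrombosim::patient(),
                            config = default_config()) {
  if (!name %in% drug_names()) {
    stop("unknown drug '", name, "'; valid names: ",
         paste(drug_names(), collapse = ", "))
  }
  bw <- patient$body_weight
  switch(name,
    alteplase = {
      total <- 0.9 * bw
      regimen("alteplase",
              list(infusion_segment(0, 60, 0.1 * total),
                   infusion_segment(60, 3600, 0.9 * total)),
              weight_based = TRUE, dose_per_kg = 0.9)
    },
    tenecteplase = regimen("tenecteplase",
                           list(infusion_segment(0, 5, 0.25 * bw)),
                           weight_based = TRUE, dose_per_kg = 0.25),
    reteplase = regimen("reteplase",
                        list(infusion_segment(0, 120, 17.4),
                             infusion_segment(120 + 1800, 120, 17.4))),
    urokinase = regimen("urokinase",
                        list(infusion_segment(0, 1800, 11.3)))
  )
}

#' Instantaneous infusion rate of a regimen
#'
#' Piecewise-constant rate: `mass/duration` inside a segment, zero outside.
#'
#' @param reg A [regimen()].
#' @param t Time(s), s (vectorized).
#' @return Infusion rate(s) in mg/s.
#' @export
iv_rate <- function(reg, t) {
  if (any(t < 0)) stop("t must be >= 0")
  rate <- numeric(length(t))
  for (seg in reg$segments) {
    inside <- t >= seg$t_start & t < seg$t_start + seg$duration
    rate[inside] <- rate[inside] + seg$mass / seg$duration
  }
  rate
}

#' Total mass delivered by a regimen
#'
#' @param reg A [regimen()].
#' @return Total dose, mg.
#' @export
regimen_total_mass <- function(reg) {
  sum(vapply(reg$segments, `[[`, 0, "mass"))
}

#' End time of the last infusion segment
#'
#' @param reg A [regimen()].
#' @return Time in s after which the infusion rate is identically zero.
#' @export
regimen_end <- function(reg) {
  max(vapply(reg$segments, function(s) s$t_start + s$duration, 0))
}

#' Segment boundary times of a regimen
#'
#' Integration breakpoints: every time at which the piecewise-constant
#' infusion rate jumps.
#'
#' @param reg A [regimen()].
#' @return Sorted numeric vector of boundary times, s.
#' @export
regimen_breaks <- function(reg) {
  b <- unlist(lapply(reg$segments,
                     function(s) c(s$t_start, s$t_start + s$duration)))
  sort(unique(b))
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen>", x$drug, "- total",
      format(regimen_total_mass(x)), "mg\n")
  for (seg in x$segments) {
    cat(sprintf("  t = %6.0f s: %6.2f mg over %5.0f s (%.4g mg/s)\n",
                seg$t_start, seg$mass, seg$duration, seg$mass / seg$duration))
  }
  invisible(x)
}
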