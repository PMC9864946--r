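#' Thermal-time germination model
#'
#' Germination is assumed to occur once a seed has accumulated its thermal
#' time requirement theta_g (degree-days above the base temperature Tb):
#' `theta_g = (T - Tb) * t_g`, where T is the incubation temperature and
#' t_g the time to germination. Across seeds, theta_g is taken to be
#' lognormally distributed with median `theta50` and log-scale dispersion
#' `theta_sigma`.
#'
#' The default parameter values are synthetic: the source experiments on
#' *Brassica napus* and *Sinapis arvensis* did not report Tb or theta
#' values, so the defaults describe a plausible fast-germinating
#' Brassicaceae seed lot (Tb = 0 degrees C, median requirement 60
#' degree-days, i.e. three days at 20 degrees C) and should be replaced by
#' fitted values when real data exist.
#'
#' @param Tb base temperature for germination, degrees C.
#' @param theta50 median thermal time to germination, degree-days (> 0).
#' @param theta_sigma lognormal sdlog of thermal time across seeds (> 0).
#' @return An object of class `thermal_model`.
#' @export
thermal_model <- function(Tb = 0, theta50 = 60, theta_sigma = 0.15) {
  if (!is.numeric(Tb) || length(Tb) != 1L || is.na(Tb))
    stop("`Tb` must be a single finite number", call. = FALSE)
  if (!is.numeric(theta50) || length(theta50) != 1L || !is.finite(theta50) ||
      theta50 <= 0)
    stop("`theta50` must be a single positive number", call. = FALSE)
  if (!is.numeric(theta_sigma) || length(theta_sigma) != 1L ||
      !is.finite(theta_sigma) || theta_sigma <= 0)
    stop("`theta_sigma` must be a single positive number", call. = FALSE)
  structure(list(Tb = Tb, theta50 = theta50, theta_sigma = theta_sigma),
            class = "thermal_model")
}

#' Time to germination under the thermal-time model
#'
#' Inverts `theta_g = (T - Tb) * t_g` to `t_g = theta_g / (T - Tb)`.
#' Below or at the base temperature no thermal time accrues and germination
#' is impossible, which is reported as an error.
#'
#' @param tm a [thermal_model()].
#' @param theta_g thermal time requirement, degree-days (> 0, vectorised).
#' @param T_inc incubation temperature, degrees C (vectorised).
#' @return Time to germination in days.
#' @export
time_to_germination <- function(tm, theta_g, T_inc) {
  if (!inherits(tm, "thermal_model"))
    stop("`tm` must be a thermal_model", call. = FALSE)
  if (any(!is.finite(theta_g)) || any(theta_g <= 0))
    stop("`theta_g` must be positive", call. = FALSE)
  if (any(!is.finite(T_inc)) || any(T_inc <= tm$Tb))
    stop("sub-base temperature: no germination is possible at T <= Tb (",
         tm$Tb, " C)", call. = FALSE)
  theta_g / (T_inc - tm$Tb)
}

# default dormancy-class thresholds: symmetric tripartition of [0, 1]
.dormancy_thresholds <- c(nd = 1 / 3, d = 2 / 3)

#' Categorical dormancy class from a continuous dormancy level
#'
#' Maps a continuous dormancy level d in \[0, 1\] to the classes used to
#' describe seedbank cycling: dormant (D), conditionally dormant (CD) and
#' nondormant (ND). The default thresholds tripartition the unit interval
#' symmetrically: d > 2/3 is D, 1/3 < d <= 2/3 is CD, d <= 1/3 is ND.
#'
#' @param level dormancy level(s) in \[0, 1\].
#' @param thresholds length-2 numeric, the ND/CD and CD/D boundaries.
#' @return Character vector of `"D"`, `"CD"` or `"ND"`.
#' @export
dormancy_class <- function(level, thresholds = .dormancy_thresholds) {
  if (any(!is.finite(level)) || any(level < 0) || any(level > 1))
    stop("dormancy `level` must lie in [0, 1]", call. = FALSE)
  unname(ifelse(level > thresholds[[2]], "D",
                ifelse(level > thresholds[[1]], "CD", "ND")))
}

#' Dormancy state: continuous level, non-deep PD type, and class
#'
#' @param level dormancy level d in \[0, 1\]; 1 is fully dormant, 0
#'   nondormant.
#' @param pd_type integer 1..6, the type of non-deep physiological dormancy
#'   (how the permissive temperature window changes as dormancy is
#'   released; see [niche_window()]).
#' @param thresholds passed to [dormancy_class()].
#' @return An object of class `dormancy_state` with fields `level`,
#'   `pd_type` and `klass`.
#' @export
dormancy_state <- function(level, pd_type = 3L,
                           thresholds = .dormancy_thresholds) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0 || level > 1)
    stop("dormancy `level` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(pd_type) || length(pd_type) != 1L ||
      !(pd_type %in% 1:6))
    stop("`pd_type` must be an integer between 1 and 6", call. = FALSE)
  structure(list(level = level, pd_type = as.integer(pd_type),
                 klass = dormancy_class(level, thresholds)),
            class = "dormancy_state")
}

#' Permissive temperature window for a dormancy state
#'
#' Non-deep physiological dormancy restricts the range of temperatures over
#' which seeds can germinate; the six PD types differ in how that window
#' changes as dormancy is released (d falls from 1 to 0):
#'
#' * **Type 1**: anchored at the taxon's minimum temperature; the upper
#'   edge rises with dormancy release (dormant seeds germinate only at low
#'   temperatures).
#' * **Type 2**: anchored at the maximum; the lower edge falls with release
#'   (dormant seeds germinate only at high temperatures).
#' * **Type 3**: anchored at an intermediate temperature `T_mid`; both
#'   edges move outwards with release.
#' * **Type 4**: fixed upper sub-range for all d.
#' * **Type 5**: fixed lower sub-range for all d.
#' * **Type 6**: the taxon's full range for all d.
#'
#' Window edges interpolate linearly in the released fraction `1 - d`
#' between a core window of breadth `breadth_frac * (Tmax - Tmin)` (the
#' fully dormant niche) and the full taxon range; a logistic alternative is
#' available. Dormancy also caps the germinable fraction inside the window:
#' `gmax = (1 - d)^gmax_gamma`, a concave release curve so that partially
#' dormant lots already germinate substantially at permissive temperatures,
#' with `gmax(1) = 0` and `gmax(0) = 1`. For the fixed-window types 4-6 a
#' floor on gmax can be set.
#'
#' @param state a [dormancy_state()].
#' @param T_range length-2 numeric, the taxon's minimum and maximum
#'   germination temperatures (degrees C).
#' @param T_mid anchor temperature for type 3, inside `T_range`.
#' @param breadth_frac breadth of the fully dormant core window as a
#'   fraction of the taxon range.
#' @param gmax_gamma exponent of the germinable-fraction release curve.
#' @param gmax_floor lower bound on gmax, applied to types 4-6 only.
#' @param interpolation `"linear"` (default) or `"logistic"` edge movement
#'   in `1 - d`.
#' @param logistic_steepness slope of the logistic alternative.
#' @return An object of class `niche_window` with fields `T_lo`, `T_hi`
#'   and `gmax`.
#' @export
niche_window <- function(state, T_range, T_mid = mean(T_range),
                         breadth_frac = 1 / 3,
                         gmax_gamma = 0.5, gmax_floor = 0,
                         interpolation = c("linear", "logistic"),
                         logistic_steepness = 8) {
  if (!inherits(state, "dormancy_state"))
    stop("`state` must be a dormancy_state", call. = FALSE)
  interpolation <- match.arg(interpolation)
  if (length(T_range) != 2L || !all(is.finite(T_range)) ||
      T_range[1] >= T_range[2])
    stop("`T_range` must be (Tmin, Tmax) with Tmin < Tmax", call. = FALSE)
  Tmin <- T_range[1]; Tmax <- T_range[2]
  if (!is.finite(T_mid) || T_mid <= Tmin || T_mid >= Tmax)
    stop("`T_mid` must lie strictly inside `T_range`", call. = FALSE)
  d <- state$level
  r <- 1 - d
  if (interpolation == "logistic") {
    p <- function(x) stats::plogis(logistic_steepness * (x - 0.5))
    r <- (p(r) - p(0)) / (p(1) - p(0))
  }
  w <- breadth_frac * (Tmax - Tmin)
  lerp <- function(a, b, t) a + t * (b - a)
  core3_lo <- max(Tmin, T_mid - w / 2)
  core3_hi <- min(Tmax, T_mid + w / 2)
  edges <- switch(as.character(state$pd_type),
    "1" = c(Tmin, lerp(Tmin + w, Tmax, r)),
    "2" = c(lerp(Tmax - w, Tmin, r), Tmax),
    "3" = c(lerp(core3_lo, Tmin, r), lerp(core3_hi, Tmax, r)),
    "4" = c(Tmax - w, Tmax),
    "5" = c(Tmin, Tmin + w),
    "6" = c(Tmin, Tmax),
    stop("`pd_type` must be an integer between 1 and 6", call. = FALSE)
  )
  gmax <- (1 - d)^gmax_gamma
  if (state$pd_type %in% 4:6) gmax <- max(gmax, gmax_floor)
  structure(list(T_lo = edges[1], T_hi = edges[2], gmax = gmax),
            class = "niche_window")
}

#' Is a temperature inside a niche window?
#'
#' @param window a [niche_window()].
#' @param T_inc temperature(s), degrees C.
#' @return Logical vector.
#' @export
in_window <- function(window, T_inc) {
  if (!inherits(window, "niche_window"))
    stop("`window` must be a niche_window", call. = FALSE)
  T_inc >= window$T_lo & T_inc <= window$T_hi
}

# default first-order dormancy release rates (per day). Stratification acts
# much faster than dry after-ripening: 5 effective days of cold versus
# about three months of dry storage, hence a 2-day versus 30-day half-life.
.release_rates <- c(after_ripening = log(2) / 30, stratification = log(2) / 2)

#' Dormancy level after a dormancy-breaking treatment
#'
#' First-order (exponential) decay of the dormancy level under dry
#' after-ripening or cold stratification:
#' `d(t) = d0 * exp(-rate * duration_days)`. The default stratification
#' rate (half-life 2 days) is much larger than the default after-ripening
#' rate (half-life 30 days), reflecting that a few days of cold, moist
#' treatment achieve what months of dry storage do.
#'
#' @param d0 initial dormancy level(s) in \[0, 1\].
#' @param agent `"after_ripening"` or `"stratification"`.
#' @param duration_days treatment duration, days (>= 0).
#' @param rate decay rate per day; `NULL` uses the agent's default.
#' @return Dormancy level(s) after treatment, in \[0, 1\].
#' @export
dormancy_after_treatment <- function(d0,
                                     agent = c("after_ripening",
                                               "stratification"),
                                     duration_days, rate = NULL) {
  agent <- match.arg(agent)
  if (any(!is.finite(d0)) || any(d0 < 0) || any(d0 > 1))
    stop("`d0` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(duration_days)) || any(duration_days < 0))
    stop("`duration_days` must be non-negative", call. = FALSE)
  if (is.null(rate)) rate <- .release_rates[[agent]]
  if (!is.finite(rate) || rate <= 0)
    stop("`rate` must be positive", call. = FALSE)
  d0 * exp(-rate * duration_days)
}
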