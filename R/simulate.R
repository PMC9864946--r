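#' Design of a germination trial simulation
#'
#' The defaults reproduce the standard Petri-dish design: five incubation
#' temperatures (5, 10, 20, 25, 30 degrees C), four replicates of 50 seeds
#' each, a daily census, and recording that stops once three consecutive
#' days pass with no new germination.
#'
#' @param temperatures_C incubation temperatures, degrees C.
#' @param n_replicates replicates (dishes) per temperature.
#' @param seeds_per_dish seeds sown per dish.
#' @param max_days hard cap on trial length, days.
#' @param stop_rule_days consecutive germination-free days that end the
#'   census (counted after the first germination; see
#'   [simulate_replicate()]).
#' @param rng_seed integer seed; every replicate draws from a substream
#'   derived deterministically from it, so adding replicates or
#'   temperatures never changes earlier ones.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(temperatures_C = c(5, 10, 20, 25, 30),
                              n_replicates = 4L, seeds_per_dish = 50L,
                              max_days = 60L, stop_rule_days = 3L,
                              rng_seed = 1L) {
  if (!length(temperatures_C) || any(!is.finite(temperatures_C)))
    stop("`temperatures_C` must be a non-empty numeric vector", call. = FALSE)
  for (nm in c("n_replicates", "seeds_per_dish", "max_days",
               "stop_rule_days")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != trunc(v))
      stop("`", nm, "` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || !is.finite(rng_seed))
    stop("`rng_seed` must be a single integer", call. = FALSE)
  structure(list(temperatures_C = as.numeric(temperatures_C),
                 n_replicates = as.integer(n_replicates),
                 seeds_per_dish = as.integer(seeds_per_dish),
                 max_days = as.integer(max_days),
                 stop_rule_days = as.integer(stop_rule_days),
                 rng_seed = as.integer(rng_seed %% .Machine$integer.max)),
            class = "simulation_design")
}

# deterministic substream seed for replicate j at temperature index ti
# (stage offsets months/pipeline stages apart); kept below 2^31 - 1
.derive_seed <- function(base, ti, j) {
  as.integer((as.double(base) + 100003 * ti + 1009 * j) %% 2147483647)
}

#' Simulate one replicate's germination census
#'
#' Mechanistic generator tying dormancy to germination timing. Each seed
#' independently:
#'
#' 1. dies with probability `dead_frac` (dead seeds never germinate and are
#'    excluded from the viable ungerminated count);
#' 2. otherwise is germinable with probability `gmax` from the dormancy
#'    state's [niche_window()] when the incubation temperature lies inside
#'    the window, and with the small `leak` probability outside it;
#' 3. if germinable, draws a thermal-time requirement
#'    `theta ~ lognormal(log(theta50), sigma_eff)` with
#'    `sigma_eff = theta_sigma * (1 + kappa * d)`: dormancy inflates the
#'    dispersion of germination timing, which is the mechanism that makes
#'    synchrony rise as dormancy is released;
#' 4. germinates on day `ceiling(theta / (T - Tb))` (the daily census
#'    detects germination at the end of the day; days are 1-based). At or
#'    below the base temperature germinable seeds simply never germinate
#'    (not an error).
#'
#' The census is then truncated by the stop rule: recording ends after
#' `stop_rule_days` consecutive germination-free days following the first
#' germination event, or at `max_days`. Seeds whose germination day falls
#' beyond the truncation point are recorded as ungerminated (they remain in
#' `viable_ungerminated`). The stop-rule clock starts at the first
#' germination because a literal day-1 clock would abort any trial whose
#' germination lag exceeds the rule length - that is, nearly all of them.
#'
#' @param design a [simulation_design()].
#' @param tm a [thermal_model()].
#' @param state a [dormancy_state()].
#' @param T_inc incubation temperature, degrees C.
#' @param kappa timing-dispersion inflation factor per unit dormancy.
#' @param leak germination probability outside the niche window.
#' @param dead_frac fraction of dead seeds.
#' @param T_range,T_mid taxon temperature range and type-3 anchor, passed
#'   to [niche_window()].
#' @param gmax_gamma,gmax_floor germinable-fraction release curve, passed
#'   to [niche_window()].
#' @param replicate_id replicate label.
#' @param seed optional integer seed for this replicate's substream; `NULL`
#'   continues from the current RNG state.
#' @return A [time_course()].
#' @export
simulate_replicate <- function(design, tm, state, T_inc,
                               kappa = 2, leak = 0.01, dead_frac = 0.05,
                               T_range = c(5, 30), T_mid = 20,
                               gmax_gamma = 0.5, gmax_floor = 0,
                               replicate_id = "R1", seed = NULL) {
  if (!inherits(design, "simulation_design"))
    stop("`design` must be a simulation_design", call. = FALSE)
  if (!inherits(tm, "thermal_model"))
    stop("`tm` must be a thermal_model", call. = FALSE)
  if (!inherits(state, "dormancy_state"))
    stop("`state` must be a dormancy_state", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  window <- niche_window(state, T_range, T_mid,
                         gmax_gamma = gmax_gamma, gmax_floor = gmax_floor)
  n <- design$seeds_per_dish
  dead <- stats::runif(n) < dead_frac
  p_germ <- if (in_window(window, T_inc)) window$gmax else leak
  germinable <- !dead & (stats::runif(n) < p_germ)

  day <- integer(0)
  if (T_inc > tm$Tb && any(germinable)) {
    sigma_eff <- tm$theta_sigma * (1 + kappa * state$level)
    theta <- stats::rlnorm(sum(germinable), meanlog = log(tm$theta50),
                           sdlog = sigma_eff)
    tg <- theta / (T_inc - tm$Tb)
    day <- pmax(1L, as.integer(ceiling(tg)))
    day <- day[day <= design$max_days]
  }

  if (length(day)) {
    tab <- tabulate(day, nbins = design$max_days)
    first <- which(tab > 0L)[1]
    stop_day <- design$max_days
    zeros <- 0L
    t <- first
    while (t < design$max_days) {
      t <- t + 1L
      if (tab[t] == 0L) {
        zeros <- zeros + 1L
        if (zeros >= design$stop_rule_days) { stop_day <- t; break }
      } else zeros <- 0L
    }
    keep <- which(tab > 0L & seq_along(tab) <= stop_day)
    counts <- tab[keep]
  } else {
    keep <- integer(0)
    counts <- integer(0)
  }

  n_observed <- sum(counts)
  viable <- n - sum(dead) - n_observed
  time_course(census_days = keep, counts = counts, seeds_sown = n,
              viable_ungerminated = viable, replicate_id = replicate_id)
}

#' Simulate a full germination trial across the temperature grid
#'
#' Applies [simulate_replicate()] over every design temperature and
#' replicate, with per-replicate RNG substreams derived deterministically
#' from `design$rng_seed`, so repeated calls with the same design are
#' bit-identical and adding replicates or temperatures never alters
#' existing ones.
#'
#' @inheritParams simulate_replicate
#' @param treatment,species labels attached to the resulting trial sets.
#' @param ... further arguments passed to [simulate_replicate()]
#'   (`kappa`, `leak`, `dead_frac`, `T_range`, `T_mid`, `gmax_gamma`,
#'   `gmax_floor`).
#' @return A list of [trial_set()] objects, one per temperature.
#' @examples
#' des <- simulation_design(rng_seed = 42)
#' tsets <- simulate_trialset(des, thermal_model(), dormancy_state(0.2, 3))
#' replicate_indices(tsets)
#' @export
simulate_trialset <- function(design, tm, state, treatment = "simulated",
                              species = "synthetic", ...) {
  if (!inherits(design, "simulation_design"))
    stop("`design` must be a simulation_design", call. = FALSE)
  temps <- design$temperatures_C
  lapply(seq_along(temps), function(ti) {
    reps <- lapply(seq_len(design$n_replicates), function(j) {
      simulate_replicate(design, tm, state, T_inc = temps[ti], ...,
                         replicate_id = paste0("R", j),
                         seed = .derive_seed(design$rng_seed, ti, j))
    })
    trial_set(reps, species = species, treatment = treatment,
              temperature_C = temps[ti])
  })
}
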