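#' Seasonal dormancy level of buried seeds
#'
#' Minimal periodic model of seedbank dormancy cycling: a cosine with a
#' 12-month period,
#' `d(m) = d_mean + d_amp * cos(2 * pi * (m - phase) / 12)`,
#' clipped to \[0, 1\]. Dormancy peaks at `month = phase` and is lowest six
#' months later.
#'
#' @param month month index (real, vectorised); 0 is the burial month.
#' @param d_mean mean dormancy level over the year.
#' @param d_amp amplitude of the seasonal cycle; `d_mean +/- d_amp` must
#'   stay inside \[0, 1\].
#' @param phase month at which dormancy peaks.
#' @return Dormancy level(s) in \[0, 1\].
#' @export
seasonal_dormancy <- function(month, d_mean = 0.5, d_amp = 0.4, phase = 0) {
  if (!is.finite(d_mean) || !is.finite(d_amp) || d_amp < 0 ||
      d_mean - d_amp < 0 || d_mean + d_amp > 1)
    stop("`d_mean` +/- `d_amp` must lie within [0, 1]", call. = FALSE)
  pmin(1, pmax(0, d_mean + d_amp * cos(2 * pi * (month - phase) / 12)))
}

#' Simulate a burial experiment with monthly exhumation assays
#'
#' Buried seeds cycle through dormancy according to [seasonal_dormancy()];
#' each month a sample is exhumed and assayed in a germination trial
#' (simulated with [simulate_trialset()] at `assay_temperature`, by default
#' the 20 degree C intermediate optimum). For every month the series
#' records the latent dormancy level and its D/CD/ND class, the mean
#' germination percentage across replicates, and the replicate-mean
#' synchrony and asynchrony indices.
#'
#' @param design a [simulation_design()]; its temperature grid is replaced
#'   by `assay_temperature` for the monthly assays, and monthly RNG
#'   substreams are derived from its `rng_seed`.
#' @param tm a [thermal_model()].
#' @param pd_type non-deep physiological dormancy type (1..6).
#' @param n_months number of monthly exhumations (>= 2); month 0 is the
#'   burial month.
#' @param d_mean,d_amp,phase seasonal dormancy parameters, see
#'   [seasonal_dormancy()].
#' @param assay_temperature incubation temperature of the monthly assays,
#'   degrees C.
#' @param basis denominator of the germination percentage, see
#'   [germination_fraction()].
#' @param species label for the simulated seed lot.
#' @param ... further arguments passed to [simulate_replicate()].
#' @return A `burial_series`: a `data.frame` with one row per month
#'   (`month`, `dormancy`, `klass`, `germination_pct`, `synchrony_mean`,
#'   `synchrony_se`, `asynchrony_mean`, `asynchrony_se`,
#'   `n_replicates_used`, `n_replicates_excluded`) carrying the per-month
#'   [trial_set()] objects in the `"trialsets"` attribute.
#' @export
run_burial <- function(design, tm, pd_type = 3L, n_months = 12L,
                       d_mean = 0.5, d_amp = 0.4, phase = 0,
                       assay_temperature = 20, basis = c("sown", "viable"),
                       species = "synthetic", ...) {
  if (!inherits(design, "simulation_design"))
    stop("`design` must be a simulation_design", call. = FALSE)
  basis <- match.arg(basis)
  if (!is.numeric(n_months) || length(n_months) != 1L || n_months < 2)
    stop("`n_months` must be at least 2", call. = FALSE)
  months <- seq.int(0L, as.integer(n_months) - 1L)
  rows <- vector("list", length(months))
  tsets <- vector("list", length(months))
  for (i in seq_along(months)) {
    m <- months[i]
    d <- seasonal_dormancy(m, d_mean, d_amp, phase)
    state <- dormancy_state(d, pd_type)
    des_m <- design
    des_m$temperatures_C <- assay_temperature
    des_m$rng_seed <- .derive_seed(design$rng_seed, 6007L * (m + 1L), 0L)
    ts <- simulate_trialset(des_m, tm, state,
                            treatment = sprintf("exhumed-month-%02d", m),
                            species = species, ...)[[1]]
    germ <- mean(vapply(ts$replicates, germination_fraction, numeric(1),
                        basis = basis)) * 100
    s <- summarize_group(ts, warn_excluded = FALSE)
    rows[[i]] <- data.frame(
      month = m, dormancy = d, klass = state$klass,
      germination_pct = germ,
      synchrony_mean = s$synchrony_mean, synchrony_se = s$synchrony_se,
      asynchrony_mean = s$asynchrony_mean, asynchrony_se = s$asynchrony_se,
      n_replicates_used = s$n_replicates_used,
      n_replicates_excluded = s$n_replicates_excluded,
      stringsAsFactors = FALSE
    )
    tsets[[i]] <- ts
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trialsets") <- tsets
  class(out) <- c("burial_series", "data.frame")
  out
}

#' Rank correlation between two monthly burial trajectories
#'
#' Spearman rank correlation (tie-corrected, two-sided) between two
#' per-month series of a burial experiment - by default the measurable
#' pair: germination percentage and mean synchrony Z. Because the latent
#' dormancy level is known in simulation, it can also be correlated
#' directly (e.g. `x = "dormancy"`), which is unavailable for real burial
#' data.
#'
#' @param series a `burial_series` from [run_burial()], or any data frame
#'   with the requested columns.
#' @param x,y column names of the two monthly series.
#' @return A list with `rho`, `p_value` and `n` (months with both values
#'   defined). At least 4 defined months are required.
#' @export
cycling_correlation <- function(series, x = "germination_pct",
                                y = "synchrony_mean") {
  if (!is.data.frame(series) || !all(c(x, y) %in% names(series)))
    stop("`series` must contain columns `", x, "` and `", y, "`",
         call. = FALSE)
  xv <- series[[x]]
  yv <- series[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 4L)
    stop("insufficient data: need at least 4 months with defined values",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(xv[ok], yv[ok], method = "spearman",
                    alternative = "two.sided")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' @export
print.burial_series <- function(x, ...) {
  cat("<burial_series>", nrow(x), "monthly exhumations\n")
  print.data.frame(x, ...)
  invisible(x)
}
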