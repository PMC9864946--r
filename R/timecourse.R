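#' Germination time course for a single replicate
#'
#' A `time_course` holds one replicate's daily germination census: the days
#' on which newly germinated seeds were recorded, the corresponding counts,
#' the number of seeds sown, and the number of viable (crush-test positive)
#' but ungerminated seeds at trial end.
#'
#' Census days are 1-based integers and must be strictly increasing.
#' Zero-count days may be recorded explicitly (they carry no index mass);
#' days absent from `census_days` carry no mass either, so gaps in the
#' census are permitted.
#'
#' @param census_days integer vector of census day indices (1-based,
#'   strictly increasing). May be empty when nothing germinated.
#' @param counts integer vector, same length as `census_days`: number of
#'   newly germinated seeds recorded on each day. Non-negative.
#' @param seeds_sown single positive integer, seeds sown in the dish.
#' @param viable_ungerminated single non-negative integer: seeds that had
#'   not germinated by trial end but were viable in the crush test.
#' @param replicate_id replicate label.
#'
#' @return An object of class `time_course`.
#' @examples
#' tc <- time_course(census_days = c(2, 3, 5), counts = c(3, 0, 1),
#'                   seeds_sown = 50, viable_ungerminated = 40)
#' synchrony_index(tc)
#' asynchrony_index(tc)
#' @export
time_course <- function(census_days, counts, seeds_sown,
                        viable_ungerminated = 0L, replicate_id = "R1") {
  census_days <- .as_count(census_days, "census_days")
  counts <- .as_count(counts, "counts")
  if (length(census_days) != length(counts))
    stop("`census_days` and `counts` must have the same length", call. = FALSE)
  if (length(census_days) > 0L && any(census_days < 1L))
    stop("census days are 1-based: all days must be >= 1", call. = FALSE)
  if (length(census_days) > 1L && any(diff(census_days) <= 0L))
    stop("census days must be strictly increasing (duplicate or unordered day)",
         call. = FALSE)
  seeds_sown <- .as_count(seeds_sown, "seeds_sown")
  viable_ungerminated <- .as_count(viable_ungerminated, "viable_ungerminated")
  if (length(seeds_sown) != 1L || seeds_sown < 1L)
    stop("`seeds_sown` must be a single positive integer", call. = FALSE)
  if (length(viable_ungerminated) != 1L)
    stop("`viable_ungerminated` must be a single non-negative integer", call. = FALSE)
  n_germ <- sum(counts)
  if (n_germ > seeds_sown)
    stop("germinated seeds (", n_germ, ") exceed seeds sown (", seeds_sown, ")",
         call. = FALSE)
  if (n_germ + viable_ungerminated > seeds_sown)
    stop("germinated + viable ungerminated seeds exceed seeds sown", call. = FALSE)
  structure(
    list(replicate_id = as.character(replicate_id),
         census_days = census_days,
         counts = counts,
         seeds_sown = seeds_sown,
         viable_ungerminated = viable_ungerminated),
    class = "time_course"
  )
}

# coerce to non-negative integer vector with a clear error
.as_count <- function(x, what) {
  if (!is.numeric(x) || anyNA(x))
    stop("`", what, "` must be numeric and free of NA", call. = FALSE)
  if (any(x < 0))
    stop("`", what, "` must be non-negative", call. = FALSE)
  if (any(x != trunc(x)))
    stop("`", what, "` must be integer-valued", call. = FALSE)
  as.integer(x)
}

# daily counts from a time_course or a bare numeric vector
.counts_of <- function(x) {
  if (inherits(x, "time_course")) x$counts
  else .as_count(x, "counts")
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> replicate", x$replicate_id, "-", x$seeds_sown, "seeds sown\n")
  if (length(x$census_days)) {
    cat("  day   :", x$census_days, "\n")
    cat("  count :", x$counts, "\n")
  } else {
    cat("  (no germination recorded)\n")
  }
  cat("  germinated:", sum(x$counts),
      " viable ungerminated:", x$viable_ungerminated, "\n")
  invisible(x)
}

#' A group of replicate time courses sharing a treatment and temperature
#'
#' @param replicates a `time_course` or a list of them (at least one).
#'   Replicate ids must be unique within the set. Heterogeneous
#'   `seeds_sown` across replicates is permitted.
#' @param species species label.
#' @param treatment treatment label (e.g. `"fresh"`, `"after-ripened"`,
#'   `"stratified"`, `"exhumed-month-03"`).
#' @param temperature_C incubation temperature in degrees Celsius.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(replicates, species = "unknown", treatment = "control",
                      temperature_C = NA_real_) {
  if (inherits(replicates, "time_course")) replicates <- list(replicates)
  if (!is.list(replicates) || length(replicates) == 0L ||
      !all(vapply(replicates, inherits, logical(1), "time_course")))
    stop("`replicates` must be a non-empty list of time_course objects",
         call. = FALSE)
  ids <- vapply(replicates, `[[`, character(1), "replicate_id")
  if (anyDuplicated(ids))
    stop("replicate ids must be unique within a trial set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(
    list(species = as.character(species),
         treatment = as.character(treatment),
         temperature_C = as.numeric(temperature_C),
         replicates = replicates),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", x$species, "/", x$treatment, "@", x$temperature_C, "C,",
      length(x$replicates), "replicate(s)\n")
  invisible(x)
}
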