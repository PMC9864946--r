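#' Summarise synchrony and asynchrony over the replicates of a trial set
#'
#' Computes the asynchrony (entropy, bits) and synchrony (Z) index for each
#' replicate, then reports the mean, standard error (sample SD divided by
#' the square root of the number of contributing replicates) and SD of each
#' index across replicates. Replicates where an index is undefined (no
#' germinated seeds for the entropy; fewer than two for Z) are excluded
#' from that index's summary and counted in `n_replicates_excluded`.
#'
#' With `pool = TRUE` the daily counts of all replicates are merged into a
#' single census before computing one pooled index per group; this ignores
#' replicate structure and is offered only as an explicit alternative,
#' never the default.
#'
#' @param ts a [trial_set()].
#' @param pool merge replicate counts by day before computing the indices?
#' @param warn_excluded emit a warning when replicates are excluded because
#'   Z is undefined?
#' @return A one-row `data.frame` with columns `species`, `treatment`,
#'   `temperature_C`, `asynchrony_mean/se/sd/n`, `synchrony_mean/se/sd/n`,
#'   `n_replicates`, `n_replicates_used`, `n_replicates_excluded`.
#'   Undefined summaries are `NA`.
#' @examples
#' reps <- list(
#'   time_course(1:2, c(3, 2), 50, replicate_id = "a"),
#'   time_course(1:2, c(4, 1), 50, replicate_id = "b")
#' )
#' summarize_group(trial_set(reps, "demo", "fresh", 20))
#' @export
summarize_group <- function(ts, pool = FALSE, warn_excluded = TRUE) {
  if (!inherits(ts, "trial_set"))
    stop("`ts` must be a trial_set", call. = FALSE)
  reps <- ts$replicates
  n_rep <- length(reps)

  if (pool) {
    days <- sort(unique(unlist(lapply(reps, `[[`, "census_days"))))
    counts <- vapply(days, function(d) {
      sum(vapply(reps, function(r) {
        i <- match(d, r$census_days)
        if (is.na(i)) 0L else r$counts[i]
      }, integer(1)))
    }, integer(1))
    pooled_total <- sum(counts)
    asyn <- if (pooled_total >= 1L) asynchrony_index(counts) else NA_real_
    syn <- if (pooled_total >= 2L) synchrony_index(counts) else NA_real_
    return(data.frame(
      species = ts$species, treatment = ts$treatment,
      temperature_C = ts$temperature_C,
      asynchrony_mean = asyn, asynchrony_se = NA_real_, asynchrony_sd = NA_real_,
      asynchrony_n = as.integer(pooled_total >= 1L),
      synchrony_mean = syn, synchrony_se = NA_real_, synchrony_sd = NA_real_,
      synchrony_n = as.integer(pooled_total >= 2L),
      n_replicates = n_rep,
      n_replicates_used = n_rep,
      n_replicates_excluded = 0L,
      stringsAsFactors = FALSE
    ))
  }

  asyn <- vapply(reps, function(r)
    tryCatch(asynchrony_index(r), error = function(e) NA_real_), numeric(1))
  syn <- vapply(reps, function(r)
    tryCatch(synchrony_index(r), error = function(e) NA_real_), numeric(1))

  n_used <- sum(!is.na(syn))
  n_excl <- n_rep - n_used
  if (n_excl > 0L && warn_excluded)
    warning(n_excl, " replicate(s) excluded from the synchrony summary: ",
            "fewer than two germinated seeds", call. = FALSE)

  stat <- function(x) {
    x <- x[!is.na(x)]
    k <- length(x)
    c(mean = if (k >= 1L) mean(x) else NA_real_,
      se = if (k >= 2L) stats::sd(x) / sqrt(k) else NA_real_,
      sd = if (k >= 2L) stats::sd(x) else NA_real_,
      n = k)
  }
  a <- stat(asyn)
  z <- stat(syn)

  data.frame(
    species = ts$species, treatment = ts$treatment,
    temperature_C = ts$temperature_C,
    asynchrony_mean = a[["mean"]], asynchrony_se = a[["se"]],
    asynchrony_sd = a[["sd"]], asynchrony_n = as.integer(a[["n"]]),
    synchrony_mean = z[["mean"]], synchrony_se = z[["se"]],
    synchrony_sd = z[["sd"]], synchrony_n = as.integer(z[["n"]]),
    n_replicates = n_rep,
    n_replicates_used = as.integer(z[["n"]]),
    n_replicates_excluded = n_excl,
    stringsAsFactors = FALSE
  )
}

#' Per-replicate index table for one or more trial sets
#'
#' @param x a [trial_set()] or a list of them.
#' @param basis denominator for the germination fraction, see
#'   [germination_fraction()].
#' @return A tidy `data.frame` with one row per replicate: grouping keys,
#'   total germinated seeds, `asynchrony` (bits), `synchrony` (Z) and
#'   `germination_fraction`. Undefined indices are `NA`.
#' @export
replicate_indices <- function(x, basis = c("sown", "viable")) {
  basis <- match.arg(basis)
  if (inherits(x, "trial_set")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "trial_set")))
    stop("`x` must be a trial_set or a list of trial_set objects", call. = FALSE)
  rows <- lapply(x, function(ts) {
    do.call(rbind, lapply(ts$replicates, function(r) {
      data.frame(
        species = ts$species, treatment = ts$treatment,
        temperature_C = ts$temperature_C, replicate = r$replicate_id,
        seeds_sown = r$seeds_sown,
        n_germinated = sum(r$counts),
        viable_ungerminated = r$viable_ungerminated,
        asynchrony = tryCatch(asynchrony_index(r),
                              error = function(e) NA_real_),
        synchrony = tryCatch(synchrony_index(r),
                             error = function(e) NA_real_),
        germination_fraction = tryCatch(germination_fraction(r, basis),
                                        error = function(e) NA_real_),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summaries across a collection of trial sets
#'
#' Re-groups the replicates of a list of trial sets by the requested keys
#' and summarises each group with [summarize_group()]. Dropping
#' `"temperature_C"` from `group_by` pools replicates across incubation
#' temperatures into a marginal summary.
#'
#' @param trialsets list of [trial_set()] objects.
#' @param group_by character vector of grouping keys, a subset of
#'   `c("species", "treatment", "temperature_C")`.
#' @inheritParams summarize_group
#' @return A `data.frame` with one summary row per group. Keys not used for
#'   grouping are reported as `NA` (temperature) or `"(all)"`.
#' @export
summarize_trialsets <- function(trialsets,
                                group_by = c("species", "treatment",
                                             "temperature_C"),
                                pool = FALSE, warn_excluded = TRUE) {
  if (inherits(trialsets, "trial_set")) trialsets <- list(trialsets)
  keys_all <- c("species", "treatment", "temperature_C")
  if (!all(group_by %in% keys_all))
    stop("`group_by` must be a subset of: ", paste(keys_all, collapse = ", "),
         call. = FALSE)
  meta <- data.frame(
    species = vapply(trialsets, `[[`, character(1), "species"),
    treatment = vapply(trialsets, `[[`, character(1), "treatment"),
    temperature_C = vapply(trialsets, `[[`, numeric(1), "temperature_C"),
    stringsAsFactors = FALSE
  )
  key <- do.call(paste, c(meta[, group_by, drop = FALSE], sep = "\r"))
  groups <- split(seq_along(trialsets), key)
  out <- lapply(groups, function(idx) {
    reps <- unlist(lapply(idx, function(i) {
      rs <- trialsets[[i]]$replicates
      # keep ids unique when pooling several trial sets into one group
      lapply(rs, function(r) {
        r$replicate_id <- paste0("ts", i, ":", r$replicate_id)
        r
      })
    }), recursive = FALSE)
    first <- trialsets[[idx[1]]]
    merged <- trial_set(
      reps,
      species = if ("species" %in% group_by) first$species else "(all)",
      treatment = if ("treatment" %in% group_by) first$treatment else "(all)",
      temperature_C = if ("temperature_C" %in% group_by)
        first$temperature_C else NA_real_
    )
    summarize_group(merged, pool = pool, warn_excluded = warn_excluded)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
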