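# Long-format census IO. One row per (species, treatment, temperature,
# replicate, census day); wide day-column layouts are rejected by design
# because they cannot represent ragged censuses or gaps unambiguously.

.required_cols <- c("species", "treatment", "replicate", "temperature_C",
                    "day", "n_germinated", "seeds_sown",
                    "viable_ungerminated")

#' Read long-format germination census data
#'
#' Reads a CSV (or TSV, by file extension or `sep`) with one row per
#' replicate and census day and the mandatory header columns `species`,
#' `treatment`, `replicate`, `temperature_C`, `day`, `n_germinated`,
#' `seeds_sown`, `viable_ungerminated`. Rows are validated and malformed
#' input is reported with 1-based file line numbers (the header is line 1).
#'
#' @param path path to the file; UTF-8, header mandatory.
#' @param sep field separator; `NULL` picks `"\t"` for `.tsv`/`.txt` and
#'   `","` otherwise.
#' @return A list of [trial_set()] objects, one per
#'   (species, treatment, temperature) group, in stable order.
#' @export
read_counts <- function(path, sep = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e)
      stop("no data could be read from ", path, ": ", conditionMessage(e),
           call. = FALSE)
  )
  missing <- setdiff(.required_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("no data rows in ", path, call. = FALSE)

  line <- seq_len(nrow(df)) + 1L  # header is line 1
  .bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      stop(msg, " at line(s) ", paste(line[idx], collapse = ", "),
           call. = FALSE)
  }
  num_ok <- function(x) is.numeric(x) & is.finite(x)
  for (col in c("day", "n_germinated", "seeds_sown", "viable_ungerminated")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    .bad(!num_ok(df[[col]]), paste0("non-numeric `", col, "`"))
  }
  .bad(df$n_germinated < 0 | df$n_germinated != trunc(df$n_germinated),
       "negative or non-integer `n_germinated`")
  .bad(df$day < 1 | df$day != trunc(df$day),
       "`day` must be a positive integer")
  .bad(df$seeds_sown < 1 | df$seeds_sown != trunc(df$seeds_sown),
       "`seeds_sown` must be a positive integer")
  .bad(df$viable_ungerminated < 0 |
         df$viable_ungerminated != trunc(df$viable_ungerminated),
       "negative or non-integer `viable_ungerminated`")

  rep_key <- paste(df$species, df$treatment, df$temperature_C, df$replicate,
                   sep = "\r")
  dup <- duplicated(paste(rep_key, df$day, sep = "\r"))
  .bad(dup, "duplicate (replicate, day) row")

  for (col in c("seeds_sown", "viable_ungerminated")) {
    n_per_rep <- tapply(df[[col]], rep_key, function(v) length(unique(v)))
    incons <- names(n_per_rep)[n_per_rep > 1L]
    .bad(rep_key %in% incons,
         paste0("`", col, "` differs within a replicate"))
  }

  group_key <- paste(df$species, df$treatment, df$temperature_C, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(group_key,
                                                levels = unique(group_key))),
                function(gidx) {
    g <- df[gidx, , drop = FALSE]
    reps <- lapply(split(seq_len(nrow(g)),
                         factor(g$replicate, levels = unique(g$replicate))),
                   function(ridx) {
      r <- g[ridx, , drop = FALSE]
      r <- r[order(r$day), , drop = FALSE]
      time_course(census_days = r$day, counts = r$n_germinated,
                  seeds_sown = r$seeds_sown[1],
                  viable_ungerminated = r$viable_ungerminated[1],
                  replicate_id = as.character(r$replicate[1]))
    })
    trial_set(unname(reps), species = g$species[1], treatment = g$treatment[1],
              temperature_C = g$temperature_C[1])
  })
  unname(out)
}

#' Write trial sets as long-format census CSV
#'
#' Inverse of [read_counts()]: one row per recorded census day. A replicate
#' with no recorded germination is preserved as a single zero-count row on
#' day 1, so a write/read round trip is semantically lossless.
#'
#' @param trialsets a [trial_set()] or list of them.
#' @param path output file path; the separator follows the extension as in
#'   [read_counts()].
#' @return `path`, invisibly.
#' @export
write_counts <- function(trialsets, path) {
  if (inherits(trialsets, "trial_set")) trialsets <- list(trialsets)
  if (!is.list(trialsets) ||
      !all(vapply(trialsets, inherits, logical(1), "trial_set")))
    stop("`trialsets` must be a trial_set or a list of them", call. = FALSE)
  rows <- lapply(trialsets, function(ts) {
    do.call(rbind, lapply(ts$replicates, function(r) {
      days <- r$census_days
      counts <- r$counts
      if (!length(days)) { days <- 1L; counts <- 0L }
      data.frame(species = ts$species, treatment = ts$treatment,
                 replicate = r$replicate_id,
                 temperature_C = ts$temperature_C,
                 day = days, n_germinated = counts,
                 seeds_sown = r$seeds_sown,
                 viable_ungerminated = r$viable_ungerminated,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
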