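#' Relative frequency of germination per census day
#'
#' Daily counts divided by the total number of germinated seeds, so the
#' frequencies sum to one and define a probability distribution of
#' germination events over census days. Zero-count days contribute zero.
#'
#' @param tc a [time_course()] or a bare vector of daily counts.
#' @return Numeric vector of relative frequencies, one per census day.
#' @export
relative_frequencies <- function(tc) {
  n <- .counts_of(tc)
  total <- sum(n)
  if (total < 1L)
    stop("relative frequencies are undefined: no germinated seeds", call. = FALSE)
  n / total
}

#' Asynchrony index: Shannon entropy of germination timing (bits)
#'
#' The entropy, in base 2, of the relative-frequency distribution of
#' germination events over census days:
#' \deqn{\bar{E} = -\sum_i f_i \log_2 f_i,}
#' with \eqn{0 \log_2 0 = 0}. It is 0 when all seeds germinate on a single
#' day and grows as germination spreads over more days; for k days with
#' germination it is at most \eqn{\log_2 k}, attained by uniform counts.
#' Dormant seed lots typically spread germination over many days and so
#' score high; dormancy release compresses the distribution and lowers the
#' index.
#'
#' @inheritParams relative_frequencies
#' @return Non-negative entropy in bits. Undefined (error) when no seed
#'   germinated.
#' @seealso [synchrony_index()] for the complementary pairwise-overlap index.
#' @export
asynchrony_index <- function(tc) {
  f <- relative_frequencies(tc)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Number of unordered pairs among n items
#'
#' \eqn{C(n,2) = n(n-1)/2}, the number of ways two seeds can be drawn from
#' the \eqn{n} that germinated on a given day. Zero for n in \{0, 1\}.
#'
#' @param n non-negative integer (vectorised).
#' @return `n * (n - 1) / 2`, exact.
#' @export
pair_combinations <- function(n) {
  if (!is.numeric(n) || anyNA(n))
    stop("`n` must be numeric and free of NA", call. = FALSE)
  if (any(n < 0))
    stop("`n` must be non-negative", call. = FALSE)
  if (any(n != trunc(n)))
    stop("`n` must be integer-valued", call. = FALSE)
  n * (n - 1) / 2
}

#' Synchrony index Z: fraction of germinated-seed pairs sharing a day
#'
#' \deqn{Z = \frac{\sum_i C(n_i, 2)}{C(N, 2)}, \qquad N = \sum_i n_i,}
#' the proportion, among all unordered pairs of germinated seeds in the
#' replicate, of pairs that completed germination on the same census day.
#' Z equals 1 when all seeds germinate on one day and 0 when no two seeds
#' ever share a day. It is defined only when at least one pair exists
#' (N >= 2); with fewer than two germinated seeds the index is undefined
#' and an error is raised rather than a silent 0, so callers can flag the
#' replicate as excluded.
#'
#' @inheritParams relative_frequencies
#' @return Z in \[0, 1\].
#' @export
synchrony_index <- function(tc) {
  n <- .counts_of(tc)
  total <- sum(n)
  if (total < 2L)
    stop("synchrony index is undefined: fewer than two germinated seeds",
         call. = FALSE)
  sum(pair_combinations(n)) / pair_combinations(total)
}

#' Final germination fraction of a replicate
#'
#' @param tc a [time_course()].
#' @param basis `"sown"` divides total germinated seeds by seeds sown;
#'   `"viable"` divides by germinated + viable ungerminated seeds (the
#'   crush-test denominator, which discounts dead seeds).
#' @return Fraction in \[0, 1\].
#' @export
germination_fraction <- function(tc, basis = c("sown", "viable")) {
  basis <- match.arg(basis)
  if (!inherits(tc, "time_course"))
    stop("`tc` must be a time_course (the denominator needs seeds_sown)",
         call. = FALSE)
  n_germ <- sum(tc$counts)
  if (basis == "sown") {
    n_germ / tc$seeds_sown
  } else {
    denom <- n_germ + tc$viable_ungerminated
    if (denom < 1L)
      stop("germination fraction on the viable basis is undefined: ",
           "no germinated or viable seeds", call. = FALSE)
    n_germ / denom
  }
}
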