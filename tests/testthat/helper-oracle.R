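# Independent oracle for the synchrony index: expand the census into one
# day label per germinated seed and count, by explicit enumeration over all
# unordered pairs, the fraction that share a day. Stays independent of the
# combinatorial formula it checks.
enumerate_pair_fraction <- function(counts) {
  days <- rep(seq_along(counts), counts)
  n <- length(days)
  stopifnot(n >= 2)
  same <- (sum(outer(days, days, "==")) - n) / 2
  same / (n * (n - 1) / 2)
}

# random census count vector with 2 <= total <= max_total
random_counts <- function(max_days = 10, max_total = 60) {
  repeat {
    k <- sample.int(max_days, 1)
    x <- stats::rpois(k, lambda = stats::runif(1, 0.5, 6))
    if (sum(x) >= 2 && sum(x) <= max_total) return(x)
  }
}

default_thermal <- function() thermal_model(Tb = 0, theta50 = 60,
                                            theta_sigma = 0.15)
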