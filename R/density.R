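# Analytic tract-length model: exponential mixture over migrant entry
# times, with a neighbor-merging correction for same-ancestry adjacency.

# Piecewise-constant pool ancestry fractions between migration events.
# Returns data.frame(upper, lower, one column per ancestry): the pool
# composition seen by a meiosis occurring at lineage time s in
# (lower, upper]; the event at `upper` is included (a migrant cohort is
# part of the pool of its own generation).
pool_fractions <- function(history) {
  ev <- history_events(history)
  times <- sort(unique(ev$t), decreasing = TRUE)
  A <- history$ancestries
  q <- setNames(numeric(length(A)), A)
  out <- matrix(0, nrow = length(times), ncol = length(A),
                dimnames = list(NULL, A))
  for (k in seq_along(times)) {
    sel <- ev$t == times[k]
    M <- sum(ev$m[sel])
    q <- q * (1 - M)
    q[ev$ancestry[sel]] <- q[ev$ancestry[sel]] + ev$m[sel]
    out[k, ] <- q
  }
  lower <- c(times[-1], 0)
  data.frame(upper = times, lower = lower, out, check.names = FALSE)
}

# Mean pool fraction of `ancestry` over lineage time (0, t]: the expected
# probability that the material on the far side of a junction formed on an
# entry-time-t lineage is of the same ancestry.
mean_pool_fraction <- function(pf, ancestry, t) {
  ov <- pmax(0, pmin(pf$upper, t) - pf$lower)
  sum(ov * pf[[ancestry]]) / t
}

# Per-entry tract-termination rates (per Morgan).  correction = "neighbor"
# applies r = t * (1 - Qbar); "none" keeps r = t.  rate_offset shifts the
# meiosis count (0 default; -1 gives the t-1 convention).
entry_rates <- function(history, correction = c("neighbor", "none"),
                        rate_offset = 0) {
  correction <- match.arg(correction)
  e <- entry_distribution(history)
  pf <- pool_fractions(history)
  r <- pmax(e$t + rate_offset, 1e-6)
  if (correction == "neighbor") {
    qbar <- vapply(seq_len(nrow(e)),
                   function(i) mean_pool_fraction(pf, e$ancestry[i], e$t[i]),
                   0)
    r <- pmax(r * (1 - qbar), 1e-6)
  }
  e$rate <- r
  e
}

#' Expected ancestry tract-length density under a migration history
#'
#' The length (in Morgans) of an ancestry-`a` tract is modelled as an
#' exponential mixture over migrant entry times: material that entered
#' `t` generations ago has passed through `t` meioses, giving junctions at
#' rate `t` per Morgan; a junction terminates the tract only when the
#' material on its far side is of a different ancestry, which thins the
#' rate to `r(a,t) = t * (1 - Qbar_a(t))` where `Qbar_a(t)` is the mean
#' pool fraction of ancestry `a` over those `t` generations
#' (`correction = "none"` drops the thinning).  Mixture weights are
#' proportional to `p(a,t) * r(a,t)` (tract counts), and the expected
#' number of tracts per haploid Morgan is `lambda_a = sum_t p(a,t) *
#' r(a,t)`.
#'
#' @param history a `migration_history`.
#' @param ancestry ancestry label present in the history.
#' @param correction same-ancestry adjacency correction (default
#'   `"neighbor"`).
#' @param rate_offset added to the meiosis count before thinning (0 by
#'   default; `-1` selects the `t-1` convention).
#' @return object of class `tract_density`: a function `f(x)` of tract
#'   length in Morgans, with the mixture components in attribute
#'   `components` (entry time, weight, rate) and the per-Morgan tract
#'   count in attribute `tracts_per_morgan`.
#' @examples
#' h <- build_history(c(EUR = 1), pulses = data.frame(t = 10, ancestry = "AFR", m = 0.2))
#' f <- expected_tract_density(h, "AFR")
#' 1 / attr(f, "components")$rate  # mean tract length, Morgans
#' @export
expected_tract_density <- function(history, ancestry,
                                   correction = c("neighbor", "none"),
                                   rate_offset = 0) {
  stopifnot(inherits(history, "migration_history"))
  if (!ancestry %in% history$ancestries)
    stop("ancestry '", ancestry, "' absent from history")
  e <- entry_rates(history, correction, rate_offset)
  e <- e[e$ancestry == ancestry & e$p > 0, , drop = FALSE]
  if (nrow(e) == 0) stop("ancestry '", ancestry, "' has no migrant entries")
  w <- e$p * e$rate
  lam <- sum(w)
  w <- w / lam
  rates <- e$rate
  f <- function(x) {
    vapply(x, function(xi) sum(w * rates * exp(-rates * xi)), 0)
  }
  structure(f, class = c("tract_density", "function"),
            components = data.frame(t = e$t, weight = w, rate = rates),
            tracts_per_morgan = lam, ancestry = ancestry)
}

#' Bin interior ancestry tracts into a length histogram
#'
#' Censored (chromosome-end) tracts are excluded from the binned counts
#' and tallied separately; tracts shorter than the first bin edge are
#' dropped.  Default bins are log-spaced from 5 to 250 cM with a final
#' open bin extending to the longest chromosome.
#'
#' @param tracts a `tract_set`.
#' @param bin_edges_cM increasing bin edges in cM; a final edge at the
#'   maximum chromosome length is appended automatically.
#' @param ancestries ancestries to tabulate (default: all present).
#' @param n_bins number of log-spaced default bins between 5 and 250 cM.
#' @return object of class `tract_histogram`: list with `edges_cM`,
#'   `counts` (ancestry x bin matrix), `n_hap`, `chrom_lengths_cM`,
#'   `n_censored`.
#' @export
tract_histogram <- function(tracts, bin_edges_cM = NULL, ancestries = NULL,
                            n_bins = 16) {
  stopifnot(inherits(tracts, "tract_set"))
  lens <- attr(tracts, "chrom_lengths_cM")
  maxL <- max(lens)
  if (is.null(bin_edges_cM))
    bin_edges_cM <- exp(seq(log(5), log(250), length.out = n_bins))
  if (is.unsorted(bin_edges_cM, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  edges <- bin_edges_cM[bin_edges_cM < maxL]
  edges <- c(edges, maxL)
  if (length(edges) < 2) stop("no usable bins below the chromosome length")
  if (is.null(ancestries)) ancestries <- sort(unique(tracts$ancestry))
  interior <- tracts$censored == "none"
  counts <- matrix(0L, nrow = length(ancestries), ncol = length(edges) - 1,
                   dimnames = list(ancestries, NULL))
  for (a in ancestries) {
    x <- tracts$length_cM[interior & tracts$ancestry == a]
    x <- x[x >= edges[1] & x < maxL]
    counts[a, ] <- hist(x, breaks = edges, plot = FALSE)$counts
  }
  structure(list(edges_cM = edges, counts = counts,
                 n_hap = attr(tracts, "n_hap"),
                 chrom_lengths_cM = lens,
                 n_censored = sum(!interior)),
            class = "tract_histogram")
}

#' @export
print.tract_histogram <- function(x, ...) {
  cat("Tract-length histogram:", ncol(x$counts), "bins over [",
      round(x$edges_cM[1], 2), ",", round(max(x$edges_cM), 1), ") cM\n")
  cat("  haploid genomes:", x$n_hap, " censored tracts excluded:",
      x$n_censored, "\n")
  tot <- rowSums(x$counts)
  for (a in rownames(x$counts)) cat(sprintf("  %s: %d tracts\n", a, tot[a]))
  invisible(x)
}

#' Expected interior tract counts per histogram bin
#'
#' For each ancestry and bin, the expected number of interior (uncensored)
#' tracts among `n_hap` haploid genomes:
#' `lambda_{a,b} = n_hap * sum_c sum_t p(a,t) r(a,t)
#'   int_bin r e^{-r x} (L_c - x)_+ dx`,
#' where the `(L_c - x)_+` factor counts the start positions at which a
#' tract of length `x` fits inside a chromosome of length `L_c` with both
#' ends interior.
#'
#' @param history a `migration_history`.
#' @param histogram a `tract_histogram` (its counts are ignored; only the
#'   bin structure, `n_hap` and chromosome lengths are used).
#' @inheritParams expected_tract_density
#' @return matrix of expected counts, same shape as `histogram$counts`.
#' @export
expected_bin_counts <- function(history, histogram,
                                correction = c("neighbor", "none"),
                                rate_offset = 0) {
  stopifnot(inherits(history, "migration_history"),
            inherits(histogram, "tract_histogram"))
  e <- entry_rates(history, correction, rate_offset)
  edges <- histogram$edges_cM / 100           # Morgans
  Lc <- histogram$chrom_lengths_cM / 100
  A <- rownames(histogram$counts)
  lam <- matrix(0, nrow = length(A), ncol = ncol(histogram$counts),
                dimnames = dimnames(histogram$counts))
  for (a in A) {
    ea <- e[e$ancestry == a & e$p > 0, , drop = FALSE]
    if (nrow(ea) == 0) next
    for (i in seq_len(nrow(ea))) {
      r <- ea$rate[i]
      contrib <- numeric(ncol(lam))
      for (L in Lc) {
        lo <- pmin(edges[-length(edges)], L)
        hi <- pmin(edges[-1], L)
        # int_a^b r e^{-rx} (L - x) dx, closed form
        I <- exp(-r * lo) * (L - lo) - exp(-r * hi) * (L - hi) -
          (exp(-r * lo) - exp(-r * hi)) / r
        contrib <- contrib + pmax(I, 0)
      }
      lam[a, ] <- lam[a, ] + histogram$n_hap * ea$p[i] * r * contrib
    }
  }
  lam
}

#' Poisson log-likelihood of observed tract counts
#'
#' `logL = sum_{a,b} [n log(lambda) - lambda - log(n!)]`; a bin with
#' `lambda = 0` and `n > 0` yields `-Inf`.
#'
#' @param observed a `tract_histogram` or a count matrix.
#' @param expected matrix of expected counts with the same shape.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(observed, expected) {
  n <- if (inherits(observed, "tract_histogram")) observed$counts else observed
  if (!identical(dim(n), dim(expected)))
    stop("observed and expected counts have different shapes")
  lam <- expected
  if (any(lam == 0 & n > 0)) return(-Inf)
  ok <- lam > 0
  sum(n[ok] * log(lam[ok]) - lam[ok] - lgamma(n[ok] + 1)) - sum(lam[!ok])
}
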