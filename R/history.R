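#' Build a multi-pulse migration history
#'
#' A migration history specifies, for every generation `t` counted
#' backwards from the present (`t = 1` is the parental generation,
#' `t = T_max` the founding event), the fraction of the population replaced
#' by new migrants of each ancestry.  The founding generation must be fully
#' specified (fractions summing to one); later pulses are single-generation
#' influxes.  Histories may optionally carry a sex split: separate female
#' and male migrant fractions whose average is the overall fraction.
#'
#' Pulse times may be non-integer (the analytic tract model is defined for
#' continuous times); forward simulation requires integer times because a
#' generation is a discrete meiosis.
#'
#' @param founding named numeric vector of founding ancestry fractions
#'   (must sum to 1), or for a sexed history a list with elements `female`
#'   and `male`, each a named simplex vector.
#' @param T_max founding depth in generations before present (integer >= 1).
#' @param pulses optional `data.frame` with columns `t`, `ancestry`, `m`
#'   (or `m_f`/`m_m` for a sexed history), one row per pulse; pulse times
#'   must satisfy `0 < t < T_max`.
#' @return An object of class `migration_history`.
#' @examples
#' h <- build_history(c(EUR = 0.8, NAM = 0.2), T_max = 15,
#'                    pulses = data.frame(t = 5, ancestry = "AFR", m = 0.1))
#' entry_distribution(h)
#' @export
build_history <- function(founding, T_max = 15, pulses = NULL) {
  if (!is.numeric(T_max) || length(T_max) != 1L || T_max < 1 ||
      T_max != round(T_max))
    stop("'T_max' must be a single integer >= 1")
  T_max <- as.integer(T_max)

  sexed <- is.list(founding) && !is.data.frame(founding)
  if (sexed) {
    if (!all(c("female", "male") %in% names(founding)))
      stop("sexed founding must be list(female = ..., male = ...)")
    f_f <- founding$female
    f_m <- founding$male
    check_simplex(f_f, "founding (female)")
    check_simplex(f_m, "founding (male)")
    if (!setequal(names(f_f), names(f_m)))
      stop("female and male founding fractions must name the same ancestries")
    f_m <- f_m[names(f_f)]
    fnd <- (f_f + f_m) / 2
  } else {
    check_simplex(founding, "founding")
    fnd <- founding
    f_f <- f_m <- NULL
  }

  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses, stringsAsFactors = FALSE)
    if (!all(c("t", "ancestry") %in% names(pulses)))
      stop("'pulses' needs columns t, ancestry and m (or m_f/m_m)")
    if (sexed) {
      if (!all(c("m_f", "m_m") %in% names(pulses)))
        stop("pulses of a sexed history need columns m_f and m_m")
      pulses$m <- (pulses$m_f + pulses$m_m) / 2
      if (any(pulses$m_f < 0 | pulses$m_f >= 1 | pulses$m_m < 0 |
              pulses$m_m >= 1))
        stop("sex-specific pulse magnitudes must lie in [0, 1)")
    } else if (!("m" %in% names(pulses))) {
      stop("'pulses' needs a magnitude column 'm'")
    }
    if (any(pulses$m <= 0 | pulses$m >= 1))
      stop("pulse magnitudes must lie in (0, 1)")
    if (any(pulses$t <= 0 | pulses$t >= T_max))
      stop("pulse times must satisfy 0 < t < T_max (the founding ",
           "generation is specified through 'founding')")
    if (anyDuplicated(pulses[c("t", "ancestry")]))
      stop("duplicate (t, ancestry) pulse entries")
    tot <- tapply(pulses$m, pulses$t, sum)
    if (any(tot > 1 + 1e-12))
      stop("total migrant fraction exceeds 1 at t = ",
           paste(names(tot)[tot > 1 + 1e-12], collapse = ", "))
    if (sexed) {
      for (col in c("m_f", "m_m")) {
        tot <- tapply(pulses[[col]], pulses$t, sum)
        if (any(tot > 1 + 1e-12))
          stop("sex-specific migrant fraction exceeds 1 at some generation")
      }
    }
  }

  ancestries <- union(names(fnd), if (!is.null(pulses)) pulses$ancestry)
  structure(list(ancestries = ancestries, T_max = T_max,
                 founding = fnd, founding_f = f_f, founding_m = f_m,
                 pulses = pulses, sexed = sexed),
            class = "migration_history")
}

check_simplex <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " fractions must be a named vector")
  if (any(x < 0) || any(x > 1))
    stop(what, " fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-8)
    stop(what, " fractions must sum to 1 (got ", format(sum(x)), ")")
  invisible(x)
}

#' @export
print.migration_history <- function(x, ...) {
  cat("Migration history:", if (x$sexed) "(sexed)" else "", "\n")
  cat("  founding at T =", x$T_max, "generations:",
      paste(sprintf("%s %.3f", names(x$founding), x$founding),
            collapse = ", "), "\n")
  if (!is.null(x$pulses)) {
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  pulse: %s m = %.3f at t = %g\n", x$pulses$ancestry[i],
                  x$pulses$m[i], x$pulses$t[i]))
  }
  invisible(x)
}

#' Migrant-fraction matrix of an integer-time history
#'
#' Rows are generations `t = 1..T_max` (backwards from the present),
#' columns ancestries.  Only defined when all pulse times are integers;
#' this is the representation the forward simulator consumes.
#'
#' @param history a `migration_history`.
#' @param sex `NULL` for the overall fractions, `"female"` or `"male"` for
#'   the sex-specific fractions of a sexed history.
#' @return numeric matrix `T_max x n_ancestries`.
#' @export
history_matrix <- function(history, sex = NULL) {
  stopifnot(inherits(history, "migration_history"))
  p <- history$pulses
  if (!is.null(p) && any(p$t != round(p$t)))
    stop("history has non-integer pulse times; forward simulation needs ",
         "integer generations")
  A <- history$ancestries
  m <- matrix(0, nrow = history$T_max, ncol = length(A),
              dimnames = list(NULL, A))
  if (is.null(sex)) {
    fnd <- history$founding
    mcol <- "m"
  } else {
    if (!history$sexed) stop("history has no sex split")
    sex <- match.arg(sex, c("female", "male"))
    fnd <- if (sex == "female") history$founding_f else history$founding_m
    mcol <- if (sex == "female") "m_f" else "m_m"
  }
  m[history$T_max, names(fnd)] <- unname(fnd)
  if (!is.null(p))
    for (i in seq_len(nrow(p)))
      m[p$t[i], p$ancestry[i]] <- m[p$t[i], p$ancestry[i]] + p[[mcol]][i]
  m
}

# All migration events of a history as a table ordered by decreasing time:
# the founding fractions plus each pulse, with per-event magnitude.
# Internal canonical form for the analytic tract model (times may be
# continuous there).
history_events <- function(history) {
  ev <- data.frame(t = rep(history$T_max, length(history$founding)),
                   ancestry = names(history$founding),
                   m = unname(history$founding),
                   stringsAsFactors = FALSE)
  if (!is.null(history$pulses))
    ev <- rbind(ev, history$pulses[c("t", "ancestry", "m")])
  ev[order(-ev$t, ev$ancestry), , drop = FALSE]
}

#' Entry-time distribution of a history
#'
#' Probability that a present-day locus descends from a migrant of
#' ancestry `a` who entered the population `t` generations ago:
#' `p(a, t) = m(t, a) * S(t)` with survival
#' `S(t) = prod over later events s < t of (1 - total migrant fraction at s)`.
#'
#' @param history a `migration_history`.
#' @return `data.frame` with columns `ancestry`, `t`, `m`, `p` (class
#'   `entry_distribution`); `p` sums to one.
#' @export
entry_distribution <- function(history) {
  stopifnot(inherits(history, "migration_history"))
  ev <- history_events(history)
  times <- sort(unique(ev$t), decreasing = TRUE)
  tot <- vapply(times, function(tt) sum(ev$m[ev$t == tt]), 0)
  # survival through all events strictly more recent than t
  surv <- vapply(ev$t, function(tt) prod(1 - tot[times < tt]), 0)
  ev$p <- ev$m * surv
  stopifnot(abs(sum(ev$p) - 1) < 1e-10)
  class(ev) <- c("entry_distribution", "data.frame")
  ev
}

#' Mean global ancestry fractions implied by a history
#'
#' Sums the entry distribution over entry times; equals the expected
#' present-day genome-wide ancestry fraction per ancestry.
#'
#' @param history a `migration_history`.
#' @return named numeric vector on the simplex.
#' @export
expected_ancestry <- function(history) {
  e <- entry_distribution(history)
  p <- tapply(e$p, e$ancestry, sum)
  out <- setNames(rep(0, length(history$ancestries)), history$ancestries)
  out[names(p)] <- p
  out
}
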