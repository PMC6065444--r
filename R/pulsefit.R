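# Multi-pulse admixture-model fitting from tract-length histograms.

#' The five competing admixture models
#'
#' All models share a founding admixture event between `founding[1]`
#' (e.g. European) and `founding[2]` (e.g. Native American) ancestry at a
#' fixed time `G0` generations ago, followed by a first pulse of
#' `pulse_ancestry` (e.g. African) admixture.  The models add further
#' pulses:
#' \describe{
#'   \item{M1}{founding + first AFR pulse (3 parameters)}
#'   \item{M2}{M1 + second AFR pulse (5)}
#'   \item{M3}{M1 + second NAM pulse (5)}
#'   \item{M4}{M1 + second AFR and second NAM pulse (7)}
#'   \item{M5}{M4 + second EUR pulse (9)}
#' }
#' Second pulses of an ancestry are constrained to be more recent than the
#' first (the founding event for EUR/NAM).  Free parameters are the
#' founding fraction of `founding[2]`, and each pulse's time and magnitude.
#'
#' @param founding character vector of the two founding ancestries.
#' @param pulse_ancestry ancestry of the post-founding pulse(s).
#' @return named list of model specifications (class `admixture_model`).
#' @export
admixture_models <- function(founding = c("EUR", "NAM"),
                             pulse_ancestry = "AFR") {
  A1 <- pulse_ancestry
  E <- founding[1]
  N <- founding[2]
  p <- function(label, ancestry, after) {
    data.frame(label = label, ancestry = ancestry, after = after,
               stringsAsFactors = FALSE)
  }
  mk <- function(id, pulses) {
    structure(list(id = id, founding = founding, pulses = pulses,
                   n_par = 1L + 2L * nrow(pulses)),
              class = "admixture_model")
  }
  a1 <- p(paste0(A1, "1"), A1, NA)
  a2 <- p(paste0(A1, "2"), A1, paste0(A1, "1"))
  n2 <- p(paste0(N, "2"), N, NA)
  e2 <- p(paste0(E, "2"), E, NA)
  list(M1 = mk("M1", a1),
       M2 = mk("M2", rbind(a1, a2)),
       M3 = mk("M3", rbind(a1, n2)),
       M4 = mk("M4", rbind(a1, a2, n2)),
       M5 = mk("M5", rbind(a1, a2, n2, e2)))
}

#' @export
print.admixture_model <- function(x, ...) {
  cat("Admixture model", x$id, "-", x$n_par, "free parameters\n")
  cat("  founding:", x$founding[1], "+", x$founding[2], "\n")
  cat("  pulses:", paste(x$pulses$label, collapse = ", "), "\n")
  invisible(x)
}

# Parameter vector layout: theta_raw = (f2, then per pulse (t or v, m)).
# A pulse with an `after` link uses v in (0,1), t = t_min + (t_after -
# t_min) * v, keeping it strictly more recent than its predecessor.
model_bounds <- function(spec, t_range = c(2, 15), m_range = c(0.005, 0.6)) {
  lo <- 0.005
  hi <- 0.995
  nm <- "f2"
  for (i in seq_len(nrow(spec$pulses))) {
    if (is.na(spec$pulses$after[i])) {
      lo <- c(lo, t_range[1] + 1e-3)
      hi <- c(hi, t_range[2] - 1e-3)
    } else {
      lo <- c(lo, 1e-3)
      hi <- c(hi, 1 - 1e-3)
    }
    lo <- c(lo, m_range[1])
    hi <- c(hi, m_range[2])
    nm <- c(nm, paste0(c("t_", "m_"), spec$pulses$label[i]))
  }
  list(lower = lo, upper = hi, names = nm)
}

# raw parameters -> natural parameters (all times in generations)
theta_natural <- function(spec, theta, t_range = c(2, 15)) {
  out <- theta
  for (i in seq_len(nrow(spec$pulses))) {
    it <- 2 * i
    if (!is.na(spec$pulses$after[i])) {
      j <- match(spec$pulses$after[i], spec$pulses$label)
      t_after <- out[2 * j]   # natural by construction (predecessors first)
      out[it] <- t_range[1] + (t_after - t_range[1]) * theta[it]
    }
  }
  out
}

# natural parameters -> migration history
theta_history <- function(spec, theta_nat, G0 = 15) {
  f2 <- theta_nat[1]
  founding <- setNames(c(1 - f2, f2), spec$founding)
  np <- nrow(spec$pulses)
  pulses <- data.frame(t = theta_nat[2 * seq_len(np)],
                       ancestry = spec$pulses$ancestry,
                       m = theta_nat[2 * seq_len(np) + 1],
                       stringsAsFactors = FALSE)
  build_history(founding, T_max = G0, pulses = pulses)
}

#' Fit an admixture model to a tract-length histogram
#'
#' Maximizes the Poisson log-likelihood of the observed interior
#' tract-length counts ([poisson_loglik()]) over the model's free
#' parameters, using bounded quasi-Newton (`L-BFGS-B`) from `n_restarts`
#' random starting points drawn uniformly within the parameter bounds
#' (pulse times in (2, `G0`), magnitudes in (0.005, 0.6)).  The founding
#' time `G0` is fixed (15 generations by default).  Confidence intervals
#' (68.3% by default, matching one standard error) are obtained by
#' parametric bootstrap: counts are resampled from the fitted expectations
#' and refitted.
#'
#' @param histogram a `tract_histogram` with at least one interior tract
#'   of every modelled ancestry.
#' @param model an `admixture_model`, or the id (`"M1"`..`"M5"`) of one of
#'   [admixture_models()] built for the ancestries of `histogram`.
#' @param n_restarts random restarts (the best is kept).
#' @param seed integer seed; required, fits are deterministic given it.
#' @param G0 founding time in generations.
#' @param correction,rate_offset passed to [expected_bin_counts()].
#' @param ci `"none"` or `"bootstrap"`.
#' @param B bootstrap replicates for `ci = "bootstrap"`.
#' @param ci_level confidence level (default 0.683).
#' @param anchor_year optional calendar anchor (year of sampling) used by
#'   `summary()` to convert generations to CE dates.
#' @param gen_time years per generation for the calendar conversion.
#' @return object of class `pulse_fit`.
#' @seealso [compare_models()], [generations_to_years()]
#' @export
fit_pulse_model <- function(histogram, model = "M1", n_restarts = 100, seed,
                            G0 = 15, correction = c("neighbor", "none"),
                            rate_offset = 0, ci = c("none", "bootstrap"),
                            B = 100, ci_level = 0.683, anchor_year = NULL,
                            gen_time = 29) {
  stopifnot(inherits(histogram, "tract_histogram"))
  if (missing(seed)) stop("'seed' is required")
  correction <- match.arg(correction)
  ci <- match.arg(ci)
  if (is.character(model)) {
    anc <- rownames(histogram$counts)
    founding <- c(intersect(c("EUR"), anc), intersect(c("NAM"), anc))
    if (length(founding) != 2)
      stop("model ids need histogram ancestries EUR and NAM; ",
           "pass an admixture_model spec for other labels")
    pulse_anc <- setdiff(anc, founding)[1]
    model <- admixture_models(founding, pulse_anc)[[model]]
    if (is.null(model)) stop("unknown model id")
  }
  stopifnot(inherits(model, "admixture_model"))
  modelled <- union(model$founding, model$pulses$ancestry)
  missing_anc <- setdiff(modelled, rownames(histogram$counts))
  if (length(missing_anc))
    stop("histogram lacks ancestries: ", paste(missing_anc, collapse = ", "))
  if (any(rowSums(histogram$counts)[modelled] == 0))
    stop("histogram has no interior tracts for some modelled ancestry")

  b <- model_bounds(model, t_range = c(2, G0))
  obs <- histogram$counts[modelled, , drop = FALSE]
  sub_hist <- histogram
  sub_hist$counts <- obs

  negll <- make_negll(model, sub_hist, G0, correction, rate_offset)

  set.seed(seed)
  best <- NULL
  n_failed <- 0L
  for (r in seq_len(n_restarts)) {
    start <- b$lower + runif(length(b$lower)) * (b$upper - b$lower)
    o <- try(optim(start, negll, method = "L-BFGS-B", lower = b$lower,
                   upper = b$upper,
                   control = list(maxit = 300, factr = 1e8)),
             silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$value) ||
        o$value >= 1e10 / 2) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts failed to converge for model ",
         model$id)

  theta_raw <- setNames(best$par, b$names)
  theta_nat <- setNames(theta_natural(model, best$par, c(2, G0)), b$names)
  history <- theta_history(model, theta_nat, G0 = G0)
  lambda <- expected_bin_counts(history, sub_hist, correction = correction,
                                rate_offset = rate_offset)
  fit <- structure(list(model = model, coefficients = theta_nat,
                        theta_raw = theta_raw, history = history,
                        logLik = -best$value, convergence = best$convergence,
                        n_restarts = n_restarts, n_failed = n_failed,
                        histogram = sub_hist, lambda = lambda,
                        correction = correction, rate_offset = rate_offset,
                        G0 = G0, seed = seed, ci = NULL,
                        ci_level = ci_level, anchor_year = anchor_year,
                        gen_time = gen_time),
                   class = "pulse_fit")
  if (ci == "bootstrap") fit$ci <- bootstrap_ci(fit, B = B, level = ci_level)
  fit
}

# Parametric bootstrap: resample bin counts from the fitted expectations,
# refit from the fitted optimum (plus jittered starts), take percentile
# intervals on the natural scale.  Intervals are widened, if necessary, to
# contain the point estimate.
bootstrap_ci <- function(fit, B = 100, level = 0.683, n_starts = 3) {
  b <- model_bounds(fit$model, t_range = c(2, fit$G0))
  est <- matrix(NA_real_, nrow = B, ncol = length(fit$theta_raw))
  for (i in seq_len(B)) {
    hist_b <- fit$histogram
    hist_b$counts[] <- rpois(length(fit$lambda), fit$lambda)
    negll <- make_negll(fit$model, hist_b, fit$G0, fit$correction,
                        fit$rate_offset)
    bb <- NULL
    for (s in seq_len(n_starts)) {
      start <- if (s == 1) fit$theta_raw else
        pmin(pmax(fit$theta_raw * exp(rnorm(length(b$lower), 0, 0.1)),
                  b$lower), b$upper)
      o <- try(optim(start, negll, method = "L-BFGS-B", lower = b$lower,
                     upper = b$upper,
                     control = list(maxit = 200, factr = 1e8)),
               silent = TRUE)
      if (inherits(o, "try-error") || !is.finite(o$value)) next
      if (is.null(bb) || o$value < bb$value) bb <- o
    }
    if (!is.null(bb))
      est[i, ] <- theta_natural(fit$model, bb$par, c(2, fit$G0))
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  a <- (1 - level) / 2
  lo <- apply(est, 2, quantile, probs = a)
  hi <- apply(est, 2, quantile, probs = 1 - a)
  ci <- cbind(lower = pmin(lo, fit$coefficients),
              upper = pmax(hi, fit$coefficients))
  rownames(ci) <- names(fit$coefficients)
  ci
}

#' @export
print.pulse_fit <- function(x, digits = 3, ...) {
  cat("Admixture pulse model", x$model$id, " logLik:",
      format(x$logLik, digits = 7), "\n")
  cat("  founding at", x$G0, "generations;", x$n_restarts, "restarts (",
      x$n_failed, "failed )\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pulse_fit <- function(object, ...) object$coefficients

#' @export
logLik.pulse_fit <- function(object, ...) {
  structure(object$logLik, df = object$model$n_par,
            nobs = length(object$histogram$counts), class = "logLik")
}

#' @export
fitted.pulse_fit <- function(object, ...) object$lambda

#' @export
residuals.pulse_fit <- function(object, type = c("pearson", "response"),
                                ...) {
  type <- match.arg(type)
  r <- object$histogram$counts - object$lambda
  if (type == "pearson") r <- r / sqrt(pmax(object$lambda, 1e-12))
  r
}

#' @export
confint.pulse_fit <- function(object, parm, level = 0.683, B = 100, ...) {
  ci <- object$ci
  if (is.null(ci) || !isTRUE(all.equal(level, object$ci_level))) {
    set.seed(object$seed + 1L)
    ci <- bootstrap_ci(object, B = B, level = level)
  }
  rownames(ci) <- names(object$coefficients)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.pulse_fit <- function(object, type = c("counts", "density"),
                              ancestry = NULL, ...) {
  type <- match.arg(type)
  if (type == "counts") return(object$lambda)
  if (is.null(ancestry)) ancestry <- rownames(object$histogram$counts)[1]
  expected_tract_density(object$history, ancestry,
                         correction = object$correction,
                         rate_offset = object$rate_offset)
}

#' @export
simulate.pulse_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    h <- object$histogram
    h$counts[] <- rpois(length(object$lambda), object$lambda)
    out[[i]] <- h
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
summary.pulse_fit <- function(object, ...) {
  np <- nrow(object$model$pulses)
  tab <- data.frame(pulse = object$model$pulses$label,
                    t = object$coefficients[2 * seq_len(np)],
                    m = object$coefficients[2 * seq_len(np) + 1])
  if (!is.null(object$ci)) {
    tab$t_lo <- object$ci[2 * seq_len(np), "lower"]
    tab$t_hi <- object$ci[2 * seq_len(np), "upper"]
  }
  if (!is.null(object$anchor_year)) {
    tab$year_CE <- generations_to_years(tab$t, object$anchor_year,
                                        object$gen_time)
  }
  structure(list(fit = object, pulses = tab), class = "summary.pulse_fit")
}

#' @export
print.summary.pulse_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPulses:\n")
  print(x$pulses, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.pulse_fit <- function(x, log = "y", ...) {
  edges <- x$histogram$edges_cM
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  anc <- rownames(x$histogram$counts)
  cols <- seq_along(anc) + 1
  obs <- x$histogram$counts
  ylim <- range(c(pmax(obs, 0.5), pmax(x$lambda, 0.5)))
  plot(NA, xlim = range(edges), ylim = ylim, log = paste0("x", log),
       xlab = "tract length (cM)", ylab = "tract count",
       main = paste("Model", x$model$id), ...)
  for (i in seq_along(anc)) {
    points(mid, pmax(obs[i, ], 0.5), col = cols[i], pch = 19)
    lines(mid, pmax(x$lambda[i, ], 0.5), col = cols[i])
  }
  graphics::legend("topright", legend = anc, col = cols, pch = 19, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Rank competing admixture-model fits
#'
#' Fits are ranked by log-likelihood (the model-choice criterion), with
#' the difference to the best model, parameter counts and AIC reported
#' alongside; exact ties are broken by fewer parameters, then model id.
#'
#' @param ... `pulse_fit` objects fitted to the same histogram, or a
#'   single list of them.
#' @return `data.frame` (class `pulse_model_comparison`) ordered by rank.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "pulse_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least two fits to compare")
  ref <- fits[[1]]$histogram
  for (f in fits) {
    stopifnot(inherits(f, "pulse_fit"))
    if (!isTRUE(all.equal(f$histogram$edges_cM, ref$edges_cM)) ||
        !identical(dim(f$histogram$counts), dim(ref$counts)) ||
        !isTRUE(all.equal(f$histogram$counts, ref$counts)))
      stop("fits were made on different histograms")
  }
  tab <- data.frame(model = vapply(fits, function(f) f$model$id, ""),
                    n_par = vapply(fits, function(f) f$model$n_par, 0L),
                    logLik = vapply(fits, function(f) f$logLik, 0))
  tab$AIC <- 2 * tab$n_par - 2 * tab$logLik
  ord <- order(-tab$logLik, tab$n_par, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_logLik <- tab$logLik - tab$logLik[1]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("pulse_model_comparison", "data.frame")
  tab
}

#' @export
print.pulse_model_comparison <- function(x, ...) {
  cat("Model comparison (ranked by log-likelihood):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Convert generations before present to calendar years
#'
#' `year = anchor_year - g * gen_time`; exact arithmetic, monotone in `g`.
#'
#' @param g generations before the anchor (numeric, may be a vector or an
#'   interval's endpoints).
#' @param anchor_year calendar year corresponding to `g = 0` (e.g. the
#'   sampling year).  There is no default: the anchor is a property of the
#'   data set.
#' @param gen_time years per generation (default 29).
#' @return calendar years CE, same shape as `g`.
#' @examples
#' generations_to_years(15, anchor_year = 1937)  # 1502
#' @export
generations_to_years <- function(g, anchor_year, gen_time = 29) {
  if (missing(anchor_year)) stop("'anchor_year' is required")
  if (any(g < 0)) stop("'g' must be non-negative")
  anchor_year - g * gen_time
}
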