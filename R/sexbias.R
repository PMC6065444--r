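# X-versus-autosome sex-bias statistics: compartment ancestry fractions,
# admixture difference ratios, paired signed-rank testing, and the
# mechanistic inversion to female/male source contributions.

#' Per-individual autosomal and X-chromosomal ancestry fractions
#'
#' Length-weighted ancestry fractions computed separately for the
#' autosomal and the X compartment of every individual.  Accepts a sexed
#' `simulated_cohort`, or separate autosomal and X tract sets (or
#' local-ancestry call sets, which are run through [extract_tracts()])
#' plus a metadata table.
#'
#' @param auto a sexed `simulated_cohort`, or autosomal tracts/calls.
#' @param x X-chromosome tracts/calls (ignored when `auto` is a cohort).
#' @param metadata `data.frame` with columns `individual`, `sex` (`"F"`/
#'   `"M"`) and optionally `group`.
#' @return `data.frame` of class `compartment_ancestry` with columns
#'   `individual`, `sex`, `group`, `ancestry`, `q_auto`, `q_x`.
#' @export
compartment_ancestry <- function(auto, x = NULL, metadata = NULL) {
  if (inherits(auto, "simulated_cohort")) {
    if (is.null(auto$tracts$compartment))
      stop("cohort has no X compartment; use simulate_sexed_cohort()")
    tr <- auto$tracts
    meta <- auto$individuals
    tr_a <- tr[tr$compartment == "auto", ]
    tr_x <- tr[tr$compartment == "X", ]
  } else {
    if (inherits(auto, "local_ancestry_calls")) auto <- extract_tracts(auto)
    if (inherits(x, "local_ancestry_calls")) x <- extract_tracts(x)
    stopifnot(inherits(auto, "tract_set"), inherits(x, "tract_set"))
    if (is.null(metadata)) stop("'metadata' is required")
    tr_a <- auto
    tr_x <- x
    meta <- metadata
  }
  ind_a <- tract_individual(tr_a)
  ind_x <- tract_individual(tr_x)
  # males must carry exactly one X haplotype
  males <- meta$individual[meta$sex == "M"]
  xh <- tapply(tr_x$haplotype, ind_x, function(h) length(unique(h)))
  bad <- intersect(names(xh)[xh > 1], as.character(males))
  if (length(bad))
    stop("male individual(s) with two X haplotypes: ",
         paste(bad, collapse = ", "))
  if (!setequal(unique(ind_a), unique(ind_x)))
    stop("individuals missing one compartment")
  ancestries <- sort(union(unique(tr_a$ancestry), unique(tr_x$ancestry)))
  qa <- proportions_by(tr_a, ind_a, ancestries)
  qx <- proportions_by(tr_x, ind_x, ancestries)
  ids <- rownames(qa)
  meta_idx <- match(ids, as.character(meta$individual))
  if (anyNA(meta_idx)) stop("metadata missing some individuals")
  out <- data.frame(
    individual = rep(ids, length(ancestries)),
    sex = rep(meta$sex[meta_idx], length(ancestries)),
    group = rep(if (!is.null(meta$group)) meta$group[meta_idx]
                else "all", length(ancestries)),
    ancestry = rep(ancestries, each = length(ids)),
    q_auto = as.vector(qa),
    q_x = as.vector(qx[ids, ancestries]),
    stringsAsFactors = FALSE)
  class(out) <- c("compartment_ancestry", "data.frame")
  out
}

#' Admixture difference ratio between X chromosome and autosomes
#'
#' For each ancestry, the difference `D = mean(q_X) - mean(q_auto)` and
#' the ratio `Delta = D / mean(q_auto)` over the individuals of a group,
#' with individual-level bootstrap percentile confidence intervals.
#' Positive values indicate an excess of female-specific contributions of
#' that ancestry; negative values male-specific excess.
#'
#' @param table a `compartment_ancestry` table.
#' @param group group label to subset on (default: all individuals).
#' @param B bootstrap replicates.
#' @param level confidence level for the percentile intervals.
#' @param seed integer seed; required.
#' @return `data.frame` of class `sex_bias_estimate`: per ancestry,
#'   `q_auto`, `q_x`, `D`, `delta`, and bootstrap CI bounds for both
#'   (`delta` is `NA` where `mean(q_auto) = 0`).
#' @export
delta_admix <- function(table, group = NULL, B = 1000, level = 0.95, seed) {
  stopifnot(inherits(table, "compartment_ancestry"))
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(group)) table <- table[table$group == group, ]
  ids <- unique(table$individual)
  if (length(ids) < 5) stop("group has fewer than 5 individuals")
  ancestries <- sort(unique(table$ancestry))
  qa <- matrix(table$q_auto, nrow = length(ids),
               dimnames = list(table$individual[seq_along(ids)], NULL))
  # reshape robustly
  qa <- tapply(table$q_auto, list(table$individual, table$ancestry), mean)
  qx <- tapply(table$q_x, list(table$individual, table$ancestry), mean)
  qa <- qa[, ancestries, drop = FALSE]
  qx <- qx[, ancestries, drop = FALSE]
  stat <- function(rows) {
    ma <- colMeans(qa[rows, , drop = FALSE])
    mx <- colMeans(qx[rows, , drop = FALSE])
    D <- mx - ma
    delta <- ifelse(ma > 0, D / ma, NA_real_)
    c(D, delta)
  }
  n <- nrow(qa)
  est <- stat(seq_len(n))
  set.seed(seed)
  boot <- t(vapply(seq_len(B),
                   function(i) stat(sample.int(n, n, replace = TRUE)),
                   numeric(2 * length(ancestries))))
  a <- (1 - level) / 2
  lo <- apply(boot, 2, quantile, probs = a, na.rm = TRUE)
  hi <- apply(boot, 2, quantile, probs = 1 - a, na.rm = TRUE)
  k <- length(ancestries)
  out <- data.frame(ancestry = ancestries,
                    q_auto = colMeans(qa), q_x = colMeans(qx),
                    D = est[seq_len(k)], delta = est[k + seq_len(k)],
                    D_lower = lo[seq_len(k)], D_upper = hi[seq_len(k)],
                    delta_lower = lo[k + seq_len(k)],
                    delta_upper = hi[k + seq_len(k)],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, group = if (is.null(group)) "all" else group, n = n,
            level = level, class = c("sex_bias_estimate", "data.frame"))
}

#' Wilcoxon signed-rank test of X-versus-autosome ancestry
#'
#' Two-sided signed-rank test on the per-individual paired differences
#' `q_X - q_auto` for one ancestry.  The exact null distribution is used
#' for up to 25 non-zero pairs (when ties permit), the normal
#' approximation with continuity correction otherwise.  If every
#' difference is zero the p-value is 1, flagged.
#'
#' @param table a `compartment_ancestry` table.
#' @param ancestry ancestry to test.
#' @param group optional group label to subset on.
#' @return list of class `xa_test`: `p_value`, `statistic`, `n_pairs`,
#'   `all_zero` flag.
#' @export
wilcoxon_xa_test <- function(table, ancestry, group = NULL) {
  stopifnot(inherits(table, "compartment_ancestry"))
  if (!is.null(group)) table <- table[table$group == group, ]
  table <- table[table$ancestry == ancestry, ]
  if (nrow(table) < 6) stop("need at least 6 paired observations")
  d <- table$q_x - table$q_auto
  nz <- sum(d != 0)
  if (nz == 0) {
    out <- list(p_value = 1, statistic = NA_real_, n_pairs = length(d),
                all_zero = TRUE)
  } else {
    wt <- suppressWarnings(
      wilcox.test(table$q_x, table$q_auto, paired = TRUE,
                  alternative = "two.sided", exact = nz <= 25,
                  correct = TRUE))
    out <- list(p_value = wt$p.value, statistic = unname(wt$statistic),
                n_pairs = length(d), all_zero = FALSE)
  }
  class(out) <- "xa_test"
  out
}

#' @export
print.xa_test <- function(x, ...) {
  cat("Wilcoxon signed-rank X-vs-autosome test:\n")
  cat("  n =", x$n_pairs, " V =", x$statistic, " p =",
      format.pval(x$p_value), if (x$all_zero) " (all differences zero)",
      "\n")
  invisible(x)
}

#' Invert autosomal and X ancestry into sex-specific contributions
#'
#' Under a single founding admixture event (hybrid isolation) with
#' constant 50/50 sex ratios, the equilibrium autosomal and X ancestry
#' fractions of an ancestry are `q_A = (s_f + s_m)/2` and
#' `q_X = (2 s_f + s_m)/3`, where `s_f`, `s_m` are the female and male
#' founding contributions.  Inverting: `s_f = 3 q_X - 2 q_A`,
#' `s_m = 4 q_A - 3 q_X`.  Estimates outside `[0, 1]` are clipped and
#' flagged.
#'
#' @param q_auto,q_x autosomal and X ancestry fractions (named vectors
#'   over ancestries, or scalars), each in `[0, 1]`.
#' @return `data.frame` of class `sex_contributions`: `ancestry`, `s_f`,
#'   `s_m`, `clipped`.
#' @examples
#' invert_sex_contributions(q_auto = 0.2, q_x = 7 / 30)  # s_f 0.3, s_m 0.1
#' @export
invert_sex_contributions <- function(q_auto, q_x) {
  if (length(q_auto) != length(q_x))
    stop("'q_auto' and 'q_x' must have the same length")
  if (any(q_auto < 0 | q_auto > 1 | q_x < 0 | q_x > 1))
    stop("ancestry fractions must lie in [0, 1]")
  s_f <- 3 * q_x - 2 * q_auto
  s_m <- 4 * q_auto - 3 * q_x
  tol <- 1e-9  # floating-point slack; only real infeasibility is flagged
  clipped <- s_f < -tol | s_f > 1 + tol | s_m < -tol | s_m > 1 + tol
  out <- data.frame(
    ancestry = if (!is.null(names(q_auto))) names(q_auto)
               else as.character(seq_along(q_auto)),
    s_f = pmin(pmax(s_f, 0), 1),
    s_m = pmin(pmax(s_m, 0), 1),
    clipped = clipped, row.names = NULL, stringsAsFactors = FALSE)
  if (any(clipped))
    attr(out, "note") <- paste("estimates outside [0, 1] were clipped;",
                               "clipped rows no longer reproduce q_auto")
  class(out) <- c("sex_contributions", "data.frame")
  out
}

#' X-chromosome ancestry recursion under hybrid isolation
#'
#' Tracks the mean X ancestry of females (`q_f`) and males (`q_m`) across
#' generations after a single founding event with female/male
#' contributions `s_f`, `s_m`: a daughter's X ancestry averages her
#' mother's X pool and her father's X (`q_f' = (q_f + q_m)/2`), a son's X
#' is maternal (`q_m' = q_f`).  The individual-mean X ancestry
#' `q_X = (q_f + q_m)/2` converges geometrically (damped oscillation) to
#' `(2 s_f + s_m)/3`; the X-copy pool mean `(2 q_f + q_m)/3` is invariant
#' from the start.
#'
#' @param s_f,s_m founding female and male contributions of the ancestry,
#'   in `[0, 1]`.
#' @param G number of generations (>= 1).
#' @return `data.frame` with columns `generation` (0..G), `q_f`, `q_m`,
#'   `q_x`; the limit `(2 s_f + s_m)/3` is attached as attribute
#'   `"limit"`.
#' @examples
#' x_recursion(0.3, 0.1, 15)  # q_x -> 7/30
#' @export
x_recursion <- function(s_f, s_m, G) {
  stopifnot(G >= 1, s_f >= 0, s_f <= 1, s_m >= 0, s_m <= 1)
  q_f <- numeric(G + 1)
  q_m <- numeric(G + 1)
  q_f[1] <- s_f
  q_m[1] <- s_m
  for (g in seq_len(G)) {
    q_f[g + 1] <- (q_f[g] + q_m[g]) / 2
    q_m[g + 1] <- q_f[g]
  }
  out <- data.frame(generation = 0:G, q_f = q_f, q_m = q_m,
                    q_x = (q_f + q_m) / 2)
  attr(out, "limit") <- (2 * s_f + s_m) / 3
  out
}
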