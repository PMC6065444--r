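#' Forward simulation of ancestry tracts under a migration history
#'
#' Simulates haploid genomes under a pulse migration history on a genetic
#' map.  Two engines are available.  With a finite `pop_size` the
#' population is an explicit pool of haploid genomes: at the founding
#' generation all are pure migrants drawn from the founding fractions; each
#' later generation a haplotype is, with probability equal to the total
#' migrant fraction of that generation, a fresh pure migrant, and otherwise
#' the meiotic product of two uniformly drawn previous-generation
#' haplotypes with Poisson(length in Morgans) crossovers at uniform genetic
#' positions.  With `pop_size = Inf` every parent is a fresh independent
#' draw (a branching recursion): no genetic drift, matching the
#' infinite-population assumptions of the analytic tract model
#' ([expected_tract_density()]); use it when comparing simulated tract
#' histograms to analytic expectations.
#'
#' X chromosomes recombine only when transmitted through a female; in this
#' unsexed simulator a transmission is female with probability 2/3 (the
#' stationary fraction of X transmissions through females).  Use
#' [simulate_sexed_cohort()] for explicit sex structure.
#'
#' @param history a `migration_history` with integer pulse times.
#' @param map a `genetic_map`.
#' @param n_hap number of present-day haploid genomes to return.
#' @param pop_size haploid population size per generation, or `Inf` for
#'   the branching (no-drift) engine.
#' @param seed integer seed; required, every run is deterministic given it.
#' @return object of class `simulated_cohort`: a list with elements
#'   `tracts` (a `tract_set`), `history`, `map`, `n_hap`, `pop_size`,
#'   `seed`.
#' @examples
#' h <- build_history(c(EUR = 0.8, AFR = 0.2), T_max = 15)
#' cohort <- simulate_tracts(h, toy_genetic_map(3), n_hap = 10, seed = 1)
#' head(cohort$tracts)
#' @export
simulate_tracts <- function(history, map, n_hap, pop_size = 2000, seed) {
  stopifnot(inherits(history, "migration_history"),
            inherits(map, "genetic_map"))
  if (missing(seed)) stop("'seed' is required")
  if (nrow(map) == 0) stop("map has no chromosomes")
  if (n_hap < 1) stop("'n_hap' must be >= 1")
  m <- history_matrix(history)
  set.seed(seed)
  if (is.finite(pop_size)) {
    if (pop_size < 2) stop("'pop_size' must be >= 2")
    if (pop_size < n_hap) stop("'pop_size' must be >= n_hap")
    raw <- sim_pool_cpp(map$length_M, map$is_x, m, as.integer(pop_size),
                        as.integer(n_hap))
  } else {
    raw <- sim_branching_cpp(map$length_M, map$is_x, m, as.integer(n_hap))
  }
  tracts <- raw_to_tracts(raw, map, history$ancestries)
  structure(list(tracts = tracts, history = history, map = map,
                 n_hap = n_hap, pop_size = pop_size, seed = seed),
            class = "simulated_cohort")
}

raw_to_tracts <- function(raw, map, ancestries) {
  df <- data.frame(haplotype = raw$haplotype,
                   chrom = map$chrom[raw$chrom],
                   start_cM = raw$start * 100,
                   end_cM = raw$end * 100,
                   ancestry = ancestries[raw$ancestry],
                   stringsAsFactors = FALSE)
  lens <- map_chrom_lengths_cM(map)
  as_tract_set(df, chrom_lengths_cM = lens,
               n_hap = length(unique(df$haplotype)))
}

#' Construct a tract set
#'
#' A tract set is a `data.frame` of maximal same-ancestry intervals
#' (half-open, cM coordinates) per haploid chromosome, carrying the
#' chromosome lengths and haplotype count as attributes.  Chromosome-end
#' tracts are flagged censored (`left`, `right` or `both`); their full
#' lengths are unobserved.
#'
#' @param df `data.frame` with columns `haplotype`, `chrom`, `start_cM`,
#'   `end_cM`, `ancestry` (and optionally `individual`, `compartment`).
#' @param chrom_lengths_cM named vector of chromosome lengths in cM.
#' @param n_hap number of haploid genomes represented.
#' @return the validated `tract_set`.
#' @export
as_tract_set <- function(df, chrom_lengths_cM, n_hap) {
  need <- c("haplotype", "chrom", "start_cM", "end_cM", "ancestry")
  if (!all(need %in% names(df)))
    stop("tract table needs columns ", paste(need, collapse = ", "))
  if (any(df$end_cM <= df$start_cM)) stop("tracts must have end > start")
  L <- chrom_lengths_cM[df$chrom]
  df$censored <- censor_flag(df$start_cM, df$end_cM, L)
  df$length_cM <- df$end_cM - df$start_cM
  structure(df, chrom_lengths_cM = chrom_lengths_cM, n_hap = n_hap,
            class = c("tract_set", "data.frame"))
}

censor_flag <- function(start, end, L, tol = 1e-9) {
  left <- start <= tol
  right <- end >= L - tol
  out <- rep("none", length(start))
  out[left & !right] <- "left"
  out[!left & right] <- "right"
  out[left & right] <- "both"
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", x$n_hap,
      if (!is.null(x$tracts$compartment)) "individuals" else "haploid genomes",
      "\n")
  cat("  pop_size:", x$pop_size, " seed:", x$seed, "\n")
  cat("  tracts:", nrow(x$tracts), "on", nrow(x$map), "chromosomes\n")
  print(x$history)
  invisible(x)
}

#' Forward simulation of a sexed cohort with X chromosomes
#'
#' Individual-based version of [simulate_tracts()] for histories carrying
#' a sex split.  Sexes are assigned 50/50 each generation; the sex-specific
#' migrant fractions apply to the migrant draw only.  Autosomes are
#' transmitted meiotically from both parents; the X is transmitted from the
#' mother always (with recombination between her two X copies) and from the
#' father only to daughters (his single X passes intact).  Males carry
#' exactly one X haplotype.
#'
#' @param history a sexed `migration_history` (see [build_history()]).
#' @param map a `genetic_map` that includes an X chromosome.
#' @param n_ind number of present-day individuals to return.
#' @param pop_size individuals per generation, or `Inf` for the branching
#'   (no-drift) engine.
#' @param seed integer seed; required.
#' @return a `simulated_cohort` whose `tracts` carry `individual`, `slot`
#'   (1 maternal / 2 paternal) and `compartment` (`"auto"`/`"X"`) columns,
#'   plus `individuals` (id, sex) and `truth` (per-individual autosomal and
#'   X ancestry fractions).
#' @export
simulate_sexed_cohort <- function(history, map, n_ind, pop_size = 2000, seed) {
  stopifnot(inherits(history, "migration_history"),
            inherits(map, "genetic_map"))
  if (missing(seed)) stop("'seed' is required")
  if (!history$sexed) stop("history carries no sex split; see build_history()")
  if (!any(map$is_x)) stop("map must include an X chromosome")
  sf <- history_matrix(history, "female")
  sm <- history_matrix(history, "male")
  auto <- map[!map$is_x, , drop = FALSE]
  xlen <- map$length_M[map$is_x]
  set.seed(seed)
  if (is.finite(pop_size)) {
    if (pop_size < 2) stop("'pop_size' must be >= 2")
    if (pop_size < n_ind) stop("'pop_size' must be >= n_ind")
    raw <- sim_sexed_cpp(auto$length_M, xlen, sf, sm, as.integer(pop_size),
                         as.integer(n_ind))
  } else {
    raw <- sim_branching_sexed_cpp(auto$length_M, xlen, sf, sm,
                                   as.integer(n_ind))
  }
  chrom_names <- c(auto$chrom, map$chrom[map$is_x])
  n_auto <- nrow(auto)
  df <- data.frame(individual = raw$individual,
                   haplotype = (raw$individual - 1L) * 2L + raw$slot,
                   slot = raw$slot,
                   chrom = chrom_names[raw$chrom],
                   compartment = ifelse(raw$chrom > n_auto, "X", "auto"),
                   start_cM = raw$start * 100,
                   end_cM = raw$end * 100,
                   ancestry = history$ancestries[raw$ancestry],
                   stringsAsFactors = FALSE)
  lens <- setNames(c(auto$length_M, xlen) * 100, chrom_names)
  tracts <- as_tract_set(df, chrom_lengths_cM = lens, n_hap = 2L * n_ind)
  individuals <- data.frame(individual = seq_len(n_ind),
                            sex = ifelse(raw$sex == 0, "F", "M"),
                            stringsAsFactors = FALSE)
  cohort <- structure(list(tracts = tracts, individuals = individuals,
                           history = history, map = map, n_hap = 2L * n_ind,
                           n_ind = n_ind, pop_size = pop_size, seed = seed),
                      class = "simulated_cohort")
  cohort$truth <- cohort_truth(cohort)
  cohort
}

# Per-individual autosomal and X ancestry fractions from the truth tracts.
cohort_truth <- function(cohort) {
  tr <- cohort$tracts
  q_auto <- proportions_by(tr[tr$compartment == "auto", ],
                           tr$individual[tr$compartment == "auto"],
                           cohort$history$ancestries)
  q_x <- proportions_by(tr[tr$compartment == "X", ],
                        tr$individual[tr$compartment == "X"],
                        cohort$history$ancestries)
  data.frame(individual = rep(as.integer(rownames(q_auto)),
                              ncol(q_auto)),
             ancestry = rep(colnames(q_auto), each = nrow(q_auto)),
             q_auto = as.vector(q_auto),
             q_x = as.vector(q_x[rownames(q_auto), colnames(q_auto)]),
             stringsAsFactors = FALSE)
}

# length-weighted ancestry fractions of tract rows grouped by `by`
proportions_by <- function(tr, by, ancestries) {
  len <- tapply(tr$length_cM, list(as.character(by), tr$ancestry), sum,
                default = 0)
  miss <- setdiff(ancestries, colnames(len))
  if (length(miss))
    len <- cbind(len, matrix(0, nrow(len), length(miss),
                             dimnames = list(NULL, miss)))
  len <- len[, ancestries, drop = FALSE]
  len / rowSums(len)
}
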