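# Per-ancestry allele frequencies and genotype emission over tracts.

#' Balding-Nichols per-ancestry allele frequencies
#'
#' Draws, for every site and ancestry, an allele frequency from the
#' Balding-Nichols distribution `Beta(p0(1-F)/F, (1-p0)(1-F)/F)` around an
#' ancestral frequency `p0`, with one differentiation parameter `F` per
#' ancestry (`F = 0` keeps `p0` unchanged).  Larger `F` means more drift
#' from the shared ancestral pool and lower within-ancestry diversity.
#'
#' @param sites site map `data.frame` (columns `chrom`, `bp`, `cM`), e.g.
#'   from [uniform_sites()].
#' @param F named vector of differentiation parameters per ancestry, each
#'   in `[0, 1)`.
#' @param p0 ancestral frequencies (length `nrow(sites)`); drawn uniformly
#'   from (0.05, 0.95) when omitted.
#' @param seed integer seed; required when `p0` is omitted or any `F > 0`.
#' @return object of class `allele_frequency_model` with the realized
#'   frequency matrix `p` (ancestry x site).
#' @export
allele_frequency_model <- function(sites, F, p0 = NULL, seed = NULL) {
  stopifnot(is.numeric(F), !is.null(names(F)))
  if (any(F < 0 | F >= 1)) stop("'F' values must lie in [0, 1)")
  S <- nrow(sites)
  if (!is.null(seed)) set.seed(seed)
  else if (is.null(p0) || any(F > 0)) stop("'seed' is required")
  if (is.null(p0)) p0 <- runif(S, 0.05, 0.95)
  if (length(p0) != S) stop("'p0' must have one entry per site")
  if (any(p0 <= 0 | p0 >= 1)) stop("'p0' must lie in (0, 1)")
  p <- matrix(NA_real_, nrow = length(F), ncol = S,
              dimnames = list(names(F), NULL))
  for (a in names(F)) {
    if (F[[a]] == 0) {
      p[a, ] <- p0
    } else {
      shape <- (1 - F[[a]]) / F[[a]]
      p[a, ] <- rbeta(S, p0 * shape, (1 - p0) * shape)
    }
  }
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  structure(list(sites = sites, F = F, p0 = p0, p = p),
            class = "allele_frequency_model")
}

#' @export
print.allele_frequency_model <- function(x, ...) {
  cat("Balding-Nichols allele-frequency model:", ncol(x$p), "sites\n")
  for (a in rownames(x$p))
    cat(sprintf("  %s: F = %.3f\n", a, x$F[[a]]))
  invisible(x)
}

#' Emit phased genotypes over simulated ancestry tracts
#'
#' Each haplotype allele is Bernoulli with the frequency of the ancestry
#' of the tract overlying the site, so the panel carries the local-ancestry
#' truth per site for masking tests.  Autosomes only: X haplotype counts
#' differ between sexes and the X is not emitted.
#'
#' @param cohort a `simulated_cohort`.
#' @param freq_model an `allele_frequency_model` whose sites lie within
#'   the cohort's autosomal chromosomes.
#' @param seed integer seed; required.
#' @return object of class `haplotype_panel`: list with `geno` (site x
#'   haplotype 0/1 matrix), `sites`, `hap_ind` (haplotype, individual),
#'   `truth` (ancestry label per site x haplotype), `ancestries`.
#' @export
simulate_genotypes <- function(cohort, freq_model, seed) {
  stopifnot(inherits(cohort, "simulated_cohort"),
            inherits(freq_model, "allele_frequency_model"))
  if (missing(seed)) stop("'seed' is required")
  sites <- freq_model$sites
  map <- cohort$map
  auto <- map$chrom[!map$is_x]
  if (!all(sites$chrom %in% auto))
    stop("freq model has sites outside the cohort's autosomes")
  lens <- map_chrom_lengths_cM(map)
  if (any(sites$cM > lens[as.character(sites$chrom)]))
    stop("site cM position beyond chromosome length")
  tr <- cohort$tracts
  if (!is.null(tr$compartment)) tr <- tr[tr$compartment == "auto", ]
  haps <- sort(unique(tr$haplotype))
  set.seed(seed)
  S <- nrow(sites)
  geno <- matrix(NA_integer_, nrow = S, ncol = length(haps))
  truth <- matrix(NA_character_, nrow = S, ncol = length(haps))
  anc_levels <- rownames(freq_model$p)
  for (j in seq_along(haps)) {
    th <- tr[tr$haplotype == haps[j], ]
    for (ch in unique(as.character(th$chrom))) {
      tc <- th[th$chrom == ch, ]
      tc <- tc[order(tc$start_cM), ]
      ssel <- which(sites$chrom == ch)
      idx <- findInterval(sites$cM[ssel], tc$start_cM)
      anc <- tc$ancestry[pmax(idx, 1)]
      pr <- freq_model$p[cbind(match(anc, anc_levels), ssel)]
      geno[ssel, j] <- rbinom(length(ssel), 1L, pr)
      truth[ssel, j] <- anc
    }
  }
  individual <- if (!is.null(tr$individual))
    vapply(haps, function(h) tr$individual[tr$haplotype == h][1], 0)
  else ceiling(haps / 2)
  haplotype_panel(geno, sites,
                  hap_ind = data.frame(haplotype = haps,
                                       individual = individual),
                  truth = truth, ancestries = anc_levels)
}

#' Construct a phased haplotype panel
#'
#' @param geno integer matrix (site x haplotype) over 0/1/`NA`.
#' @param sites site map (`chrom`, `bp`, `cM`).
#' @param hap_ind `data.frame` mapping `haplotype` to `individual` (and
#'   optionally `group`).
#' @param truth optional per-site local-ancestry label matrix (same shape
#'   as `geno`).
#' @param ancestries optional ancestry labels.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(geno, sites, hap_ind = NULL, truth = NULL,
                            ancestries = NULL) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites))
    stop("'geno' must have one row per site")
  vals <- unique(as.vector(geno))
  if (!all(vals %in% c(0L, 1L, NA)))
    stop("panel must be biallelic 0/1 (or NA)")
  if (is.null(hap_ind))
    hap_ind <- data.frame(haplotype = seq_len(ncol(geno)),
                          individual = ceiling(seq_len(ncol(geno)) / 2))
  if (nrow(hap_ind) != ncol(geno))
    stop("'hap_ind' must have one row per haplotype")
  if (!is.null(truth) && !identical(dim(truth), dim(geno)))
    stop("'truth' must match 'geno' in shape")
  structure(list(geno = geno, sites = sites, hap_ind = hap_ind,
                 truth = truth, ancestries = ancestries),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$geno), "sites x", ncol(x$geno),
      "haplotypes (", length(unique(x$hap_ind$individual)),
      "individuals )\n")
  miss <- mean(is.na(x$geno))
  if (miss > 0) cat(sprintf("  missing/masked: %.1f%%\n", 100 * miss))
  invisible(x)
}
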