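# Weir-Cockerham FST for haploid (phased / masked) samples.

#' Weighted Weir-Cockerham FST between two haploid samples
#'
#' Per-locus variance components for haploid allele counts over `r = 2`
#' populations:
#' `MSP = sum_i n_i (p_i - pbar)^2 / (r - 1)`,
#' `MSG = sum_i n_i p_i (1 - p_i) / sum_i (n_i - 1)`,
#' `n_c = (n - sum_i n_i^2 / n) / (r - 1)`,
#' per-locus `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)`, and the
#' weighted (ratio-of-sums) estimate
#' `theta_w = sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)` across loci.
#' Missing alleles are dropped per locus; loci with fewer than 2 observed
#' alleles in either sample are skipped.  Fixed differences give
#' `theta = 1`; the estimate is invariant under allele relabeling.
#'
#' @param panel_1,panel_2 `haplotype_panel` objects (possibly masked) on
#'   the same sites, or plain 0/1 site-by-haplotype matrices.
#' @return object of class `fst_result`: `theta_w`, `per_locus`
#'   (`data.frame` with `num`, `den`, `theta`), `n_loci_used`.
#' @export
wc_fst <- function(panel_1, panel_2) {
  g1 <- if (inherits(panel_1, "haplotype_panel")) panel_1$geno else
    as.matrix(panel_1)
  g2 <- if (inherits(panel_2, "haplotype_panel")) panel_2$geno else
    as.matrix(panel_2)
  if (nrow(g1) != nrow(g2)) stop("panels differ in site count")
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowMeans(g1, na.rm = TRUE)
  p2 <- rowMeans(g2, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  n <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / n
  MSP <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2        # / (r - 1) = 1
  MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n - 2)
  n_c <- n - (n1^2 + n2^2) / n                           # / (r - 1) = 1
  num <- MSP - MSG
  den <- MSP + (n_c - 1) * MSG
  num[!ok] <- NA
  den[!ok] <- NA
  usable <- ok & den > 0
  if (!any(usable))
    stop("all loci monomorphic or unusable; FST undefined")
  theta_w <- sum(num[usable]) / sum(den[usable])
  per_locus <- data.frame(num = num, den = den,
                          theta = ifelse(den > 0, num / den, NA))
  structure(list(theta_w = theta_w, per_locus = per_locus,
                 n_loci_used = sum(usable)), class = "fst_result")
}

#' @export
print.fst_result <- function(x, digits = 4, ...) {
  cat("Weir-Cockerham weighted FST (haploid):",
      format(x$theta_w, digits = digits), "over", x$n_loci_used, "loci\n")
  invisible(x)
}
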