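# Allele-sharing dissimilarity and classical (metric) multidimensional
# scaling, including the masked-haplotype projection against reference
# panels.

#' Pairwise allele-sharing dissimilarity
#'
#' Genotype mode compares individuals: per-locus dissimilarity
#' `1 - IBS/2` (0 for identical genotypes, 1/2 for one shared allele, 1
#' for opposite homozygotes), averaged over jointly non-missing loci.
#' Haplotype mode compares haplotypes: the mismatch fraction over jointly
#' non-missing sites.  Pairs with fewer than `min_overlap` jointly
#' observed sites get `NA` and are flagged.
#'
#' @param panel a `haplotype_panel` (possibly masked).
#' @param mode `"genotype"` or `"haplotype"`.
#' @param min_overlap minimum jointly observed sites per pair.
#' @return object of class `asd_matrix`: list with `D` (dissimilarity),
#'   `overlap` (jointly observed site counts) and `mode`.
#' @export
pairwise_asd <- function(panel, mode = c("genotype", "haplotype"),
                         min_overlap = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  mode <- match.arg(mode)
  if (mode == "haplotype") {
    X <- panel$geno
    labels <- as.character(panel$hap_ind$haplotype)
  } else {
    inds <- unique(panel$hap_ind$individual)
    if (ncol(panel$geno) < 2) stop("need at least 2 haplotypes")
    X <- vapply(inds, function(i) {
      cols <- which(panel$hap_ind$individual == i)
      rowSums(panel$geno[, cols, drop = FALSE])  # NA if any hap missing
    }, numeric(nrow(panel$geno)))
    labels <- as.character(inds)
  }
  if (ncol(X) < 2) stop("need at least 2 items")
  W <- !is.na(X)
  overlap <- crossprod(W)
  if (mode == "haplotype") {
    Xo <- X
    Xo[!W] <- 0
    s11 <- crossprod(Xo)
    si <- crossprod(Xo, W)
    mism <- si + t(si) - 2 * s11
    D <- mism / overlap
  } else {
    # genotypes 0/1/2: per-locus |g_i - g_j| / 2 averaged over overlap
    I <- lapply(0:2, function(v) {
      M <- (X == v)
      M[!W] <- FALSE
      M * 1
    })
    num <- matrix(0, ncol(X), ncol(X))
    for (a in 0:2) for (b in 0:2) if (a != b)
      num <- num + abs(a - b) / 2 * crossprod(I[[a + 1]], I[[b + 1]])
    D <- num / overlap
  }
  D[overlap < min_overlap] <- NA
  diag(D) <- 0
  dimnames(D) <- dimnames(overlap) <- list(labels, labels)
  structure(list(D = D, overlap = overlap, mode = mode,
                 min_overlap = min_overlap), class = "asd_matrix")
}

#' @export
print.asd_matrix <- function(x, ...) {
  cat("ASD matrix (", x$mode, " mode): ", nrow(x$D), " items\n", sep = "")
  und <- sum(is.na(x$D[upper.tri(x$D)]))
  if (und > 0) cat("  undefined pairs (overlap <", x$min_overlap, "):",
                   und, "\n")
  invisible(x)
}

#' Classical (metric) multidimensional scaling of a dissimilarity matrix
#'
#' Double-centering of squared dissimilarities and eigendecomposition
#' (Torgerson scaling, as in `stats::cmdscale`); the top `k` axes with
#' positive eigenvalues are returned.  Items with undefined pairs are
#' dropped one at a time (most undefined first) until the matrix is
#' complete, and reported.
#'
#' @param D an `asd_matrix` or a symmetric dissimilarity matrix.
#' @param k number of dimensions.
#' @return object of class `mds_result`: `points` (items x k, centered),
#'   `eig` (all eigenvalues, decreasing), `prop` (share of positive
#'   eigenvalue mass per returned axis), `dropped` (item labels).
#' @export
classical_mds <- function(D, k = 2) {
  if (inherits(D, "asd_matrix")) D <- D$D
  D <- as.matrix(D)
  dropped <- character(0)
  while (anyNA(D) && nrow(D) > 2) {
    worst <- which.max(rowSums(is.na(D)))
    dropped <- c(dropped, rownames(D)[worst])
    D <- D[-worst, -worst, drop = FALSE]
  }
  if (anyNA(D)) stop("too many undefined pairs to embed")
  mds <- cmdscale(as.dist(D), k = min(k, nrow(D) - 1L), eig = TRUE)
  pos <- sum(mds$eig > 1e-12)
  if (k > pos)
    stop("k = ", k, " exceeds the number of positive eigenvalues (", pos,
         ")")
  pts <- mds$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  structure(list(points = pts, eig = mds$eig,
                 prop = mds$eig[seq_len(k)] / sum(pmax(mds$eig, 0)),
                 n_negative = sum(mds$eig < -1e-12), dropped = dropped),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("Metric MDS:", nrow(x$points), "items x", ncol(x$points), "axes\n")
  cat("  axis variance shares:",
      paste(sprintf("%.1f%%", 100 * x$prop), collapse = ", "), "\n")
  if (x$n_negative > 0)
    cat("  negative eigenvalues (excluded):", x$n_negative, "\n")
  if (length(x$dropped))
    cat("  dropped items:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mds_result <- function(x, dims = c(1, 2), col = 1, ...) {
  plot(x$points[, dims[1]], x$points[, dims[2]],
       xlab = colnames(x$points)[dims[1]],
       ylab = colnames(x$points)[dims[2]], col = col, ...)
  invisible(x)
}

#' Ancestry-specific MDS of masked haplotypes against reference panels
#'
#' Projects ancestry-masked haplotypes together with unmasked reference
#' haplotypes through haplotype-mode allele-sharing dissimilarity followed
#' by classical MDS.  Masked haplotypes must share at least `min_overlap`
#' jointly observed sites with every reference haplotype; those that do
#' not are dropped and reported.  With fully unmasked input this reduces
#' exactly to [pairwise_asd()] + [classical_mds()].
#'
#' @param masked a `masked_panel` (or unmasked `haplotype_panel`).
#' @param reference one `haplotype_panel` or a named list of them (one per
#'   reference population), sharing the masked panel's site map.
#' @param k dimensions.
#' @param min_overlap minimum jointly observed sites per (masked,
#'   reference) pair.
#' @return an `mds_result` with an extra element `which`: `data.frame`
#'   (`item`, `panel`) locating every embedded haplotype.
#' @export
aspca_mds <- function(masked, reference, k = 2, min_overlap = 500) {
  stopifnot(inherits(masked, "haplotype_panel"))
  if (inherits(reference, "haplotype_panel")) reference <- list(ref = reference)
  sites_key <- function(s) paste(s$chrom, s$bp)
  key0 <- sites_key(masked$sites)
  genos <- list(masked$geno)
  src <- rep("masked", ncol(masked$geno))
  for (nm in names(reference)) {
    r <- reference[[nm]]
    if (!identical(sites_key(r$sites), key0))
      stop("reference panel '", nm, "' does not share the site map")
    genos <- c(genos, list(r$geno))
    src <- c(src, rep(nm, ncol(r$geno)))
  }
  G <- do.call(cbind, genos)
  labels <- paste0(src, ".", sequence(vapply(genos, ncol, 0L)))
  colnames(G) <- labels
  comb <- haplotype_panel(G, masked$sites,
                          hap_ind = data.frame(haplotype = labels,
                                               individual = labels))
  asd <- pairwise_asd(comb, mode = "haplotype", min_overlap = min_overlap)
  # drop masked haplotypes failing the overlap rule against any reference
  is_ref <- src != "masked"
  keep <- rep(TRUE, length(src))
  for (i in which(!is_ref))
    if (anyNA(asd$D[i, is_ref])) keep[i] <- FALSE
  dropped_overlap <- labels[!keep]
  D <- asd$D[keep, keep, drop = FALSE]
  mds <- classical_mds(structure(list(D = D), class = "asd_matrix")$D, k = k)
  mds$dropped <- union(dropped_overlap, mds$dropped)
  emb <- rownames(mds$points)
  mds$which <- data.frame(item = emb,
                          panel = src[keep][match(emb, labels[keep])],
                          stringsAsFactors = FALSE)
  mds
}
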