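# Panel-level diversity statistics: windowed haplotype heterozygosity and
# IBD-segment sharing summaries.

#' Windowed haplotype heterozygosity
#'
#' Cuts each chromosome into non-overlapping windows of fixed genetic
#' length, concatenates each haplotype's alleles within a window into a
#' haplotype string, and computes the unbiased heterozygosity
#' `(n/(n-1)) (1 - sum_h p_h^2)` over the string frequencies.  Haplotypes
#' with missing data in a window are excluded from that window; windows
#' with fewer than `min_sites` sites or fewer than 2 complete haplotypes
#' are excluded and counted.
#'
#' @param panel a `haplotype_panel`.
#' @param window_cM window length in cM.
#' @param min_sites minimum sites per window.
#' @return object of class `het_profile`: `windows` (`data.frame` with
#'   per-window site counts, haplotype counts and heterozygosity),
#'   `genome_mean`, `n_excluded`.
#' @export
haplotype_heterozygosity <- function(panel, window_cM = 0.5, min_sites = 2) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sites <- panel$sites
  rows <- NULL
  n_excl <- 0L
  for (ch in unique(as.character(sites$chrom))) {
    sel <- which(sites$chrom == ch)
    cm <- sites$cM[sel]
    breaks <- seq(0, max(cm) + window_cM, by = window_cM)
    win <- findInterval(cm, breaks, rightmost.closed = FALSE)
    for (w in unique(win)) {
      idx <- sel[win == w]
      if (length(idx) < min_sites) {
        n_excl <- n_excl + 1L
        next
      }
      sub <- panel$geno[idx, , drop = FALSE]
      complete <- colSums(is.na(sub)) == 0
      n <- sum(complete)
      if (n < 2) {
        n_excl <- n_excl + 1L
        next
      }
      strings <- apply(sub[, complete, drop = FALSE], 2, paste0,
                       collapse = "")
      ph <- table(strings) / n
      het <- n / (n - 1) * (1 - sum(ph^2))
      rows <- rbind(rows, data.frame(
        chrom = ch, start_cM = breaks[w], end_cM = breaks[w + 1],
        n_sites = length(idx), n_hap = n, het = het,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) stop("no qualifying windows")
  structure(list(windows = rows, genome_mean = mean(rows$het),
                 n_excluded = n_excl, window_cM = window_cM,
                 min_sites = min_sites), class = "het_profile")
}

#' @export
print.het_profile <- function(x, ...) {
  cat("Haplotype heterozygosity:", nrow(x$windows), "windows of",
      x$window_cM, "cM (", x$n_excluded, "excluded )\n")
  cat("  genome-wide mean:", format(x$genome_mean, digits = 4), "\n")
  invisible(x)
}

#' Read an IBD segment table
#'
#' Refined-IBD-style whitespace-separated columns: sample1, hap1, sample2,
#' hap2, chromosome, start (bp), end (bp), LOD, length (cM).
#'
#' @param path file path.
#' @return `data.frame` of class `ibd_segments` with columns
#'   `individual_1`, `individual_2`, `chrom`, `start_bp`, `end_bp`,
#'   `length_cM`, `length_Mb`.
#' @export
read_ibd_segments <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 9) stop("expected at least 9 columns")
  out <- data.frame(individual_1 = as.character(d[[1]]),
                    individual_2 = as.character(d[[3]]),
                    chrom = d[[5]], start_bp = d[[6]], end_bp = d[[7]],
                    length_cM = d[[9]],
                    length_Mb = (d[[7]] - d[[6]]) / 1e6,
                    stringsAsFactors = FALSE)
  class(out) <- c("ibd_segments", "data.frame")
  out
}

#' Summarize IBD sharing per pair and per group
#'
#' Drops segments below the minimum genetic length, totals the shared
#' physical length (Mb) per unordered pair of individuals, and averages
#' the totals over all within-group and between-group pairs (pairs
#' sharing no retained segment contribute 0).
#'
#' @param segments an `ibd_segments` table (or any `data.frame` with
#'   columns `individual_1`, `individual_2`, `length_cM`, `length_Mb`).
#' @param groups named vector mapping every individual to a group label.
#' @param min_cM minimum segment length in cM (default 3).
#' @return list of class `ibd_summary`: `pairs` (per-pair totals),
#'   `group_means` (`group_1`, `group_2`, `mean_Mb`, `n_pairs`).
#' @export
ibd_pair_summary <- function(segments, groups, min_cM = 3) {
  need <- c("individual_1", "individual_2", "length_cM", "length_Mb")
  if (!all(need %in% names(segments)))
    stop("segments need columns ", paste(need, collapse = ", "))
  ids <- names(groups)
  if (is.null(ids)) stop("'groups' must be a named vector")
  seg_ids <- unique(c(segments$individual_1, segments$individual_2))
  miss <- setdiff(seg_ids, ids)
  if (length(miss))
    stop("individual(s) without group label: ", paste(miss, collapse = ", "))
  seg <- segments[segments$length_cM >= min_cM, , drop = FALSE]
  a <- pmin(seg$individual_1, seg$individual_2)
  b <- pmax(seg$individual_1, seg$individual_2)
  key <- paste(a, b, sep = "\r")
  tot <- tapply(seg$length_Mb, key, sum)
  # universe of pairs from the group map
  cmb <- utils::combn(sort(ids), 2)
  pkey <- paste(cmb[1, ], cmb[2, ], sep = "\r")
  pair_tot <- setNames(rep(0, length(pkey)), pkey)
  pair_tot[names(tot)[names(tot) %in% pkey]] <-
    tot[names(tot) %in% pkey]
  pairs <- data.frame(individual_1 = cmb[1, ], individual_2 = cmb[2, ],
                      total_Mb = unname(pair_tot),
                      group_1 = unname(groups[cmb[1, ]]),
                      group_2 = unname(groups[cmb[2, ]]),
                      stringsAsFactors = FALSE)
  g1 <- pmin(pairs$group_1, pairs$group_2)
  g2 <- pmax(pairs$group_1, pairs$group_2)
  gm <- aggregate(pairs$total_Mb, list(group_1 = g1, group_2 = g2),
                  function(x) c(mean(x), length(x)))
  group_means <- data.frame(group_1 = gm$group_1, group_2 = gm$group_2,
                            mean_Mb = gm$x[, 1], n_pairs = gm$x[, 2],
                            stringsAsFactors = FALSE)
  structure(list(pairs = pairs, group_means = group_means,
                 min_cM = min_cM), class = "ibd_summary")
}

#' @export
print.ibd_summary <- function(x, ...) {
  cat("IBD sharing summary (segments >=", x$min_cM, "cM):\n")
  print(x$group_means, row.names = FALSE, digits = 4)
  invisible(x)
}
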