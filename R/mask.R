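# Ancestry masking of haplotype panels and individual selection.

#' Select individuals by minimum ancestry fraction
#'
#' Boundary-inclusive: an individual at exactly the threshold is kept.
#' Default thresholds in downstream analyses are 40% European, 75%
#' African, 15% Native American.
#'
#' @param proportions `ancestry_proportions` matrix at individual level
#'   (or any matrix/data.frame with individuals as rows and ancestries as
#'   columns).
#' @param ancestry target ancestry column.
#' @param threshold minimum fraction in `[0, 1]`.
#' @return character vector of selected individual ids (rownames); warns
#'   when the selection is empty.
#' @export
select_individuals <- function(proportions, ancestry, threshold) {
  p <- as.matrix(proportions)
  if (!ancestry %in% colnames(p))
    stop("ancestry '", ancestry, "' not in proportions")
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  sel <- rownames(p)[p[, ancestry] >= threshold]
  if (length(sel) == 0)
    warning("no individuals reach ", threshold, " ", ancestry, " ancestry")
  sel
}

#' Mask a haplotype panel to one ancestry
#'
#' Sets to missing every allele whose local-ancestry call differs from the
#' target ancestry, leaving only the haplotype material inherited from
#' that ancestry.  Reference panels are left unmasked by construction
#' (only pass the panel to be masked).
#'
#' @param panel a `haplotype_panel`.
#' @param calls per-site ancestry labels aligned to the panel: a
#'   `local_ancestry_calls` object (codes are translated through its code
#'   book), a character matrix of labels with the panel's shape, or
#'   `NULL` to use the panel's own simulation truth.
#' @param ancestry target ancestry label.
#' @return object of class `masked_panel` (also a `haplotype_panel`) with
#'   attributes `target` and `unmasked_sites` (per-haplotype count).
#' @export
mask_panel <- function(panel, calls = NULL, ancestry) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(calls)) {
    if (is.null(panel$truth))
      stop("panel has no local-ancestry truth; supply 'calls'")
    lab <- panel$truth
  } else if (inherits(calls, "local_ancestry_calls")) {
    if (!identical(dim(calls$codes), dim(panel$geno)))
      stop("calls are not aligned to the panel")
    lab <- matrix(calls$code_book[as.character(calls$codes)],
                  nrow = nrow(calls$codes))
  } else {
    lab <- as.matrix(calls)
    if (!identical(dim(lab), dim(panel$geno)))
      stop("calls are not aligned to the panel")
  }
  geno <- panel$geno
  geno[lab != ancestry] <- NA_integer_
  out <- panel
  out$geno <- geno
  attr(out, "target") <- ancestry
  attr(out, "unmasked_sites") <- colSums(!is.na(geno))
  class(out) <- c("masked_panel", class(panel))
  out
}
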