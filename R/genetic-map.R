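#' Construct a genetic map
#'
#' A map is a set of chromosomes with genetic lengths in Morgans; at most
#' one chromosome may be flagged as the X.  Coordinates along a chromosome
#' run from 0 cM; tract intervals are half-open `[start, end)`.
#'
#' @param lengths_M numeric vector of chromosome lengths in Morgans,
#'   optionally named.
#' @param is_x logical vector (same length) flagging the X chromosome;
#'   defaults to all autosomes.
#' @return object of class `genetic_map`: a `data.frame` with columns
#'   `chrom`, `length_M`, `is_x`.
#' @examples
#' genetic_map(c(chr1 = 2, chr2 = 1.5))
#' @export
genetic_map <- function(lengths_M, is_x = NULL) {
  if (any(lengths_M <= 0)) stop("chromosome lengths must be positive")
  if (is.null(is_x)) is_x <- rep(FALSE, length(lengths_M))
  if (length(is_x) != length(lengths_M))
    stop("'is_x' must match 'lengths_M' in length")
  if (sum(is_x) > 1) stop("at most one chromosome may be flagged X")
  nm <- names(lengths_M)
  if (is.null(nm)) {
    nm <- paste0("chr", seq_along(lengths_M))
    if (any(is_x)) nm[is_x] <- "chrX"
  }
  structure(data.frame(chrom = nm, length_M = unname(lengths_M),
                       is_x = is_x, stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Toy genetic map for simulations and examples
#'
#' Equal-length autosomes plus an optional X chromosome.  Not a human map;
#' real analyses should supply their own.
#'
#' @param n_autosomes number of autosomes.
#' @param autosome_M genetic length of each autosome in Morgans.
#' @param include_x add an X chromosome?
#' @param x_M genetic length of the X (sex-averaged transmission is handled
#'   by the simulator, so this is the female map length).
#' @return a `genetic_map`.
#' @export
toy_genetic_map <- function(n_autosomes = 5, autosome_M = 1, include_x = FALSE,
                            x_M = 1.8) {
  len <- rep(autosome_M, n_autosomes)
  names(len) <- paste0("chr", seq_len(n_autosomes))
  if (include_x) {
    len <- c(len, chrX = x_M)
    genetic_map(len, is_x = c(rep(FALSE, n_autosomes), TRUE))
  } else {
    genetic_map(len)
  }
}

#' Evenly spaced sites along a genetic map
#'
#' Generates a site map (chrom, bp, cM) with constant genetic spacing,
#' using a nominal 1 cM/Mb to place physical positions.
#'
#' @param map a `genetic_map`.
#' @param spacing_cM genetic distance between adjacent sites.
#' @param offset_cM position of the first site on each chromosome.
#' @return `data.frame` with columns `chrom`, `bp`, `cM`.
#' @export
uniform_sites <- function(map, spacing_cM = 0.2, offset_cM = spacing_cM / 2) {
  stopifnot(inherits(map, "genetic_map"))
  out <- lapply(seq_len(nrow(map)), function(i) {
    cm <- seq(offset_cM, map$length_M[i] * 100 - 1e-9, by = spacing_cM)
    data.frame(chrom = map$chrom[i], bp = round(cm * 1e6), cM = cm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

map_chrom_lengths_cM <- function(map) {
  setNames(map$length_M * 100, map$chrom)
}
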