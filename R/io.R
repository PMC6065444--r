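# Plain-text interchange: tract TSV with a commented header carrying the
# chromosome lengths and haplotype count so a round trip is lossless.

#' Write a tract set as TSV
#'
#' Columns: `haplotype_id`, `chrom`, `start_cM`, `end_cM`, `ancestry`,
#' `censored` (plus `individual`/`compartment` when present).  Chromosome
#' lengths and the haplotype count are stored in `#`-prefixed header
#' lines.
#'
#' @param tracts a `tract_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracts_tsv <- function(tracts, path) {
  stopifnot(inherits(tracts, "tract_set"))
  lens <- attr(tracts, "chrom_lengths_cM")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(lens))
    cat(sprintf("#chrom\t%s\t%.10g\n", names(lens)[i], lens[i]), file = con)
  cat(sprintf("#n_hap\t%d\n", attr(tracts, "n_hap")), file = con)
  df <- as.data.frame(tracts)
  names(df)[names(df) == "haplotype"] <- "haplotype_id"
  df$length_cM <- NULL
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tract set written by [write_tracts_tsv()]
#'
#' @param path file path.
#' @return a `tract_set`.
#' @export
read_tracts_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  lens <- c()
  n_hap <- NA_integer_
  for (h in hdr) {
    f <- strsplit(sub("^#", "", h), "\t")[[1]]
    if (f[1] == "chrom") lens[f[2]] <- as.numeric(f[3])
    if (f[1] == "n_hap") n_hap <- as.integer(f[2])
  }
  if (length(lens) == 0 || is.na(n_hap))
    stop("missing #chrom / #n_hap header lines")
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[names(df) == "haplotype_id"] <- "haplotype"
  df$censored <- NULL
  as_tract_set(df, chrom_lengths_cM = lens, n_hap = n_hap)
}

#' Write cohort metadata (individual, sex, group) as TSV
#'
#' @param metadata `data.frame` with columns `individual`, `sex` and
#'   optionally `group`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
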