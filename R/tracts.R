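# From per-site local-ancestry calls to ancestry tracts and tract
# statistics.

#' Construct a per-site local-ancestry call set
#'
#' Holds a site map, a matrix of integer ancestry codes (one row per site,
#' one column per haplotype, RFMix Viterbi style), the code book mapping
#' codes to ancestry labels, and an optional haplotype-to-individual map.
#'
#' @param sites `data.frame` with columns `chrom`, `bp`, `cM`, sorted by
#'   chromosome and position.
#' @param codes integer matrix `n_sites x n_hap`.
#' @param code_book named character vector: names are the integer codes,
#'   values the ancestry labels (e.g. `c("1" = "EUR", "2" = "AFR")`).
#' @param hap_ind optional `data.frame` with columns `haplotype`,
#'   `individual`.
#' @param chrom_lengths_cM optional named vector of chromosome lengths;
#'   defaults to the last site position per chromosome.
#' @return object of class `local_ancestry_calls`.
#' @export
local_ancestry_calls <- function(sites, codes, code_book, hap_ind = NULL,
                                 chrom_lengths_cM = NULL) {
  codes <- as.matrix(codes)
  if (nrow(sites) != nrow(codes))
    stop("row count of 'codes' must equal the number of sites")
  if (!all(c("chrom", "cM") %in% names(sites)))
    stop("'sites' needs columns chrom and cM")
  known <- as.integer(names(code_book))
  bad <- setdiff(unique(as.vector(codes)), known)
  if (length(bad))
    stop("ancestry code(s) absent from code book: ",
         paste(bad, collapse = ", "))
  ord_ok <- tapply(sites$cM, sites$chrom, function(x) !is.unsorted(x))
  if (!all(ord_ok)) stop("sites must be sorted by cM within chromosome")
  if (is.null(chrom_lengths_cM))
    chrom_lengths_cM <- tapply(sites$cM, sites$chrom, max)
  if (!is.null(hap_ind) && nrow(hap_ind) != ncol(codes))
    stop("'hap_ind' must have one row per haplotype")
  structure(list(sites = sites, codes = codes, code_book = code_book,
                 hap_ind = hap_ind,
                 chrom_lengths_cM = chrom_lengths_cM[
                   unique(as.character(sites$chrom))]),
            class = "local_ancestry_calls")
}

#' @export
print.local_ancestry_calls <- function(x, ...) {
  cat("Local-ancestry calls:", nrow(x$codes), "sites x", ncol(x$codes),
      "haplotypes on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  cat("  ancestries:", paste(x$code_book, collapse = ", "), "\n")
  invisible(x)
}

#' Read an RFMix-style Viterbi ancestry matrix
#'
#' One whitespace-separated row per site, one integer ancestry code column
#' per haplotype, no header; the code book lives in a side file (two
#' columns: code, label).
#'
#' @param path path to the call matrix.
#' @param code_book named character vector, or path to the side file.
#' @param site_map `data.frame` with columns `chrom`, `bp`, `cM` matching
#'   the rows of the matrix.
#' @inheritParams local_ancestry_calls
#' @return a `local_ancestry_calls` object.
#' @export
read_local_ancestry <- function(path, code_book, site_map, hap_ind = NULL,
                                chrom_lengths_cM = NULL) {
  if (is.character(code_book) && length(code_book) == 1 &&
      file.exists(code_book)) {
    cb <- read.table(code_book, header = FALSE, stringsAsFactors = FALSE)
    code_book <- setNames(cb[[2]], cb[[1]])
  }
  codes <- as.matrix(read.table(path, header = FALSE))
  dimnames(codes) <- NULL
  if (nrow(codes) != nrow(site_map))
    stop("matrix has ", nrow(codes), " rows but site map has ",
         nrow(site_map), " sites")
  local_ancestry_calls(site_map, codes, code_book, hap_ind,
                       chrom_lengths_cM)
}

#' Write an RFMix-style Viterbi ancestry matrix
#'
#' @param calls a `local_ancestry_calls` object.
#' @param path output path for the matrix.
#' @param code_book_path output path for the code-book side file.
#' @return `path`, invisibly.
#' @export
write_local_ancestry <- function(calls, path,
                                 code_book_path = paste0(path, ".codes")) {
  write.table(calls$codes, path, row.names = FALSE, col.names = FALSE,
              quote = FALSE, sep = " ")
  write.table(data.frame(code = names(calls$code_book),
                         label = unname(calls$code_book)),
              code_book_path, row.names = FALSE, col.names = FALSE,
              quote = FALSE, sep = "\t")
  invisible(path)
}

#' Extract ancestry tracts from per-site calls
#'
#' Maximal runs of identical ancestry codes become tracts.  Tract
#' boundaries are placed at the cM midpoint between adjacent discordant
#' sites (unbiased under symmetric call error); the first and last tract
#' of each chromosome extend to the chromosome ends and are flagged
#' censored.
#'
#' @param calls a `local_ancestry_calls` object (at least 2 sites per
#'   chromosome).
#' @return a `tract_set`.
#' @export
extract_tracts <- function(calls) {
  stopifnot(inherits(calls, "local_ancestry_calls"))
  chroms <- unique(as.character(calls$sites$chrom))
  H <- ncol(calls$codes)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sel <- calls$sites$chrom == ch
    if (sum(sel) < 2)
      stop("chromosome ", ch, " has fewer than 2 sites")
    pos <- calls$sites$cM[sel]
    L <- unname(calls$chrom_lengths_cM[ch])
    sub <- calls$codes[sel, , drop = FALSE]
    pieces <- vector("list", H)
    for (h in seq_len(H)) {
      r <- rle(sub[, h])
      k <- length(r$lengths)
      last_idx <- cumsum(r$lengths)
      first_next <- pos[pmin(last_idx + 1, length(pos))]
      bounds <- (pos[last_idx] + first_next) / 2   # midpoints
      ends <- c(bounds[-k], L)
      starts <- c(0, ends[-k])
      pieces[[h]] <- data.frame(haplotype = h, chrom = ch,
                                start_cM = starts, end_cM = ends,
                                ancestry = unname(
                                  calls$code_book[as.character(r$values)]),
                                stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, pieces)
  }
  df <- do.call(rbind, out)
  if (!is.null(calls$hap_ind))
    df$individual <- calls$hap_ind$individual[df$haplotype]
  as_tract_set(df, chrom_lengths_cM = calls$chrom_lengths_cM, n_hap = H)
}

#' Global ancestry proportions from tracts
#'
#' Length-weighted (cM) ancestry fractions per haplotype, individual or
#' group.  Rows lie on the simplex.  If the tract set carries no
#' `individual` column, consecutive haplotype pairs (1,2), (3,4), ... are
#' taken to be individuals.  Group-level rows are unweighted means of the
#' individual rows.
#'
#' @param tracts a `tract_set`.
#' @param level `"haplotype"`, `"individual"` or `"group"`.
#' @param groups for `level = "group"`: named vector mapping individual id
#'   to group label.
#' @return matrix (class `ancestry_proportions`) with one row per unit and
#'   one column per ancestry.
#' @export
global_proportions <- function(tracts,
                               level = c("haplotype", "individual", "group"),
                               groups = NULL) {
  stopifnot(inherits(tracts, "tract_set"))
  if (nrow(tracts) == 0) stop("empty tract set")
  level <- match.arg(level)
  ancestries <- sort(unique(tracts$ancestry))
  ind <- tract_individual(tracts)
  by <- switch(level,
               haplotype = tracts$haplotype,
               individual = ind,
               group = ind)
  p <- proportions_by(tracts, by, ancestries)
  if (level == "group") {
    if (is.null(groups)) stop("'groups' is required at group level")
    miss <- setdiff(rownames(p), names(groups))
    if (length(miss))
      stop("individuals without group label: ", paste(miss, collapse = ", "))
    g <- groups[rownames(p)]
    p <- do.call(rbind, lapply(split(seq_len(nrow(p)), g), function(i)
      colMeans(p[i, , drop = FALSE])))
  }
  structure(p, level = level, class = c("ancestry_proportions", "matrix",
                                        "array"))
}

tract_individual <- function(tracts) {
  if (!is.null(tracts$individual)) tracts$individual
  else ceiling(tracts$haplotype / 2)
}

#' Classify a tract length as excluded, short or long
#'
#' Lengths of at most 5 cM are excluded from tract-class statistics;
#' lengths in (5, 50] cM are short; above 50 cM long.
#'
#' @param length_cM positive tract length(s) in cM.
#' @return factor with levels `excluded`, `short`, `long`.
#' @export
classify_tract <- function(length_cM) {
  if (any(length_cM <= 0)) stop("tract lengths must be positive")
  cls <- ifelse(length_cM <= 5, "excluded",
                ifelse(length_cM <= 50, "short", "long"))
  factor(cls, levels = c("excluded", "short", "long"))
}

#' Short/long tract-class statistics
#'
#' Classifies tracts ([classify_tract()]) and computes, per group, the two
#' comparison tables: the ancestry composition within each tract class
#' (what fraction of all short tracts are of each ancestry), and the class
#' split within each ancestry (what fraction of an ancestry's classified
#' tracts are short versus long).  Proportions by tract count are primary;
#' length-weighted proportions are reported alongside.
#'
#' @param tracts a `tract_set`.
#' @param groups optional named vector mapping individual id to group; by
#'   default all tracts form one group.
#' @return object of class `tract_class_table`: list with elements
#'   `composition`, `split` (both `data.frame`s), `counts` (group x
#'   ancestry x class array) and `empty_classes` (flagged group/class
#'   combinations without classified tracts).
#' @export
tract_class_stats <- function(tracts, groups = NULL) {
  stopifnot(inherits(tracts, "tract_set"))
  cls <- classify_tract(tracts$length_cM)
  ind <- tract_individual(tracts)
  grp <- if (is.null(groups)) rep("all", nrow(tracts)) else {
    miss <- setdiff(unique(as.character(ind)), names(groups))
    if (length(miss))
      stop("individuals without group label: ", paste(miss, collapse = ", "))
    as.character(groups[as.character(ind)])
  }
  ancestries <- sort(unique(tracts$ancestry))
  gl <- sort(unique(grp))
  counts <- table(factor(grp, gl), factor(tracts$ancestry, ancestries), cls)
  lens <- tapply(tracts$length_cM,
                 list(factor(grp, gl), factor(tracts$ancestry, ancestries),
                      cls), sum, default = 0)
  comp <- split_tab <- NULL
  empty <- character(0)
  for (g in gl) {
    for (k in c("short", "long")) {
      nc <- counts[g, , k]
      nl <- lens[g, , k]
      if (sum(nc) == 0) {
        empty <- c(empty, paste(g, k, sep = "/"))
        next
      }
      comp <- rbind(comp, data.frame(group = g, class = k,
                                     ancestry = ancestries,
                                     prop_count = as.numeric(nc / sum(nc)),
                                     prop_length = as.numeric(nl / sum(nl)),
                                     stringsAsFactors = FALSE))
    }
    for (a in ancestries) {
      nc <- counts[g, a, c("short", "long")]
      nl <- lens[g, a, c("short", "long")]
      if (sum(nc) == 0) {
        empty <- c(empty, paste(g, a, sep = "/"))
        next
      }
      split_tab <- rbind(split_tab,
                         data.frame(group = g, ancestry = a,
                                    class = c("short", "long"),
                                    prop_count = as.numeric(nc / sum(nc)),
                                    prop_length = as.numeric(nl / sum(nl)),
                                    stringsAsFactors = FALSE))
    }
  }
  if (length(empty))
    warning("no classified tracts for: ", paste(empty, collapse = ", "))
  structure(list(composition = comp, split = split_tab, counts = counts,
                 lengths = lens, empty_classes = empty),
            class = "tract_class_table")
}

#' @export
print.tract_class_table <- function(x, ...) {
  cat("Tract-class statistics (count-based proportions):\n")
  cat("\nComposition within class:\n")
  print(x$composition, row.names = FALSE, digits = 3)
  cat("\nShort/long split within ancestry:\n")
  print(x$split, row.names = FALSE, digits = 3)
  if (length(x$empty_classes))
    cat("\nFlagged empty classes:", paste(x$empty_classes, collapse = ", "),
        "\n")
  invisible(x)
}
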