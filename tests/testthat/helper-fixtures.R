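# Shared fixture builders; everything is generated in code.

fix_history_single_pulse <- function(t = 10, m = 0.2,
                                     founding = c(EUR = 0.8, NAM = 0.2)) {
  build_history(founding, T_max = 15,
                pulses = data.frame(t = t, ancestry = "AFR", m = m))
}

fix_sexed_history <- function(s_f = 0.3, s_m = 0.1) {
  build_history(list(female = c(AFR = s_f, EUR = 1 - s_f),
                     male = c(AFR = s_m, EUR = 1 - s_m)), T_max = 15)
}

# tiny call set: codes matrix over a single chromosome
fix_calls <- function(codes, pos = seq_len(nrow(as.matrix(codes))) - 1,
                      chrom_len = max(pos), chrom = "chr1",
                      code_book = c("1" = "A", "2" = "B", "3" = "C")) {
  codes <- as.matrix(codes)
  sites <- data.frame(chrom = chrom, bp = round(pos * 1e6), cM = pos)
  local_ancestry_calls(sites, codes, code_book,
                       chrom_lengths_cM = setNames(chrom_len, chrom))
}

# hand-built tract set
fix_tracts <- function(lengths_cM, ancestry, haplotype = 1,
                       chrom_len = sum(lengths_cM) + 10) {
  ends <- cumsum(lengths_cM)
  df <- data.frame(haplotype = haplotype, chrom = "chr1",
                   start_cM = c(0, ends[-length(ends)]), end_cM = ends,
                   ancestry = ancestry, stringsAsFactors = FALSE)
  as_tract_set(df, chrom_lengths_cM = c(chr1 = chrom_len),
               n_hap = length(unique(haplotype)))
}

# compartment-ancestry table built directly from q values
fix_compartment <- function(q_auto, q_x, sex = NULL) {
  n <- length(q_auto)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  out <- rbind(
    data.frame(individual = as.character(seq_len(n)), sex = sex,
               group = "all", ancestry = "AFR", q_auto = q_auto, q_x = q_x),
    data.frame(individual = as.character(seq_len(n)), sex = sex,
               group = "all", ancestry = "EUR", q_auto = 1 - q_auto,
               q_x = 1 - q_x))
  class(out) <- c("compartment_ancestry", "data.frame")
  out
}

expect_simplex_rows <- function(m, tol = 1e-8) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
  expect_true(all(m >= -tol))
}
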