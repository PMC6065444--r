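# Fast internal negative log-likelihood for fit_pulse_model: the same
# quantity as poisson_loglik(obs, expected_bin_counts(...)), delegated to
# compiled code (src/pulse_negll.cpp) because the optimizer evaluates it
# tens of thousands of times per fit.  Takes the raw parameter vector
# (linked pulse times still on the (0,1) scale).

make_negll <- function(model, histogram, G0, correction, rate_offset,
                       t_min = 2) {
  modelled <- union(model$founding, model$pulses$ancestry)
  obs <- histogram$counts[modelled, , drop = FALSE]
  storage.mode(obs) <- "double"
  edges <- histogram$edges_cM / 100
  Lt <- table(histogram$chrom_lengths_cM / 100)
  after <- ifelse(is.na(model$pulses$after), 0L,
                  match(model$pulses$after, model$pulses$label))
  anc_idx <- c(match(model$founding, modelled),
               match(model$pulses$ancestry, modelled))
  lo_e <- edges[-length(edges)]
  hi_e <- edges[-1]
  Lu <- as.numeric(names(Lt))
  Lw <- as.numeric(Lt)
  n_hap <- as.numeric(histogram$n_hap)
  neighbor <- correction == "neighbor"
  lg <- sum(lgamma(obs + 1))
  function(theta) {
    pulse_negll_cpp(theta, after, anc_idx, G0, obs, lo_e, hi_e, Lu, Lw,
                    n_hap, neighbor, rate_offset, t_min, lg)
  }
}
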