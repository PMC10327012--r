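# Shared fixtures and independent oracles for the test suite.

rs_params <- function() {
  izhikevich_params(C = 100, k = 0.7, Vr = -60, Vt = -40, Vpeak = 35,
                    Vmin = -50, a = 0.03, b = -2, d = 100)
}

fs_params <- function() {
  izhikevich_params(C = 20, k = 1, Vr = -55, Vt = -40, Vpeak = 25,
                    Vmin = -45, a = 0.15, b = 0.5, d = 10)
}

# Exact single-parcel connection oracle by enumeration of the binomial
# hit-count distribution (integer bouton count nb, per-bouton hit
# probability q): independent of the closed-form product formula.
enumerate_connection <- function(nb, q) {
  k <- 0:nb
  pk <- dbinom(k, nb, q)
  p <- sum(pk[k > 0])
  lambda <- sum(k * pk)
  list(probability = p, expected_synapses = lambda,
       contacts = sum(k[k > 0] * pk[k > 0]) / p)
}

# Chi-square goodness-of-fit of observed counts against Binomial(M, p),
# binning the support into roughly equal-probability bins with expected
# counts >= 5.
binomial_gof_pvalue <- function(counts, M, p, n_bins = 10) {
  qs <- unique(qbinom(seq(0, 1, length.out = n_bins + 1), M, p))
  edges <- qs[-c(1, length(qs))]
  probs <- diff(c(0, pbinom(edges, M, p), 1))
  obs <- table(cut(counts, breaks = c(-Inf, edges, Inf)))
  suppressWarnings(
    stats::chisq.test(as.integer(obs), p = probs, rescale.p = TRUE)$p.value
  )
}

# Spike-to-spike TPM recurrence iterated directly (algebraic oracle for
# periodic trains, independent of psc_amplitude_train's event loop).
iterate_tpm_recurrence <- function(params, interval, n, tol = 1e-12) {
  p <- as_tpm_params(params)
  Ef <- exp(-interval / p$tau_f)
  Er <- exp(-interval / p$tau_r)
  u_plus <- p$U
  R_minus <- 1
  rel <- R_minus * u_plus
  for (i in seq_len(n)) {
    R_plus <- R_minus - R_minus * u_plus
    R_next <- 1 - (1 - R_plus) * Er
    u_next <- u_plus * Ef + p$U * (1 - u_plus * Ef)
    if (abs(R_next - R_minus) < tol && abs(u_next - u_plus) < tol) {
      R_minus <- R_next
      u_plus <- u_next
      break
    }
    R_minus <- R_next
    u_plus <- u_next
  }
  R_minus * u_plus
}
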