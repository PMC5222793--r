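# Shared fixtures: small grids and short sessions keep the unit tests fast;
# the acceptance suite uses the full-size defaults.

tiny_grid <- function(sizes = c(5L, 5L, 4L, 3L, 3L), ...) {
  csf_param_grid(sizes = sizes, ...)
}

small_grid <- function() csf_param_grid(sizes = c(12L, 12L, 12L, 5L, 5L))

normal_truth <- function(sfs = stimulus_grid()$sfs) {
  csf_sensitivity(sfs, 100, 0.8, 4)
}

# brute-force posterior computed with plain loops over every node, using
# only detect_prob; independent of the engine's vectorized/tabulated paths
brute_force_posterior <- function(trials, grid) {
  ax <- grid$axes
  sz <- grid$sizes
  prior <- build_prior(grid)$mass
  lp <- array(0, sz)
  for (i1 in seq_len(sz[1])) for (i2 in seq_len(sz[2]))
    for (i3 in seq_len(sz[3])) for (i4 in seq_len(sz[4]))
      for (i5 in seq_len(sz[5])) {
        th <- list(M = 10^ax$M[i1], A = 10^ax$A[i2], F = 10^ax$F[i3],
                   beta = 10^ax$beta[i4], gamma = grid$gamma,
                   delta = 10^ax$delta[i5])
        P <- detect_prob(trials$sf_cpd, trials$contrast, th)
        lp[i1, i2, i3, i4, i5] <- log(prior[i1, i2, i3, i4, i5]) +
          sum(ifelse(trials$response == 1, log(P), log1p(-P)))
      }
  w <- exp(lp - max(lp))
  w / sum(w)
}
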