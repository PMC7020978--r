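# Exhaustive sign-pattern oracle for the signed-rank test, independent of
# the package implementation: enumerates all 2^n assignments of signs to the
# observed absolute-difference ranks.
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_low <- mean(w_all <= w_obs + 1e-9)
  p_high <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}
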