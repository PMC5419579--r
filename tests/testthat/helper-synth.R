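# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# draw n multivariate-normal vectors with mean mu and correlation R
rmvn_chol <- function(n, mu, R) {
  ch <- chol(R + diag(1e-8, nrow(R)))
  t(mu + crossprod(ch, matrix(rnorm(nrow(R) * n), nrow(R), n)))
}

# a small cached LD panel reused by several files
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_haplotypes(800, 40, 2e5, rho = 0.85, seed = 424242)
    cache
  }
})

# z-score ncp giving a fixed analytic power at genome-wide alpha
z_at_power <- function(power, alpha = 5e-8) {
  ncp <- uniroot(function(l)
    pchisq(qchisq(1 - alpha, 1), 1, ncp = l, lower.tail = FALSE) - power,
    c(0.1, 200))$root
  sqrt(ncp)
}
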