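# Direct numerical maximisation of the observed-data MVN likelihood via a
# Cholesky parameterisation -- the independent oracle for the EM fits.
# Only suitable for tiny instances.
direct_mvn_mle <- function(y) {
  y <- as.matrix(y)
  p <- ncol(y)
  nll <- function(par) {
    mu <- par[seq_len(p)]
    l <- matrix(0, p, p)
    l[lower.tri(l, diag = TRUE)] <- par[-seq_len(p)]
    diag(l) <- exp(diag(l))
    s <- l %*% t(l)
    ll <- 0
    for (i in seq_len(nrow(y))) {
      o <- which(!is.na(y[i, ]))
      if (!length(o)) next
      ll <- ll + mvtnorm::dmvnorm(y[i, o], mu[o], s[o, o, drop = FALSE],
                                  log = TRUE)
    }
    -ll
  }
  init <- c(colMeans(y, na.rm = TRUE), rep(0, p * (p + 1) / 2))
  fit <- optim(init, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  list(loglik = -fit$value)
}

# small bivariate MVN with MCAR masking on the second column
mcar_bivariate <- function(n, rho, miss = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- mvtnorm::rmvnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    x[runif(n) < miss, 2] <- NA
    x
  })
}
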