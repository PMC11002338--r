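# Shared fixtures and independent oracles, built in code at test time.

# small, well-spread gradient table (one b0 + n directions)
test_gtab <- function(n_dirs = 32, bvalue = 1000) {
  dirs <- dwi_directions(n_dirs)
  gradient_table(c(0, rep(bvalue, n_dirs)), rbind(c(0, 0, 0), dirs))
}

# two-slab regions with pure tissue (f = 0), spec'd slab diffusivities
pure_tissue_regions <- function(proj = c(1.2e-3, 0.6e-3, 1.7e-3),
                                assoc = c(1.2e-3, 1.7e-3, 0.6e-3),
                                bg = c(0.8e-3, 0.8e-3, 0.8e-3)) {
  list(background = list(evals = bg, f = 0),
       projection = list(evals = proj, f = 0),
       association = list(evals = assoc, f = 0))
}

# closed-form FA, written independently of the package implementation
oracle_fa <- function(l1, l2, l3) {
  sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
}

# analytic mean of a Rician(nu, sigma) variate via the Laguerre half form,
# exponentially scaled Bessel functions to survive large SNR
oracle_rician_mean <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# dense log-g trapezoid oracle for the JZS linear-model Bayes factor
oracle_bf10_trapezoid <- function(y, X, r_eff2, n_grid = 1e6) {
  n <- length(y)
  k <- ncol(X)
  if (k == 0L) return(1)
  yc <- y - mean(y)
  R2 <- 1 - sum(lm.fit(X, yc)$residuals^2) / sum(yc^2)
  b <- n * r_eff2 / 2
  t <- seq(-40, 40, length.out = n_grid)
  g <- exp(t)
  logf <- (n - 1 - k) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - R2)) +
    0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g + t
  M <- max(logf)
  exp(M) * sum(exp(logf - M)) * (t[2] - t[1])
}

# Rouder-style JZS two-sample Bayes factor from the t statistic, adaptive
# quadrature on the log-g axis; rscale is the Cauchy scale on the
# standardized group difference
oracle_bf10_ttest <- function(tstat, n1, n2, rscale) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  b <- rscale^2 / 2
  logf <- function(s) {
    g <- exp(s)
    -0.5 * log1p(N * g) - (nu + 1) / 2 * log1p(tstat^2 / ((1 + N * g) * nu)) +
      0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g + s
  }
  M <- optimize(logf, c(-40, 40), maximum = TRUE)$objective
  num <- integrate(function(s) exp(logf(s) - M), -50, 50, rel.tol = 1e-12)$value
  exp(M + log(num) + (nu + 1) / 2 * log1p(tstat^2 / nu))
}

# centered design column for a 2-level factor coded -1/2, +1/2
oracle_group_column <- function(group) {
  x <- ifelse(group == levels(as.factor(group))[1], -0.5, 0.5)
  x - mean(x)
}
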