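# Independent oracles, kept deliberately naive: nested loops and direct
# linear algebra, no log-space tricks, no shared code with the package.

# Colocalisation by explicit enumeration of causal-configuration pairs:
# trait 1 causal at i (or none), trait 2 causal at j (or none).
oracle_coloc <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  bf1 <- exp(l1); bf2 <- exp(l2)
  n <- length(bf1)
  S <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(n)) S["h1"] <- S["h1"] + p1 * bf1[i]
  for (j in seq_len(n)) S["h2"] <- S["h2"] + p2 * bf2[j]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) S["h4"] <- S["h4"] + p12 * bf1[i] * bf2[j]
    else S["h3"] <- S["h3"] + p1 * p2 * bf1[i] * bf2[j]
  }
  unname(S / sum(S))
}

# Fine-mapping by direct MVN densities: for each causal set C,
# V = R + sigma^2 R[,C] R[C,], log-lik via solve()/determinant().
oracle_finemap <- function(z, R, max_causal, gamma = 0.01, sigma = 5) {
  n <- length(z)
  configs <- list(integer())
  for (cs in seq_len(max_causal))
    configs <- c(configs, combn(n, cs, simplify = FALSE))
  lp <- sapply(configs, function(C) {
    V <- R
    if (length(C))
      V <- R + sigma^2 * R[, C, drop = FALSE] %*% R[C, , drop = FALSE]
    ld <- determinant(V, logarithm = TRUE)$modulus
    ll <- -0.5 * as.numeric(ld) - 0.5 * as.numeric(t(z) %*% solve(V, z))
    ll + length(C) * log(gamma) + (n - length(C)) * log(1 - gamma)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  pip <- numeric(n)
  for (k in seq_along(configs)) pip[configs[[k]]] <-
    pip[configs[[k]]] + w[k]
  pip
}

# Benjamini-Hochberg by the literal recipe: sort, p * m / rank, running
# minimum from the largest rank down, map back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# P(Z1 < a, Z2 < b) under bivariate normal with correlation rho, by 1-D
# quadrature of the conditional normal.
oracle_orthant <- function(a, b, rho) {
  f <- function(x) pnorm((b - rho * x) / sqrt(1 - rho^2)) * dnorm(x)
  integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# haplotype (allelic) correlation implied by the Gaussian copula with
# latent correlation rho and allele frequencies f1, f2
oracle_copula_hap_cor <- function(rho, f1, f2) {
  p11 <- oracle_orthant(qnorm(f1), qnorm(f2), rho)
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# latent rho giving a target haplotype correlation at frequencies f1, f2
oracle_copula_calibrate <- function(target_r, f1, f2) {
  uniroot(function(rho) oracle_copula_hap_cor(rho, f1, f2) - target_r,
          c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}
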