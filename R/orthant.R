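# Numerical kernels for the two multivariate-normal probabilities the
# strategy models need. Both are deterministic (no quasi-Monte-Carlo).

# P(lo <= Z_i <= hi for all i) for k equicorrelated unit normals with
# common mean delta and pairwise correlation rho, via the one-factor
# reduction Z_i = sqrt(rho) U + sqrt(1-rho) eps_i + delta:
#   P = int phi(u) [Phi((hi - delta - sqrt(rho) u)/s)
#                   - Phi((lo - delta - sqrt(rho) u)/s)]^k du,  s = sqrt(1-rho)
equicorr_box_prob <- function(lo, hi, delta, k, rho, abs.tol = 1e-9) {
  if (rho == 0) {
    return((pnorm(hi - delta) - pnorm(lo - delta))^k)
  }
  s <- sqrt(1 - rho)
  sr <- sqrt(rho)
  f <- function(u) {
    dnorm(u) * (pnorm((hi - delta - sr * u) / s) -
                pnorm((lo - delta - sr * u) / s))^k
  }
  res <- tryCatch(
    integrate(f, -Inf, Inf, abs.tol = abs.tol, rel.tol = abs.tol,
              subdivisions = 400L),
    error = function(e) {
      stop(errorCondition(
        paste0("orthant quadrature failed: ", conditionMessage(e),
               sprintf(" (k=%d, rho=%g, delta=%g)", k, rho, delta)),
        class = c("qrprates_computation_error", "error")
      ))
    }
  )
  min(max(res$value, 0), 1)
}

# P(lo <= Z_j <= hi for all j) for the sequential z statistics
# Z_j = S_{n_j} / sqrt(v n_j) of one accumulating data set, with means
# `means` and Corr(Z_i, Z_j) = sqrt(n_i/n_j) for n_i <= n_j.  Because each
# Z_{j+1} depends on the past only through Z_j,
#   Z_{j+1} = r_j Z_j + sqrt(1 - r_j^2) e_j + (mu_{j+1} - r_j mu_j),
#   r_j = sqrt(n_j / n_{j+1}),
# so the joint box probability follows from propagating the subdensity of
# the surviving (not yet rejected) process through each look with
# Simpson-rule integration on a fixed grid.
sequential_box_prob <- function(n_sizes, means, lo, hi, nodes = 801L) {
  k <- length(n_sizes)
  if (k == 1L) {
    return(pnorm(hi - means[1L]) - pnorm(lo - means[1L]))
  }
  glo <- max(lo, min(means) - 8.5)
  ghi <- min(hi, max(means) + 8.5)
  if (glo >= ghi) return(0)
  nodes <- as.integer(nodes)
  if (nodes %% 2L == 0L) nodes <- nodes + 1L  # Simpson needs odd count
  grid <- seq(glo, ghi, length.out = nodes)
  h <- grid[2L] - grid[1L]
  w <- h / 3 * c(1, rep(c(4, 2), length.out = nodes - 2L), 1)
  dens <- dnorm(grid, mean = means[1L])
  for (j in seq_len(k - 1L)) {
    r <- sqrt(n_sizes[j] / n_sizes[j + 1L])
    s <- sqrt(1 - r^2)
    shift <- means[j + 1L] - r * means[j]
    K <- outer(grid, grid, function(z, x) dnorm((z - r * x - shift) / s) / s)
    dens <- as.vector(K %*% (dens * w))
  }
  min(max(sum(dens * w), 0), 1)
}
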