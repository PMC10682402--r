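# Independent numerical oracles used across tests. These deliberately
# avoid the closed-form code paths they are checking.

# Mean of the Weibull lifespan law by quadrature of the survival function
integral_mean <- function(r, alpha) {
  stats::integrate(function(g) exp(-(r * g)^alpha), 0, Inf,
                   rel.tol = 1e-12, subdivisions = 2000L)$value
}

# Variance via the second-moment identity E[X^2] = int 2 g S(g) dg
integral_var <- function(r, alpha) {
  m2 <- stats::integrate(function(g) 2 * g * exp(-(r * g)^alpha), 0, Inf,
                         rel.tol = 1e-12, subdivisions = 2000L)$value
  m2 - integral_mean(r, alpha)^2
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws: term genes are 1..K, count draws with overlap >= k
enum_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Textbook Benjamini-Hochberg step-up, computed literally:
# q_i = min over j with p_(j) >= p_i of p_(j) * m / rank_j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(sp[js] * m / js))
  }, 0)
}

# Small strain panel spanning the lifespan range seen in deletion screens
benchmark_specs <- function(n_strain = 50) {
  alphas <- seq(2, 7, length.out = n_strain)
  target_means <- seq(15, 36, length.out = n_strain)
  data.frame(strain = sprintf("s%02d", seq_len(n_strain)),
             r = exp(lgamma(1 + 1 / alphas)) / target_means,
             alpha = alphas, stringsAsFactors = FALSE)
}
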