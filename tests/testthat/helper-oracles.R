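# Independent oracles used to cross-check package computations.

# Nonlinear maximum-likelihood sinusoid fit by iteratively refined grid
# search over (A, phi, M); deliberately ignorant of the linearized OLS
# route used by fit_sinusoid().
grid_search_sinusoid <- function(times, values, period = 24,
                                 n_refine = 40) {
  w <- 2 * pi / period
  rss <- function(A, phi, M) sum((values - M - A * sin(w * times + phi))^2)
  a_lo <- 0; a_hi <- 2 * (max(values) - min(values)) + 1
  p_lo <- 0; p_hi <- 2 * pi
  m_lo <- min(values) - 1; m_hi <- max(values) + 1
  best <- c(A = 0, phi = 0, M = mean(values))
  for (it in seq_len(n_refine)) {
    a_gr <- seq(a_lo, a_hi, length.out = 11)
    p_gr <- seq(p_lo, p_hi, length.out = 13)
    m_gr <- seq(m_lo, m_hi, length.out = 11)
    sc <- expand.grid(A = a_gr, phi = p_gr, M = m_gr)
    v <- mapply(rss, sc$A, sc$phi, sc$M)
    best <- unlist(sc[which.min(v), ])
    shrink <- 0.55
    da <- (a_hi - a_lo) * shrink / 2
    dp <- (p_hi - p_lo) * shrink / 2
    dm <- (m_hi - m_lo) * shrink / 2
    a_lo <- max(best[1] - da, 0); a_hi <- best[1] + da
    p_lo <- best[2] - dp; p_hi <- best[2] + dp
    m_lo <- best[3] - dm; m_hi <- best[3] + dm
  }
  # simplex polish from the grid optimum (guards against a refinement
  # window that shrank past the optimum on a flat RSS surface)
  op <- stats::optim(best, function(p) rss(max(p[1], 0), p[2], p[3]),
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000))
  best <- op$par
  list(A = max(unname(best[1]), 0), phi = unname(best[2]) %% (2 * pi),
       M = unname(best[3]))
}

# Exhaustive Kruskal-Wallis permutation p-value by direct enumeration
# of all distinct label assignments (two groups only).
exhaustive_kw_p_two_groups <- function(values, n1) {
  n <- length(values)
  idx <- utils::combn(n, n1)
  labels0 <- function(pick) {
    g <- rep("b", n); g[pick] <- "a"; g
  }
  h_obs <- kw_statistic(values, labels0(seq_len(n1)))
  h_all <- apply(idx, 2, function(pick) kw_statistic(values, labels0(pick)))
  mean(h_all >= h_obs - 1e-12)
}

# Upper-tail chi-square probability for df = 4 in closed form,
# independent of pchisq: P(X > x) = exp(-x/2) * (1 + x/2).
chisq4_upper <- function(x) exp(-x / 2) * (1 + x / 2)

# Small deterministic study used by several test files.
small_study <- function(seed = 42, n_pangenes = 30, n_inbreds = 12, ...) {
  simulate_study(sim_config(n_pangenes = n_pangenes,
                            n_inbreds = n_inbreds, seed = seed, ...))
}
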