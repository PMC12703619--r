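# Independent oracles used across the suite. These are deliberately naive
# (truncated-power bases, explicit Newton steps, double loops) and share no
# code with the package implementation they check.

# Natural cubic spline space via the textbook truncated-power construction:
# with knots xi_1 < ... < xi_K (boundary knots included), the natural space is
# span{1, x, N_1, ..., N_{K-2}} where N_k = d_k - d_{K-1} and
# d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k).
oracle_natural_spline <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  stopifnot(K >= 2)
  dk <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  cols <- list(x)
  if (K > 2) {
    for (k in seq_len(K - 2)) cols[[length(cols) + 1]] <- dk(k) - dk(K - 1)
  }
  do.call(cbind, cols)
}

# max distance between the column spaces of two bases (each augmented with an
# intercept): largest residual norm of one basis' columns after projection
# onto the other's span, symmetrized, scaled by column norm
colspace_distance <- function(A, B) {
  A <- cbind(1, A)
  B <- cbind(1, B)
  resid_of <- function(M, onto) {
    Q <- qr.Q(qr(onto))
    R <- M - Q %*% (t(Q) %*% M)
    max(sqrt(colSums(R^2)) / pmax(sqrt(colSums(M^2)), 1e-12))
  }
  max(resid_of(A, B), resid_of(B, A))
}

# Poisson log-link MLE by explicit Newton-Raphson on the score equations
oracle_newton_poisson <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.5)
  for (i in seq_len(maxit)) {
    mu <- exp(X %*% beta)
    score <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * as.numeric(mu))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(X %*% beta)
  H <- t(X) %*% (X * as.numeric(mu))
  list(beta = as.numeric(beta), cov = solve(H))
}

# cross-basis design by explicit double loops over lags and basis columns;
# takes the marginal exposure/lag bases as plain matrices
oracle_crossbasis_loops <- function(Bc, C, max_lag) {
  n <- nrow(Bc)
  dvar <- ncol(Bc)
  dlag <- ncol(C)
  out <- matrix(NA_real_, n, dvar * dlag)
  for (t in seq_len(n)) {
    if (t <= max_lag) next
    for (i in seq_len(dvar)) {
      for (j in seq_len(dlag)) {
        acc <- 0
        for (l in 0:max_lag) acc <- acc + Bc[t - l, i] * C[l + 1, j]
        out[t, (i - 1) * dlag + j] <- acc
      }
    }
  }
  out
}

# brute-force piecewise linear interpolation over a segment table
oracle_piecewise_iaqi <- function(conc, seg) {
  vapply(conc, function(cc) {
    if (cc > max(seg$bp_hi)) return(max(seg$iaqi_hi))
    for (r in seq_len(nrow(seg))) {
      if (cc >= seg$bp_lo[r] && cc <= seg$bp_hi[r]) {
        return((seg$iaqi_hi[r] - seg$iaqi_lo[r]) /
                 (seg$bp_hi[r] - seg$bp_lo[r]) * (cc - seg$bp_lo[r]) +
                 seg$iaqi_lo[r])
      }
    }
    stop("no segment")
  }, numeric(1))
}

# small synthetic daily series for structural tests
make_tiny_series <- function(n = 60, seed = 11) {
  set.seed(seed)
  data.frame(
    date = as.Date("2015-01-01") + 0:(n - 1),
    deaths_total = rpois(n, 20),
    pressure = rnorm(n, 1000, 3),
    temp_mean = rnorm(n, 20, 4),
    wind_mean = rlnorm(n, 0.6, 0.4),
    humidity_mean = pmin(100, pmax(0, rnorm(n, 75, 8))),
    aqi = round(runif(n, 15, 120))
  )
}
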