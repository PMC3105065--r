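# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, brute-force decompositions and a
# finite-difference PDE solver.

# Closed-form OLS slope: sum((x-xbar)(y-ybar)) / sum((x-xbar)^2)
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Second-order finite-difference solution of d/dz(phi*Ds*dC/dz) + P(z) = 0
# with C(0) = c_top and zero flux at the bottom, on a uniform grid (cm).
# Returns concentrations at the grid nodes.
fd_profile_oracle <- function(boundaries_um, rates, c_top, porosity,
                              diffusivity, n_nodes = 2001) {
  D <- porosity * diffusivity * 1e4            # cm2 s-1
  b_cm <- boundaries_um / 1e4
  L <- b_cm[length(b_cm)] - b_cm[1]
  h <- L / (n_nodes - 1)
  z <- b_cm[1] + h * (seq_len(n_nodes) - 1)
  zone <- pmin(pmax(findInterval(z, b_cm, rightmost.closed = TRUE), 1),
               length(rates))
  P <- rates[zone]
  # interior: D*(C[i-1] - 2C[i] + C[i+1])/h^2 = -P[i]
  main <- rep(-2, n_nodes); lower <- rep(1, n_nodes - 1); upper <- rep(1, n_nodes - 1)
  rhs <- -P * h^2 / D
  # Dirichlet at node 1
  main[1] <- 1; upper[1] <- 0; rhs[1] <- c_top
  # zero flux at bottom via ghost node: C[n-1] appears twice
  main[n_nodes] <- -2; lower[n_nodes - 1] <- 2; rhs[n_nodes] <- -P[n_nodes] * h^2 / D
  A <- diag(main)
  A[cbind(2:n_nodes, 1:(n_nodes - 1))] <- lower
  A[cbind(1:(n_nodes - 1), 2:n_nodes)] <- upper
  list(z_um = z * 1e4, conc = solve(A, rhs))
}

# Brute-force balanced 2x2x2 ANOVA by +/-1 contrasts: each of the 7 terms
# has one df; SS_term = (sum(sign * y))^2 / N for the sign pattern given by
# the product of the +/-1 codes of the factors in the term.
anova_oracle <- function(y, A, B, C) {
  sA <- ifelse(A == levels(factor(A))[1], -1, 1)
  sB <- ifelse(B == levels(factor(B))[1], -1, 1)
  sC <- ifelse(C == levels(factor(C))[1], -1, 1)
  N <- length(y)
  terms <- list(A = sA, B = sB, C = sC, AB = sA * sB, AC = sA * sC,
                BC = sB * sC, ABC = sA * sB * sC)
  ss <- vapply(terms, function(s) sum(s * y)^2 / N, numeric(1))
  cell <- interaction(A, B, C)
  sse <- sum((y - ave(y, cell))^2)
  dfe <- N - 8
  list(ss = ss, sse = sse, f = (ss / 1) / (sse / dfe), dfe = dfe)
}

# Closed-form Welch t statistic, Satterthwaite df, two-sided p
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form Pearson r and its t-transform p-value
pearson_oracle <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}
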