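# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they serve as the reference.

# E[x1^p1 ... xd^pd] for a standard multivariate normal: product of
# univariate moments, (p-1)!! for even p, 0 for odd p.
gaussian_moment <- function(p) {
  prod(vapply(p, function(k) {
    if (k %% 2 == 1) return(0)
    if (k == 0) return(1)
    prod(seq(k - 1, 1, by = -2))
  }, numeric(1)))
}

# all exponent vectors of total degree <= deg in d variables
monomials_upto <- function(d, deg) {
  grid <- do.call(expand.grid, rep(list(0:deg), d))
  grid[rowSums(grid) <= deg & rowSums(grid) > 0, , drop = FALSE]
}

# one step of the exact Kalman filter for x_k = F x + v, y = B x + w
kalman_step <- function(m, P, y, F, Q, B, R) {
  mp <- drop(F %*% m)
  Pp <- F %*% P %*% t(F) + Q
  S <- B %*% Pp %*% t(B) + R
  L <- Pp %*% t(B) %*% solve(S)
  mf <- mp + drop(L %*% (y - drop(B %*% mp)))
  Pf <- Pp - L %*% B %*% Pp
  list(mp = mp, Pp = Pp, mf = mf, Pf = (Pf + t(Pf)) / 2)
}

# random symmetric positive-definite matrix
random_spd <- function(d, jitter = 0.5) {
  M <- matrix(rnorm(d * d), d)
  crossprod(M) / d + jitter * diag(d)
}

# Literal sequential PDF truncation via eigendecomposition + Gram-Schmidt
# rotation: the textbook route, kept independent of the package's rank-one
# implementation.
truncate_belief_literal <- function(mean, cov, lower, upper) {
  d <- length(mean)
  for (i in seq_len(d)) {
    ci <- lower[i]; di <- upper[i]
    if (!is.finite(ci) && !is.finite(di)) next
    e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
    S <- e$vectors
    Dh <- diag(sqrt(pmax(e$values, 0)), d)
    ei <- rep(0, d); ei[i] <- 1
    v <- drop(Dh %*% t(S) %*% ei)               # first Gram-Schmidt seed
    sdi <- sqrt(sum(v^2))
    if (sdi < 1e-12) next
    # orthonormal G with first row v/||v||, remaining rows via QR
    M <- diag(d); M[, 1] <- v
    Qm <- qr.Q(qr(M))
    if (sum(Qm[, 1] * v) < 0) Qm[, 1] <- -Qm[, 1]
    G <- t(Qm)
    ct <- (ci - mean[i]) / sdi
    dt <- (di - mean[i]) / sdi
    if (ct < -8.5 && dt > 8.5) next
    tm <- truncated_normal_moments(ct, dt)
    zbar <- c(tm$mean, rep(0, d - 1))
    Qz <- diag(c(tm$variance, rep(1, d - 1)), d)
    Mback <- S %*% Dh %*% t(G)
    mean <- drop(Mback %*% zbar) + mean
    cov <- Mback %*% Qz %*% t(Mback)
    cov <- (cov + t(cov)) / 2
  }
  list(mean = mean, cov = cov)
}

# default benchmark noise for the 8-gene fixture
fixture_noise <- function() grn_noise(0.01 * diag(8), 0.01 * diag(8))
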