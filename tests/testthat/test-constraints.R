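test_that("penalty layouts put weight only on the coefficient block", {
  n <- 3
  lasso <- penalty_spec(n, "lasso", lambda = 2)
  expect_equal(lasso$lam[grnkf:::idx_x(n)], rep(0, n))
  expect_equal(lasso$lam[grnkf:::idx_mu(n)], rep(0, n))
  expect_equal(lasso$lam[grnkf:::idx_a(n)], rep(2, n^2))
  E <- matrix(0, n, n); E[1, 2] <- 1; E[3, 1] <- 1
  ind <- penalty_spec(n, "indicator", lambda = 5, E = E)
  expect_equal(sum(ind$lam > 0), 2)
  # row-major placement: e_12 penalizes a_12, the 2nd coefficient
  expect_equal(ind$lam[grnkf:::idx_a_entry(n, 1, 2)], 5)
  expect_equal(ind$lam[grnkf:::idx_a_entry(n, 3, 1)], 5)
  expect_error(penalty_spec(n, "indicator", lambda = 1, E = 2 * E),
               "weighted-indicator")
  wt <- penalty_spec(n, "weighted-indicator", lambda = 1, E = 5 * E)
  expect_equal(wt$lam[grnkf:::idx_a_entry(n, 1, 2)], 5)
  expect_error(penalty_spec(n, "lasso", lambda = -1), "nonnegative")
})

test_that("MAP cost and gradient agree with hand values and finite differences", {
  model <- measurement_model(matrix(1), matrix(1))
  pred <- gaussian_belief(0, matrix(1))
  expect_equal(map_cost(1, y = 2, pred, model), 2)        # 1 + 1
  expect_equal(map_gradient(0, y = 2, pred, model), -4)   # -2*2 + 0
  expect_equal(map_cost(0, y = 0, pred, model), 0)
  set.seed(6)
  for (i in 1:5) {
    d <- 4; m <- 2
    pred <- gaussian_belief(rnorm(d), random_spd(d))
    mod <- measurement_model(matrix(rnorm(m * d), m), random_spd(m, 0.3))
    y <- rnorm(m)
    x <- rnorm(d)
    g <- map_gradient(x, y, pred, mod)
    h <- 1e-5
    gnum <- vapply(seq_len(d), function(j) {
      e <- rep(0, d); e[j] <- h
      (map_cost(x + e, y, pred, mod) - map_cost(x - e, y, pred, mod)) / (2 * h)
    }, numeric(1))
    expect_equal(g, gnum, tolerance = 1e-5)
    # the Kalman filtered mean is the unconstrained minimizer
    xstar <- update_linear(pred, y, mod)$filtered$mean
    expect_lt(sqrt(sum(map_gradient(xstar, y, pred, mod)^2)), 1e-8)
    expect_lt(map_cost(xstar, y, pred, mod),
              map_cost(xstar + 0.1 * rnorm(d), y, pred, mod))
  }
})

test_that("soft thresholding shrinks componentwise", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  u <- rnorm(10)
  expect_equal(soft_threshold(u, 0), u)
  expect_true(all(abs(soft_threshold(u, 0.3)) <= abs(u)))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("Barzilai-Borwein steps follow the quotient with guarded fallbacks", {
  s <- rnorm(5)
  expect_equal(bb_step(s, s), 1)
  expect_equal(bb_step(c(1, 0), c(2, 0)), 2)
  expect_equal(bb_step(rep(0, 3), rnorm(3), fallback = 7), 7)
  expect_equal(bb_step(c(1, 0), c(-1, 0), fallback = 0.5), 0.5)
  expect_equal(bb_step(c(1e-10, 0), c(1e10, 0)), 1e8)       # clamped
})

test_that("iterative thresholding recovers the Kalman mean at zero penalty", {
  set.seed(31)
  for (i in 1:5) {
    n <- 2                                     # augmented dimension 8
    d <- augmented_dim(n)
    pred <- gaussian_belief(rnorm(d), random_spd(d))
    mod <- grnkf:::grn_measurement_model(n, random_spd(n, 0.3))
    y <- rnorm(n)
    pen <- penalty_spec(n, "lasso", lambda = 0)
    got <- iterative_thresholding_update(pred, y, mod, pen)
    expect_equal(got$mean, update_linear(pred, y, mod)$filtered$mean,
                 tolerance = 1e-6)
  }
})

test_that("a huge penalty zeroes the coefficient block exactly", {
  n <- 2
  d <- augmented_dim(n)
  set.seed(8)
  pred <- gaussian_belief(rnorm(d), random_spd(d))
  mod <- grnkf:::grn_measurement_model(n, 0.3 * diag(n))
  pen <- penalty_spec(n, "lasso", lambda = 1e9)
  got <- iterative_thresholding_update(pred, y = rnorm(n), mod, pen)
  expect_equal(got$mean[grnkf:::idx_a(n)], rep(0, n^2))
  expect_false(all(got$mean == 0))             # unpenalized blocks survive
})

test_that("the penalized solution matches a brute-force grid on a 2-D toy", {
  # diagonal two-dimensional problem with direct observation of both
  # coordinates; the grid oracle scans a 2001 x 2001 lattice on [-2, 2]^2
  pred <- gaussian_belief(c(0.8, -0.6), diag(c(0.5, 0.25)))
  mod <- measurement_model(diag(2), diag(c(0.2, 0.4)))
  y <- c(1.2, -0.2)
  lam <- c(1.5, 2.0)
  pen <- structure(list(lam = lam, mode = "lasso", lambda = NA, E = NULL,
                        n = NA), class = "penalty_spec")
  got <- iterative_thresholding_update(pred, y, mod, pen, eps = 1e-12,
                                       max_iter = 2000)
  grid <- seq(-2, 2, length.out = 2001)
  obj_coord <- function(x, yv, mv, pv, rv, lv)
    (yv - x)^2 / rv + (x - mv)^2 / pv + lv * abs(x)
  # the objective separates over coordinates for diagonal P, R, B = I
  x1 <- grid[which.min(obj_coord(grid, y[1], 0.8, 0.5, 0.2, lam[1]))]
  x2 <- grid[which.min(obj_coord(grid, y[2], -0.6, 0.25, 0.4, lam[2]))]
  expect_equal(got$mean, c(x1, x2), tolerance = 2 * diff(grid)[1])
  # fixed point of the thresholding map at several step scales
  g <- map_gradient(got$mean, y, pred, mod)
  for (a in c(0.7, 1, 3))
    expect_equal(got$mean, soft_threshold(got$mean - g / a, lam / a),
                 tolerance = 1e-6)
})

test_that("the penalized objective never beats itself at the Kalman mean", {
  set.seed(91)
  for (i in 1:5) {
    n <- 2
    pred <- gaussian_belief(rnorm(augmented_dim(n)),
                            random_spd(augmented_dim(n)))
    mod <- grnkf:::grn_measurement_model(n, random_spd(n, 0.3))
    y <- rnorm(n)
    pen <- penalty_spec(n, "lasso", lambda = 0.8)
    got <- iterative_thresholding_update(pred, y, mod, pen)
    kal <- update_linear(pred, y, mod)$filtered$mean
    obj <- function(x) map_cost(x, y, pred, mod) + sum(pen$lam * abs(x))
    expect_lte(got$objective, obj(kal) + 1e-9)
  }
})

test_that("truncated normal moments match closed forms", {
  tm <- truncated_normal_moments(-Inf, Inf)
  expect_equal(tm$mean, 0)
  expect_equal(tm$variance, 1)
  for (a in c(0.3, 1, 2.5)) {
    tm <- truncated_normal_moments(-a, a)
    expect_equal(tm$mean, 0, tolerance = 1e-14)
    expect_lt(tm$variance, 1)
  }
  half <- truncated_normal_moments(0, Inf)
  expect_equal(half$mean, sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(half$variance, 1 - 2 / pi, tolerance = 1e-10)
  # numerical-integration oracle on generic intervals
  for (b in list(c(-1, 0.5), c(0.2, 2), c(-3, -1))) {
    Z <- stats::integrate(stats::dnorm, b[1], b[2])$value
    m1 <- stats::integrate(function(z) z * stats::dnorm(z), b[1], b[2])$value / Z
    m2 <- stats::integrate(function(z) z^2 * stats::dnorm(z), b[1], b[2])$value / Z
    tm <- truncated_normal_moments(b[1], b[2])
    expect_equal(tm$mean, m1, tolerance = 1e-8)
    expect_equal(tm$variance, m2 - m1^2, tolerance = 1e-8)
  }
  expect_error(truncated_normal_moments(1, 1), "c_t < d_t")
  expect_error(truncated_normal_moments(40, 41), "negligible")
})

test_that("range truncation reduces to scalar truncated moments", {
  rc <- range_constraint(0, Inf)
  out <- apply_range_constraints(gaussian_belief(0, matrix(1)), rc)
  expect_equal(out$mean, sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(drop(out$cov), 1 - 2 / pi, tolerance = 1e-10)
})

test_that("unbounded constraints leave the belief unchanged", {
  set.seed(17)
  d <- 5
  bel <- gaussian_belief(rnorm(d), random_spd(d))
  rc <- range_constraint(rep(-Inf, d), rep(Inf, d))
  out <- apply_range_constraints(bel, rc)
  expect_equal(out$mean, bel$mean, tolerance = 1e-10)
  expect_equal(out$cov, bel$cov, tolerance = 1e-10)
  # very wide finite bounds: idempotent to high accuracy
  wide <- range_constraint(rep(-100, d), rep(100, d))
  o1 <- apply_range_constraints(bel, wide)
  o2 <- apply_range_constraints(o1, wide)
  expect_equal(o1$mean, bel$mean, tolerance = 1e-8)
  expect_equal(o2$mean, o1$mean, tolerance = 1e-8)
  expect_equal(o2$cov, o1$cov, tolerance = 1e-8)
})

test_that("rank-one truncation equals the literal decomposition route", {
  set.seed(23)
  for (i in 1:8) {
    d <- 4
    bel <- gaussian_belief(rnorm(d), random_spd(d))
    lower <- rep(-Inf, d); upper <- rep(Inf, d)
    which_b <- sample(d, 2)
    lower[which_b] <- bel$mean[which_b] - runif(2, 0.2, 1.5)
    upper[which_b] <- bel$mean[which_b] + runif(2, 0.1, 1)
    got <- apply_range_constraints(bel, range_constraint(lower, upper))
    ref <- truncate_belief_literal(bel$mean, bel$cov, lower, upper)
    expect_equal(got$mean, ref$mean, tolerance = 1e-8)
    expect_equal(got$cov, ref$cov, tolerance = 1e-8)
    # constrained components end inside their bounds
    expect_true(all(got$mean[which_b] >= lower[which_b] - 1e-9))
    expect_true(all(got$mean[which_b] <= upper[which_b] + 1e-9))
    # truncated directions never gain variance
    expect_true(all(diag(got$cov)[which_b] <=
                      diag(bel$cov)[which_b] + 1e-9))
  }
})

test_that("coefficient bounds map the prior matrix onto the augmented layout", {
  E <- fixture_prior_indicator()
  rc <- coefficient_bounds(E, tight = 0.1, loose = 10)
  n <- 8
  expect_equal(rc$d, 80)
  expect_true(all(is.infinite(rc$lower[grnkf:::idx_x(n)])))
  expect_true(all(is.infinite(rc$upper[grnkf:::idx_mu(n)])))
  expect_equal(sum(rc$upper[grnkf:::idx_a(n)] == 0.1), 6)
  expect_equal(sum(rc$lower[grnkf:::idx_a(n)] == -10), 58)
  expect_equal(rc$upper[grnkf:::idx_a_entry(n, 2, 5)], 0.1)
  expect_error(range_constraint(1, -1), "lower bounds")
})
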