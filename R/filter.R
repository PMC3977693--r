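#' Gaussian belief over a state vector
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix, symmetric within 1e-9 (symmetrized on
#'   construction).
#' @return An object of class \code{gaussian_belief}.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov))
    stop("mean/cov dimensions disagree")
  if (max(abs(cov - t(cov))) > 1e-9 * max(1, max(abs(cov))))
    stop("cov is not symmetric")
  structure(list(mean = mean, cov = (cov + t(cov)) / 2,
                 d = length(mean)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("gaussian_belief: dim %d, trace(cov) = %.4g\n",
              x$d, sum(diag(x$cov))))
  invisible(x)
}

#' Linear measurement model
#'
#' @param B m x d observation matrix (full row rank). For the augmented GRN
#'   model this is the selector \code{[I_n, 0]} picking the expression block.
#' @param R m x m measurement-noise covariance.
#' @return An object of class \code{measurement_model}.
#' @export
measurement_model <- function(B, R) {
  B <- as.matrix(B); R <- as.matrix(R)
  if (nrow(B) != nrow(R) || nrow(R) != ncol(R))
    stop("B/R dimensions disagree")
  if (qr(B)$rank < nrow(B)) stop("B must have full row rank")
  structure(list(B = B, R = (R + t(R)) / 2, m = nrow(B), d = ncol(B)),
            class = "measurement_model")
}

# selector model y = x-block + noise for n genes
grn_measurement_model <- function(n, R) {
  measurement_model(cbind(diag(n), matrix(0, n, n^2 + n)), R)
}

#' Sigma-point prediction step
#'
#' Propagates a Gaussian belief through a nonlinear drift \code{f} using a
#' unit-Gaussian quadrature rule: transformed points
#' \eqn{\xi_i = S\gamma_i + \hat{x}} are pushed through \code{f}; the
#' predicted mean is their weighted average and the predicted covariance the
#' weighted outer-product spread plus the process noise, symmetrized.
#'
#' @param belief a \code{\link{gaussian_belief}}.
#' @param f drift: either a function of one vector, or the string
#'   \code{"grn"} to use the vectorized augmented sigmoid dynamics (requires
#'   \code{n}).
#' @param Q_aug process-noise covariance (d x d).
#' @param rule a \code{quadrature_rule} of matching dimension.
#' @param n gene count, required when \code{f = "grn"}.
#' @return The predicted \code{gaussian_belief}.
#' @export
predict_belief <- function(belief, f, Q_aug, rule, n = NULL) {
  stopifnot(inherits(belief, "gaussian_belief"),
            inherits(rule, "quadrature_rule"))
  if (rule$d != belief$d) stop("rule dimension does not match belief")
  S <- sqrt_factor(belief$cov)$S
  Xi <- rule$points %*% t(S)
  Xi <- sweep(Xi, 2, belief$mean, "+")
  if (identical(f, "grn")) {
    if (is.null(n)) stop("n is required for the grn drift")
    FX <- augmented_dynamics_batch(Xi, n)
  } else {
    FX <- do.call(rbind, lapply(seq_len(rule$N),
                                function(i) as.numeric(f(Xi[i, ]))))
  }
  m <- drop(colSums(FX * rule$weights))
  Dev <- sweep(FX, 2, m)
  P <- crossprod(Dev, Dev * rule$weights) + Q_aug
  gaussian_belief(m, (P + t(P)) / 2)
}

#' Linear-Gaussian measurement update
#'
#' The standard Kalman update for a linear observation \code{y = B x + noise}:
#' gain \eqn{L = P B^T (R + B P B^T)^{-1}}, filtered mean
#' \eqn{\hat{x} + L(y - B\hat{x})}, filtered covariance \eqn{P - L B P}
#' (symmetrized).
#'
#' @param predicted the predicted \code{\link{gaussian_belief}}.
#' @param y measurement vector (length m).
#' @param model a \code{\link{measurement_model}}.
#' @param k time index stored in the returned record (default \code{NA}).
#' @return A \code{filter_step} record: \code{k}, \code{predicted},
#'   \code{filtered}, \code{innovation}, \code{gain}.
#' @export
update_linear <- function(predicted, y, model, k = NA_integer_) {
  stopifnot(inherits(predicted, "gaussian_belief"),
            inherits(model, "measurement_model"))
  B <- model$B
  P <- predicted$cov
  PBt <- P %*% t(B)
  Sinn <- model$R + B %*% PBt
  Sinn <- (Sinn + t(Sinn)) / 2
  L <- t(tryCatch(solve(Sinn, t(PBt)), error = function(e)
    stop("innovation covariance is not invertible: ", conditionMessage(e))))
  innov <- as.numeric(y) - drop(B %*% predicted$mean)
  mean_f <- predicted$mean + drop(L %*% innov)
  cov_f <- P - L %*% B %*% P
  structure(list(k = k, predicted = predicted,
                 filtered = gaussian_belief(mean_f, (cov_f + t(cov_f)) / 2),
                 innovation = innov, gain = L),
            class = "filter_step")
}

#' Sigma-point measurement update for a nonlinear observation map
#'
#' Computes the predicted measurement, innovation covariance and
#' state-measurement cross covariance by quadrature over the predicted
#' belief, then applies the Gaussian conditional-mean update. For an affine
#' \code{h} this reproduces \code{\link{update_linear}} exactly (degree-3
#' exactness); it is provided for observation models beyond the identity
#' selector.
#'
#' @param predicted the predicted \code{\link{gaussian_belief}}.
#' @param y measurement vector.
#' @param h observation function, vector to vector.
#' @param R measurement-noise covariance.
#' @param rule a \code{quadrature_rule} of the belief's dimension.
#' @param k time index for the record.
#' @return A \code{filter_step} record.
#' @export
update_general <- function(predicted, y, h, R, rule, k = NA_integer_) {
  stopifnot(inherits(predicted, "gaussian_belief"),
            inherits(rule, "quadrature_rule"))
  if (rule$d != predicted$d) stop("rule dimension does not match belief")
  S <- sqrt_factor(predicted$cov)$S
  Xi <- rule$points %*% t(S)
  Xi <- sweep(Xi, 2, predicted$mean, "+")
  HX <- do.call(rbind, lapply(seq_len(rule$N),
                              function(i) as.numeric(h(Xi[i, ]))))
  yhat <- drop(colSums(HX * rule$weights))
  DevX <- sweep(Xi, 2, predicted$mean)
  DevY <- sweep(HX, 2, yhat)
  Pyy <- crossprod(DevY, DevY * rule$weights)
  Pxy <- crossprod(DevX, DevY * rule$weights)
  Sinn <- (R + Pyy + t(R + Pyy)) / 2
  L <- t(tryCatch(solve(Sinn, t(Pxy)), error = function(e)
    stop("innovation covariance is not invertible: ", conditionMessage(e))))
  innov <- as.numeric(y) - yhat
  mean_f <- predicted$mean + drop(L %*% innov)
  cov_f <- predicted$cov - L %*% t(Pxy)
  structure(list(k = k, predicted = predicted,
                 filtered = gaussian_belief(mean_f, (cov_f + t(cov_f)) / 2),
                 innovation = innov, gain = L),
            class = "filter_step")
}

#' Analytic Jacobian of the augmented sigmoid drift
#'
#' Blocks (writing \eqn{g_j = g(x_j; \mu_j)}): expression/expression
#' \eqn{A\,\mathrm{diag}(g'_j)}; expression/coefficient
#' \eqn{\partial (Ag)_i / \partial a_{rj} = \delta_{ir} g_j}; expression/
#' steepness \eqn{a_{ij} x_j g_j (1 - g_j)}; the parameter rows are the
#' identity (parameter random walk).
#'
#' @param xbar augmented state vector.
#' @param n gene count.
#' @return A \code{(n^2+2n)} square Jacobian matrix.
#' @export
augmented_jacobian <- function(xbar, n) {
  d <- augmented_dim(n)
  if (length(xbar) != d) stop("xbar has wrong length")
  dec <- decode_params(xbar[-idx_x(n)], n)
  x <- xbar[idx_x(n)]
  g <- sigmoid_activation(x, pmax(dec$mu, .Machine$double.eps))
  gp <- dec$mu * g * (1 - g)         # dg/dx
  gmu <- x * g * (1 - g)             # dg/dmu
  J <- matrix(0, d, d)
  J[idx_x(n), idx_x(n)] <- dec$A * rep(gp, each = n)
  for (i in seq_len(n))
    J[i, n + (i - 1L) * n + seq_len(n)] <- g
  J[idx_x(n), idx_mu(n)] <- dec$A * rep(gmu, each = n)
  J[-idx_x(n), -idx_x(n)] <- diag(n^2 + n)
  J
}

#' One EKF step on the augmented model
#'
#' First-order linearized prediction (analytic Jacobian, see
#' \code{\link{augmented_jacobian}}) followed by the standard Kalman update.
#' Serves as the baseline the sigma-point filters are compared against.
#'
#' @param belief the filtered \code{\link{gaussian_belief}} at time k-1.
#' @param y measurement at time k.
#' @param n gene count.
#' @param Q_aug augmented process-noise covariance.
#' @param model a \code{\link{measurement_model}}.
#' @param k time index for the record.
#' @return A \code{filter_step} record.
#' @export
ekf_step <- function(belief, y, n, Q_aug, model, k = NA_integer_) {
  stopifnot(inherits(belief, "gaussian_belief"))
  FJ <- augmented_jacobian(belief$mean, n)
  m <- augmented_dynamics(belief$mean, n)
  P <- FJ %*% belief$cov %*% t(FJ) + Q_aug
  predicted <- gaussian_belief(m, (P + t(P)) / 2)
  update_linear(predicted, y, model, k = k)
}

#' Run a filter over a measurement series
#'
#' Joint state-parameter estimation: the regulatory coefficients (row-major)
#' and sigmoid steepness are appended to the expression state and estimated
#' sequentially by the chosen filter. The belief is initialized from the
#' first measurement (expression block), a Gaussian draw for the parameters
#' (coefficients \code{N(0, 0.2)}, steepness \code{N(1.5, 0.2)}), and prior
#' covariance \code{diag(R, 0.2 I)}; filtering then consumes measurements
#' from the second time point on.
#'
#' @param measurements K x n matrix of observed expression levels (K >= 2).
#' @param filter one of \code{"ukf"}, \code{"ckf3"}, \code{"ckf5"},
#'   \code{"ekf"}.
#' @param noise a \code{\link{grn_noise}} object.
#' @param kappa UKF tuning parameter; default \code{3 - n} where n is the
#'   gene count (not the augmented dimension).
#' @param penalty optional \code{\link{penalty_spec}}: the filtered mean is
#'   replaced by the L1-penalized MAP solution at every update (the filtered
#'   covariance is kept from the standard update, which defines no penalized
#'   covariance).
#' @param range_constraint optional \code{\link{range_constraint}}: after
#'   each standard update the belief is truncated to the bounds and the
#'   pseudo mean/covariance carried into the next prediction.
#' @param init_seed seed for the random parameter initialization.
#' @param theta0 optional explicit initial parameter vector (overrides the
#'   random draw).
#' @param P0 optional explicit initial covariance.
#' @param divergence_bound abort when the covariance Frobenius norm exceeds
#'   this bound (default 1e6).
#' @param keep_steps store per-step records (default TRUE).
#' @return An object of class \code{grn_fit}: \code{params} (the decoded
#'   final estimate, steepness clamped positive), \code{theta} (raw final
#'   parameter block), \code{belief} (final filtered belief), \code{steps}
#'   (list of \code{filter_step}, if kept), \code{trace} (data frame with
#'   per-step innovation norm and parameter-covariance trace), and the
#'   configuration used.
#' @export
run_filter <- function(measurements, filter = c("ukf", "ckf3", "ckf5", "ekf"),
                       noise, kappa = NULL, penalty = NULL,
                       range_constraint = NULL, init_seed = 1L,
                       theta0 = NULL, P0 = NULL,
                       divergence_bound = 1e6, keep_steps = TRUE) {
  filter <- match.arg(filter)
  measurements <- as.matrix(measurements)
  K <- nrow(measurements); n <- ncol(measurements)
  if (K < 2) stop("need at least two time points")
  stopifnot(inherits(noise, "grn_noise"))
  if (noise$n != n) stop("noise dimension does not match measurements")
  d <- augmented_dim(n)
  if (is.null(kappa)) kappa <- 3 - n
  rule <- switch(filter,
                 ukf = unscented_points(d, kappa),
                 ckf3 = cubature3_points(d),
                 ckf5 = cubature5_points(d),
                 ekf = NULL)
  model <- grn_measurement_model(n, noise$R)
  if (is.null(theta0)) {
    theta0 <- with_seed(init_seed,
                        c(rnorm(n^2, 0, sqrt(0.2)), rnorm(n, 1.5, sqrt(0.2))))
  }
  if (length(theta0) != n^2 + n) stop("theta0 has wrong length")
  if (is.null(P0)) {
    P0 <- matrix(0, d, d)
    P0[idx_x(n), idx_x(n)] <- noise$R
    diag(P0)[-idx_x(n)] <- 0.2
  }
  belief <- gaussian_belief(c(measurements[1, ], theta0), P0)
  steps <- if (keep_steps) vector("list", K - 1) else NULL
  trace <- data.frame(k = integer(K - 1), innovation_norm = numeric(K - 1),
                      param_cov_trace = numeric(K - 1))
  for (k in 2:K) {
    y <- measurements[k, ]
    if (filter == "ekf") {
      step <- ekf_step(belief, y, n, noise$Q_aug, model, k = k)
    } else {
      predicted <- predict_belief(belief, "grn", noise$Q_aug, rule, n = n)
      step <- update_linear(predicted, y, model, k = k)
    }
    if (!is.null(penalty)) {
      mean_pen <- iterative_thresholding_update(step$predicted, y, model,
                                                penalty)$mean
      step$filtered <- gaussian_belief(mean_pen, step$filtered$cov)
    }
    if (!is.null(range_constraint)) {
      step$filtered <- apply_range_constraints(step$filtered,
                                               range_constraint)
    }
    belief <- step$filtered
    cn <- sqrt(sum(belief$cov^2))
    if (!is.finite(cn) || cn > divergence_bound)
      stop(sprintf("filter diverged at step k = %d (covariance norm %.3g)",
                   k, cn))
    if (keep_steps) steps[[k - 1]] <- step
    trace$k[k - 1] <- k
    trace$innovation_norm[k - 1] <- sqrt(sum(step$innovation^2))
    trace$param_cov_trace[k - 1] <- sum(diag(belief$cov)[-idx_x(n)])
  }
  theta <- belief$mean[-idx_x(n)]
  dec <- decode_params(theta, n)
  params <- grn_params(dec$A, pmax(dec$mu, .Machine$double.eps))
  structure(list(params = params, theta = theta, belief = belief,
                 steps = steps, trace = trace,
                 config = list(filter = filter, kappa = kappa,
                               penalty = penalty,
                               range_constraint = range_constraint,
                               init_seed = init_seed)),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("grn_fit: %s filter, %d genes, final param-cov trace %.4g\n",
              x$config$filter, x$params$n,
              utils::tail(x$trace$param_cov_trace, 1)))
  invisible(x)
}

#' Export a fit's convergence trace
#'
#' Writes one row per filtering step: time index, innovation norm, and the
#' trace of the parameter-block covariance (a scalar convergence summary).
#'
#' @param fit a \code{grn_fit}.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_filter_trace <- function(fit, path) {
  stopifnot(inherits(fit, "grn_fit"))
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
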