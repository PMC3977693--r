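#' Unit-Gaussian quadrature point sets
#'
#' The sigma-point filters approximate Gaussian-weighted integrals
#' \eqn{\int h(x)\phi(x; 0, I)\,dx \approx \sum_i w_i h(\gamma_i)} with a
#' deterministic weighted point set. Three rules are provided: the
#' unscented transform (degree 3, tunable \eqn{\kappa}), the third-degree
#' spherical-radial cubature rule, and the fifth-degree cubature rule built
#' from the vertices and edge midpoints of a regular simplex (Mysovskikh
#' construction).
#'
#' @param points N x d matrix of abscissas.
#' @param weights length-N weights summing to 1 (weights may be negative for
#'   some parameterizations).
#' @param degree polynomial exactness degree (3 or 5).
#' @param kappa the unscented-transform tuning parameter, if applicable.
#' @return An object of class \code{quadrature_rule}.
#' @keywords internal
quadrature_rule <- function(points, weights, degree, kappa = NULL) {
  stopifnot(nrow(points) == length(weights))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  structure(list(points = points, weights = weights,
                 degree = as.integer(degree), kappa = kappa,
                 d = ncol(points), N = nrow(points)),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("quadrature_rule: %d points in %d dims, degree %d%s\n",
              x$N, x$d, x$degree,
              if (!is.null(x$kappa)) sprintf(" (kappa = %g)", x$kappa) else ""))
  invisible(x)
}

#' Unscented-transform points
#'
#' 2d+1 points: the origin with weight \eqn{\kappa/(d+\kappa)} and
#' \eqn{\pm\sqrt{d+\kappa}\,e_i} each with weight \eqn{1/(2(d+\kappa))}.
#' Degree-3 exact for any admissible \eqn{\kappa}; all weights are
#' nonnegative iff \eqn{\kappa \ge 0} (a negative origin weight is legal
#' but can destabilize covariance propagation).
#'
#' @param d dimension (>= 1).
#' @param kappa tuning parameter, must satisfy \code{d + kappa > 0}.
#' @return A \code{quadrature_rule} with \code{2d + 1} points.
#' @export
unscented_points <- function(d, kappa = 3 - d) {
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1")
  if (d + kappa <= 0) stop("d + kappa must be positive")
  s <- sqrt(d + kappa)
  pts <- rbind(rep(0, d), s * diag(d), -s * diag(d))
  w <- c(kappa / (d + kappa), rep(1 / (2 * (d + kappa)), 2 * d))
  quadrature_rule(pts, w, degree = 3L, kappa = kappa)
}

#' Third-degree cubature points
#'
#' 2d points \eqn{\pm\sqrt{d}\,e_i} with uniform weight \eqn{1/(2d)};
#' identical to the unscented transform at \eqn{\kappa = 0} minus its
#' zero-weight origin point.
#'
#' @param d dimension (>= 1).
#' @return A \code{quadrature_rule} with \code{2d} points, degree 3.
#' @export
cubature3_points <- function(d) {
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1")
  s <- sqrt(d)
  quadrature_rule(rbind(s * diag(d), -s * diag(d)),
                  rep(1 / (2 * d), 2 * d), degree = 3L)
}

# unit regular-simplex vertices in d dims: d+1 rows, unit norm, pairwise
# inner products -1/d
simplex_vertices <- function(d) {
  V <- matrix(0, d + 1, d)
  for (i in seq_len(d + 1)) {
    for (j in seq_len(d)) {
      if (j < i) {
        V[i, j] <- -sqrt((d + 1) / (d * (d - j + 2) * (d - j + 1)))
      } else if (j == i) {
        V[i, j] <- sqrt((d + 1) * (d - i + 1) / (d * (d - i + 2)))
      }
    }
  }
  V
}

#' Fifth-degree cubature points
#'
#' The spherical-radial rule of degree 5 using Mysovskikh's simplex
#' construction: the origin, the d+1 scaled vertices \eqn{s_1^{(i)}} of a
#' regular unit simplex and their negatives, and the d(d+1)/2 normalized
#' pairwise midpoints \eqn{s_2^{(i)}} and their negatives, all scaled by
#' \eqn{\sqrt{d+2}}. Point count \eqn{d^2 + 3d + 3}. The vertex weight is
#' negative for d > 7; the rule remains degree-5 exact but, like any
#' negative-weight rule, can yield indefinite covariance estimates.
#'
#' For d = 1 the pairwise-midpoint set is empty and the construction
#' degenerates; a 3-point Gauss-Hermite rule (also degree-5 exact in one
#' dimension) is returned instead, with a message.
#'
#' @param d dimension (>= 1; see Details for d = 1).
#' @return A \code{quadrature_rule} of degree 5.
#' @export
cubature5_points <- function(d) {
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1")
  if (d == 1) {
    message("cubature5_points: d = 1 has no simplex midpoint set; ",
            "using the 3-point Gauss-Hermite rule (degree-5 exact in 1-D)")
    return(quadrature_rule(matrix(c(0, sqrt(3), -sqrt(3)), 3, 1),
                           c(2 / 3, 1 / 6, 1 / 6), degree = 5L))
  }
  V1 <- simplex_vertices(d)                     # (d+1) x d, unit norm
  pairs <- which(upper.tri(matrix(0, d + 1, d + 1)), arr.ind = TRUE)
  V2 <- sqrt(d / (2 * (d - 1))) * (V1[pairs[, 1], , drop = FALSE] +
                                   V1[pairs[, 2], , drop = FALSE])
  s <- sqrt(d + 2)
  pts <- rbind(rep(0, d), s * V1, -s * V1, s * V2, -s * V2)
  w0 <- 2 / (d + 2)
  w1 <- d^2 * (7 - d) / (2 * (d + 1)^2 * (d + 2)^2)
  w2 <- 2 * (d - 1)^2 / ((d + 1)^2 * (d + 2)^2)
  w <- c(w0, rep(w1, 2 * (d + 1)), rep(w2, d * (d + 1)))
  quadrature_rule(pts, w, degree = 5L)
}

#' Square-root factor of a covariance matrix
#'
#' Finds \code{S} with \code{S \%*\% t(S)} equal to \code{P}. Cholesky is
#' attempted first (after symmetrization), then retried with a small
#' diagonal jitter of \code{1e-10 * trace(P)/d}, and finally a symmetric
#' eigendecomposition factor is used, which also covers rank-deficient
#' \code{P} (augmented-state covariances can be near-singular because the
#' parameter block carries zero process noise).
#'
#' @param P symmetric positive semidefinite matrix.
#' @param tol relative tolerance for the negative-eigenvalue check.
#' @return A list with \code{S} (lower-triangular or eigen factor) and
#'   \code{method} (\code{"cholesky"} or \code{"svd"}).
#' @export
sqrt_factor <- function(P, tol = 1e-8) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  P <- (P + t(P)) / 2
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (!is.null(ch)) return(list(S = t(ch), method = "cholesky"))
  d <- nrow(P)
  jit <- 1e-10 * max(sum(diag(P)), .Machine$double.eps) / d
  ch <- tryCatch(chol(P + jit * diag(d)), error = function(e) NULL)
  if (!is.null(ch)) return(list(S = t(ch), method = "cholesky"))
  e <- eigen(P, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (min(e$values) < -tol * scale)
    stop("P is not positive semidefinite")
  list(S = e$vectors %*% diag(sqrt(pmax(e$values, 0)), d), method = "svd")
}

#' Gaussian-weighted integral of a vector-valued map
#'
#' Approximates \eqn{\int h(x)\,\phi(x;\,mean,\,cov)\,dx} as
#' \eqn{\sum_i w_i h(S\gamma_i + mean)} with \code{S} from
#' \code{\link{sqrt_factor}}. Exact for polynomial \code{h} up to the
#' rule's degree, hence exact for affine \code{h} under any rule.
#'
#' @param h function taking a numeric vector, returning a numeric vector of
#'   fixed length.
#' @param mean mean vector of the Gaussian weight.
#' @param cov covariance matrix of the Gaussian weight.
#' @param rule a \code{quadrature_rule} of matching dimension.
#' @return Numeric vector: the weighted sum of propagated points.
#' @export
gaussian_integral <- function(h, mean, cov, rule) {
  stopifnot(inherits(rule, "quadrature_rule"))
  if (rule$d != length(mean)) stop("rule dimension does not match mean")
  S <- sqrt_factor(cov)$S
  Xi <- rule$points %*% t(S)
  Xi <- sweep(Xi, 2, mean, "+")
  vals <- do.call(rbind, lapply(seq_len(rule$N),
                                function(i) as.numeric(h(Xi[i, ]))))
  drop(colSums(vals * rule$weights))
}
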