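#' Call network links from an estimated coefficient matrix
#'
#' A directed link j -> i is called when \code{|a_ij| > tau}. The threshold
#' is the pipeline's one silent parameter: the filters return continuous
#' coefficient estimates and the benchmark tables depend on where the
#' magnitude cut is placed, so \code{tau} is always explicit. Diagonal
#' (self-regulation) entries are called and scored like any other entry.
#'
#' @param A_hat estimated n x n coefficient matrix.
#' @param tau nonnegative magnitude threshold (default 0.3; see
#'   \code{\link{tau_sweep}} for calibration).
#' @param signed if \code{TRUE}, called links carry the sign of the
#'   estimated coefficient (activation +1 / repression -1) so that
#'   \code{\link{evaluate_links}} can score the regulation type; if
#'   \code{FALSE} (default) the adjacency is 0/1.
#' @return n x n adjacency matrix (0/1, or signed when
#'   \code{signed = TRUE}).
#' @export
call_links <- function(A_hat, tau = 0.3, signed = FALSE) {
  if (tau < 0) stop("tau must be nonnegative")
  A_hat <- as.matrix(A_hat)
  adj <- (abs(A_hat) > tau) * 1
  if (signed) adj <- adj * sign(A_hat)
  adj
}

#' Confusion counts and rates for a predicted network
#'
#' Scores every entry of the predicted adjacency against the truth
#' (including the diagonal) and reports the confusion counts together with
#' \deqn{TPR = TP/(TP+FN), \quad FPR = FP/(FP+TN), \quad PPV = TP/(TP+FP).}
#' A rate whose denominator is zero is reported as \code{NA}, never as a
#' division by zero.
#'
#' Scoring is sign-aware when both matrices carry signs: a called link at a
#' true-link position whose sign disagrees with the truth predicts a
#' regulation of the wrong type and is counted as a false positive; that
#' position then contributes to neither TP nor FN, so TP + FN can fall
#' below the number of true links. For 0/1 inputs this reduces to ordinary
#' presence/absence scoring.
#'
#' @param predicted adjacency matrix: 0/1 or signed (see
#'   \code{\link{call_links}}).
#' @param truth adjacency matrix of the same shape (0/1 or signed; a
#'   coefficient matrix works, only its sign pattern is used).
#' @return A list with \code{counts} (\code{tp}, \code{fp}, \code{tn},
#'   \code{fn}) and \code{metrics} (\code{tpr}, \code{fpr}, \code{ppv}).
#' @export
evaluate_links <- function(predicted, truth) {
  predicted <- sign(as.matrix(predicted))
  truth <- sign(as.matrix(truth))
  if (!all(dim(predicted) == dim(truth))) stop("shape mismatch")
  tp <- sum(predicted != 0 & truth != 0 & predicted == truth)
  fp <- sum(predicted != 0 & (truth == 0 | predicted != truth))
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth != 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = list(tpr = rate(tp, tp + fn),
                      fpr = rate(fp, fp + tn),
                      ppv = rate(tp, tp + fp)))
}

#' Rates from confusion counts
#'
#' Computes TPR, FPR and PPV directly from the four confusion counts, for
#' scoring published confusion tables without the underlying matrices.
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return A list with \code{tpr}, \code{fpr}, \code{ppv} (\code{NA} where
#'   the denominator is zero).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(tpr = rate(tp, tp + fn), fpr = rate(fp, fp + tn),
       ppv = rate(tp, tp + fp))
}

#' Infer a regulatory network from an expression time series
#'
#' End-to-end single-series pipeline: runs the chosen filter on the
#' measurements (see \code{\link{run_filter}}), decodes the final
#' coefficient and steepness estimates, and calls links at the magnitude
#' threshold \code{tau}.
#'
#' @inheritParams run_filter
#' @param tau link-calling threshold passed to \code{\link{call_links}}.
#' @param signed emit a signed adjacency (default TRUE, so downstream
#'   evaluation can score the regulation type).
#' @param ... further arguments forwarded to \code{\link{run_filter}}.
#' @return A list: \code{params} (estimated \code{grn_params}),
#'   \code{adjacency} (called links), \code{fit} (the full \code{grn_fit}).
#' @export
infer_network <- function(measurements, filter = "ukf", noise,
                          tau = 0.3, signed = TRUE, ...) {
  fit <- run_filter(measurements, filter = filter, noise = noise, ...)
  list(params = fit$params,
       adjacency = call_links(fit$params$A, tau, signed = signed),
       fit = fit)
}

#' Monte-Carlo benchmark of filters on a known network
#'
#' Repeats simulate / infer / evaluate over seeded runs: each run draws a
#' fresh trajectory from the ground-truth network and a fresh random
#' parameter initialization, runs each requested filter, and scores the
#' signed called links against the true signed adjacency (see
#' \code{\link{evaluate_links}}). Per-run seeds are
#' \code{base_seed + run}; initialization seeds are offset so the
#' trajectory and the initial guess are independent draws. Diverged runs
#' are recorded and excluded from the aggregates, never silently dropped.
#'
#' @param params ground-truth \code{\link{grn_params}} (default: the 8-gene
#'   \code{\link{fixture_network}}).
#' @param noise a \code{\link{grn_noise}}; default
#'   \code{Q = R = 0.01 I}.
#' @param runs number of Monte-Carlo runs (default 50).
#' @param K time points per run (default 40).
#' @param filters character vector of filters to benchmark.
#' @param kappa UKF tuning parameter (default \code{3 - n} genes).
#' @param penalty optional \code{\link{penalty_spec}} applied in every run.
#' @param range_constraint optional \code{\link{range_constraint}}.
#' @param tau link-calling threshold.
#' @param base_seed integer base seed.
#' @return An object of class \code{grn_benchmark}: \code{per_run} (one row
#'   per filter x run with counts and metrics), \code{summary} (min / max /
#'   avg per filter and metric, averaging per-run metrics), \code{estimates}
#'   (per filter, the list of estimated coefficient matrices, for threshold
#'   sweeps), \code{excluded} (diverged runs), \code{config}.
#' @export
monte_carlo_benchmark <- function(params = fixture_network(),
                                  noise = NULL, runs = 50, K = 40,
                                  filters = "ukf", kappa = NULL,
                                  penalty = NULL, range_constraint = NULL,
                                  tau = 0.3, base_seed = 1L) {
  stopifnot(inherits(params, "grn_params"), runs >= 1)
  n <- params$n
  if (is.null(noise)) noise <- grn_noise(0.01 * diag(n), 0.01 * diag(n))
  truth <- sign(params$A)
  rows <- list()
  estimates <- stats::setNames(
    lapply(filters, function(f) vector("list", runs)), filters)
  excluded <- data.frame(filter = character(0), run = integer(0),
                         message = character(0))
  for (f in filters) {
    for (r in seq_len(runs)) {
      seed_r <- as.integer(base_seed) + r
      traj <- simulate_trajectory(params, noise, K, seed = seed_r)
      res <- tryCatch(
        infer_network(traj$measurements, filter = f, noise = noise,
                      tau = tau, kappa = kappa, penalty = penalty,
                      range_constraint = range_constraint,
                      init_seed = seed_r + 1000003L, keep_steps = FALSE),
        error = function(e) e)
      if (inherits(res, "error")) {
        excluded <- rbind(excluded, data.frame(
          filter = f, run = r, message = conditionMessage(res)))
        next
      }
      estimates[[f]][[r]] <- res$params$A
      ev <- evaluate_links(call_links(res$params$A, tau, signed = TRUE),
                           truth)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = f, run = r, seed = seed_r,
        tp = ev$counts$tp, fp = ev$counts$fp,
        tn = ev$counts$tn, fn = ev$counts$fn,
        tpr = ev$metrics$tpr, fpr = ev$metrics$fpr, ppv = ev$metrics$ppv)
    }
  }
  per_run <- do.call(rbind, rows)
  structure(list(per_run = per_run,
                 summary = summarize_benchmark(per_run),
                 estimates = estimates, excluded = excluded,
                 config = list(runs = runs, K = K, filters = filters,
                               kappa = kappa, tau = tau,
                               penalty = penalty,
                               range_constraint = range_constraint,
                               base_seed = as.integer(base_seed),
                               noise = noise, params = params)),
            class = "grn_benchmark")
}

# min/max/avg per filter and metric from the per-run table
summarize_benchmark <- function(per_run) {
  metrics <- c("tp", "fp", "tn", "fn", "tpr", "fpr", "ppv")
  out <- list()
  for (f in unique(per_run$filter)) {
    sub <- per_run[per_run$filter == f, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      out[[length(out) + 1L]] <- data.frame(
        filter = f, metric = m,
        min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
        avg = mean(v, na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}

#' @export
print.grn_benchmark <- function(x, ...) {
  cat(sprintf("grn_benchmark: %d runs x {%s}, tau = %g, base seed %d\n",
              x$config$runs, paste(x$config$filters, collapse = ", "),
              x$config$tau, x$config$base_seed))
  rates <- x$summary[x$summary$metric %in% c("tpr", "fpr", "ppv"), ]
  print(rates, row.names = FALSE, digits = 4)
  if (nrow(x$excluded) > 0)
    cat(sprintf("excluded %d diverged run(s)\n", nrow(x$excluded)))
  invisible(x)
}

#' Benchmark a filter's average metric
#'
#' Convenience accessor for a single min/max/avg cell of a benchmark
#' summary.
#'
#' @param bench a \code{grn_benchmark}.
#' @param filter filter name.
#' @param metric one of \code{"tp"}, \code{"fp"}, \code{"tn"}, \code{"fn"},
#'   \code{"tpr"}, \code{"fpr"}, \code{"ppv"}.
#' @param stat \code{"avg"} (default), \code{"min"} or \code{"max"}.
#' @return A scalar.
#' @export
benchmark_metric <- function(bench, filter, metric, stat = "avg") {
  stopifnot(inherits(bench, "grn_benchmark"))
  row <- bench$summary[bench$summary$filter == filter &
                         bench$summary$metric == metric, ]
  if (nrow(row) != 1) stop("no such filter/metric in the benchmark")
  row[[stat]]
}

#' Sweep the link-calling threshold over stored estimates
#'
#' Re-calls links at each candidate threshold from the coefficient
#' estimates stored in a benchmark and recomputes the average rates. Used
#' to calibrate the operating point: the filters are threshold-free, so
#' the achievable (TPR, FPR) pairs trace a curve over \code{tau}.
#'
#' @param bench a \code{grn_benchmark} (its \code{estimates} are reused; no
#'   filtering is re-run).
#' @param taus numeric vector of candidate thresholds.
#' @return A data frame with one row per filter x tau: average
#'   \code{tpr}, \code{fpr}, \code{ppv} over the completed runs.
#' @export
tau_sweep <- function(bench, taus = seq(0.05, 1, by = 0.05)) {
  stopifnot(inherits(bench, "grn_benchmark"))
  truth <- sign(bench$config$params$A)
  out <- list()
  for (f in names(bench$estimates)) {
    mats <- Filter(Negate(is.null), bench$estimates[[f]])
    for (tau in taus) {
      evs <- lapply(mats, function(A) {
        evaluate_links(call_links(A, tau, signed = TRUE), truth)$metrics
      })
      out[[length(out) + 1L]] <- data.frame(
        filter = f, tau = tau,
        tpr = mean(vapply(evs, `[[`, numeric(1), "tpr"), na.rm = TRUE),
        fpr = mean(vapply(evs, `[[`, numeric(1), "fpr"), na.rm = TRUE),
        ppv = mean(vapply(evs, `[[`, numeric(1), "ppv"), na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
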