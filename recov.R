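library(grnkf)
noise <- grn_noise(0.01 * diag(3), 0.01 * diag(3))
for (s in 1:20) {
  A <- grnkf:::with_seed(5000 + s, {
    A <- matrix(2 * sample(c(-1, 0, 0, 1), 9, replace = TRUE), 3)
    while (all(A == 0)) A <- matrix(2 * sample(c(-1, 0, 0, 1), 9, replace = TRUE), 3)
    A
  })
  p <- grn_params(A, rep(2, 3))
  traj <- simulate_trajectory(p, noise, 200, seed = 6000 + s)
  fit <- run_filter(traj$measurements, "ukf", noise, init_seed = 7000 + s, keep_steps = FALSE)
  strong <- abs(A) == 2
  ok <- all(sign(fit$params$A[strong]) == sign(A[strong]))
  if (!ok) {
    bad <- which(sign(fit$params$A) != sign(A) & strong)
    # range of each gene expression (excitation) in last 100 steps
    sdx <- apply(traj$states[101:200,], 2, sd)
    cat(sprintf("seed %d FAIL: bad entries %s, Ahat there: %s, truth %s, sd(x)=%s\n",
        s, paste(bad, collapse=","), paste(round(fit$params$A[bad],2), collapse=","),
        paste(A[bad], collapse=","), paste(round(sdx,3), collapse=",")))
  }
}
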