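# Shared fixtures: one default parameter set and reference subject per run.
PARAMS <- rn_parameters()
REF_F <- reference_subject("F", params = PARAMS)

# Classical fixed-step RK4 for dQ/dt = A Q + b: an integrator independent of
# both deSolve and the matrix-exponential propagation.
rk4_affine <- function(A, b, y0, dt_h, n_steps) {
  h <- dt_h / n_steps
  y <- y0
  f <- function(y) A %*% y + b
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  drop(y)
}

# Random well-conditioned compartmental matrix: non-negative off-diagonal,
# strictly dominant negative diagonal.
random_rate_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0, 2), n, n)
  diag(A) <- 0
  diag(A) <- -colSums(A) - runif(n, 0.1, 1)
  A
}

cex_at <- function(series, t) series$c_ex_Bq_per_m3[match(t, series$time_min)]
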