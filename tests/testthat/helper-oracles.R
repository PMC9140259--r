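# Brute-force primal EL oracle, independent of the dual Newton path:
# the three equality constraints (sum to one, two zero moments) define an
# affine subspace; parameterise w = w0 + N u with N an orthonormal null
# space basis and maximise the concave objective sum(log w) over u by BFGS
# with analytic gradient (the log barrier keeps w positive automatically).
el_primal_oracle <- function(r, g2) {
  n <- length(r)
  A <- rbind(rep(1, n), r, g2)      # A w = (1, 0, 0)
  w0 <- qr.solve(A, c(1, 0, 0))     # least-norm particular solution
  N <- svd(A, nu = 0, nv = n)$v[, (qr(A)$rank + 1L):n, drop = FALSE]
  if (any(w0 <= 0)) {
    # move the particular solution into the positive orthant: maximise a
    # smooth soft-minimum of the weights over the null space
    for (k in c(50, 200, 1000)) {
      softmin <- function(u) {
        w <- w0 + drop(N %*% u)
        m <- max(-k * w)
        (m + log(sum(exp(-k * w - m)))) / k   # stable log-sum-exp
      }
      push <- stats::optim(rep(0, ncol(N)), softmin, method = "BFGS",
                           control = list(maxit = 2000, reltol = 1e-15))
      w_try <- w0 + drop(N %*% push$par)
      if (all(w_try > 1e-8)) break
    }
    w0 <- w_try
    stopifnot(all(w0 > 0))
  }
  negll <- function(u) {
    w <- w0 + drop(N %*% u)
    if (any(w <= 0)) return(1e10 + sum(pmax(-w, 0)))
    -sum(log(w))
  }
  grad <- function(u) {
    w <- w0 + drop(N %*% u)
    if (any(w <= 0)) return(rep(0, length(u)))
    -drop(crossprod(N, 1 / w))
  }
  opt <- stats::optim(rep(0, ncol(N)), negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  w <- w0 + drop(N %*% opt$par)
  list(weights = w, log_el = sum(log(w)),
       constraint_resid = max(abs(drop(A %*% w) - c(1, 0, 0))))
}

# dense multivariate-normal log kernel with precision P (no normalising
# constant), used as an oracle for the spatial prior kernels
mvn_log_kernel <- function(x, P) -0.5 * drop(crossprod(x, P %*% x))

# conditional mean/variance of component i implied by a precision matrix
precision_conditional <- function(P, x, i) {
  list(mean = -sum(P[i, -i] * x[-i]) / P[i, i], variance = 1 / P[i, i])
}

# small fixture: 3-area path graph 1-2-3
path_graph3 <- function() sbel::build_adjacency(cbind(c(1, 2), c(2, 3)),
                                                n_areas = 3)

fast_config <- function(...) {
  sbel::sampler_config(n_iter = 2000, burn_in = 500, thin = 5, n_chains = 1,
                       pilot_length = 400, seed = 42, ...)
}
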