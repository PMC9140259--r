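#' Empirical-likelihood moment functions for the area-level model
#'
#' Builds the two estimating-equation contributions used throughout the
#' package: the raw residual \eqn{r_i = y_i - \mu_i} (location constraint)
#' and the standardised squared residual \eqn{g_{2i} = r_i^2/\sigma_i^2 - 1}
#' (scale constraint). An empirical likelihood places weights \eqn{w_i} on
#' the areas so that both weighted moments vanish.
#'
#' @param y numeric response vector (typically log SIR per area).
#' @param mu numeric vector of fitted means, same length as \code{y}.
#' @param sigma2 numeric vector of per-area sampling variances (recycled if
#'   scalar); all entries must be strictly positive.
#' @return An object of class \code{"sbel_moments"}: list with elements
#'   \code{r}, \code{g2} and \code{n}.
#' @examples
#' m <- build_moments(c(1, 2), c(0, 3), c(1, 1))
#' m$r   # 1 -1
#' m$g2  # 0  0
#' @export
build_moments <- function(y, mu, sigma2) {
  y <- as.numeric(y); mu <- as.numeric(mu)
  n <- length(y)
  if (length(mu) != n)
    stop("'y' and 'mu' must have equal length")
  if (length(sigma2) == 1L) sigma2 <- rep(as.numeric(sigma2), n)
  if (length(sigma2) != n)
    stop("'sigma2' must be scalar or match length(y)")
  if (anyNA(y) || anyNA(mu) || anyNA(sigma2) ||
      any(!is.finite(y)) || any(!is.finite(mu)) || any(!is.finite(sigma2)))
    stop("non-finite values in moment inputs")
  bad <- which(sigma2 <= 0)
  if (length(bad))
    stop("non-positive sampling variance for area(s): ",
         paste(bad, collapse = ", "))
  r <- y - mu
  g2 <- r^2 / sigma2 - 1
  structure(list(r = r, g2 = g2, n = n), class = "sbel_moments")
}

# Necessary feasibility condition: 0 must lie in the interior of the convex
# hull of the moment points, so each coordinate must either be identically
# zero or take both strict signs.
.el_hull_ok <- function(f) {
  for (j in seq_len(ncol(f))) {
    cj <- f[, j]
    if (all(cj == 0)) next
    if (min(cj) >= 0 || max(cj) <= 0) return(FALSE)
  }
  TRUE
}

#' Solve the two-constraint empirical-likelihood problem
#'
#' Maximises \eqn{\sum_i \log w_i} subject to \eqn{\sum_i w_i = 1},
#' \eqn{w_i > 0} and the two moment constraints
#' \eqn{\sum_i w_i r_i = 0}, \eqn{\sum_i w_i g_{2i} = 0}.
#' The default solver works in the standard dual: \eqn{w_i = 1/\{n(1 +
#' \lambda^\top f_i)\}} with \eqn{f_i = (r_i, g_{2i})^\top} and the
#' Lagrange multiplier \eqn{\lambda} located by damped Newton iteration.
#' \code{type = "et"} instead returns exponential-tilting weights
#' \eqn{w_i \propto \exp(\lambda^\top f_i)} (the entropy-maximising
#' solution), found by Newton on the convex dual
#' \eqn{\sum_i \exp(\lambda^\top f_i)}.
#'
#' Infeasibility (the origin outside the interior of the convex hull of the
#' moment points, or failure to meet the constraint tolerance) is not an
#' error: it is reported through the \code{feasible} flag with
#' \code{log_el = -Inf}, because the sampler treats it as a rejected
#' proposal.
#'
#' @param m an \code{"sbel_moments"} object from \code{\link{build_moments}}.
#' @param type \code{"owen"} (default) or \code{"et"}.
#' @param tol convergence tolerance on the scaled constraint residuals.
#' @param max_iter maximum Newton iterations.
#' @return An object of class \code{"el_solution"}: list with \code{weights},
#'   \code{lambda}, \code{log_el}, \code{feasible}, \code{iterations}.
#' @examples
#' m <- build_moments(c(1, 0), c(0, 1), 1)  # r = (1, -1), g2 = (0, 0)
#' sol <- solve_el(m)
#' sol$weights  # 0.5 0.5
#' @export
solve_el <- function(m, type = c("owen", "et"), tol = 1e-9, max_iter = 100L) {
  type <- match.arg(type)
  stopifnot(inherits(m, "sbel_moments"))
  n <- m$n
  if (n < 2L) stop("need at least two areas")
  f <- cbind(m$r, m$g2)
  if (anyNA(f) || any(!is.finite(f)))
    stop("non-finite values in moment vector")

  infeasible <- function(iter) {
    structure(list(weights = NULL, lambda = c(NA_real_, NA_real_),
                   log_el = -Inf, feasible = FALSE, iterations = iter),
              class = "el_solution")
  }
  if (!.el_hull_ok(f)) return(infeasible(0L))

  # column scaling for a well-conditioned Newton system
  s <- apply(abs(f), 2, max)
  s[s == 0] <- 1
  fs <- sweep(f, 2, s, "/")

  if (type == "owen") sol <- .el_newton_owen(fs, n, tol, max_iter)
  else sol <- .el_newton_et(fs, n, tol, max_iter)
  if (!sol$ok) return(infeasible(sol$iter))

  w <- sol$w
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-10) return(infeasible(sol$iter))
  structure(list(weights = w, lambda = sol$lambda / s,
                 log_el = sum(log(w)), feasible = TRUE,
                 iterations = sol$iter),
            class = "el_solution")
}

# Damped Newton ascent on the concave dual h(lambda) = sum log(1 + lambda'f),
# whose stationary point gives the Owen weights w_i = 1/(n(1 + lambda'f_i)).
.el_newton_owen <- function(f, n, tol, max_iter) {
  lam <- c(0, 0)
  z <- rep(1, n)
  # push the gradient well below `tol`: at stationarity sum(w) - 1 equals
  # -lambda' grad, so a slack gradient leaves a visible weight-sum error
  tol <- min(tol, 1e-12)
  for (iter in seq_len(max_iter)) {
    w <- 1 / (n * z)
    grad <- c(sum(w * f[, 1]), sum(w * f[, 2]))           # constraint residual
    if (max(abs(grad)) < tol)
      return(list(ok = TRUE, w = w, lambda = lam, iter = iter))
    u <- w / z                                            # 1/(n z^2)
    h11 <- sum(u * f[, 1]^2); h22 <- sum(u * f[, 2]^2)
    h12 <- sum(u * f[, 1] * f[, 2])
    det <- h11 * h22 - h12 * h12
    if (!is.finite(det) || det <= 1e-300 * max(h11 * h22, 1))
      return(list(ok = FALSE, iter = iter))
    step <- c(h22 * grad[1] - h12 * grad[2],
              h11 * grad[2] - h12 * grad[1]) / det
    # step-halving to keep all 1 + lambda'f_i strictly positive
    alpha <- 1
    repeat {
      lam_new <- lam + alpha * step
      z_new <- 1 + f[, 1] * lam_new[1] + f[, 2] * lam_new[2]
      if (min(z_new) > 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) return(list(ok = FALSE, iter = iter))
    }
    lam <- lam_new; z <- z_new
  }
  list(ok = FALSE, iter = max_iter)
}

# Damped Newton on the convex exponential-tilting dual
# K(lambda) = log sum exp(lambda'f); minimiser gives
# w_i = exp(lambda'f_i) / sum_j exp(lambda'f_j).
.el_newton_et <- function(f, n, tol, max_iter) {
  lam <- c(0, 0)
  lse <- function(l) {
    eta <- f[, 1] * l[1] + f[, 2] * l[2]
    m <- max(eta)
    m + log(sum(exp(eta - m)))
  }
  K <- lse(lam)
  for (iter in seq_len(max_iter)) {
    eta <- f[, 1] * lam[1] + f[, 2] * lam[2]
    e <- exp(eta - max(eta))
    w <- e / sum(e)
    grad <- c(sum(w * f[, 1]), sum(w * f[, 2]))
    if (max(abs(grad)) < tol)
      return(list(ok = TRUE, w = w, lambda = lam, iter = iter))
    h11 <- sum(w * f[, 1]^2) - grad[1]^2
    h22 <- sum(w * f[, 2]^2) - grad[2]^2
    h12 <- sum(w * f[, 1] * f[, 2]) - grad[1] * grad[2]
    det <- h11 * h22 - h12 * h12
    if (!is.finite(det) || det <= 1e-300 * max(h11 * h22, 1))
      return(list(ok = FALSE, iter = iter))
    step <- -c(h22 * grad[1] - h12 * grad[2],
               h11 * grad[2] - h12 * grad[1]) / det
    # line search on the convex dual objective
    alpha <- 1
    repeat {
      lam_new <- lam + alpha * step
      K_new <- lse(lam_new)
      if (is.finite(K_new) && K_new <= K + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-14) return(list(ok = FALSE, iter = iter))
    }
    lam <- lam_new; K <- K_new
    if (any(!is.finite(lam))) return(list(ok = FALSE, iter = iter))
  }
  list(ok = FALSE, iter = max_iter)
}

#' Log empirical likelihood at a given parameter configuration
#'
#' Evaluates the EL "likelihood" term \eqn{\prod_i w_i} of the posterior at
#' mean \eqn{\mu = X\beta + \psi}: the quantity the Metropolis--Hastings
#' acceptance ratios compare across proposals.
#'
#' @param y response vector.
#' @param X n x (p+1) design matrix (first column ones).
#' @param beta coefficient vector, length ncol(X).
#' @param psi spatial random-effect vector, length n.
#' @param sigma2 per-area variances (scalar or vector).
#' @param type EL flavour, passed to \code{\link{solve_el}}.
#' @return list with \code{log_el}, \code{weights} (NULL if infeasible) and
#'   \code{feasible}.
#' @export
log_el_at <- function(y, X, beta, psi, sigma2, type = "owen") {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (ncol(X) != length(beta)) stop("length(beta) must equal ncol(X)")
  if (length(psi) != length(y)) stop("length(psi) must equal length(y)")
  mu <- drop(X %*% beta) + psi
  sol <- solve_el(build_moments(y, mu, sigma2), type = type)
  list(log_el = sol$log_el, weights = sol$weights, feasible = sol$feasible)
}

#' @export
print.el_solution <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("EL solution: n = %d, log-EL = %.6f (%d Newton iterations)\n",
                length(x$weights), x$log_el, x$iterations))
    cat("lambda:", format(x$lambda, digits = 6), "\n")
  } else {
    cat("EL solution: infeasible (origin outside moment convex hull)\n")
  }
  invisible(x)
}
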