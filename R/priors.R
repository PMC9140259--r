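#' Spatial prior specification
#'
#' Bundles a prior family for the area random effects with its precomputed
#' structure matrices. Families:
#' \describe{
#'   \item{\code{"ig"}}{independent Gaussian, precision \eqn{\tau I}
#'     (the Leroux family at \eqn{\rho = 0}).}
#'   \item{\code{"bym"}}{intrinsic CAR, precision \eqn{\tau R}
#'     (the Leroux family at \eqn{\rho = 1}; improper, rank n - c).}
#'   \item{\code{"leroux"}}{precision \eqn{\tau\{(1-\rho)I + \rho R\}}.}
#'   \item{\code{"moran"}}{reduced-rank Moran basis: \eqn{\psi = M\psi^*}
#'     with \eqn{\psi^* \sim N(0, \{\tau M'(B_+ - B)M\}^{-1})}.}
#' }
#'
#' @param family one of \code{"ig"}, \code{"bym"}, \code{"leroux"},
#'   \code{"moran"}.
#' @param adj an \code{"adjacency"} object.
#' @param rho Leroux mixing parameter (required for \code{"leroux"}).
#' @param X design matrix (required for \code{"moran"}).
#' @param tol Moran eigenvalue cutoff, see \code{\link{moran_basis}}.
#' @return An object of class \code{"spatial_prior"}: list with
#'   \code{family}, \code{rho}, precision structure \code{Q0} (so the prior
#'   precision of the sampled spatial coefficients is \eqn{\tau Q_0}),
#'   its rank \code{k}, the coefficient dimension \code{dim}, and for the
#'   Moran family the basis \code{M}.
#' @export
spatial_prior_spec <- function(family = c("ig", "bym", "leroux", "moran"),
                               adj, rho = NULL, X = NULL, tol = 1e-8) {
  family <- match.arg(family)
  stopifnot(inherits(adj, "adjacency"))
  n <- adj$n
  if (family %in% c("bym", "leroux") && any(adj$n_nb == 0))
    stop("CAR priors require every area to have at least one neighbour")
  out <- switch(family,
    ig = list(rho = 0, Q0 = diag(n), k = n, dim = n, M = NULL),
    bym = {
      if (!adj$connected)
        warning("intrinsic CAR on a disconnected graph: rank n - ",
                adj$n_components)
      list(rho = 1, Q0 = intrinsic_R(adj), k = n - adj$n_components,
           dim = n, M = NULL)
    },
    leroux = {
      if (is.null(rho)) stop("family 'leroux' requires 'rho'")
      if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
      R <- intrinsic_R(adj)
      k <- if (rho < 1) n else n - adj$n_components
      list(rho = rho, Q0 = leroux_Dminus(R, rho), k = k, dim = n, M = NULL)
    },
    moran = {
      if (is.null(X)) stop("family 'moran' requires the design matrix 'X'")
      mb <- moran_basis(adj, X, tol = tol)
      list(rho = NA_real_, Q0 = mb$moran_precision, k = mb$q, dim = mb$q,
           M = mb$M)
    })
  structure(c(list(family = family, adj = adj), out),
            class = "spatial_prior")
}

#' @export
print.spatial_prior <- function(x, ...) {
  cat(sprintf("Spatial prior: %s (%d areas", x$family, x$adj$n))
  if (x$family == "leroux") cat(sprintf(", rho = %g", x$rho))
  if (x$family == "moran") cat(sprintf(", basis dimension q = %d", x$dim))
  cat(")\n")
  invisible(x)
}

#' Hyperparameters of the SBEL prior hierarchy
#'
#' @param g Zellner scaling of the coefficient prior precision relative to
#'   \eqn{\tau}; 10 gives the coefficient prior about 10\% weight.
#' @param alpha1,alpha2 Gamma hyperparameters for \eqn{\tau}.
#' @param tau_density \code{"as_printed"} uses the kernel
#'   \eqn{\tau^{1+\alpha_1} e^{-\alpha_2\tau}}; \code{"standard_gamma"} the
#'   usual Gamma(\eqn{\alpha_1,\alpha_2}) kernel
#'   \eqn{\tau^{\alpha_1-1} e^{-\alpha_2\tau}}.
#' @param include_tau_power include the \eqn{\tau}-power normalisation
#'   factors of the \eqn{\psi} and \eqn{\beta} kernels in the \eqn{\tau}
#'   update (they cancel in the \eqn{\psi} and \eqn{\beta} updates).
#' @return list of class \code{"sbel_hyperparams"}.
#' @export
hyperparams <- function(g = 10, alpha1 = 1, alpha2 = 1,
                        tau_density = c("as_printed", "standard_gamma"),
                        include_tau_power = TRUE) {
  tau_density <- match.arg(tau_density)
  if (g <= 0 || alpha1 <= 0 || alpha2 <= 0)
    stop("'g', 'alpha1' and 'alpha2' must be positive")
  structure(list(g = g, alpha1 = alpha1, alpha2 = alpha2,
                 tau_density = tau_density,
                 include_tau_power = isTRUE(include_tau_power)),
            class = "sbel_hyperparams")
}

#' Log prior kernels
#'
#' Log densities up to additive constants not involving the sampled
#' quantities. \code{log_prior_psi} evaluates the Gaussian spatial kernel
#' \eqn{-\tfrac12 \tau\, \psi' Q_0 \psi} (plus \eqn{(k/2)\log\tau} when
#' \code{include_tau_power}); for the Moran family \code{psi} is the basis
#' coefficient vector \eqn{\psi^*}. \code{log_prior_beta} evaluates the
#' Zellner-style anchor kernel
#' \eqn{-\tfrac12 g \tau (\beta - \tilde\beta)'(\beta - \tilde\beta)};
#' \code{log_prior_tau} the Gamma-type kernel chosen in
#' \code{\link{hyperparams}}.
#'
#' @param psi spatial coefficient vector (length \code{spec$dim}).
#' @param tau precision parameter (> 0).
#' @param spec a \code{"spatial_prior"} object.
#' @param include_tau_power include the \eqn{(k/2)\log\tau} (resp.
#'   \eqn{((p+1)/2)\log\tau}) factor.
#' @return a single numeric log-kernel value.
#' @export
log_prior_psi <- function(psi, tau, spec, include_tau_power = FALSE) {
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be positive")
  stopifnot(inherits(spec, "spatial_prior"))
  if (length(psi) != spec$dim)
    stop("length(psi) must equal the prior coefficient dimension ", spec$dim)
  val <- -0.5 * tau * drop(crossprod(psi, spec$Q0 %*% psi))
  if (include_tau_power) val <- val + 0.5 * spec$k * log(tau)
  val
}

#' @rdname log_prior_psi
#' @param beta coefficient vector.
#' @param beta_anchor anchor point \eqn{\tilde\beta} (the WLS estimate).
#' @param hp a \code{"sbel_hyperparams"} object.
#' @export
log_prior_beta <- function(beta, tau, beta_anchor, hp,
                           include_tau_power = FALSE) {
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be positive")
  d <- beta - beta_anchor
  val <- -0.5 * hp$g * tau * sum(d * d)
  if (include_tau_power) val <- val + 0.5 * length(beta) * log(tau)
  val
}

#' @rdname log_prior_psi
#' @export
log_prior_tau <- function(tau, hp) {
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be positive")
  expo <- if (hp$tau_density == "as_printed") 1 + hp$alpha1 else hp$alpha1 - 1
  expo * log(tau) - hp$alpha2 * tau
}

#' Weighted least-squares coefficient anchor
#'
#' \eqn{\tilde\beta = \beta_{WLS}} with weights \eqn{1/\sigma_i^2} when
#' per-area sampling variances are available, ordinary least squares
#' otherwise.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param sigma2 optional per-area variances.
#' @return coefficient vector of length ncol(X).
#' @export
beta_wls <- function(y, X, sigma2 = NULL) {
  X <- as.matrix(X)
  if (is.null(sigma2)) {
    fit <- lm.fit(X, y)
  } else {
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, length(y))
    fit <- lm.wfit(X, y, w = 1 / sigma2)
  }
  unname(fit$coefficients)
}
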