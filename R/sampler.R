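#' Sampler configuration
#'
#' Defaults mirror the full-length protocol (three chains of one million
#' iterations, 100,000 burn-in, thinning 10); desk-scale analyses and the
#' package tests override them downwards.
#'
#' @param n_iter iterations per chain (post-pilot).
#' @param burn_in burn-in iterations discarded from each chain.
#' @param thin thinning interval for stored draws.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain c uses \code{seed + c}.
#' @param pilot_length iterations of the adaptive pilot phase (proposal
#'   tuning is frozen afterwards so the retained kernel is valid).
#' @param adapt_interval pilot adaptation window.
#' @param target_accept acceptance-rate band aimed for by the pilot.
#' @param scale_psi,scale_beta,scale_tau initial random-walk proposal
#'   scales.
#' @param psi_moment_beta which beta enters the EL moments of the psi
#'   update: \code{"mele"} (the step-1 maximum-EL estimate, as described)
#'   or \code{"current"} (the coherent joint sampler).
#' @param el_type EL flavour, see \code{\link{solve_el}}.
#' @param likelihood \code{"el"} for the empirical-likelihood posterior;
#'   \code{"none"} drops the likelihood term (prior-only sampling, used for
#'   validating the prior kernels and the tau conditional).
#' @param fix optional character vector naming blocks to hold at their
#'   initial values (subset of \code{"psi"}, \code{"beta"}, \code{"tau"});
#'   a validation hook for studying one conditional at a time.
#' @param init optional named list of starting values (\code{psi} in the
#'   prior coefficient space, \code{beta}, \code{tau}) overriding the
#'   default initialisation.
#' @param rho_grid default grid for \code{\link{grid_search_rho}}.
#' @param verbose emit structured progress lines.
#' @return list of class \code{"sampler_config"}.
#' @export
sampler_config <- function(n_iter = 1e6, burn_in = 1e5, thin = 10,
                           n_chains = 3, seed = 1L, pilot_length = 10000,
                           adapt_interval = 100,
                           target_accept = c(0.2, 0.4),
                           scale_psi = 0.02, scale_beta = 0.05,
                           scale_tau = 0.1,
                           psi_moment_beta = c("mele", "current"),
                           el_type = "owen",
                           likelihood = c("el", "none"),
                           rho_grid = c(seq(0, 0.9, by = 0.1), 0.95, 0.99, 1),
                           fix = NULL, init = NULL,
                           verbose = FALSE) {
  psi_moment_beta <- match.arg(psi_moment_beta)
  likelihood <- match.arg(likelihood)
  if (!is.null(fix) && !all(fix %in% c("psi", "beta", "tau")))
    stop("'fix' may only name psi, beta or tau")
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  if (thin < 1) stop("'thin' must be >= 1")
  if (any(c(scale_psi, scale_beta, scale_tau) <= 0))
    stop("proposal scales must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 pilot_length = as.integer(pilot_length),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept, scale_psi = scale_psi,
                 scale_beta = scale_beta, scale_tau = scale_tau,
                 psi_moment_beta = psi_moment_beta, el_type = el_type,
                 likelihood = likelihood, rho_grid = rho_grid,
                 fix = fix, init = init, verbose = isTRUE(verbose)),
            class = "sampler_config")
}

# Starting values: beta at its maximum empirical-likelihood estimate
# (numerical optimiser seeded at the WLS fit), psi = 0, and -- when per-area
# sampling variances are absent -- sigma_i^2 set to the constant residual
# variance of the WLS fit.
sbel_initialize <- function(data, hp = hyperparams(), el_type = "owen",
                            require_el = TRUE) {
  stopifnot(inherits(data, "area_dataset"))
  y <- data$y; X <- data$X
  anchor <- beta_wls(y, X, data$sigma2)
  sigma2 <- data$sigma2
  if (is.null(sigma2)) {
    res <- y - drop(X %*% anchor)
    s2 <- sum(res^2) / max(1, length(y) - ncol(X))
    if (s2 < 1e-12)
      stop("response is an exact linear fit of the covariates: residual ",
           "variance is zero at beta_WLS so the EL scale constraint is ",
           "infeasible for every beta")
    sigma2 <- rep(s2, length(y))
  }
  if (!require_el)
    return(list(beta0 = anchor, beta_anchor = anchor, sigma2 = sigma2,
                log_el0 = NA_real_))
  obj <- function(b) {
    s <- log_el_at(y, X, b, rep(0, length(y)), sigma2, type = el_type)
    if (!s$feasible) 1e8 else -s$log_el
  }
  f_wls <- obj(anchor)
  opt <- tryCatch(
    stats::optim(anchor, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) list(par = anchor, value = f_wls))
  beta0 <- if (opt$value <= f_wls) opt$par else anchor
  if (obj(beta0) >= 1e7)
    stop("empirical likelihood infeasible at every candidate beta ",
         "(tried the MELE search from beta_WLS = ",
         paste(signif(anchor, 4), collapse = ", "), ")")
  list(beta0 = unname(beta0), beta_anchor = anchor, sigma2 = sigma2,
       log_el0 = -obj(beta0))
}

# log EL helper returning the full solution (or feasible = FALSE)
.el_eval <- function(y, X, beta, psi, sigma2, el_type) {
  mu <- drop(X %*% beta) + psi
  solve_el(build_moments(y, mu, sigma2), type = el_type)
}

# One Metropolis-Hastings chain. `prop` carries frozen proposal choleskys
# (L_psi: d x d, L_beta: (p+1) x (p+1)) and the tau scale. Returns stored
# draws plus acceptance rates. Spatial coefficients theta live in the
# prior's coefficient space (psi itself, or Moran basis coordinates).
.run_chain <- function(y, X, Z, spec, sigma2, hp, config, prop,
                       beta0, beta_anchor, beta_mom, chain_seed,
                       n_iter, burn_in, thin, adapt = FALSE) {
  set.seed(chain_seed)
  n <- length(y); pp <- ncol(X); d <- spec$dim
  use_el <- config$likelihood == "el"
  mele_mode <- config$psi_moment_beta == "mele" && use_el
  Q0 <- spec$Q0

  fix <- config$fix %||% character()
  init <- config$init %||% list()
  beta <- init$beta %||% beta0
  theta <- init$psi %||% rep(0, d)
  psi <- if (is.null(Z)) theta else drop(Z %*% theta)
  tau <- init$tau %||% stats::rgamma(1, hp$alpha1, hp$alpha2)
  qf <- drop(crossprod(theta, Q0 %*% theta))

  if (use_el) {
    sol <- .el_eval(y, X, beta, psi, sigma2, config$el_type)
    if (!sol$feasible)
      stop("chain initialisation failed: EL infeasible at the starting state")
    logel_beta <- sol$log_el; logw_beta <- log(sol$weights)
    if (mele_mode) {
      solm <- .el_eval(y, X, beta_mom, psi, sigma2, config$el_type)
      if (!solm$feasible)
        stop("chain initialisation failed: EL infeasible at the MELE beta")
      logel_psi <- solm$log_el
    } else logel_psi <- logel_beta
  } else {
    logel_beta <- 0; logel_psi <- 0; logw_beta <- rep(0, n)
  }

  n_store <- if (n_iter > burn_in) (n_iter - burn_in) %/% thin else 0L
  st_beta <- matrix(NA_real_, n_store, pp)
  st_theta <- matrix(NA_real_, n_store, d)
  st_tau <- numeric(n_store)
  st_loglik <- matrix(NA_real_, n_store, n)
  s_idx <- 0L

  acc <- c(psi = 0L, beta = 0L, tau = 0L)
  win <- c(psi = 0L, beta = 0L, tau = 0L)
  mult <- c(psi = 1, beta = 1, tau = 1)
  pilot_theta <- if (adapt) matrix(NA_real_, n_iter, d) else NULL
  pilot_beta <- if (adapt) matrix(NA_real_, n_iter, pp) else NULL

  lo <- config$target_accept[1]; hi <- config$target_accept[2]
  mid <- mean(config$target_accept)

  for (t in seq_len(n_iter)) {
    ## --- psi block -------------------------------------------------------
    if (!("psi" %in% fix)) {
    theta_star <- theta + mult["psi"] * drop(prop$L_psi %*% stats::rnorm(d))
    psi_star <- if (is.null(Z)) theta_star else drop(Z %*% theta_star)
    qf_star <- drop(crossprod(theta_star, Q0 %*% theta_star))
    ok <- TRUE
    if (use_el) {
      solm <- .el_eval(y, X, beta_mom_cur <- if (mele_mode) beta_mom else beta,
                       psi_star, sigma2, config$el_type)
      ok <- solm$feasible
      if (ok && mele_mode) {
        solc <- .el_eval(y, X, beta, psi_star, sigma2, config$el_type)
        ok <- solc$feasible
      } else solc <- solm
    }
    if (ok) {
      lr <- -0.5 * tau * (qf_star - qf)
      if (use_el) lr <- lr + solm$log_el - logel_psi
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        theta <- theta_star; psi <- psi_star; qf <- qf_star
        if (use_el) {
          logel_psi <- solm$log_el
          logel_beta <- solc$log_el; logw_beta <- log(solc$weights)
        }
        acc["psi"] <- acc["psi"] + 1L; win["psi"] <- win["psi"] + 1L
      }
    }
    }

    ## --- beta block ------------------------------------------------------
    if (!("beta" %in% fix)) {
    beta_star <- beta + mult["beta"] * drop(prop$L_beta %*% stats::rnorm(pp))
    ok <- TRUE
    if (use_el) {
      solb <- .el_eval(y, X, beta_star, psi, sigma2, config$el_type)
      ok <- solb$feasible
    }
    if (ok) {
      db <- beta_star - beta_anchor; dc <- beta - beta_anchor
      lr <- -0.5 * hp$g * tau * (sum(db * db) - sum(dc * dc))
      if (use_el) lr <- lr + solb$log_el - logel_beta
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        beta <- beta_star
        if (use_el) {
          logel_beta <- solb$log_el; logw_beta <- log(solb$weights)
          if (!mele_mode) logel_psi <- logel_beta
        }
        acc["beta"] <- acc["beta"] + 1L; win["beta"] <- win["beta"] + 1L
      }
    }
    }

    ## --- tau block (EL term cancels) ------------------------------------
    if (!("tau" %in% fix)) {
    tau_star <- tau + mult["tau"] * prop$s_tau * stats::rnorm(1)
    if (tau_star > 0) {
      db <- beta - beta_anchor
      lr <- -0.5 * (tau_star - tau) * (qf + hp$g * sum(db * db)) +
        log_prior_tau(tau_star, hp) - log_prior_tau(tau, hp)
      if (hp$include_tau_power)
        lr <- lr + 0.5 * (spec$k + pp) * (log(tau_star) - log(tau))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        tau <- tau_star
        acc["tau"] <- acc["tau"] + 1L; win["tau"] <- win["tau"] + 1L
      }
    }
    }

    ## --- pilot adaptation ------------------------------------------------
    if (adapt) {
      pilot_theta[t, ] <- theta; pilot_beta[t, ] <- beta
      if (t %% config$adapt_interval == 0L) {
        rate <- win / config$adapt_interval
        for (b in names(mult)) {
          if (rate[b] < lo || rate[b] > hi)
            mult[b] <- mult[b] * exp(rate[b] - mid)
        }
        win[] <- 0L
      }
    }

    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      s_idx <- s_idx + 1L
      st_beta[s_idx, ] <- beta
      st_theta[s_idx, ] <- theta
      st_tau[s_idx] <- tau
      st_loglik[s_idx, ] <- logw_beta
    }
    if (config$verbose && t %% 5000L == 0L)
      message(sprintf("iter %d | accept psi %.3f beta %.3f tau %.3f",
                      t, acc["psi"] / t, acc["beta"] / t, acc["tau"] / t))
  }

  list(beta = st_beta, theta = st_theta, tau = st_tau, loglik = st_loglik,
       accept = acc / n_iter, mult = mult,
       pilot_theta = pilot_theta, pilot_beta = pilot_beta)
}

# Pilot-chain proposal tuning: stage 1 adapts scalar multipliers on
# identity-shaped proposals; stage 2 rebuilds the proposal covariance
# Haario-style (2.38^2/d times the pilot draw covariance) and re-adapts a
# scalar multiplier. The result is frozen before the retained phase.
.tune_proposals <- function(y, X, Z, spec, sigma2, hp, config,
                            beta0, beta_anchor, beta_mom) {
  d <- spec$dim; pp <- ncol(X)
  prop <- list(L_psi = diag(config$scale_psi, d),
               L_beta = diag(config$scale_beta, pp),
               s_tau = config$scale_tau)
  half <- max(config$adapt_interval, config$pilot_length %/% 2L)
  for (stage in 1:2) {
    pil <- .run_chain(y, X, Z, spec, sigma2, hp, config, prop,
                      beta0, beta_anchor, beta_mom,
                      chain_seed = config$seed + 10000L * stage,
                      n_iter = half, burn_in = half + 1L, thin = 1L,
                      adapt = TRUE)
    scale_chol <- function(L, m) L * m
    if (stage == 1L) {
      keep <- seq(half %/% 2L, half)
      cv_t <- stats::cov(pil$pilot_theta[keep, , drop = FALSE])
      cv_b <- stats::cov(pil$pilot_beta[keep, , drop = FALSE])
      jitter <- function(cv, base) {
        tr <- sum(diag(cv))
        if (!is.finite(tr) || tr <= 0) return(diag(base^2, nrow(cv)))
        cv + diag(1e-8 + 1e-3 * tr / nrow(cv), nrow(cv))
      }
      L1 <- tryCatch(t(chol((2.38^2 / d) * jitter(cv_t, config$scale_psi))),
                     error = function(e) scale_chol(prop$L_psi, pil$mult["psi"]))
      L2 <- tryCatch(t(chol((2.38^2 / pp) * jitter(cv_b, config$scale_beta))),
                     error = function(e) scale_chol(prop$L_beta, pil$mult["beta"]))
      prop <- list(L_psi = L1, L_beta = L2,
                   s_tau = prop$s_tau * pil$mult["tau"])
    } else {
      prop <- list(L_psi = scale_chol(prop$L_psi, pil$mult["psi"]),
                   L_beta = scale_chol(prop$L_beta, pil$mult["beta"]),
                   s_tau = prop$s_tau * pil$mult["tau"])
    }
  }
  prop
}

#' Run the SBEL Metropolis--Hastings sampler
#'
#' Step 1 initialises at the maximum empirical-likelihood estimate of beta;
#' steps 2--4 update the spatial effects, the coefficients and the
#' precision in turn with random-walk proposals, gating every proposal on
#' feasibility of the EL weight constraints. A pilot phase tunes the
#' proposal covariances and is frozen before the retained draws.
#'
#' @param data an \code{"area_dataset"} with adjacency.
#' @param spec a \code{"spatial_prior"} (see \code{\link{spatial_prior_spec}}).
#' @param config a \code{"sampler_config"}.
#' @param hp a \code{"sbel_hyperparams"}.
#' @return An object of class \code{"sbel_chains"}: per-chain stored draws
#'   of beta, the spatial coefficients, tau, the pointwise log-EL matrix
#'   (log weights), acceptance rates and the resolved configuration.
#' @export
run_sbel <- function(data, spec, config = sampler_config(),
                     hp = hyperparams()) {
  stopifnot(inherits(data, "area_dataset"), inherits(spec, "spatial_prior"))
  init <- sbel_initialize(data, hp, el_type = config$el_type,
                          require_el = config$likelihood == "el")
  y <- data$y; X <- data$X
  Z <- spec$M   # NULL for full-dimension priors

  prop <- .tune_proposals(y, X, Z, spec, init$sigma2, hp, config,
                          init$beta0, init$beta_anchor, init$beta0)
  chains <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    chains[[c]] <- .run_chain(y, X, Z, spec, init$sigma2, hp, config, prop,
                              init$beta0, init$beta_anchor, init$beta0,
                              chain_seed = config$seed + c,
                              n_iter = config$n_iter,
                              burn_in = config$burn_in, thin = config$thin)
    chains[[c]]$pilot_theta <- NULL; chains[[c]]$pilot_beta <- NULL
    if (config$verbose)
      message(sprintf("chain %d done | accept psi %.3f beta %.3f tau %.3f",
                      c, chains[[c]]$accept["psi"],
                      chains[[c]]$accept["beta"], chains[[c]]$accept["tau"]))
  }
  structure(list(chains = chains, spec_family = spec$family,
                 rho = spec$rho, M = spec$M, k = spec$k, dim = spec$dim,
                 config = config, hp = hp, data = data,
                 beta0 = init$beta0, beta_anchor = init$beta_anchor,
                 sigma2 = init$sigma2),
            class = "sbel_chains")
}

#' @export
print.sbel_chains <- function(x, ...) {
  S <- nrow(x$chains[[1]]$beta)
  cat(sprintf(
    "SBEL chains: %s prior, %d chain(s) x %d stored draws (%d areas)\n",
    x$spec_family, length(x$chains), S, x$data$n))
  acc <- sapply(x$chains, `[[`, "accept")
  cat("mean acceptance:",
      paste(sprintf("%s %.3f", rownames(acc), rowMeans(acc)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit a spatial Bayesian empirical likelihood model
#'
#' High-level wrapper: builds the spatial prior, runs the sampler and
#' summarises the posterior.
#'
#' @param data an \code{"area_dataset"} with adjacency.
#' @param prior one of \code{"ig"}, \code{"bym"}, \code{"leroux"},
#'   \code{"moran"}.
#' @param rho Leroux mixing parameter (only for \code{prior = "leroux"}).
#' @param config a \code{"sampler_config"}.
#' @param hp a \code{"sbel_hyperparams"}.
#' @return An \code{"sbel_fit"}; see \code{\link{summarize_chains}}.
#' @examples
#' \donttest{
#' sim <- generate_scenario(scenario_spec(25, "high", seed = 7))
#' fit <- sbel(sim$data, prior = "ig",
#'             config = sampler_config(n_iter = 2000, burn_in = 500,
#'                                     thin = 5, n_chains = 1,
#'                                     pilot_length = 500))
#' fit
#' }
#' @export
sbel <- function(data, prior = c("ig", "bym", "leroux", "moran"),
                 rho = NULL, config = sampler_config(),
                 hp = hyperparams()) {
  prior <- match.arg(prior)
  spec <- spatial_prior_spec(prior, data$adjacency, rho = rho, X = data$X)
  chains <- run_sbel(data, spec, config = config, hp = hp)
  summarize_chains(chains)
}

#' Grid search over the Leroux mixing parameter
#'
#' Fits the SBEL-Leroux model at each candidate rho and ranks the fits by
#' WAIC; the endpoints rho = 0 and rho = 1 reproduce the independent
#' Gaussian and intrinsic CAR models.
#'
#' @param data an \code{"area_dataset"} with adjacency.
#' @param config a \code{"sampler_config"}.
#' @param hp hyperparameters.
#' @param rho_grid candidate values (defaults to \code{config$rho_grid}).
#' @return list with \code{best_rho}, \code{table} (rho, waic, p_waic,
#'   lppd, plus any per-rho failure message) and the \code{best_fit}.
#' @export
grid_search_rho <- function(data, config = sampler_config(),
                            hp = hyperparams(), rho_grid = NULL) {
  if (is.null(rho_grid)) rho_grid <- config$rho_grid
  rows <- vector("list", length(rho_grid))
  best <- NULL; best_waic <- Inf
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    fit <- tryCatch(sbel(data, prior = "leroux", rho = rho,
                         config = config, hp = hp),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(rho = rho, waic = NA_real_, p_waic = NA_real_,
                              lppd = NA_real_, error = conditionMessage(fit))
    } else {
      rows[[i]] <- data.frame(rho = rho, waic = fit$waic,
                              p_waic = fit$p_waic, lppd = fit$lppd,
                              error = NA_character_)
      if (fit$waic < best_waic) { best_waic <- fit$waic; best <- fit }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(best)) stop("every grid point failed to fit")
  list(best_rho = tab$rho[which.min(tab$waic)], table = tab,
       best_fit = best)
}
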