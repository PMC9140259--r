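#' Stable WAIC from pointwise log-likelihood draws
#'
#' The widely applicable information criterion with the variance-based
#' (stable) penalty: \eqn{lppd = \sum_i \log\{S^{-1}\sum_t \exp L_{ti}\}}
#' (computed by log-sum-exp), \eqn{p_{waic} = \sum_i Var_t(L_{\cdot i})}
#' (sample variance), \eqn{WAIC = -2(lppd - p_{waic})}. In the SBEL models
#' the pointwise contributions are the log EL weights \eqn{\log w_i}, so
#' lppd is bounded above by \eqn{-n\log n} and the WAIC floor is
#' \eqn{2n\log n}.
#'
#' @param L draws x areas matrix of pointwise log-likelihood values.
#' @return list with \code{waic}, \code{lppd}, \code{p_waic}.
#' @examples
#' L <- matrix(log(1 / 56), nrow = 100, ncol = 56)
#' waic(L)$waic  # 2 * 56 * log(56) = 450.57
#' @export
waic <- function(L) {
  L <- as.matrix(L)
  S <- nrow(L)
  if (S < 2) stop("WAIC needs at least two draws")
  if (any(!is.finite(L))) stop("non-finite pointwise log-likelihood values")
  # columnwise log-sum-exp
  mx <- apply(L, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(L, 2, mx)))))
  p_waic <- sum(apply(L, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio
#' \eqn{\sqrt{\{(S-1)/S\, W + B/S\}/W}}, clamped below at 1 (identical
#' chains give exactly 1 under the clamped convention).
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains of
#'   >= 10 draws).
#' @return the PSRF (scalar, >= 1).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least two chains")
  S <- unique(lengths(chains))
  if (length(S) != 1) stop("chains must have equal length")
  if (S < 10) stop("chains too short for the diagnostic")
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- S * stats::var(means)
  if (W <= 0) return(1)
  max(1, sqrt(((S - 1) / S * W + B / S) / W))
}

#' Posterior summaries, convergence diagnostics and WAIC
#'
#' Pools the post-burn-in draws across chains and reports, per parameter,
#' the posterior mean, equal-tailed 95\% credible interval and PSRF;
#' area-level random-effect and smoothed-value (\eqn{e^{\mu_i}}) summaries;
#' and the stable WAIC computed from the stored log EL weights.
#'
#' @param chains an \code{"sbel_chains"} object from \code{\link{run_sbel}}.
#' @return An object of class \code{"sbel_fit"}: list with the parameter
#'   \code{summary} data frame, \code{waic}, \code{p_waic}, \code{lppd},
#'   \code{psi_mean}/\code{psi_ci}, \code{smoothed} (per-area posterior
#'   summaries of \eqn{e^{\mu_i}}), acceptance rates and the underlying
#'   \code{chains}.
#' @export
summarize_chains <- function(chains) {
  stopifnot(inherits(chains, "sbel_chains"))
  ch <- chains$chains
  if (nrow(ch[[1]]$beta) == 0) stop("no stored draws to summarise")
  pp <- ncol(ch[[1]]$beta)
  n <- chains$data$n

  beta_all <- do.call(rbind, lapply(ch, `[[`, "beta"))
  tau_all <- do.call(c, lapply(ch, `[[`, "tau"))
  L_all <- do.call(rbind, lapply(ch, `[[`, "loglik"))

  psrf <- function(extract) {
    if (length(ch) < 2) return(NA_real_)
    gelman_rubin(lapply(ch, extract))
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

  rows <- vector("list", pp + 1L)
  for (j in seq_len(pp)) {
    ci <- qs(beta_all[, j])
    rows[[j]] <- data.frame(parameter = paste0("beta", j - 1L),
                            mean = mean(beta_all[, j]),
                            ci_low = ci[1], ci_high = ci[2],
                            psrf = psrf(function(c) c$beta[, j]))
  }
  ci <- qs(tau_all)
  rows[[pp + 1L]] <- data.frame(parameter = "tau", mean = mean(tau_all),
                                ci_low = ci[1], ci_high = ci[2],
                                psrf = psrf(function(c) c$tau))
  summary_df <- do.call(rbind, rows)

  # random effects on the area scale (map basis coefficients through M)
  psi_draws <- do.call(rbind, lapply(ch, function(c) {
    if (is.null(chains$M)) c$theta else c$theta %*% t(chains$M)
  }))
  psi_mean <- colMeans(psi_draws)
  psi_ci <- t(apply(psi_draws, 2, qs))

  # smoothed fitted values exp(X beta + psi)
  mu_draws <- beta_all %*% t(chains$data$X) + psi_draws
  sm <- exp(mu_draws)
  smoothed <- data.frame(id = chains$data$ids,
                         mean = colMeans(sm),
                         ci_low = apply(sm, 2, function(v) qs(v)[1]),
                         ci_high = apply(sm, 2, function(v) qs(v)[2]))

  w <- if (chains$config$likelihood == "el") waic(L_all)
       else list(waic = NA_real_, lppd = NA_real_, p_waic = NA_real_)
  acc <- rowMeans(sapply(ch, `[[`, "accept"))

  structure(list(summary = summary_df, waic = w$waic, lppd = w$lppd,
                 p_waic = w$p_waic, psi_mean = psi_mean, psi_ci = psi_ci,
                 smoothed = smoothed, accept = acc,
                 family = chains$spec_family, rho = chains$rho,
                 n_draws = nrow(beta_all), chains = chains),
            class = "sbel_fit")
}

#' @export
print.sbel_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SBEL fit: %s prior%s | %d pooled draws | WAIC = %s\n",
              x$family,
              if (x$family == "leroux") sprintf(" (rho = %g)", x$rho) else "",
              x$n_draws,
              if (is.na(x$waic)) "NA (prior-only run)"
              else formatC(x$waic, format = "f", digits = 2)))
  df <- x$summary
  df[c("mean", "ci_low", "ci_high", "psrf")] <-
    lapply(df[c("mean", "ci_low", "ci_high", "psrf")], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write fit summaries to CSV
#'
#' Writes a parameter-level table (model, parameter, mean, ci_low, ci_high,
#' psrf), a one-row model-level table (waic, p_waic, lppd, selected rho)
#' and the per-area smoothed values.
#'
#' @param fit an \code{"sbel_fit"}.
#' @param dir output directory (created if needed).
#' @param model_name label used in the \code{model} column and filenames.
#' @return the directory, invisibly.
#' @export
write_fit_csv <- function(fit, dir, model_name = fit$family) {
  stopifnot(inherits(fit, "sbel_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- cbind(model = model_name, fit$summary)
  utils::write.csv(pt, file.path(dir, paste0(model_name, "_parameters.csv")),
                   row.names = FALSE)
  mt <- data.frame(model = model_name, waic = fit$waic, p_waic = fit$p_waic,
                   lppd = fit$lppd,
                   selected_rho = if (is.null(fit$rho)) NA_real_ else fit$rho)
  utils::write.csv(mt, file.path(dir, paste0(model_name, "_model.csv")),
                   row.names = FALSE)
  utils::write.csv(fit$smoothed,
                   file.path(dir, paste0(model_name, "_smoothed.csv")),
                   row.names = FALSE)
  invisible(dir)
}
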