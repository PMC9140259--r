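test_that("initialisation maximises the empirical likelihood over beta", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 3))
  init <- sbel:::sbel_initialize(sim$data)
  # MELE cannot be worse than the WLS anchor
  at_wls <- log_el_at(sim$data$y, sim$data$X, init$beta_anchor,
                      rep(0, 25), init$sigma2)
  expect_gte(init$log_el0, at_wls$log_el - 1e-8)
  # fallback variance is the constant WLS residual variance
  expect_equal(length(unique(init$sigma2)), 1L)
  expect_gt(init$sigma2[1], 0)
})

test_that("MELE agrees with a two-dimensional grid-search oracle", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 19))
  init <- sbel:::sbel_initialize(sim$data)
  step <- 0.025
  grid0 <- init$beta_anchor[1] + seq(-0.5, 0.5, by = step)
  grid1 <- init$beta_anchor[2] + seq(-0.5, 0.5, by = step)
  best <- -Inf; arg <- c(NA, NA)
  for (b0 in grid0) for (b1 in grid1) {
    s <- log_el_at(sim$data$y, sim$data$X, c(b0, b1), rep(0, 25),
                   init$sigma2)
    if (s$feasible && s$log_el > best) { best <- s$log_el; arg <- c(b0, b1) }
  }
  expect_gte(init$log_el0, best - 1e-6)
  # the log-EL surface is flat near its maximum, so compare by value: the
  # grid point nearest the MELE must attain the grid optimum
  near <- c(grid0[which.min(abs(grid0 - init$beta0[1]))],
            grid1[which.min(abs(grid1 - init$beta0[2]))])
  s_near <- log_el_at(sim$data$y, sim$data$X, near, rep(0, 25), init$sigma2)
  expect_true(s_near$feasible)
  expect_gte(s_near$log_el, best - 0.05)
})

test_that("an exact linear response is rejected with a diagnostic", {
  adj <- make_lattice(3)
  x <- rnorm(9)
  y <- 1 + 2 * x   # exact fit, zero residual variance
  data <- area_dataset(y, cbind(1, x), adjacency = adj)
  expect_error(sbel:::sbel_initialize(data), "exact linear fit")
})

test_that("identical seeds give identical chains and thinning bookkeeping holds", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 3))
  spec <- spatial_prior_spec("ig", sim$data$adjacency)
  cfg <- sampler_config(n_iter = 600, burn_in = 200, thin = 5, n_chains = 2,
                        pilot_length = 200, seed = 77)
  a <- run_sbel(sim$data, spec, config = cfg)
  b <- run_sbel(sim$data, spec, config = cfg)
  expect_identical(a$chains[[1]]$beta, b$chains[[1]]$beta)
  expect_identical(a$chains[[2]]$tau, b$chains[[2]]$tau)
  expect_identical(a$chains[[1]]$loglik, b$chains[[1]]$loglik)
  # distinct chains differ
  expect_false(identical(a$chains[[1]]$beta, a$chains[[2]]$beta))

  # n_iter = burn_in + thin stores exactly one draw per chain
  cfg1 <- sampler_config(n_iter = 205, burn_in = 200, thin = 5, n_chains = 1,
                         pilot_length = 100, seed = 1)
  one <- run_sbel(sim$data, spec, config = cfg1)
  expect_equal(nrow(one$chains[[1]]$beta), 1L)
  expect_equal(length(one$chains[[1]]$tau), 1L)
})

test_that("stored draws satisfy the EL constraint set when re-solved", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 3))
  ch <- run_sbel(sim$data, spatial_prior_spec("leroux", sim$data$adjacency,
                                              rho = 0.5),
                 config = sampler_config(n_iter = 800, burn_in = 300,
                                         thin = 25, n_chains = 1,
                                         pilot_length = 300, seed = 2))
  c1 <- ch$chains[[1]]
  expect_true(all(c1$tau > 0))
  expect_true(all(c1$accept > 0 & c1$accept < 1))
  for (t in seq_along(c1$tau)) {
    sol <- sbel:::.el_eval(sim$data$y, sim$data$X, c1$beta[t, ],
                           c1$theta[t, ], ch$sigma2, "owen")
    expect_true(sol$feasible)
    expect_lt(abs(sum(sol$weights) - 1), 1e-10)
    # stored pointwise log-lik matches the re-solved weights
    expect_equal(c1$loglik[t, ], log(sol$weights), tolerance = 1e-8)
  }
})

test_that("acceptance rates land in a workable band after pilot tuning", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 13))
  ch <- run_sbel(sim$data, spatial_prior_spec("ig", sim$data$adjacency),
                 config = sampler_config(n_iter = 2000, burn_in = 500,
                                         thin = 5, n_chains = 1,
                                         pilot_length = 1000, seed = 4))
  acc <- ch$chains[[1]]$accept
  expect_gt(acc["beta"], 0.05); expect_lt(acc["beta"], 0.6)
  expect_gt(acc["psi"], 0.05); expect_lt(acc["psi"], 0.7)
})

test_that("beta components converge on a small fixture (PSRF < 1.1)", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 3))
  fit <- sbel(sim$data, prior = "ig",
              config = sampler_config(n_iter = 6000, burn_in = 1000,
                                      thin = 5, n_chains = 3,
                                      pilot_length = 1000, seed = 11))
  psrf <- fit$summary$psrf[fit$summary$parameter %in% c("beta0", "beta1")]
  expect_true(all(psrf < 1.1))
})

test_that("prior-only psi sampling recovers the Leroux Gaussian", {
  # EL term disabled, tau fixed at 1: psi draws on the 3-area path graph
  # with rho = 0.5 must reproduce N(0, Dminus^{-1}), and thereby the
  # closed-form full-conditional moments
  p3 <- path_graph3()
  y <- c(0.1, -0.2, 0.3)  # irrelevant under prior-only sampling
  data <- area_dataset(y, matrix(1, 3, 1), adjacency = p3)
  spec <- spatial_prior_spec("leroux", p3, rho = 0.5)
  cfg <- sampler_config(n_iter = 60000, burn_in = 5000, thin = 2,
                        n_chains = 1, pilot_length = 2000, seed = 8,
                        likelihood = "none", fix = c("beta", "tau"),
                        init = list(tau = 1, beta = c(0)))
  ch <- run_sbel(data, spec, config = cfg)
  draws <- ch$chains[[1]]$theta
  S_emp <- cov(draws)
  S_true <- solve(leroux_Dminus(intrinsic_R(p3), 0.5))
  expect_lt(max(abs(S_emp - S_true)), 0.12)
  expect_lt(max(abs(colMeans(draws))), 0.1)

  # conditional moments of area 2 via regression on its neighbours
  cm <- conditional_moments_leroux(c(1, 0, -1), 2, 0.5, 1, p3)
  fitlm <- lm(draws[, 2] ~ draws[, 1] + draws[, 3])
  w_true <- 0.5 / (2 * 0.5 + 0.5)   # rho / (n_i rho + 1 - rho)
  expect_equal(unname(coef(fitlm)[2]), w_true, tolerance = 0.06)
  expect_equal(unname(coef(fitlm)[3]), w_true, tolerance = 0.06)
  expect_equal(summary(fitlm)$sigma^2, cm$variance, tolerance = 0.08)
})

test_that("prior-only tau update reproduces its conjugate Gamma conditional", {
  # with psi and beta held fixed and the EL disabled, the tau conditional
  # is Gamma(alpha1 + 2 + k/2 + (p+1)/2, alpha2 + qf/2 + g ||db||^2 / 2)
  # under the as-printed tau kernel with the power factors included
  p3 <- path_graph3()
  y <- c(0.4, -0.1, 0.2)
  data <- area_dataset(y, matrix(1, 3, 1), adjacency = p3)
  spec <- spatial_prior_spec("leroux", p3, rho = 0.5)
  hp <- hyperparams()
  psi_fix <- c(0.8, -0.3, 0.5)
  beta_fix <- 0.9
  cfg <- sampler_config(n_iter = 60000, burn_in = 5000, thin = 2,
                        n_chains = 1, pilot_length = 2000, seed = 15,
                        likelihood = "none", fix = c("psi", "beta"),
                        init = list(psi = psi_fix, beta = beta_fix,
                                    tau = 1))
  ch <- run_sbel(data, spec, config = cfg, hp = hp)
  tau <- ch$chains[[1]]$tau

  qf <- drop(crossprod(psi_fix, leroux_Dminus(intrinsic_R(p3), 0.5) %*%
                         psi_fix))
  db <- beta_fix - ch$beta_anchor
  shape <- hp$alpha1 + 2 + spec$k / 2 + 1 / 2
  rate <- hp$alpha2 + qf / 2 + hp$g * sum(db^2) / 2

  # batch-means standard errors to respect chain autocorrelation
  bm_se <- function(x, nb = 50) {
    bs <- tapply(x, rep(seq_len(nb), each = length(x) / nb), mean)
    sd(bs) / sqrt(nb)
  }
  expect_lt(abs(mean(tau) - shape / rate), 3 * bm_se(tau))
  expect_equal(var(tau), shape / rate^2, tolerance = 0.1)
})

test_that("Leroux endpoints reproduce the IG and intrinsic-CAR fits exactly", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 6))
  cfg <- sampler_config(n_iter = 800, burn_in = 300, thin = 5, n_chains = 1,
                        pilot_length = 300, seed = 21)
  ig <- run_sbel(sim$data, spatial_prior_spec("ig", sim$data$adjacency),
                 config = cfg)
  le0 <- run_sbel(sim$data, spatial_prior_spec("leroux", sim$data$adjacency,
                                               rho = 0),
                  config = cfg)
  expect_identical(ig$chains[[1]]$beta, le0$chains[[1]]$beta)
  expect_identical(ig$chains[[1]]$tau, le0$chains[[1]]$tau)

  bym <- run_sbel(sim$data, spatial_prior_spec("bym", sim$data$adjacency),
                  config = cfg)
  le1 <- run_sbel(sim$data, spatial_prior_spec("leroux", sim$data$adjacency,
                                               rho = 1),
                  config = cfg)
  expect_identical(bym$chains[[1]]$beta, le1$chains[[1]]$beta)
})

test_that("rho grid search returns the full table and sensible selections", {
  sim <- generate_scenario(scenario_spec(25, "high", seed = 301))
  cfg <- sampler_config(n_iter = 1200, burn_in = 400, thin = 5, n_chains = 1,
                        pilot_length = 400, seed = 301)
  single <- grid_search_rho(sim$data, config = cfg, rho_grid = 0.4)
  expect_equal(single$best_rho, 0.4)
  expect_equal(nrow(single$table), 1L)

  gs <- grid_search_rho(sim$data, config = cfg, rho_grid = c(0, 0.5, 1))
  expect_equal(nrow(gs$table), 3L)
  expect_true(all(is.finite(gs$table$waic)))
  expect_equal(gs$best_fit$waic, min(gs$table$waic))
})

test_that("strong spatial structure drives the selected rho upward", {
  sel <- numeric(6)
  for (r in 1:6) {
    sim <- generate_scenario(scenario_spec(25, "high", seed = 300 + r))
    cfg <- sampler_config(n_iter = 2500, burn_in = 500, thin = 5,
                          n_chains = 1, pilot_length = 600, seed = 300 + r)
    gs <- grid_search_rho(sim$data, config = cfg,
                          rho_grid = c(0.1, 0.5, 0.9))
    sel[r] <- gs$best_rho
  }
  expect_gt(mean(sel >= 0.5), 0.5)
})

test_that("the EL posterior matches a brute-force importance-sampling oracle", {
  # 4-area path graph, beta and tau fixed: psi draws from the EL-gated MH
  # (coherent current-beta mode) must match importance sampling from the
  # Leroux prior reweighted by the EL likelihood
  adj <- build_adjacency(t(cbind(c(1, 2), c(2, 3), c(3, 4))), n_areas = 4)
  y <- c(1.2, -0.9, 0.6, -0.8)
  sig2 <- rep(0.5, 4)
  data <- area_dataset(y, matrix(1, 4, 1), adjacency = adj, sigma2 = sig2)
  spec <- spatial_prior_spec("leroux", adj, rho = 0.5)

  cfg <- sampler_config(n_iter = 60000, burn_in = 6000, thin = 5,
                        n_chains = 1, pilot_length = 2000, seed = 3,
                        fix = c("beta", "tau"),
                        psi_moment_beta = "current",
                        init = list(beta = 0, tau = 1))
  ch <- suppressWarnings(run_sbel(data, spec, config = cfg))
  th <- ch$chains[[1]]$theta

  set.seed(99)
  Q <- leroux_Dminus(intrinsic_R(adj), 0.5)
  U <- chol(solve(Q))
  M <- 120000
  PS <- matrix(rnorm(M * 4), M, 4) %*% U
  logw <- rep(-Inf, M)
  for (m in 1:M) {
    s <- solve_el(build_moments(y, PS[m, ], sig2))
    logw[m] <- s$log_el
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  expect_gt(1 / sum(w^2), 5000)   # effective sample size sanity
  is_mean <- colSums(PS * w)
  is_var <- colSums(PS^2 * w) - is_mean^2

  expect_lt(max(abs(colMeans(th) - is_mean)), 0.06)
  expect_lt(max(abs(apply(th, 2, var) - is_var)), 0.08)
})
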