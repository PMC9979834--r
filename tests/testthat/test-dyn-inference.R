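# Small shared synthetic experiment and fit for the inference tests.
small_dyn <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- generate_dynamics_experiment(seed = 77,
                                          design = design_spec(n_blocks = 2))
      dd <- dynamics_dataset(sim$table)
      fit <- fit_dynamics(dd, "overgrowth", chains = 2, iter = 3000,
                          warmup = 1500, thin = 3, seed = 5)
      memo <<- list(sim = sim, dd = dd, fit = fit)
    }
    memo
  }
})

test_that("pointwise log-likelihood matches an independent RK4 + dmultinom oracle", {
  sim <- generate_dynamics_experiment(seed = 55,
                                      design = design_spec(n_blocks = 1))
  dd <- dynamics_dataset(sim$table)
  p1 <- dyn_params("overgrowth", a0 = 0.1, a1 = 0.9, a2 = -0.2, delta = 1,
                   b0 = 0.01, b1 = 0.5, b2 = -0.2, extra = 0.3,
                   r_A = 0.4, r_O = 0.5)
  p3 <- dyn_params("overgrowth", a0 = 0.05, a1 = 0.5, a2 = -0.3, delta = 1,
                   b0 = 0.02, b1 = 0.8, b2 = -0.15, extra = 1,
                   r_A = 0.4, r_O = 0.5)
  ll <- dyn_log_lik(list(p1, p3), dd)
  expect_equal(length(ll), nrow(dd$obs))
  expect_true(all(is.finite(ll)))
  pars <- list(`1` = p1, `3` = p3)
  set.seed(1)
  for (i in sample(seq_len(nrow(dd$obs)), 12)) {
    o <- dd$obs[i, ]
    sched <- dd$schedules[[o$panel]]
    oracle_tr <- rk4_solve(pars[[as.character(o$depth)]], sched,
                           seq_len(max(dd$obs$week)), h = 2e-3)
    st <- oracle_tr[oracle_tr$time == o$week, ]
    u1 <- if (o$phase == "post") st$x_post else st$x_pre
    u2 <- if (o$phase == "post") st$y1_post else st$y1_pre
    p <- pmax(c(u2, 1 - u1 - u2, u1), 1e-9); p <- p / sum(p)
    oracle <- dmultinom(c(o$aurita, o$bare, o$competitors), prob = p,
                        log = TRUE)
    expect_equal(ll[i], oracle, tolerance = 1e-5)
  }
})

test_that("the probability floor keeps early-week zero states finite", {
  meta <- data.frame(panel = "q1", block = 1, depth = 1, treatment = "C",
                     mistaken_week = NA_integer_)
  obs <- data.frame(panel = "q1", week = 1, phase = "pre", aurita = 0,
                    bare = 90, competitors = 10, n = 100, depth = 1,
                    treatment = "C", block = 1, applied = FALSE)
  dd <- make_dynamics_data(obs, list(q1 = data.frame(week = integer(0),
                                                     action = character(0))),
                           meta)
  # polyp settlement essentially zero: predicted polyp share underflows
  p <- dyn_params("basic", a0 = 0.1, a1 = 0.5, a2 = -0.2, delta = 1,
                  b0 = 1e-30, b1 = 0.1, b2 = -0.2)
  ll <- dyn_log_lik(list(p), dd)
  expect_true(is.finite(ll))
  # doubling the counts changes the log-pmf by the combinatorial constant
  # plus twice the cross-entropy term
  obs2 <- obs; obs2$aurita <- 0; obs2$bare <- 180; obs2$competitors <- 20
  obs2$n <- 200
  dd2 <- make_dynamics_data(obs2, dd$schedules, meta)
  ll2 <- dyn_log_lik(list(p), dd2)
  tr <- solve_dynamics(p, times = 1)
  pr <- pmax(c(tr$y1, 1 - tr$x - tr$y1, tr$x), 1e-9); pr <- pr / sum(pr)
  const1 <- lgamma(101) - lgamma(91) - lgamma(11)
  const2 <- lgamma(201) - lgamma(181) - lgamma(21)
  xent <- sum(c(0, 90, 10) * log(pr))
  expect_equal(ll2 - ll, (const2 - const1) + xent, tolerance = 1e-6)
})

test_that("control panels contribute one record per week", {
  m <- small_dyn()
  ctrl <- m$dd$obs[m$dd$obs$treatment == "C", ]
  normal_ctrl <- ctrl[!ctrl$panel %in%
                        m$sim$table$meta$panel[!is.na(m$sim$table$meta$mistaken_week)], ]
  expect_true(all(table(normal_ctrl$panel, normal_ctrl$week) == 1))
  expect_true(all(normal_ctrl$phase == "pre"))
})

test_that("same-seed fits are identical and diagnostics are reported", {
  sim <- generate_dynamics_experiment(seed = 2,
                                      design = design_spec(n_blocks = 1))
  dd <- dynamics_dataset(sim$table)
  f1 <- fit_dynamics(dd, "basic", chains = 1, iter = 300, warmup = 150,
                     thin = 1, seed = 9)
  f2 <- fit_dynamics(dd, "basic", chains = 1, iter = 300, warmup = 150,
                     thin = 1, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_equal(ncol(f1$draws), 2 * 6 + 2)
  expect_true(all(f1$draws[, "a2_1m"] < 0) && all(f1$draws[, "r_O"] < 1))
})

test_that("with no data the posterior reproduces the prior", {
  meta <- data.frame(panel = c("q1", "q2"), block = 1, depth = c(1, 3),
                     treatment = "C", mistaken_week = NA_integer_)
  obs <- data.frame(panel = character(0), week = integer(0),
                    phase = character(0), aurita = integer(0),
                    bare = integer(0), competitors = integer(0),
                    n = integer(0), depth = numeric(0),
                    treatment = character(0), block = integer(0),
                    applied = logical(0))
  scheds <- list(q1 = data.frame(week = integer(0), action = character(0)),
                 q2 = data.frame(week = integer(0), action = character(0)))
  dd <- make_dynamics_data(obs, scheds, meta)
  # prior-only target (no likelihood): cheap iterations, so run long enough
  # for the random walk to traverse the long left tails on the log scale
  fit <- fit_dynamics(dd, "basic", chains = 2, iter = 30000, warmup = 15000,
                      thin = 10, seed = 30)
  # removal fractions: uniform(0, 1)
  expect_equal(mean(fit$draws[, "r_A"]), 0.5, tolerance = 0.1)
  expect_gt(quantile(fit$draws[, "r_O"], 0.9), 0.72)
  # rate magnitudes: half-normal(1), mean sqrt(2/pi) = 0.798
  expect_equal(mean(fit$draws[, "a0_1m"]), sqrt(2 / pi), tolerance = 0.15)
  expect_equal(mean(abs(fit$draws[, "b2_3m"])), sqrt(2 / pi), tolerance = 0.15)
})

test_that("PSIS-LOO comparison of identical models gives zero difference", {
  m <- small_dyn()
  cmp <- psis_loo_compare(list(a = m$fit, b = m$fit))
  expect_equal(cmp$delta_elpd, c(0, 0))
  expect_equal(cmp$se_diff, c(0, 0))
  lo <- psis_loo(m$fit)
  expect_equal(lo$elpd, sum(lo$elpd_i))
  expect_lt(lo$elpd, 0)
})

test_that("pointwise log-likelihood sums to the sampler's total", {
  m <- small_dyn()
  s <- nrow(m$fit$draws)
  k <- 7
  v <- m$fit$draws[s, ]
  pl <- lapply(1:2, function(d) {
    dyn_params("overgrowth", a0 = v[(d - 1) * k + 1], a1 = v[(d - 1) * k + 2],
               a2 = v[(d - 1) * k + 3], delta = 1, b0 = v[(d - 1) * k + 4],
               b1 = v[(d - 1) * k + 5], b2 = v[(d - 1) * k + 6],
               extra = v[(d - 1) * k + 7], r_A = v["r_A"], r_O = v["r_O"])
  })
  ll <- dyn_log_lik(pl, m$dd)
  expect_equal(sum(ll), sum(m$fit$ll_pointwise[s, ]), tolerance = 1e-8)
})

test_that("posterior predictive simulation respects the design", {
  m <- small_dyn()
  sims <- posterior_predictive(m$fit, ndraws = 3, seed = 4)
  expect_length(sims, 3)
  expect_equal(nrow(sims[[1]]), nrow(m$dd$obs))
  expect_true(all(sims[[1]]$aurita + sims[[1]]$bare + sims[[1]]$competitors
                  == 100))
  # empty design gives an empty table
  empty <- m$fit
  empty$data$obs <- m$dd$obs[0, ]
  empty$setup$obs_mat <- m$fit$setup$obs_mat[0, , drop = FALSE]
  sims0 <- posterior_predictive(empty, ndraws = 2, seed = 1)
  expect_equal(nrow(sims0[[1]]), 0)
})

test_that("typical-panel trajectories show event sawtooth and smooth controls", {
  m <- small_dyn()
  tp <- typical_panel_trajectories(m$fit, times = seq(0.5, 8, 0.5),
                                   ndraws = 40, seed = 2)
  ctrl <- tp[tp$treatment == "C" & tp$depth == 1, ]
  expect_true(all(ctrl$phase == "pre"))
  # O treatment: competitor cover drops by about (1 - r_O) at applications
  o3 <- tp[tp$treatment == "O" & tp$depth == 3, ]
  pre <- o3[o3$time == 4 & o3$phase == "pre", "competitors"]
  post <- o3[o3$time == 4 & o3$phase == "post", "competitors"]
  r_O_hat <- mean(m$fit$draws[, "r_O"])
  expect_equal(post / pre, 1 - r_O_hat, tolerance = 0.05)
})

test_that("removal diagnostics pair pre/post proportions with model slopes", {
  m <- small_dyn()
  rd <- removal_diagnostics(m$dd, m$fit)
  oo <- rd$points[rd$points$action == "O", ]
  expect_gt(nrow(oo), 10)
  # generating r_O = 0.5: regression through the origin has slope near 0.5
  slope <- sum(oo$pre * oo$post) / sum(oo$pre^2)
  expect_equal(slope, 0.5, tolerance = 0.06)
  # competitors untouched by A applications: slope near 1
  by <- rd$points[rd$points$group == "competitors_untargeted", ]
  slope1 <- sum(by$pre * by$post) / sum(by$pre^2)
  expect_equal(slope1, 1, tolerance = 0.06)
  expect_equal(rd$slopes$slope[rd$slopes$group == "competitors"],
               1 - mean(m$fit$draws[, "r_O"]))
  # no applications: empty output
  ctrl_obs <- m$dd$obs[m$dd$obs$treatment == "C" & m$dd$obs$phase == "pre", ]
  dd0 <- make_dynamics_data(ctrl_obs, m$dd$schedules, m$dd$meta)
  dd0$schedules <- lapply(dd0$schedules, function(s) s[0, ])
  rd0 <- removal_diagnostics(dd0, m$fit)
  expect_equal(nrow(rd0$points), 0)
})

test_that("PSIS tail smoothing matches the generalized-Pareto tail", {
  set.seed(123)
  # heavy-tailed ratios: khat should be estimated and weights bounded
  lr <- rt(4000, df = 3)
  sm <- polypcomp:::psis_smooth(lr)
  expect_true(is.finite(sm$khat))
  expect_lte(max(sm$log_weights), 0)
  # light tails: smoothing leaves order intact
  lr2 <- rnorm(4000)
  sm2 <- polypcomp:::psis_smooth(lr2)
  expect_lt(sm2$khat, 0.5)
})
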