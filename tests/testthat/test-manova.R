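# A small shared fit keeps the MANOVA tests fast: 6 blocks, short chains.
small_manova <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      g <- generate_manova_dataset(seed = 42,
                                   design = design_spec(n_blocks = 6))
      fit <<- fit_manova(g$data, "no_interaction", chains = 2, iter = 1500,
                         warmup = 700, thin = 1, seed = 7)
      attr(fit, "truth") <<- g$truth
    }
    fit
  }
})

test_that("log-likelihood matches a brute-force multinomial oracle", {
  Y <- matrix(rep(20, 5), 1)
  colnames(Y) <- c("aurita_panel", "bare", "botrylloides", "bugula", "molgula")
  data <- structure(list(counts = Y, n = 100,
                         design = data.frame(panel = "p", block = 1, depth = 1,
                                             treatment = "C"),
                         parts = colnames(Y), week = 8),
                    class = "manova_data")
  ll <- manova_log_lik(list(mu = rep(0, 4)), data)
  oracle <- lgamma(101) - 5 * lgamma(21) + 100 * log(0.2)
  expect_equal(ll, oracle)
  # and for a non-uniform state the oracle still agrees
  mu <- c(0.4, -0.3, 0.2, 0.1)
  p <- ilr_inv(mu, default_basis())
  y <- c(30, 25, 20, 15, 10)
  data$counts[1, ] <- y; data$n <- 100
  oracle <- lgamma(101) - sum(lgamma(y + 1)) + sum(y * log(p))
  expect_equal(manova_log_lik(list(mu = mu), data), oracle)
  # empty observation contributes zero
  data$counts[1, ] <- 0; data$n <- 0
  expect_equal(manova_log_lik(list(mu = mu), data), 0)
  # non-finite predictors are rejected
  data$counts[1, ] <- y; data$n <- 100
  expect_error(manova_log_lik(list(mu = c(Inf, 0, 0, 0)), data), "finite")
})

test_that("sum-to-zero coding leaves no translation invariance", {
  g <- generate_manova_dataset(seed = 3, design = design_spec(n_blocks = 3))
  data <- g$data
  base <- list(mu = g$truth$mu, alpha = g$truth$alpha, beta = g$truth$beta)
  ll0 <- manova_log_lik(base, data)
  shifted <- base
  shifted$beta <- sweep(base$beta, 2, c(0.3, 0, 0, 0), `+`)
  expect_false(isTRUE(all.equal(manova_log_lik(shifted, data), ll0)))
})

test_that("same seed reproduces identical draws", {
  g <- generate_manova_dataset(seed = 10, design = design_spec(n_blocks = 3))
  f1 <- fit_manova(g$data, "no_depth", chains = 1, iter = 200, warmup = 100,
                   seed = 5)
  f2 <- fit_manova(g$data, "no_depth", chains = 1, iter = 200, warmup = 100,
                   seed = 5)
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$draws$Sigma, f2$draws$Sigma)
})

test_that("posterior recovers generating fixed effects", {
  fit <- small_manova()
  truth <- attr(fit, "truth")
  # treatment effect on the first two ilr coordinates (the strongly
  # informed aurita/bare vs competitor balances)
  Ct <- rbind(diag(2), c(-1, -1))
  for (cc in 1:2) {
    bO <- fit$draws$fb[, c(2 * cc - 1, 2 * cc)] %*% Ct[3, ]
    qs <- quantile(bO, c(0.01, 0.99))
    expect_gt(truth$beta["O", cc], qs[1])
    expect_lt(truth$beta["O", cc], qs[2])
  }
  expect_lt(max(abs(coef(fit)$mu - truth$mu)), 0.5)
})

test_that("symmetric data concentrate treatment effects near zero", {
  # identical counts on every panel: no treatment signal
  Y <- matrix(rep(c(10, 30, 20, 20, 20), each = 18), 18, 5)
  colnames(Y) <- c("aurita_panel", "bare", "botrylloides", "bugula", "molgula")
  meta <- .design_meta_for_test(3)
  data <- structure(list(counts = Y, n = rowSums(Y), design = meta,
                         parts = colnames(Y), week = 8),
                    class = "manova_data")
  fit <- fit_manova(data, "no_interaction", chains = 2, iter = 1000,
                    warmup = 500, seed = 2)
  Ct <- rbind(diag(2), c(-1, -1))
  for (k in 1:3) {
    bk <- sapply(1:4, function(cc)
      mean(fit$draws$fb[, c(2 * cc - 1, 2 * cc)] %*% Ct[k, ]))
    expect_lt(max(abs(bk)), 0.25)
  }
})

test_that("treatment compositions obey the perturbation identity without interaction", {
  fit <- small_manova()
  d <- fit$draws
  s <- c(1, 50, 200)
  compJK <- treatment_composition(fit, depth = 1, treatment = "O")[s, ]
  B <- fit$basis
  for (i in seq_along(s)) {
    mu_c <- ilr_inv(d$mu[s[i], ], B)
    a_c <- ilr_inv(d$fa[s[i], ], B)
    b_c <- ilr_inv(c(-d$fb[s[i], 1] - d$fb[s[i], 2],
                     -d$fb[s[i], 3] - d$fb[s[i], 4],
                     -d$fb[s[i], 5] - d$fb[s[i], 6],
                     -d$fb[s[i], 7] - d$fb[s[i], 8]), B)
    expect_equal(unname(compJK[i, ]),
                 unname(perturb(perturb(mu_c, a_c), b_c)), tolerance = 1e-10)
  }
  # all-zero draws give the uniform composition
  fake <- fit
  fake$draws$mu[1, ] <- 0; fake$draws$fa[1, ] <- 0; fake$draws$fb[1, ] <- 0
  expect_equal(unname(treatment_composition(fake, 1, "C")[1, ]), rep(0.2, 5))
})

test_that("logit contrasts vanish for identical treatments and match shares", {
  fit <- small_manova()
  lc <- logit_contrast(fit, "aurita", c("C", "C"), depth = 1)
  expect_true(all(lc$draws == 0))
  lcO <- logit_contrast(fit, "competitors", c("O", "C"), depth = 3)
  compO <- treatment_composition(fit, 3, "O")
  compC <- treatment_composition(fit, 3, "C")
  manual <- qlogis(rowSums(compO[, 3:5])) - qlogis(rowSums(compC[, 3:5]))
  expect_equal(lcO$draws, manual)
  expect_error(logit_contrast(fit, "aurita", c("O", "X"), 1), "valid pair")
})

test_that("the ternary decomposition is lossless under the default basis", {
  fit <- small_manova()
  et <- effect_ternaries(fit, depth = 1, treatment = "A")
  comp <- treatment_composition(fit, 1, "A")
  for (i in c(1, 11)) {
    amal <- et$amalgam[i, ]; sub <- et$subcomp[i, ]
    lam <- amal[3] / exp(mean(log(sub)))
    rec <- close_comp(c(amal[1], amal[2], lam * sub))
    expect_equal(unname(rec), unname(comp[i, ]), tolerance = 1e-10)
  }
  # uniform input maps to uniform ternaries
  fake <- fit
  fake$draws$mu[1, ] <- 0; fake$draws$fa[1, ] <- 0; fake$draws$fb[1, ] <- 0
  et0 <- effect_ternaries(fake, 1, "C")
  expect_equal(unname(et0$amalgam[1, ]), rep(1 / 3, 3))
  expect_equal(unname(et0$subcomp[1, ]), rep(1 / 3, 3))
})

test_that("treatment compositions are invariant to the orthonormal basis", {
  fit <- small_manova()
  B1 <- unclass(fit$basis); B2 <- unclass(alt_basis())
  R <- B2 %*% t(B1)   # rotation between coordinate systems
  rot <- fit
  rot$basis <- alt_basis()
  rot$draws$mu <- fit$draws$mu %*% t(R)
  rot$draws$fa <- fit$draws$fa %*% t(R)
  # fb columns are (coord1: free1, free2, coord2: ...): rebuild per free row
  fb1 <- fit$draws$fb[, c(1, 3, 5, 7)] %*% t(R)
  fb2 <- fit$draws$fb[, c(2, 4, 6, 8)] %*% t(R)
  rot$draws$fb <- cbind(fb1[, 1], fb2[, 1], fb1[, 2], fb2[, 2],
                        fb1[, 3], fb2[, 3], fb1[, 4], fb2[, 4])
  c1 <- treatment_composition(fit, 1, "O")
  c2 <- treatment_composition(rot, 1, "O")
  expect_lt(max(abs(c1 - c2)), 1e-8)
  l1 <- logit_contrast(fit, "aurita", c("O", "C"), 1)
  l2 <- logit_contrast(rot, "aurita", c("O", "C"), 1)
  expect_lt(max(abs(l1$draws - l2$draws)), 1e-8)
})

test_that("HPD regions contain the right mass and scale with the sample", {
  set.seed(99)
  Zs <- matrix(rnorm(20000), ncol = 2) * 0.4
  B3 <- ternary_basis()
  samples <- ilr_inv(Zs, B3)
  hp <- hpd_region_2d(samples, 0.95)
  expect_false(hp$degenerate)
  expect_gt(hp$contained, 0.93); expect_lt(hp$contained, 0.97)
  # near-circular boundary in ilr coordinates for isotropic samples
  b <- hp$boundary[[1]]
  rad <- sqrt(b$ilr1^2 + b$ilr2^2)
  expect_lt(diff(range(rad)) / mean(rad), 0.35)
  # doubling the spread doubles the boundary extent
  hp2 <- hpd_region_2d(ilr_inv(Zs * 2, B3), 0.95)
  r2 <- sqrt(hp2$boundary[[1]]$ilr1^2 + hp2$boundary[[1]]$ilr2^2)
  expect_equal(mean(r2) / mean(rad), 2, tolerance = 0.15)
  # degenerate samples flagged
  same <- matrix(rep(c(0.2, 0.3, 0.5), each = 1200), ncol = 3)
  expect_true(hpd_region_2d(same)$degenerate)
  expect_error(hpd_region_2d(samples[1:10, ]), "1000")
})

test_that("LOCO returns zero difference for identical variants and sane errors", {
  g <- generate_manova_dataset(seed = 12, design = design_spec(n_blocks = 3))
  lc <- suppressWarnings(
    loco_cv(g$data, c("no_depth", "no_depth"), seed = 4, chains = 1,
            iter = 400, warmup = 200, mc_draws = 50, mc_reps = 30))
  expect_equal(lc$delta_elpd, c(0, 0), tolerance = 1e-9)
  expect_equal(lc$se_diff, c(0, 0), tolerance = 1e-9)
  two <- .drop_block_for_test(g$data, 3)
  expect_error(loco_cv(two, "no_depth"), "3 blocks")
})
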