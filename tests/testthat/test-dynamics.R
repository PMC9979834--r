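test_that("right-hand side limits match the model structure", {
  set.seed(2)
  p <- random_dyn_params("basic")
  # empty panel: only settlement acts
  expect_equal(dyn_rhs(p, 0, 0), c(dx = p$a0, dy1 = p$b0))
  # full occupancy by competitors: only their death acts
  expect_equal(dyn_rhs(p, 1, 0), c(dx = p$a2, dy1 = 0))
  expect_lt(dyn_rhs(p, 1, 0)[1], 0)
})

test_that("every non-basic variant with its parameter at zero reproduces the basic model", {
  set.seed(5)
  for (i in 1:25) {
    base <- random_dyn_params("basic")
    st <- c(runif(1, 0, 0.6), runif(1, 0, 0.3))
    r0 <- dyn_rhs(base, st[1], st[2])
    for (v in c("settlement_facilitation", "growth_facilitation",
                "overgrowth", "protection")) {
      pv <- base; pv$variant <- v; pv$extra <- 0
      class(pv) <- "dyn_params"
      expect_identical(dyn_rhs(pv, st[1], st[2]), r0)
    }
  }
})

test_that("parameter validation enforces sign constraints", {
  expect_error(dyn_params("basic", a0 = -0.1, a1 = 1, a2 = -0.1, b0 = 0.1,
                          b1 = 1, b2 = -0.1), "positive")
  expect_error(dyn_params("basic", a0 = 0.1, a1 = 1, a2 = 0.1, b0 = 0.1,
                          b1 = 1, b2 = -0.1), "negative")
  expect_error(dyn_params("basic", a0 = 0.1, a1 = 1, a2 = -0.1, b0 = 0.1,
                          b1 = 1, b2 = -0.1, r_A = 1.2), "removal fractions")
})

test_that("solver matches closed-form exponential decay", {
  p <- dyn_params("basic", a0 = 1e-300, a1 = 1e-300, a2 = -0.37, delta = 1,
                  b0 = 1e-300, b1 = 1e-300, b2 = -0.2)
  tr <- solve_dynamics(p, times = c(0.5, 1, 2, 5), init = c(0.8, 0.1))
  expect_equal(tr$x, 0.8 * exp(-0.37 * tr$time), tolerance = 1e-6)
  expect_equal(tr$y1, 0.1 * exp(-0.2 * tr$time), tolerance = 1e-6)
})

test_that("removal events reduce the targeted state by the removal fraction", {
  set.seed(9)
  p <- random_dyn_params("basic", r_O = 0.5, r_A = 0.3)
  sched <- data.frame(week = 3L, action = "O")
  tr <- solve_dynamics(p, sched, times = 1:5)
  pre <- tr[tr$time == 3 & tr$phase == "pre", ]
  post <- tr[tr$time == 3 & tr$phase == "post", ]
  expect_equal(post$x, 0.5 * pre$x)
  expect_equal(post$y1, pre$y1)
  schedA <- data.frame(week = 2L, action = "A")
  trA <- solve_dynamics(p, schedA, times = 1:3)
  expect_equal(trA$y1[trA$time == 2 & trA$phase == "post"],
               0.7 * trA$y1[trA$time == 2 & trA$phase == "pre"])
})

test_that("adaptive solver agrees with an independent fixed-step RK4 oracle", {
  set.seed(14)
  for (v in c("basic", "overgrowth", "protection")) {
    p <- random_dyn_params(v)
    sched <- data.frame(week = c(2L, 4L), action = c("A", "O"))
    tr <- solve_dynamics(p, sched, times = 1:5)
    oracle <- rk4_solve(p, sched, 1:5)
    pre <- tr[tr$phase == "pre", ]
    expect_equal(pre$x, oracle$x_pre, tolerance = 1e-6)
    expect_equal(pre$y1, oracle$y1_pre, tolerance = 1e-6)
  }
})

test_that("trajectories are invariant under time-unit rescaling", {
  set.seed(17)
  p <- random_dyn_params("overgrowth")
  c_fac <- 3.5
  ps <- p
  for (nm in c("a0", "a1", "a2", "b0", "b1", "b2", "extra"))
    ps[[nm]] <- p[[nm]] / c_fac
  class(ps) <- "dyn_params"
  tr <- solve_dynamics(p, times = c(1, 2, 4))
  trs <- solve_dynamics(ps, times = c(1, 2, 4) * c_fac)
  expect_equal(tr$x, trs$x, tolerance = 1e-7)
  expect_equal(tr$y1, trs$y1, tolerance = 1e-7)
})

test_that("analytic community matrix matches finite differences with the paper's sign pattern", {
  set.seed(23)
  for (i in 1:50) {
    v <- sample(c("basic", "settlement_facilitation", "growth_facilitation",
                  "overgrowth", "protection"), 1)
    p <- random_dyn_params(v)
    u <- c(runif(1, 0.05, 0.6), runif(1, 0.05, 0.3))
    if (sum(u) > 0.95) u <- u * 0.9 / sum(u)
    M <- community_matrix(p, u[1], u[2] / p$delta)
    # central finite differences of the proportional rates in (u1, u2)
    g <- function(u1, u2) {
      r <- dyn_rhs(p, u1, u2 / p$delta)
      c(r[1] / u1, p$delta * r[2] / u2)
    }
    h <- 1e-6
    FD <- cbind((g(u[1] + h, u[2]) - g(u[1] - h, u[2])) / (2 * h),
                (g(u[1], u[2] + h) - g(u[1], u[2] - h)) / (2 * h))
    expect_equal(unname(M), unname(FD), tolerance = 1e-6)
    if (v == "basic") expect_true(all(M < 0))
  }
  # boundary state rejected
  p <- random_dyn_params("basic")
  expect_error(community_matrix(p, 0, 0.1), "interior")
})

test_that("overgrowth can turn the effect of polyps on competitors positive", {
  p <- dyn_params("overgrowth", a0 = 0.05, a1 = 0.3, a2 = -0.2, delta = 1,
                  b0 = 0.02, b1 = 0.5, b2 = -0.2, extra = 2)
  M <- community_matrix(p, 0.3, 0.25)
  expect_gt(M[1, 2], 0)
  # entry (2,1) becomes more negative: overgrowth hurts polyps
  pb <- p; pb$variant <- "basic"; pb$extra <- 0; class(pb) <- "dyn_params"
  expect_lt(M[2, 1], community_matrix(pb, 0.3, 0.25)[2, 1])
})

test_that("effect field is negative everywhere for the basic model and continuous", {
  set.seed(29)
  p <- random_dyn_params("basic")
  fld <- polyp_effect_field(p, resolution = 25)
  expect_true(all(is.finite(fld$effect)))
  expect_true(all(fld$effect < 0))
  expect_true(all(fld$u1 + fld$u2 <= 1 - 1e-3 + 1e-12))
  # Lipschitz spot-check along u2 at fixed u1
  sub <- fld[abs(fld$u1 - fld$u1[100]) < 1e-12, ]
  sub <- sub[order(sub$u2), ]
  d <- diff(sub$effect) / diff(sub$u2)
  expect_lt(max(abs(d)), 1e3)
})

test_that("settlement facilitation is positive only at low competitor, high free-space states", {
  p <- dyn_params("settlement_facilitation", a0 = 0.3, a1 = 1.2, a2 = -0.2,
                  delta = 1, b0 = 0.02, b1 = 0.5, b2 = -0.2, extra = 0.5)
  fld <- polyp_effect_field(p, resolution = 40)
  pos <- fld[fld$effect > 0, ]
  expect_gt(nrow(pos), 0)
  neg <- fld[fld$effect < 0, ]
  expect_lt(max(pos$u1), median(neg$u1))   # low competitor share
  expect_gt(min(pos$free), median(neg$free))  # high bare-panel share
})
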