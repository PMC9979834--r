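# Shared fixtures built in code: a tiny two-panel experiment table and an
# independent fixed-step RK4 integrator used as an oracle for the adaptive
# solver and the C++ likelihood.

tiny_counts_row <- function(panel, week, phase, named) {
  cats <- panel_categories()
  counts <- setNames(integer(length(cats)), cats)
  counts[names(named)] <- named
  data.frame(panel = panel, week = week, phase = phase,
             category = cats, count = as.integer(counts))
}

# two panels (one C, one A at the other depth), two weeks, 100 points each
tiny_experiment <- function() {
  meta <- data.frame(panel = c("p1", "p2"), block = c(1, 1),
                     depth = c(1, 3), treatment = c("C", "A"),
                     mistaken_week = NA_integer_)
  w1 <- c(aurita_panel = 2, bare = 80, botrylloides = 8, bugula = 6,
          molgula = 4)
  w2 <- c(aurita_panel = 5, bare = 55, botrylloides = 15, bugula = 13,
          molgula = 10, other = 2)
  w2_post <- c(aurita_panel = 2, bare = 58, botrylloides = 15, bugula = 13,
               molgula = 10, other = 2)
  counts <- rbind(
    tiny_counts_row("p1", 1, "pre", w1), tiny_counts_row("p1", 1, "post", w1),
    tiny_counts_row("p1", 2, "pre", w2), tiny_counts_row("p1", 2, "post", w2),
    tiny_counts_row("p2", 1, "pre", w1), tiny_counts_row("p2", 1, "post", w1),
    tiny_counts_row("p2", 2, "pre", w2),
    tiny_counts_row("p2", 2, "post", w2_post))
  env <- data.frame(week = rep(1:2, 2), depth = rep(c(1, 3), each = 2),
                    dissolved_oxygen = c(8, 8.2, 7.4, 7.6),
                    temperature = c(19, 18.5, 18.8, 18.2),
                    salinity = c(14.4, 14.5, 14.5, 14.6))
  applications <- data.frame(panel = "p2", week = 2L, action = "A")
  experiment_table(counts, meta, env, applications, validate = FALSE)
}

# fixed-step classical RK4 for the model right-hand side, in (x, y1)
# coordinates, with removal events at integer times; independent of the
# package's adaptive Dormand-Prince integrator
rk4_solve <- function(params, schedule, times, h = 1e-3) {
  state <- c(0, 0)
  out <- NULL
  t <- 0
  for (tt in times) {
    nstep <- ceiling((tt - t) / h)
    hh <- (tt - t) / nstep
    for (s in seq_len(nstep)) {
      k1 <- dyn_rhs(params, state[1], state[2])
      k2 <- dyn_rhs(params, state[1] + hh / 2 * k1[1], state[2] + hh / 2 * k1[2])
      k3 <- dyn_rhs(params, state[1] + hh / 2 * k2[1], state[2] + hh / 2 * k2[2])
      k4 <- dyn_rhs(params, state[1] + hh * k3[1], state[2] + hh * k3[2])
      state <- state + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- tt
    pre <- state
    i <- if (nrow(schedule)) match(tt, schedule$week) else NA
    if (!is.na(i)) {
      if (schedule$action[i] == "A") state[2] <- state[2] * (1 - params$r_A)
      else state[1] <- state[1] * (1 - params$r_O)
    }
    out <- rbind(out, c(time = tt, x_pre = pre[1], y1_pre = pre[2],
                        x_post = state[1], y1_post = state[2]))
  }
  as.data.frame(out)
}

# random valid parameter set for a variant (rates on scales seen in the data)
random_dyn_params <- function(variant = "basic", r_A = NULL, r_O = NULL) {
  dyn_params(variant,
             a0 = runif(1, 0.01, 0.5), a1 = runif(1, 0.1, 1.5),
             a2 = -runif(1, 0.05, 0.5), delta = runif(1, 0.5, 2),
             b0 = runif(1, 0.005, 0.1), b1 = runif(1, 0.1, 1.5),
             b2 = -runif(1, 0.05, 0.5),
             extra = if (variant == "basic") 0 else runif(1, 0.05, 1.5),
             r_A = r_A %||% runif(1, 0.2, 0.8),
             r_O = r_O %||% runif(1, 0.2, 0.8))
}

random_composition <- function(D = 5) {
  close_comp(rgamma(D, shape = 2))
}

# an alternative orthonormal 5-part basis (different sequential partition)
alt_basis <- function() {
  sbp_basis(list(list(1L, 2:5), list(2L, 3:5), list(3L, 4:5), list(4L, 5L)),
            D = 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-design metadata (design of the study) for hand-built manova datasets
.design_meta_for_test <- function(n_blocks = 3) {
  grid <- expand.grid(treatment = c("C", "A", "O"), depth = c(1, 3),
                      block = seq_len(n_blocks), stringsAsFactors = FALSE)
  data.frame(panel = sprintf("P%02d", seq_len(nrow(grid))),
             block = grid$block, depth = grid$depth,
             treatment = grid$treatment)
}

.drop_block_for_test <- function(data, block) {
  keep <- data$design$block != block
  structure(list(counts = data$counts[keep, , drop = FALSE],
                 n = data$n[keep], design = data$design[keep, , drop = FALSE],
                 parts = data$parts, week = data$week),
            class = "manova_data")
}

# dynamics_data built directly from components (for small inference tests)
make_dynamics_data <- function(obs, schedules, meta) {
  structure(list(obs = obs, schedules = schedules, meta = meta),
            class = "dynamics_data")
}
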