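# Generator of synthetic settlement-panel experiments with the statistical
# structure both analyses assume: deterministic space-competition dynamics
# with weekly removal events and multinomial point counts for the time-series
# track, and the latent hierarchical compositional model for the
# final-composition track. Defaults reproduce the study design: 10 blocks x
# 2 depths x 3 treatments = 60 panels, 8 weekly samplings of 100 points,
# polyp removals from week 3 (A), competitor removals from week 2 (O), and
# one mistaken A application on a 1 m control panel in week 2.

#' Design of a synthetic settlement-panel experiment
#'
#' @param n_blocks number of spatial blocks (default 10).
#' @param depths the two depths in metres.
#' @param treatments treatment labels (control, polyp removal, competitor
#'   removal).
#' @param n_weeks weekly samplings (deployment is week 0, unobserved).
#' @param points points per photograph.
#' @param mistake optional list(block, depth, week): a one-off mistaken "A"
#'   application to the control panel of that block and depth. The study's
#'   mistake (a 1 m control in week 2) is injected by default; use
#'   `mistake = NULL` for a clean design.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 10, depths = c(1, 3),
                        treatments = c("C", "A", "O"), n_weeks = 8,
                        points = 100,
                        mistake = list(block = 2, depth = 1, week = 2)) {
  stopifnot(n_blocks >= 1, length(depths) == 2, n_weeks >= 1)
  if (!is.null(mistake) &&
      (mistake$block > n_blocks || !mistake$depth %in% depths ||
         mistake$week > n_weeks))
    mistake <- NULL   # reduced designs drop the default mistake injection
  structure(list(n_blocks = n_blocks, depths = depths,
                 treatments = treatments, n_weeks = n_weeks, points = points,
                 mistake = mistake),
            class = "design_spec")
}

# panel metadata table of a design
.design_meta <- function(design) {
  grid <- expand.grid(treatment = design$treatments, depth = design$depths,
                      block = seq_len(design$n_blocks),
                      stringsAsFactors = FALSE)
  meta <- data.frame(panel = sprintf("P%02d", seq_len(nrow(grid))),
                     block = grid$block, depth = grid$depth,
                     treatment = grid$treatment,
                     mistaken_week = NA_integer_)
  mk <- design$mistake
  if (!is.null(mk)) {
    i <- which(meta$block == mk$block & meta$depth == mk$depth &
                 meta$treatment == "C")
    if (!length(i)) stop("mistake refers to a nonexistent control panel")
    meta$mistaken_week[i[1]] <- mk$week
  }
  meta
}

#' Scenario preset for the synthetic generator
#'
#' Loads a named preset (versioned JSON config shipped with the package):
#' per-depth dynamic parameters and removal fractions for the time-series
#' track, and baseline/effect compositions plus random-effect scales for the
#' final-composition track.
#'
#' @param name preset name (currently "default").
#' @return object of class `scenario_preset`: list with `dyn` (list of
#'   `dyn_params` per depth), `manova` (mu, alpha, beta in ilr coordinates;
#'   Z, Sigma), and the raw config.
#' @export
scenario_preset <- function(name = "default") {
  path <- system.file("extdata", paste0("preset_", name, ".json"),
                      package = "polypcomp")
  if (path == "") stop("unknown preset: ", name)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  dyn <- list(
    `1` = do.call(dyn_params, c(list(variant = cfg$dynamics$variant),
                                as.list(cfg$dynamics$depth_1m),
                                list(r_A = cfg$dynamics$r_A,
                                     r_O = cfg$dynamics$r_O))),
    `3` = do.call(dyn_params, c(list(variant = cfg$dynamics$variant),
                                as.list(cfg$dynamics$depth_3m),
                                list(r_A = cfg$dynamics$r_A,
                                     r_O = cfg$dynamics$r_O))))
  basis <- default_basis()
  mu <- ilr(close_comp(cfg$manova$baseline_composition), basis)
  a1 <- ilr(close_comp(cfg$manova$depth_1m_perturbation), basis)
  alpha <- rbind(a1, -a1)
  bA <- ilr(close_comp(cfg$manova$treatment_perturbations$A), basis)
  bO <- ilr(close_comp(cfg$manova$treatment_perturbations$O), basis)
  # sum-to-zero over treatments: C is minus the sum of the A and O effects,
  # recentred so the three effects average to zero
  ctr <- (bA + bO) / 3
  beta <- rbind(C = -ctr, A = bA - ctr, O = bO - ctr)
  structure(list(
    name = cfg$name, version = cfg$version, dyn = dyn,
    ac_share = cfg$dynamics$aurita_on_competitor_share,
    split_alpha = unlist(cfg$dynamics$competitor_split_alpha),
    manova = list(mu = mu, alpha = alpha, beta = beta, gamma = NULL,
                  Z = diag(4) * cfg$manova$block_sd^2,
                  Sigma = diag(4) * cfg$manova$panel_sd^2),
    config = cfg), class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset '", x$name, "' (version ", x$version, ")\n", sep = "")
  cat("  dynamics variant:", x$dyn[[1]]$variant, "\n")
  invisible(x)
}

# weekly paired environmental series with study-like depth differences
.generate_env <- function(design) {
  wk <- seq_len(design$n_weeks)
  shallow_do <- rnorm(length(wk), 8.5, 0.6)
  shallow_tmp <- 19 - 0.25 * wk + rnorm(length(wk), 0, 0.4)
  shallow_sal <- rnorm(length(wk), 14.5, 0.15)
  env <- rbind(
    data.frame(week = wk, depth = design$depths[1],
               dissolved_oxygen = shallow_do, temperature = shallow_tmp,
               salinity = shallow_sal),
    data.frame(week = wk, depth = design$depths[2],
               dissolved_oxygen = shallow_do - 0.73 + rnorm(length(wk), 0, 1),
               temperature = shallow_tmp - 0.26 + rnorm(length(wk), 0, 0.2),
               salinity = shallow_sal + 0.09 + rnorm(length(wk), 0, 0.15)))
  env$salinity[env$week == 5] <- NA  # no salinity measurements in week 5
  env
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

#' Generate a synthetic dynamics experiment
#'
#' Simulates the full experiment: per-panel deterministic trajectories of the
#' chosen model variant with the panel's removal schedule, multinomial point
#' counts at each weekly sampling (pre- and post-treatment), competitor
#' counts split among named taxa by a fixed per-panel Dirichlet draw (so the
#' taxon-inclusion rule of the final-composition analysis is exercised), and
#' a small share of polyps recorded on competitors. The generating truth is
#' retained for recovery tests.
#'
#' @param preset a `scenario_preset` (or name passed to [scenario_preset()]).
#' @param design a `design_spec`.
#' @param seed integer seed.
#' @return list with `table` (a validated `experiment_table`) and `truth`
#'   (generating parameters and per-panel trajectories).
#' @export
generate_dynamics_experiment <- function(preset = scenario_preset(),
                                         design = design_spec(), seed = 1) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  set.seed(seed)
  meta <- .design_meta(design)
  app <- derive_schedule(meta, design$n_weeks)
  cats <- panel_categories()
  comp_cats <- .competitor_categories()
  rows <- vector("list", nrow(meta))
  truth_states <- vector("list", nrow(meta))
  depth_names <- as.character(design$depths)
  for (i in seq_len(nrow(meta))) {
    pars <- preset$dyn[[match(as.character(meta$depth[i]), depth_names)]]
    sched <- app[app$panel == meta$panel[i], c("week", "action"), drop = FALSE]
    traj <- solve_dynamics(pars, sched, times = seq_len(design$n_weeks))
    truth_states[[i]] <- traj
    split_w <- .rdirichlet1(preset$split_alpha)
    draw_counts <- function(x, y1) {
      u1 <- x; u2 <- pars$delta * y1
      p <- numeric(length(cats)); names(p) <- cats
      p["aurita_panel"] <- u2
      p["aurita_competitor"] <- preset$ac_share * u1
      p["bare"] <- max(0, 1 - u1 - u2)
      p[comp_cats] <- u1 * (1 - preset$ac_share) * split_w
      drop(rmultinom(1, design$points, p))
    }
    out_pre <- traj[traj$phase == "pre", ]
    panel_rows <- vector("list", design$n_weeks)
    for (w in seq_len(design$n_weeks)) {
      ypre <- draw_counts(out_pre$x[w], out_pre$y1[w])
      applied <- w %in% sched$week
      ypost <- if (applied) {
        st <- traj[traj$time == w & traj$phase == "post", ]
        draw_counts(st$x, st$y1)
      } else ypre
      panel_rows[[w]] <- data.frame(
        panel = meta$panel[i], week = w,
        phase = rep(c("pre", "post"), each = length(cats)),
        category = rep(cats, 2), count = c(ypre, ypost))
    }
    rows[[i]] <- do.call(rbind, panel_rows)
  }
  counts <- do.call(rbind, rows)
  env <- .generate_env(design)
  tbl <- experiment_table(counts, meta, env, app, points = design$points)
  list(table = tbl,
       truth = list(params = preset$dyn, r_A = preset$dyn[[1]]$r_A,
                    r_O = preset$dyn[[1]]$r_O, states = truth_states,
                    meta = meta))
}

#' Generate a synthetic final-composition dataset
#'
#' Draws directly from the latent hierarchical compositional model: block
#' effects from N(0, Z), panel effects from N(0, Sigma), cell means mu +
#' alpha_j + beta_k in ilr space, and multinomial counts at the closed
#' inverse-ilr compositions.
#'
#' @param preset a `scenario_preset` (its `manova` component is used).
#' @param design a `design_spec`.
#' @param seed integer seed.
#' @param points multinomial total per panel (default from design).
#' @return list with `data` (a `manova_data`) and `truth` (generating
#'   effects and random effects).
#' @export
generate_manova_dataset <- function(preset = scenario_preset(),
                                    design = design_spec(), seed = 1,
                                    points = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  set.seed(seed)
  points <- points %||% design$points
  mp <- preset$manova
  meta <- .design_meta(design)
  basis <- default_basis()
  depths <- sort(unique(meta$depth))
  blocks <- sort(unique(meta$block))
  draw_mvn0 <- function(n, S) {
    if (all(S == 0)) return(matrix(0, n, ncol(S)))
    matrix(rnorm(n * ncol(S)), ncol = ncol(S)) %*% chol(S)
  }
  delta <- draw_mvn0(length(blocks), mp$Z)
  eps <- draw_mvn0(nrow(meta), mp$Sigma)
  j <- match(meta$depth, depths)
  k <- match(meta$treatment, c("C", "A", "O"))
  eta <- matrix(mp$mu, nrow(meta), 4, byrow = TRUE) +
    mp$alpha[j, , drop = FALSE] + mp$beta[k, , drop = FALSE] +
    delta[match(meta$block, blocks), , drop = FALSE] + eps
  if (!is.null(mp$gamma))
    for (i in seq_len(nrow(meta))) eta[i, ] <- eta[i, ] + mp$gamma[j[i], k[i], ]
  rho <- ilr_inv(eta, basis)
  Y <- t(vapply(seq_len(nrow(meta)), function(i)
    drop(rmultinom(1, points, rho[i, ])), numeric(5)))
  colnames(Y) <- c("aurita_panel", "bare", "botrylloides", "bugula", "molgula")
  rownames(Y) <- meta$panel
  data <- structure(list(counts = Y, n = rowSums(Y),
                         design = meta[, c("panel", "block", "depth", "treatment")],
                         parts = colnames(Y), week = design$n_weeks),
                    class = "manova_data")
  list(data = data,
       truth = list(mu = mp$mu, alpha = mp$alpha, beta = mp$beta,
                    gamma = mp$gamma, Z = mp$Z, Sigma = mp$Sigma,
                    delta = delta, epsilon = eps, rho = rho))
}
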