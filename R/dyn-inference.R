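# Bayesian fitting of the space-competition ODE models to panel time series.
#
# Likelihood: each observation's 3-category counts (polyps on panel, bare,
# potential competitors) are multinomial with probabilities (u2, 1-u1-u2, u1)
# taken from the deterministic trajectory of that panel's depth and schedule,
# at the pre- or post-event state. Cover data cannot separate the polyp
# density y1 from the area per polyp delta, so the model is fitted in
# relative-abundance coordinates (delta fixed at 1): the fitted polyp
# settlement rate is the product delta*b0 (reported "db0") and the overgrowth
# rate is a_{1,y1}/delta. Parameters are independent between depths; the
# removal fractions r_A, r_O are shared across depths and weeks.
#
# Sampler: adaptive Metropolis (Haario-style covariance adaptation during
# warmup) on log / logit transformed parameters, initialized near the
# posterior mode found by Nelder-Mead.

.dyn_parnames <- function(variant, depths) {
  base <- c("a0", "a1", "a2", "db0", "b1", "b2")
  if (variant != "basic") base <- c(base, .extra_name(variant))
  c(as.vector(t(outer(paste0(depths, "m"), base,
                      function(d, p) paste0(p, "_", d)))),
    "r_A", "r_O")
}

# prepare C++ likelihood arguments from a dynamics_data
.dyn_setup <- function(data) {
  obs <- data$obs
  depths <- sort(unique(data$meta$depth))
  n_weeks <- if (nrow(obs)) max(obs$week) else 8L
  sig <- vapply(data$schedules, function(s) paste(s$week, s$action, collapse = ";"),
                character(1))
  panel_depth <- data$meta$depth[match(names(data$schedules), data$meta$panel)]
  gkey <- paste(panel_depth, sig[names(data$schedules)])
  ukey <- unique(gkey)
  group_of_panel <- match(gkey, ukey)
  names(group_of_panel) <- names(data$schedules)
  group_cp <- vector("list", length(ukey))
  group_par_row <- integer(length(ukey))
  for (g in seq_along(ukey)) {
    pnl <- names(group_of_panel)[match(g, group_of_panel)]
    group_cp[[g]] <- .checkpoints(seq_len(n_weeks), data$schedules[[pnl]])
    group_par_row[g] <- match(data$meta$depth[match(pnl, data$meta$panel)], depths)
  }
  list(group_cp = group_cp, group_par_row = group_par_row,
       obs_mat = cbind(group = group_of_panel[obs$panel],
                       week = obs$week, phase = as.integer(obs$phase == "post")),
       counts = cbind(obs$aurita, obs$bare, obs$competitors),
       depths = depths, n_weeks = n_weeks)
}

# theta (unconstrained) -> natural parameter matrix (2 x 7) + removals
.dyn_untransform <- function(theta, variant, ndepth = 2) {
  k <- if (variant == "basic") 6L else 7L
  par2 <- matrix(0, ndepth, 7)
  for (d in seq_len(ndepth)) {
    v <- exp(theta[(d - 1) * k + 1:k])
    par2[d, 1:2] <- v[1:2]
    par2[d, 3] <- -v[3]
    par2[d, 4:5] <- v[4:5]
    par2[d, 6] <- -v[6]
    if (k == 7L) par2[d, 7] <- v[7]
  }
  r <- plogis(theta[ndepth * k + 1:2])
  list(par2 = par2, r_A = r[1], r_O = r[2])
}

# log prior + Jacobian on the unconstrained scale: half-normal(prior_scale)
# on each rate magnitude (exp transform), uniform(0,1) on removals (logit)
.dyn_lprior <- function(theta, nmag, prior_scale) {
  mag <- exp(theta[seq_len(nmag)])
  lp <- sum(-0.5 * (mag / prior_scale)^2 + theta[seq_len(nmag)])
  lr <- theta[nmag + 1:2]
  lp + sum(lr - 2 * log1p(exp(lr)))
}

#' Pointwise log-likelihood of a space-competition model
#'
#' One multinomial log-pmf per observation of a dynamics dataset, evaluated
#' along the deterministic trajectories implied by per-depth parameters and
#' each panel's removal schedule. Probabilities are floored at `floor_p` (and
#' renormalized) to keep early-week exact zeros finite.
#'
#' @param params_by_depth list of `dyn_params`, one per depth (sorted), all
#'   of the same variant and with common `r_A`, `r_O`.
#' @param data a `dynamics_data` (see [dynamics_dataset()]).
#' @param floor_p probability floor (default 1e-9).
#' @return numeric vector, one entry per row of `data$obs`.
#' @export
dyn_log_lik <- function(params_by_depth, data, floor_p = 1e-9) {
  setup <- .dyn_setup(data)
  if (length(params_by_depth) != length(setup$depths))
    stop("need one parameter set per depth")
  variant <- params_by_depth[[1]]$variant
  par2 <- do.call(rbind, lapply(params_by_depth, .upar))
  loglik_dyn_cpp(.variant_id(variant), par2,
                 params_by_depth[[1]]$r_A, params_by_depth[[1]]$r_O,
                 setup$group_cp, setup$group_par_row, setup$obs_mat,
                 setup$counts, floor_p)
}

#' Fit a space-competition model to panel time series
#'
#' Adaptive-Metropolis posterior sampling for one model variant. Priors are
#' half-normal with mode zero (scale `prior_scale`) on the magnitude of each
#' rate parameter, with the sign constraints imposed by the parameterization,
#' and uniform(0, 1) on the removal fractions.
#'
#' @param data a `dynamics_data`.
#' @param variant model variant (see [dyn_params()]).
#' @param chains,iter,warmup,thin sampler settings. Defaults give
#'   3 x 1500 kept draws.
#' @param seed integer seed (reproducible draws).
#' @param prior_scale half-normal prior scale for rate magnitudes.
#' @param floor_p multinomial probability floor.
#' @return object of class `dynamics_fit`: `draws` (kept draws, natural
#'   scale, named columns), `ll_pointwise` (draws x observations),
#'   `diagnostics` (R-hat, ESS), `acceptance`, `variant`, `data`.
#' @export
fit_dynamics <- function(data, variant = "overgrowth", chains = 3,
                         iter = 5000, warmup = 2000, thin = 2, seed = 1,
                         prior_scale = 1, floor_p = 1e-9) {
  stopifnot(inherits(data, "dynamics_data"), iter > warmup)
  variant <- match.arg(variant, .dyn_variants)
  vid <- .variant_id(variant)
  setup <- .dyn_setup(data)
  ndepth <- length(setup$depths)
  k <- if (variant == "basic") 6L else 7L
  nmag <- ndepth * k
  npar <- nmag + 2L
  pn <- .dyn_parnames(variant, setup$depths)
  N <- nrow(setup$obs_mat)

  lpost <- function(theta) {
    if (any(abs(theta) > 30)) return(list(lp = -Inf, ll = rep(-Inf, N)))
    u <- .dyn_untransform(theta, variant, ndepth)
    ll <- tryCatch(
      loglik_dyn_cpp(vid, u$par2, u$r_A, u$r_O, setup$group_cp,
                     setup$group_par_row, setup$obs_mat, setup$counts,
                     floor_p),
      error = function(e) rep(-Inf, N))
    lp <- sum(ll) + .dyn_lprior(theta, nmag, prior_scale)
    if (!is.finite(lp)) lp <- -Inf
    list(lp = lp, ll = ll)
  }

  set.seed(seed)
  # posterior-mode initialization (shared across chains, jittered per chain):
  # Nelder-Mead from a neutral start, polished by BFGS on the smooth surface
  theta0 <- c(rep(log(0.3), nmag), 0, 0)
  nlp <- function(th) -lpost(th)$lp
  opt <- tryCatch({
    o1 <- optim(theta0, nlp, method = "Nelder-Mead",
                control = list(maxit = 5000))
    tryCatch(optim(o1$par, nlp, method = "BFGS",
                   control = list(maxit = 200)),
             error = function(e) o1)
  }, error = function(e) list(par = theta0))
  chain_seeds <- sample.int(2^31 - 2, chains)
  keep_each <- floor((iter - warmup) / thin)

  run_chain <- function(cseed) {
    set.seed(cseed)
    theta <- opt$par + rnorm(npar, 0, 0.05)
    cur <- lpost(theta)
    while (!is.finite(cur$lp)) {
      theta <- opt$par + rnorm(npar, 0, 0.01)
      cur <- lpost(theta)
    }
    draws <- matrix(NA_real_, keep_each, npar)
    llmat <- matrix(NA_real_, keep_each, N)
    lpv <- numeric(keep_each)
    mu <- theta; Scov <- diag(npar) * 1e-4
    lsc <- log(2.38^2 / npar)
    naccept <- 0L; kept <- 0L
    chol_S <- chol(Scov + diag(npar) * 1e-8)
    for (t in seq_len(iter)) {
      prop <- theta + exp(lsc / 2) * drop(rnorm(npar) %*% chol_S)
      cand <- lpost(prop)
      acc <- log(runif(1)) < cand$lp - cur$lp
      if (acc) { theta <- prop; cur <- cand; naccept <- naccept + 1L }
      if (t <= warmup) {
        g <- 1 / max(10, t)^0.6
        mu <- mu + g * (theta - mu)
        Scov <- Scov + g * (tcrossprod(theta - mu) - Scov)
        lsc <- lsc + 2 * g * ((if (acc) 1 else 0) - 0.234)
        if (t %% 50 == 0 || t == warmup)
          chol_S <- chol(Scov + diag(npar) * 1e-8)
      }
      if (t > warmup && (t - warmup) %% thin == 0L) {
        kept <- kept + 1L
        u <- .dyn_untransform(theta, variant, ndepth)
        nat <- c(t(cbind(u$par2[, 1:k, drop = FALSE]))[seq_len(nmag)],
                 u$r_A, u$r_O)
        draws[kept, ] <- nat
        llmat[kept, ] <- cur$ll
        lpv[kept] <- cur$lp
      }
    }
    list(draws = draws, ll = llmat, lp = lpv, acc = naccept / iter)
  }

  res <- lapply(chain_seeds, run_chain)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws) <- pn
  llmat <- do.call(rbind, lapply(res, `[[`, "ll"))
  rhat <- apply(draws, 2, split_rhat, chains = chains)
  ess <- apply(draws, 2, ess_basic, chains = chains)

  structure(list(draws = draws, ll_pointwise = llmat,
                 lp = unlist(lapply(res, `[[`, "lp")),
                 diagnostics = list(rhat = rhat, ess = ess),
                 acceptance = mean(vapply(res, `[[`, numeric(1), "acc")),
                 variant = variant, data = data, setup = setup,
                 chains = chains, iter = iter, warmup = warmup, thin = thin,
                 seed = seed, prior_scale = prior_scale, floor_p = floor_p,
                 map = opt$par),
            class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat("Space-competition model fit (", x$variant, ")\n", sep = "")
  cat("  ", nrow(x$setup$obs_mat), " observations, ", x$chains, " chains x ",
      floor((x$iter - x$warmup) / x$thin), " kept draws, acceptance ",
      sprintf("%.2f", x$acceptance), "\n", sep = "")
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
summary.dynamics_fit <- function(object, ...) {
  d <- object$draws
  tab <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2, sd),
                    lower = apply(d, 2, function(z) hpd_interval(z)[1]),
                    upper = apply(d, 2, function(z) hpd_interval(z)[2]),
                    rhat = object$diagnostics$rhat,
                    ess = object$diagnostics$ess, row.names = NULL)
  structure(list(table = tab, variant = object$variant),
            class = "summary.dynamics_fit")
}

#' @export
print.summary.dynamics_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (", x$variant, "); 95% HPD intervals\n", sep = "")
  tab <- x$table
  tab[, 2:5] <- round(tab[, 2:5], digits)
  tab$rhat <- round(tab$rhat, 3); tab$ess <- round(tab$ess)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dynamics_fit <- function(object, ...) colMeans(object$draws)

# dyn_params list (one per depth) from a draw row
.params_from_draw <- function(fit, s) {
  k <- if (fit$variant == "basic") 6L else 7L
  v <- fit$draws[s, ]
  lapply(seq_along(fit$setup$depths), function(d) {
    block <- v[(d - 1) * k + 1:k]
    dyn_params(fit$variant, a0 = block[1], a1 = block[2], a2 = block[3],
               delta = 1, b0 = block[4], b1 = block[5], b2 = block[6],
               extra = if (k == 7L) block[7] else 0,
               r_A = v[length(v) - 1], r_O = v[length(v)])
  })
}

#' PSIS-LOO expected log predictive density
#'
#' Pareto-smoothed importance-sampling leave-one-out cross-validation from
#' the pointwise log-likelihood draws of a fit: importance ratios 1/p(y_i |
#' theta_s) are tail-smoothed by a generalized-Pareto fit and truncated, and
#' elpd_i is the smoothed-weighted average of the likelihood.
#'
#' @param fit a `dynamics_fit` (or any object with an `ll_pointwise` matrix).
#' @return object of class `psis_loo`: list with `elpd` (total), `elpd_i`,
#'   `se`, `khat` (Pareto shape per observation).
#' @export
psis_loo <- function(fit) {
  llm <- if (is.matrix(fit)) fit else fit$ll_pointwise
  N <- ncol(llm)
  elpd_i <- numeric(N); khat <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-llm[, i])
    elpd_i[i] <- logsumexp(sm$log_weights + llm[, i]) - logsumexp(sm$log_weights)
    khat[i] <- sm$khat
  }
  structure(list(elpd = sum(elpd_i), elpd_i = elpd_i,
                 se = sqrt(N * var(elpd_i)), khat = khat),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO elpd %.1f (SE %.1f), %d observations\n",
              x$elpd, x$se, length(x$elpd_i)))
  bad <- sum(is.finite(x$khat) & x$khat > 0.7)
  if (bad) cat("  ", bad, " observation(s) with Pareto k > 0.7\n", sep = "")
  invisible(x)
}

#' Compare fitted dynamic models by PSIS-LOO
#'
#' @param fits named list of `dynamics_fit` objects for the same dataset
#'   (pointwise log-likelihood arrays aligned over observations).
#' @return `elpd_comparison` data.frame: model, elpd, delta_elpd (from the
#'   best model), se_diff (sqrt(N) x sd of pointwise differences), khat_max.
#' @export
psis_loo_compare <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$variant, character(1))
  loos <- lapply(fits, psis_loo)
  N <- length(loos[[1]]$elpd_i)
  if (!all(vapply(loos, function(l) length(l$elpd_i), integer(1)) == N))
    stop("pointwise log-likelihood arrays are not aligned")
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  best <- which.max(elpd)
  se <- vapply(seq_along(loos), function(m) {
    if (m == best) return(0)
    sqrt(N) * sd(loos[[m]]$elpd_i - loos[[best]]$elpd_i)
  }, numeric(1))
  khat_max <- vapply(loos, function(l) {
    k <- l$khat[is.finite(l$khat)]
    if (length(k)) max(k) else NA_real_
  }, numeric(1))
  for (m in seq_along(loos)) {
    frac_bad <- mean(is.finite(loos[[m]]$khat) & loos[[m]]$khat > 0.7)
    if (frac_bad > 0.1)
      warning(sprintf("model %s: %.0f%% of observations have Pareto k > 0.7",
                      names(fits)[m], 100 * frac_bad))
  }
  ord <- order(-elpd)
  structure(data.frame(model = names(fits)[ord], elpd = elpd[ord],
                       delta_elpd = (elpd - elpd[best])[ord],
                       se_diff = se[ord], khat_max = khat_max[ord],
                       row.names = NULL),
            class = c("elpd_comparison", "data.frame"),
            loos = loos, se_unit = "observation")
}

#' Posterior predictive simulation of panel time series
#'
#' Draws multinomial counts along trajectories simulated from posterior
#' draws, for the panels, schedules and observation layout of the fitted
#' dataset (or a design with the same structure).
#'
#' @param fit a `dynamics_fit`.
#' @param ndraws number of posterior draws to simulate from.
#' @param seed integer seed.
#' @param points points per photograph (default 100).
#' @return list of data.frames shaped like `fit$data$obs` (one per draw)
#'   with simulated `aurita`, `bare`, `competitors` counts.
#' @export
posterior_predictive <- function(fit, ndraws = 100, seed = 1, points = 100) {
  set.seed(seed)
  S <- nrow(fit$draws)
  use <- sample.int(S, min(ndraws, S))
  obs <- fit$data$obs
  setup <- fit$setup
  out <- vector("list", length(use))
  for (oi in seq_along(use)) {
    s <- use[oi]
    pl <- .params_from_draw(fit, s)
    par2 <- do.call(rbind, lapply(pl, .upar))
    sim <- obs
    if (nrow(obs)) {
      states <- lapply(seq_along(setup$group_cp), function(g)
        solve_dyn_cpp(.variant_id(fit$variant), par2[setup$group_par_row[g], ],
                      setup$group_cp[[g]], pl[[1]]$r_A, pl[[1]]$r_O, 0, 0))
      for (i in seq_len(nrow(obs))) {
        st <- states[[setup$obs_mat[i, 1]]]
        w <- setup$obs_mat[i, 2]
        post <- setup$obs_mat[i, 3] == 1L
        u1 <- if (post) st[w, 3] else st[w, 1]
        u2 <- if (post) st[w, 4] else st[w, 2]
        p <- pmax(c(u2, 1 - u1 - u2, u1), fit$floor_p)
        y <- rmultinom(1, points, p / sum(p))
        sim$aurita[i] <- y[1]; sim$bare[i] <- y[2]; sim$competitors[i] <- y[3]
        sim$n[i] <- points
      }
    }
    out[[oi]] <- sim
  }
  out
}

#' @export
simulate.dynamics_fit <- function(object, nsim = 1, seed = 1, ...) {
  posterior_predictive(object, ndraws = nsim, seed = seed, ...)
}

#' Typical-panel posterior trajectories
#'
#' Posterior mean relative abundances (polyps, bare, competitors) over time
#' with 95% HPD bands, for a typical panel from each treatment x depth cell:
#' no applications in the control, polyp removal from week 3 in A, competitor
#' removal from week 2 in O.
#'
#' @param fit a `dynamics_fit`.
#' @param times output grid (weeks).
#' @param ndraws posterior draws used for the bands.
#' @param seed integer seed for the draw subsample.
#' @return data.frame: depth, treatment, time, phase, and mean/lower/upper
#'   for each of aurita, bare, competitors.
#' @export
typical_panel_trajectories <- function(fit, times = seq(0.25, 8, by = 0.25),
                                       ndraws = 200, seed = 1) {
  set.seed(seed)
  S <- nrow(fit$draws)
  use <- sample.int(S, min(ndraws, S))
  n_weeks <- fit$setup$n_weeks
  scheds <- list(C = data.frame(week = integer(0), action = character(0)),
                 A = data.frame(week = 3:n_weeks, action = "A"),
                 O = data.frame(week = 2:n_weeks, action = "O"))
  out <- list()
  for (d in seq_along(fit$setup$depths)) {
    for (tr in names(scheds)) {
      tms <- sort(unique(c(times, scheds[[tr]]$week)))
      cp <- .checkpoints(tms, scheds[[tr]])
      arr <- array(NA_real_, c(length(use), length(tms) + sum(cp[, 2] > 0), 3))
      tvec <- NULL; pvec <- NULL
      for (oi in seq_along(use)) {
        pl <- .params_from_draw(fit, use[oi])
        st <- solve_dyn_cpp(.variant_id(fit$variant), .upar(pl[[d]]), cp,
                            pl[[1]]$r_A, pl[[1]]$r_O, 0, 0)
        pre <- cbind(st[, 2], 1 - st[, 1] - st[, 2], st[, 1])
        ev <- cp[, 2] > 0
        rows <- pre; tt <- tms; ph <- rep("pre", length(tms))
        if (any(ev)) {
          post <- cbind(st[ev, 4], 1 - st[ev, 3] - st[ev, 4], st[ev, 3])
          rows <- rbind(pre, post)
          tt <- c(tms, tms[ev]); ph <- c(ph, rep("post", sum(ev)))
          ord <- order(tt, ph != "pre")
          rows <- rows[ord, , drop = FALSE]; tt <- tt[ord]; ph <- ph[ord]
        }
        arr[oi, , ] <- rows
        tvec <- tt; pvec <- ph
      }
      sm <- apply(arr, c(2, 3), mean)
      lo <- apply(arr, c(2, 3), function(z) hpd_interval(z)[1])
      hi <- apply(arr, c(2, 3), function(z) hpd_interval(z)[2])
      out[[length(out) + 1L]] <- data.frame(
        depth = fit$setup$depths[d], treatment = tr, time = tvec, phase = pvec,
        aurita = sm[, 1], aurita_lo = lo[, 1], aurita_hi = hi[, 1],
        bare = sm[, 2], bare_lo = lo[, 2], bare_hi = hi[, 2],
        competitors = sm[, 3], competitors_lo = lo[, 3],
        competitors_hi = hi[, 3])
    }
  }
  do.call(rbind, out)
}

#' Removal diagnostics: post- versus pre-treatment cover
#'
#' For every application, pairs the observed pre- and post-treatment sample
#' proportion of the targeted group (polyps for A actions, competitors for O
#' actions) together with the proportion of the non-targeted competitors
#' under A actions (to check for accidental removal). Model-implied slopes
#' through the origin are 1 - r_A and 1 - r_O with 95% HPD bands.
#'
#' @param data a `dynamics_data`.
#' @param fit a `dynamics_fit` on that data.
#' @return list with `points` (panel, week, action, group, pre, post) and
#'   `slopes` (action, group, slope mean, HPD bounds).
#' @export
removal_diagnostics <- function(data, fit) {
  obs <- data$obs
  key <- paste(obs$panel, obs$week)
  post <- obs[obs$phase == "post", , drop = FALSE]
  rows <- list()
  if (nrow(post)) {
    pre <- obs[obs$phase == "pre", , drop = FALSE]
    m <- match(paste(post$panel, post$week), paste(pre$panel, pre$week))
    sched_act <- function(p, w) {
      s <- data$schedules[[p]]
      s$action[match(w, s$week)]
    }
    act <- mapply(sched_act, post$panel, post$week)
    target <- ifelse(act == "A", "aurita", "competitors")
    rows[["target"]] <- data.frame(
      panel = post$panel, week = post$week, action = act, group = target,
      pre = ifelse(act == "A", pre$aurita[m] / pre$n[m],
                   pre$competitors[m] / pre$n[m]),
      post = ifelse(act == "A", post$aurita / post$n,
                    post$competitors / post$n))
    a_rows <- act == "A"
    if (any(a_rows))
      rows[["bystander"]] <- data.frame(
        panel = post$panel[a_rows], week = post$week[a_rows], action = "A",
        group = "competitors_untargeted",
        pre = pre$competitors[m][a_rows] / pre$n[m][a_rows],
        post = post$competitors[a_rows] / post$n[a_rows])
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(panel = character(0), week = integer(0), action = character(0),
               group = character(0), pre = numeric(0), post = numeric(0))
  rownames(points) <- NULL
  sl <- function(dr) c(mean(dr), hpd_interval(dr))
  sA <- sl(1 - fit$draws[, "r_A"]); sO <- sl(1 - fit$draws[, "r_O"])
  slopes <- data.frame(action = c("A", "O", "A"),
                       group = c("aurita", "competitors",
                                 "competitors_untargeted"),
                       slope = c(sA[1], sO[1], 1),
                       lower = c(sA[2], sO[2], 1), upper = c(sA[3], sO[3], 1))
  list(points = points, slopes = slopes)
}
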