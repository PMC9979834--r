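# Bayesian latent hierarchical compositional MANOVA.
#
# Observation model: y_i ~ multinomial(n_i, rho_i) with
# ilr(rho_i) = mu + alpha_{depth(i)} + beta_{treat(i)} (+ gamma_{jk})
#              + delta_{block(i)} + epsilon_i,
# delta_l ~ N(0, Z), epsilon_i ~ N(0, Sigma), in the 4-dimensional ilr space
# of the 5-part final composition. Effects are sum-to-zero coded. Sampling is
# Metropolis-within-Gibbs: vectorized random-walk updates for panel and block
# effects, blocked random-walk updates for fixed effects, recentring moves
# between levels of the hierarchy to decorrelate them, and conjugate
# inverse-Wishart Gibbs draws for Z and Sigma.

.treatment_levels <- c("C", "A", "O")

# sum-to-zero coding matrices
.code_depth <- function() matrix(c(1, -1), 2, 1)          # 2 levels, 1 free col
.code_treat <- function() rbind(diag(2), c(-1, -1))       # 3 levels, 2 free rows

.variant_flags <- function(variant) {
  variant <- match.arg(variant, c("no_interaction", "full", "no_treatment", "no_depth"))
  list(variant = variant,
       depth = variant != "no_depth",
       treatment = variant != "no_treatment",
       interaction = variant == "full")
}

# linear predictor matrix (P x 4) from a parameter state
.manova_eta <- function(st, idx, flags) {
  eta <- matrix(st$mu, nrow = length(idx$j), ncol = 4, byrow = TRUE)
  if (flags$depth) eta <- eta + outer(ifelse(idx$j == 1L, 1, -1), st$fa)
  if (flags$treatment) {
    beta <- .code_treat() %*% st$fb            # 3 x 4
    eta <- eta + beta[idx$k, , drop = FALSE]
  }
  if (flags$interaction) {
    Tm <- .code_treat() %*% st$g               # 3 x 4, columns sum to zero
    eta <- eta + Tm[idx$k, , drop = FALSE] * ifelse(idx$j == 1L, 1, -1)
  }
  eta + st$delta[idx$l, , drop = FALSE] + st$eps
}

# per-panel multinomial log-likelihood kernel (constants dropped):
# sum(y * e) - n log(sum(exp(e))), e = eta %*% V
.ll_panels <- function(eta, Y, n, Vt) {
  E <- eta %*% Vt
  rowSums(Y * E) - n * log(rowSums(exp(E)))
}

#' Multinomial log-likelihood of the compositional MANOVA
#'
#' Full log-likelihood (with multinomial constants) of a parameter state:
#' the sum over panels of the multinomial log-pmf at
#' rho = ilr_inv(mu + alpha_j + beta_k [+ gamma_jk] + delta_l + epsilon_i).
#'
#' @param params list with `mu` (4-vector), `alpha` (2 x 4, rows sum to 0),
#'   `beta` (3 x 4, rows C/A/O summing to 0), optional `gamma` (array 2 x 3
#'   x 4, doubly centred), `delta` (blocks x 4), `epsilon` (panels x 4).
#'   Missing terms are treated as zero.
#' @param data a `manova_data` object (see [manova_subset()]).
#' @param basis 5-part contrast matrix.
#' @return scalar log-likelihood.
#' @export
manova_log_lik <- function(params, data, basis = default_basis()) {
  idx <- .manova_index(data)
  P <- nrow(data$counts)
  eta <- matrix(params$mu %||% rep(0, 4), P, 4, byrow = TRUE)
  if (!is.null(params$alpha)) eta <- eta + params$alpha[idx$j, , drop = FALSE]
  if (!is.null(params$beta)) eta <- eta + params$beta[idx$k, , drop = FALSE]
  if (!is.null(params$gamma)) {
    for (i in seq_len(P)) eta[i, ] <- eta[i, ] + params$gamma[idx$j[i], idx$k[i], ]
  }
  if (!is.null(params$delta)) eta <- eta + params$delta[idx$l, , drop = FALSE]
  if (!is.null(params$epsilon)) eta <- eta + params$epsilon
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  P5 <- ilr_inv(eta, basis)
  sum(mult_logpmf_rows(data$counts, P5))
}

.manova_index <- function(data) {
  depths <- sort(unique(data$design$depth))
  list(j = match(data$design$depth, depths),
       k = match(data$design$treatment, .treatment_levels),
       l = match(data$design$block, sort(unique(data$design$block))),
       depths = depths,
       blocks = sort(unique(data$design$block)))
}

#' Fit the hierarchical compositional MANOVA
#'
#' Posterior sampling for the latent hierarchical compositional MANOVA by an
#' adaptive Metropolis-within-Gibbs sampler (random-walk updates with
#' recentring moves; conjugate inverse-Wishart draws for the block and panel
#' covariance matrices). Fixed effects have independent N(0, prior_sd^2)
#' priors on each ilr coordinate; Z and Sigma have inverse-Wishart(nu0 = 6,
#' I) priors.
#'
#' @param data a `manova_data` (see [manova_subset()]).
#' @param variant one of "no_interaction" (depth + treatment, the model used
#'   for reported summaries), "full" (adds the depth x treatment
#'   interaction), "no_treatment" (depth only), "no_depth" (treatment only).
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain, including warmup (default 4000).
#' @param warmup adaptation iterations discarded (default 2000).
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed; draws are reproducible given the seed.
#' @param prior_sd prior standard deviation of fixed-effect coordinates.
#' @return object of class `manova_fit` with elements `draws` (matrices, one
#'   row per kept draw: `mu`, `fa`, `fb`, `g`, `Z`, `Sigma`, `lp`),
#'   `epsilon_mean`, `delta_mean`, `diagnostics` (R-hat, bulk ESS),
#'   `variant`, `basis`, `data`, `acceptance`.
#' @export
fit_manova <- function(data, variant = "no_interaction", chains = 4,
                       iter = 4000, warmup = 2000, thin = 2, seed = 1,
                       prior_sd = 2.5) {
  stopifnot(inherits(data, "manova_data"), iter > warmup)
  flags <- .variant_flags(variant)
  idx <- .manova_index(data)
  Y <- data$counts; n <- data$n
  basis <- default_basis()
  Vt <- unclass(basis)   # 4 x 5: eta %*% Vt gives clr-scale scores
  P <- nrow(Y); L <- length(idx$blocks)
  nu0 <- 6; S0 <- diag(4)
  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, chains)
  keep_each <- floor((iter - warmup) / thin)

  run_chain <- function(cseed) {
    set.seed(cseed)
    # init: mu at the ilr of the pooled composition, effects jittered small
    pooled <- zero_replace(colSums(Y))
    st <- list(mu = ilr(pooled, basis) + rnorm(4, 0, 0.1),
               fa = rnorm(4, 0, 0.1), fb = matrix(rnorm(8, 0, 0.1), 2, 4),
               g = matrix(rnorm(8, 0, 0.1), 2, 4),
               delta = matrix(0, L, 4), eps = matrix(0, P, 4),
               Z = diag(4) * 0.05, Sigma = diag(4) * 0.1)
    if (!flags$depth) st$fa <- rep(0, 4)
    if (!flags$treatment) st$fb <- matrix(0, 2, 4)
    if (!flags$interaction) st$g <- matrix(0, 2, 4)
    scales <- list(eps = 0.3, delta = 0.3, mu = 0.1, fa = 0.1, fb = 0.1,
                   g = 0.1, rec = 0.1, recb = 0.1)
    acc <- list(); for (nm in names(scales)) acc[[nm]] <- c(0, 0)
    ll <- .ll_panels(.manova_eta(st, idx, flags), Y, n, Vt)
    out <- list(mu = matrix(NA_real_, keep_each, 4),
                fa = matrix(NA_real_, keep_each, 4),
                fb = matrix(NA_real_, keep_each, 8),
                g = matrix(NA_real_, keep_each, 8),
                Z = matrix(NA_real_, keep_each, 16),
                Sigma = matrix(NA_real_, keep_each, 16),
                lp = numeric(keep_each))
    eps_sum <- matrix(0, P, 4); delta_sum <- matrix(0, L, 4)
    kept <- 0L

    adapt <- function(nm, rate, t, target = 0.25) {
      scales[[nm]] <<- exp(log(scales[[nm]]) + (rate - target) / t^0.6)
    }

    for (t in seq_len(iter)) {
      Qs <- chol2inv(chol(st$Sigma))
      Qz <- chol2inv(chol(st$Z))

      # --- panel effects, vectorized over panels ---
      prop <- st$eps + scales$eps * matrix(rnorm(P * 4), P, 4)
      st2 <- st; st2$eps <- prop
      ll2 <- .ll_panels(.manova_eta(st2, idx, flags), Y, n, Vt)
      dpr <- -0.5 * (rowSums((prop %*% Qs) * prop) - rowSums((st$eps %*% Qs) * st$eps))
      ok <- log(runif(P)) < ll2 - ll + dpr
      st$eps[ok, ] <- prop[ok, ]
      ll[ok] <- ll2[ok]
      if (t <= warmup) adapt("eps", mean(ok), t)
      acc$eps <- acc$eps + c(sum(ok), P)

      # --- block effects, vectorized over blocks ---
      propd <- st$delta + scales$delta * matrix(rnorm(L * 4), L, 4)
      st2 <- st; st2$delta <- propd
      ll2 <- .ll_panels(.manova_eta(st2, idx, flags), Y, n, Vt)
      dll <- tapply(ll2 - ll, idx$l, sum)
      dpr <- -0.5 * (rowSums((propd %*% Qz) * propd) - rowSums((st$delta %*% Qz) * st$delta))
      okb <- log(runif(L)) < as.numeric(dll) + dpr
      st$delta[okb, ] <- propd[okb, ]
      if (any(okb)) {
        sel <- idx$l %in% which(okb)
        ll[sel] <- ll2[sel]
      }
      if (t <= warmup) adapt("delta", mean(okb), t)
      acc$delta <- acc$delta + c(sum(okb), L)

      # --- fixed-effect blocks ---
      upd_fixed <- function(nm, dim) {
        cur <- st[[nm]]
        prop <- cur + scales[[nm]] * rnorm(dim)
        st2 <- st; st2[[nm]] <- prop
        ll2 <- .ll_panels(.manova_eta(st2, idx, flags), Y, n, Vt)
        dpr <- -0.5 * (sum(prop^2) - sum(cur^2)) / prior_sd^2
        if (log(runif(1)) < sum(ll2 - ll) + dpr) {
          st[[nm]] <<- prop; ll <<- ll2
          acc[[nm]] <<- acc[[nm]] + c(1, 1)
          if (t <= warmup) adapt(nm, 1, t)
        } else {
          acc[[nm]] <<- acc[[nm]] + c(0, 1)
          if (t <= warmup) adapt(nm, 0, t)
        }
      }
      upd_fixed("mu", 4)
      if (flags$depth) upd_fixed("fa", 4)
      if (flags$treatment) upd_fixed("fb", 8)
      if (flags$interaction) upd_fixed("g", 8)

      # --- recentring: shift mu against all panel effects (likelihood
      #     invariant; accepted on the prior ratio) ---
      v <- scales$rec * rnorm(4)
      dpr <- -0.5 * (sum((st$mu + v)^2) - sum(st$mu^2)) / prior_sd^2
      epr <- st$eps; epr <- sweep(epr, 2, v)
      dpr <- dpr - 0.5 * (sum((epr %*% Qs) * epr) - sum((st$eps %*% Qs) * st$eps))
      if (log(runif(1)) < dpr) {
        st$mu <- st$mu + v; st$eps <- epr
        acc$rec <- acc$rec + c(1, 1)
        if (t <= warmup) adapt("rec", 1, t, 0.3)
      } else {
        acc$rec <- acc$rec + c(0, 1)
        if (t <= warmup) adapt("rec", 0, t, 0.3)
      }

      # --- recentring blocks against their panels, vectorized ---
      Vb <- scales$recb * matrix(rnorm(L * 4), L, 4)
      dpr_d <- -0.5 * (rowSums(((st$delta + Vb) %*% Qz) * (st$delta + Vb)) -
                         rowSums((st$delta %*% Qz) * st$delta))
      eshift <- st$eps - Vb[idx$l, , drop = FALSE]
      qf_new <- rowSums((eshift %*% Qs) * eshift)
      qf_old <- rowSums((st$eps %*% Qs) * st$eps)
      dpr_e <- -0.5 * tapply(qf_new - qf_old, idx$l, sum)
      okr <- log(runif(L)) < dpr_d + as.numeric(dpr_e)
      if (any(okr)) {
        st$delta[okr, ] <- st$delta[okr, ] + Vb[okr, ]
        sel <- idx$l %in% which(okr)
        st$eps[sel, ] <- eshift[sel, ]
      }
      acc$recb <- acc$recb + c(sum(okr), L)
      if (t <= warmup) adapt("recb", mean(okr), t, 0.3)

      # --- conjugate covariance draws ---
      st$Sigma <- rinvwishart(nu0 + P, S0 + crossprod(st$eps))
      st$Z <- rinvwishart(nu0 + L, S0 + crossprod(st$delta))

      if (t > warmup && (t - warmup) %% thin == 0L) {
        kept <- kept + 1L
        out$mu[kept, ] <- st$mu
        out$fa[kept, ] <- st$fa
        out$fb[kept, ] <- as.vector(st$fb)
        out$g[kept, ] <- as.vector(st$g)
        out$Z[kept, ] <- as.vector(st$Z)
        out$Sigma[kept, ] <- as.vector(st$Sigma)
        out$lp[kept] <- sum(ll) -
          0.5 * sum((st$eps %*% chol2inv(chol(st$Sigma))) * st$eps) -
          0.5 * sum((st$delta %*% chol2inv(chol(st$Z))) * st$delta)
        eps_sum <- eps_sum + st$eps
        delta_sum <- delta_sum + st$delta
      }
    }
    out$eps_mean <- eps_sum / keep_each
    out$delta_mean <- delta_sum / keep_each
    out$acc <- acc
    out
  }

  res <- lapply(chain_seeds, run_chain)
  draws <- list()
  for (nm in c("mu", "fa", "fb", "g", "Z", "Sigma"))
    draws[[nm]] <- do.call(rbind, lapply(res, `[[`, nm))
  draws$lp <- unlist(lapply(res, `[[`, "lp"))

  # diagnostics on reported scalars
  diag_pars <- cbind(draws$mu,
                     if (flags$depth) draws$fa,
                     if (flags$treatment) draws$fb,
                     if (flags$interaction) draws$g,
                     log(draws$Z[, c(1, 6, 11, 16)]),
                     log(draws$Sigma[, c(1, 6, 11, 16)]))
  rhat <- apply(diag_pars, 2, split_rhat, chains = chains)
  ess <- apply(diag_pars, 2, ess_basic, chains = chains)

  structure(list(
    draws = draws,
    epsilon_mean = Reduce(`+`, lapply(res, `[[`, "eps_mean")) / chains,
    delta_mean = Reduce(`+`, lapply(res, `[[`, "delta_mean")) / chains,
    diagnostics = list(rhat = rhat, ess = ess),
    variant = flags$variant, flags = flags, basis = basis, data = data,
    idx = idx, chains = chains, iter = iter, warmup = warmup, thin = thin,
    seed = seed, prior_sd = prior_sd,
    acceptance = lapply(res[[1]]$acc, function(a) a[1] / max(1, a[2]))
  ), class = "manova_fit")
}

# expand stored free parameters to full effect arrays for draw s (or all)
.manova_effects <- function(fit, s = NULL) {
  d <- fit$draws
  pick <- function(M) if (is.null(s)) M else M[s, , drop = FALSE]
  list(mu = pick(d$mu),
       alpha1 = pick(d$fa),                       # depth 1; depth 2 = -alpha1
       fb = pick(d$fb), g = pick(d$g))
}

#' Fitted treatment-cell compositions
#'
#' Per-draw composition for a depth x treatment cell with block and panel
#' effects set to zero: ilr_inv(mu + alpha_j + beta_k [+ gamma_jk]).
#'
#' @param fit a `manova_fit`.
#' @param depth one of the two depths of the design (metres).
#' @param treatment "C", "A" or "O".
#' @return matrix of 5-part compositions, one row per posterior draw.
#' @export
treatment_composition <- function(fit, depth, treatment) {
  j <- match(depth, fit$idx$depths)
  k <- match(treatment, .treatment_levels)
  if (is.na(j)) stop("unknown depth; design depths: ",
                     paste(fit$idx$depths, collapse = ", "))
  if (is.na(k)) stop("unknown treatment")
  d <- fit$draws
  eta <- d$mu
  if (fit$flags$depth) eta <- eta + d$fa * ifelse(j == 1L, 1, -1)
  Ct <- .code_treat()
  if (fit$flags$treatment)
    eta <- eta + cbind(d$fb[, 1:2] %*% Ct[k, ], d$fb[, 3:4] %*% Ct[k, ],
                       d$fb[, 5:6] %*% Ct[k, ], d$fb[, 7:8] %*% Ct[k, ])
  if (fit$flags$interaction)
    eta <- eta + ifelse(j == 1L, 1, -1) *
      cbind(d$g[, 1:2] %*% Ct[k, ], d$g[, 3:4] %*% Ct[k, ],
            d$g[, 5:6] %*% Ct[k, ], d$g[, 7:8] %*% Ct[k, ])
  ilr_inv(eta, fit$basis)
}

#' Posterior logit contrasts between removal treatments
#'
#' Per-draw difference in logit share between two treatments at a given
#' depth, for either the share of polyps on panel or the total share of
#' potential competitors, with block and panel effects at zero. The headline
#' study contrasts are logit(A. aurita) for (O, C) and
#' logit(potential competitors) for (A, C).
#'
#' @param fit a `manova_fit`.
#' @param part "aurita" (part 1) or "competitors" (parts 3 + 4 + 5).
#' @param treatments length-2 character vector (k1, k2); the contrast is
#'   logit(share at k1) - logit(share at k2).
#' @param depth depth in metres.
#' @return object of class `logit_contrast`: list with `draws`, `mean`,
#'   `lower`, `upper` (central 95%), and the identifiers.
#' @export
logit_contrast <- function(fit, part = c("aurita", "competitors"),
                           treatments = c("O", "C"), depth) {
  part <- match.arg(part)
  if (length(treatments) != 2L || !all(treatments %in% .treatment_levels))
    stop("treatments must be a valid pair from C, A, O")
  share <- function(tr) {
    comp <- treatment_composition(fit, depth, tr)
    if (part == "aurita") comp[, 1] else rowSums(comp[, 3:5])
  }
  dr <- qlogis(share(treatments[1])) - qlogis(share(treatments[2]))
  qs <- quantile(dr, c(0.025, 0.975), names = FALSE)
  structure(list(draws = dr, mean = mean(dr), lower = qs[1], upper = qs[2],
                 part = part, treatments = treatments, depth = depth),
            class = "logit_contrast")
}

#' @export
print.logit_contrast <- function(x, digits = 2, ...) {
  cat(sprintf("logit(%s), %s - %s at %s m: posterior mean %.*f, 95%% CI (%.*f, %.*f)\n",
              x$part, x$treatments[1], x$treatments[2], format(x$depth),
              digits, x$mean, digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Orthogonal ternary decomposition of a treatment-cell composition
#'
#' Splits the fitted 5-part composition draws into the two 3-part displays:
#' (A. aurita, bare, gm(competitors)) via geometric-mean amalgamation, and
#' the subcomposition of the three competitor taxa. Under the default
#' sequential-binary-partition basis these correspond to the first two and
#' last two ilr coordinates respectively, so the decomposition is lossless.
#'
#' @param fit a `manova_fit`.
#' @param depth,treatment cell identifiers.
#' @return list with `amalgam` and `subcomp`, matrices of 3-part rows.
#' @export
effect_ternaries <- function(fit, depth, treatment) {
  comp <- treatment_composition(fit, depth, treatment)
  amal <- t(apply(comp, 1, gm_amalgamate))
  sub <- t(apply(comp, 1, subcomposition, parts = 3:5))
  list(amalgam = amal, subcomp = sub)
}

# bilinear interpolation of a kde2d grid at points
.interp2 <- function(kde, px, py) {
  ix <- findInterval(px, kde$x, all.inside = TRUE)
  iy <- findInterval(py, kde$y, all.inside = TRUE)
  fx <- (px - kde$x[ix]) / diff(kde$x)[1]
  fy <- (py - kde$y[iy]) / diff(kde$y)[1]
  kde$z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    kde$z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    kde$z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    kde$z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Highest-posterior-density region of 3-part composition draws
#'
#' Boundary of the smallest region containing the requested posterior mass,
#' estimated by a Gaussian kernel density in the 2-D ilr coordinates of the
#' 3-part composition (bandwidth by the normal reference rule) and mapped
#' back to ternary plot coordinates.
#'
#' @param samples matrix of 3-part compositions (rows), at least 1000.
#' @param level posterior mass (default 0.95).
#' @param basis 3-part contrast matrix.
#' @param gridsize kernel density grid resolution.
#' @return object of class `hpd_region`: list of boundary data.frames (ilr1,
#'   ilr2, x, y and the 3 parts), the density `threshold`, the `contained`
#'   fraction of samples, and a `degenerate` flag.
#' @export
hpd_region_2d <- function(samples, level = 0.95, basis = ternary_basis(),
                          gridsize = 151) {
  if (nrow(samples) < 1000) stop("need at least 1000 samples")
  Zc <- ilr(samples, basis)
  if (var(Zc[, 1]) < 1e-18 && var(Zc[, 2]) < 1e-18) {
    return(structure(list(boundary = list(), threshold = Inf, contained = 1,
                          degenerate = TRUE, center = colMeans(Zc)),
                     class = "hpd_region"))
  }
  pad <- 4 * c(MASS::bandwidth.nrd(Zc[, 1]), MASS::bandwidth.nrd(Zc[, 2]))
  kde <- MASS::kde2d(Zc[, 1], Zc[, 2], n = gridsize,
                     lims = c(range(Zc[, 1]) + c(-1, 1) * pad[1],
                              range(Zc[, 2]) + c(-1, 1) * pad[2]))
  dens <- .interp2(kde, Zc[, 1], Zc[, 2])
  thr <- quantile(dens, 1 - level, names = FALSE)
  cl <- grDevices::contourLines(kde$x, kde$y, kde$z, levels = thr)
  boundary <- lapply(cl, function(b) {
    comp <- ilr_inv(cbind(b$x, b$y), basis)
    xy <- ternary_xy(comp)
    data.frame(ilr1 = b$x, ilr2 = b$y, x = xy[, 1], y = xy[, 2],
               p1 = comp[, 1], p2 = comp[, 2], p3 = comp[, 3])
  })
  structure(list(boundary = boundary, threshold = thr,
                 contained = mean(dens >= thr), degenerate = FALSE),
            class = "hpd_region")
}

#' @export
print.hpd_region <- function(x, ...) {
  if (x$degenerate) cat("Degenerate (zero-variance) HPD region: a point\n")
  else cat(sprintf("HPD region: %d boundary curve(s), contains %.1f%% of samples\n",
                   length(x$boundary), 100 * x$contained))
  invisible(x)
}

#' @export
print.manova_fit <- function(x, ...) {
  cat("Hierarchical compositional MANOVA (", x$variant, " variant)\n", sep = "")
  cat("  ", nrow(x$data$counts), " panels, ", length(x$idx$blocks), " blocks, ",
      x$chains, " chains x ", x$iter - x$warmup, " post-warmup draws\n", sep = "")
  cat(sprintf("  max split R-hat %.3f, min bulk ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
summary.manova_fit <- function(object, ...) {
  d <- object$draws
  Ct <- .code_treat()
  qs <- function(M, nm) {
    data.frame(parameter = nm, mean = colMeans(M),
               lower = apply(M, 2, quantile, 0.025),
               upper = apply(M, 2, quantile, 0.975), row.names = NULL)
  }
  tabs <- list(qs(d$mu, paste0("mu[", 1:4, "]")))
  if (object$flags$depth)
    tabs <- c(tabs, list(qs(d$fa, paste0("alpha[1m,", 1:4, "]"))))
  if (object$flags$treatment) {
    for (k in 1:3) {
      B <- sapply(1:4, function(cc) d$fb[, c(2 * cc - 1, 2 * cc)] %*% Ct[k, ])
      tabs <- c(tabs, list(qs(B, paste0("beta[", .treatment_levels[k], ",", 1:4, "]"))))
    }
  }
  tabs <- c(tabs, list(qs(d$Z[, c(1, 6, 11, 16)], paste0("Z[", 1:4, ",", 1:4, "]")),
                       qs(d$Sigma[, c(1, 6, 11, 16)], paste0("Sigma[", 1:4, ",", 1:4, "]"))))
  out <- do.call(rbind, tabs)
  structure(list(table = out, diagnostics = object$diagnostics,
                 variant = object$variant), class = "summary.manova_fit")
}

#' @export
print.summary.manova_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (", x$variant, " variant)\n", sep = "")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("max R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
coef.manova_fit <- function(object, ...) {
  d <- object$draws
  Ct <- .code_treat()
  beta <- array(0, c(3, 4), dimnames = list(.treatment_levels, NULL))
  for (k in 1:3)
    beta[k, ] <- sapply(1:4, function(cc)
      mean(d$fb[, c(2 * cc - 1, 2 * cc)] %*% Ct[k, ]))
  list(mu = colMeans(d$mu),
       alpha = rbind(`1` = colMeans(d$fa), `2` = -colMeans(d$fa)),
       beta = beta,
       Z = matrix(colMeans(d$Z), 4, 4),
       Sigma = matrix(colMeans(d$Sigma), 4, 4))
}
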