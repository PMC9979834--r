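# Leave-one-cluster-out cross-validation for the compositional MANOVA.
# Clusters are blocks of panels: the natural "new observation" for this
# design is a new block, so predictive densities are marginal with respect
# to block and panel effects, integrated by Monte Carlo.

# subset a manova_data by block
.drop_block <- function(data, block) {
  keep <- data$design$block != block
  structure(list(counts = data$counts[keep, , drop = FALSE],
                 n = data$n[keep],
                 design = data$design[keep, , drop = FALSE],
                 parts = data$parts, week = data$week),
            class = "manova_data")
}

# log marginal predictive density of a held-out block given a fit:
# log (1/(S M)) sum_{s,m} prod_i multinomial(y_i | ilr_inv(fixed_i + delta_sm
# + eps_ism)), with delta ~ N(0, Z_s), eps ~ N(0, Sigma_s) simulated fresh.
.block_lpd <- function(fit, data, block, mc_draws = 400, mc_reps = 100) {
  sel <- data$design$block == block
  Y <- data$counts[sel, , drop = FALSE]
  idx_all <- .manova_index(data)
  j <- idx_all$j[sel]; k <- idx_all$k[sel]
  npan <- nrow(Y)
  d <- fit$draws
  S <- nrow(d$mu)
  use <- if (S > mc_draws) round(seq(1, S, length.out = mc_draws)) else seq_len(S)
  Vt <- unclass(fit$basis)
  Ct <- .code_treat()
  lconst <- mult_logpmf_rows(Y, matrix(1, npan, ncol(Y)))  # combinatorial part
  ll_sm <- matrix(NA_real_, length(use), mc_reps)
  for (si in seq_along(use)) {
    s <- use[si]
    # fixed part of eta per held-out panel
    eta_fix <- matrix(d$mu[s, ], npan, 4, byrow = TRUE)
    if (fit$flags$depth)
      eta_fix <- eta_fix + outer(ifelse(j == 1L, 1, -1), d$fa[s, ])
    if (fit$flags$treatment) {
      fb <- matrix(d$fb[s, ], 2, 4)
      beta <- Ct %*% fb
      eta_fix <- eta_fix + beta[k, , drop = FALSE]
    }
    if (fit$flags$interaction) {
      g <- matrix(d$g[s, ], 2, 4)
      Tm <- Ct %*% g
      eta_fix <- eta_fix + Tm[k, , drop = FALSE] * ifelse(j == 1L, 1, -1)
    }
    Zc <- chol(matrix(d$Z[s, ], 4, 4))
    Sc <- chol(matrix(d$Sigma[s, ], 4, 4))
    delta <- matrix(rnorm(mc_reps * 4), mc_reps, 4) %*% Zc
    eps <- matrix(rnorm(mc_reps * npan * 4), mc_reps * npan, 4) %*% Sc
    # rows grouped by replicate: (rep 1: panels 1..npan, rep 2: ...)
    eta <- eta_fix[rep(seq_len(npan), mc_reps), , drop = FALSE] +
      delta[rep(seq_len(mc_reps), each = npan), , drop = FALSE] + eps
    E <- eta %*% Vt
    ll_i <- rowSums(Y[rep(seq_len(npan), mc_reps), , drop = FALSE] * E) -
      rowSums(Y) * log(rowSums(exp(E))) + lconst
    ll_sm[si, ] <- colSums(matrix(ll_i, npan, mc_reps))
  }
  lls <- as.vector(ll_sm)
  lpd <- logsumexp(lls) - log(length(lls))
  # effective sample size of the (self-normalized) integration weights
  w <- exp(lls - max(lls))
  list(lpd = lpd, mc_ess = sum(w)^2 / sum(w^2))
}

#' Leave-one-cluster-out cross-validation over MANOVA variants
#'
#' For each model variant, refits the model with each block of panels left
#' out and computes the log predictive density of the held-out block, with
#' block and panel effects integrated out by Monte Carlo (fresh draws of
#' delta ~ N(0, Z) and epsilon ~ N(0, Sigma) per posterior draw). Reports
#' elpd (sum over blocks), the difference from the best variant, and the
#' standard error of each difference, sqrt(B) times the standard deviation
#' of the per-block differences.
#'
#' @param data a `manova_data` with at least 3 blocks.
#' @param variants character vector of variant names (see [fit_manova()]).
#' @param seed integer seed.
#' @param chains,iter,warmup sampler settings passed to [fit_manova()]
#'   (reduced defaults: LOCO refits the model `variants x blocks` times).
#' @param mc_draws posterior draws used in the integration.
#' @param mc_reps random-effect replicates per posterior draw.
#' @return object of class `elpd_comparison`: data.frame with columns
#'   `model`, `elpd`, `delta_elpd`, `se_diff`, plus attributes
#'   `block_lpd` (matrix) and `mc_ess_min`.
#' @export
loco_cv <- function(data, variants = c("no_interaction", "full",
                                       "no_treatment", "no_depth"),
                    seed = 1, chains = 2, iter = 1200, warmup = 600,
                    mc_draws = 400, mc_reps = 100) {
  blocks <- sort(unique(data$design$block))
  if (length(blocks) < 3L) stop("need at least 3 blocks")
  set.seed(seed)
  # seeds keyed by variant name so duplicated variants give identical fits
  uv <- unique(variants)
  seed_pool <- matrix(sample.int(2^31 - 2, length(uv) * length(blocks)),
                      length(uv), length(blocks))
  fit_seeds <- seed_pool[match(variants, uv), , drop = FALSE]
  lpd <- matrix(NA_real_, length(variants), length(blocks),
                dimnames = list(variants, paste0("block", blocks)))
  mc_ess <- lpd
  for (vi in seq_along(variants)) {
    for (bi in seq_along(blocks)) {
      train <- .drop_block(data, blocks[bi])
      fit <- fit_manova(train, variant = variants[vi], chains = chains,
                        iter = iter, warmup = warmup,
                        seed = fit_seeds[vi, bi])
      set.seed(fit_seeds[vi, bi] %% 2^30 + 1)
      r <- .block_lpd(fit, data, blocks[bi], mc_draws, mc_reps)
      lpd[vi, bi] <- r$lpd
      mc_ess[vi, bi] <- r$mc_ess
    }
  }
  elpd <- rowSums(lpd)
  best <- which.max(elpd)
  dl <- elpd - elpd[best]
  se <- vapply(seq_along(variants), function(vi) {
    if (vi == best) return(0)
    diffs <- lpd[vi, ] - lpd[best, ]
    sqrt(length(blocks)) * sd(diffs)
  }, numeric(1))
  ord <- order(-elpd)
  out <- data.frame(model = variants[ord], elpd = elpd[ord],
                    delta_elpd = dl[ord], se_diff = se[ord],
                    row.names = NULL)
  if (min(mc_ess) < 10)
    warning("Monte Carlo integration ESS below 10 for some blocks; ",
            "increase mc_reps")
  structure(out, class = c("elpd_comparison", "data.frame"),
            block_lpd = lpd, mc_ess_min = min(mc_ess),
            se_unit = "block")
}

#' @export
print.elpd_comparison <- function(x, digits = 1, ...) {
  cat("Model comparison by expected log predictive density\n")
  tab <- as.data.frame(x)
  tab$elpd <- round(tab$elpd, digits)
  tab$delta_elpd <- round(tab$delta_elpd, digits)
  tab$se_diff <- round(tab$se_diff, digits)
  if (!is.null(tab$khat_max)) tab$khat_max <- round(tab$khat_max, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
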