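# The five ODE models of competition for space between potential competitors
# (cover x) and A. aurita polyps (density y1, occupying area delta per polyp):
#
#   dx/dt  = a0 (1 - x - delta y1) + a1 x (1 - x - delta y1) + a2 x
#   dy1/dt = b0 (1 - x - delta y1) + b1 y1 (1 - x - delta y1) + b2 y1
#
# with one extra mechanism per non-basic variant: settlement facilitation
# (a0 -> a0 + m0 delta y1), growth facilitation (a1 -> a1 + m1 delta y1),
# overgrowth of polyps by competitors (+ a1y1 x y1 to dx/dt and
# - (a1y1/delta) x y1 to dy1/dt), or protection from predators
# (a2 -> a2 exp(-m2 delta y1)). Weekly removal events multiply y1 by
# (1 - r_A) or x by (1 - r_O).

.dyn_variants <- c("basic", "settlement_facilitation", "growth_facilitation",
                   "overgrowth", "protection")

.variant_id <- function(variant) {
  match(match.arg(variant, .dyn_variants), .dyn_variants) - 1L
}

.extra_name <- function(variant) {
  switch(variant, basic = NA_character_,
         settlement_facilitation = "m0", growth_facilitation = "m1",
         overgrowth = "a1y1", protection = "m2")
}

#' Rate parameters of a space-competition model
#'
#' Constructs and validates the parameter set of one model variant. Sign
#' constraints: settlement (`a0`, `b0`), growth/budding (`a1`, `b1`), area
#' per polyp (`delta`) and the variant parameter are positive; death rates
#' (`a2`, `b2`) are negative; removal fractions lie in (0, 1).
#'
#' @param variant one of "basic", "settlement_facilitation",
#'   "growth_facilitation", "overgrowth", "protection".
#' @param a0 competitor settlement rate (per week).
#' @param a1 competitor growth rate (per week).
#' @param a2 competitor death rate (per week, negative).
#' @param delta substrate area occupied per polyp.
#' @param b0 polyp settlement rate (polyps per area per week).
#' @param b1 polyp budding rate (per week).
#' @param b2 polyp death rate (per week, negative).
#' @param extra variant parameter: `m0` (settlement facilitation, per week),
#'   `m1` (growth facilitation, per week), `a1y1` (overgrowth rate, area per
#'   polyp per week), or `m2` (protection, dimensionless). Ignored for
#'   "basic".
#' @param r_A,r_O removal fractions for the polyp (A) and competitor (O)
#'   treatments.
#' @return object of class `dyn_params`.
#' @export
dyn_params <- function(variant = "basic", a0, a1, a2, delta = 1, b0, b1, b2,
                       extra = 0, r_A = 0.5, r_O = 0.5) {
  variant <- match.arg(variant, .dyn_variants)
  if (!(a0 > 0 && a1 > 0 && b0 > 0 && b1 > 0 && delta > 0))
    stop("a0, a1, b0, b1, delta must be positive")
  if (!(a2 < 0 && b2 < 0)) stop("death rates a2, b2 must be negative")
  if (variant != "basic" && extra < 0)
    stop("variant parameter must be nonnegative")
  if (!(r_A > 0 && r_A < 1 && r_O > 0 && r_O < 1))
    stop("removal fractions must lie in (0, 1)")
  structure(list(variant = variant, a0 = a0, a1 = a1, a2 = a2, delta = delta,
                 b0 = b0, b1 = b1, b2 = b2, extra = extra,
                 extra_name = .extra_name(variant), r_A = r_A, r_O = r_O),
            class = "dyn_params")
}

#' @export
print.dyn_params <- function(x, ...) {
  cat("Space-competition model parameters (", x$variant, ")\n", sep = "")
  v <- unlist(x[c("a0", "a1", "a2", "delta", "b0", "b1", "b2")])
  if (x$variant != "basic") v <- c(v, setNames(x$extra, x$extra_name))
  v <- c(v, r_A = x$r_A, r_O = x$r_O)
  print(round(v, 4))
  invisible(x)
}

# internal relative-abundance parameter vector (a0, a1, a2, delta*b0, b1, b2,
# extra), with the overgrowth rate rescaled to a1y1/delta
.upar <- function(params) {
  extra_u <- if (params$variant == "overgrowth") params$extra / params$delta
             else params$extra
  c(params$a0, params$a1, params$a2, params$delta * params$b0,
    params$b1, params$b2, extra_u)
}

#' Right-hand side of a space-competition model
#'
#' Exact evaluation of (dx/dt, dy1/dt) at a state.
#'
#' @param params a `dyn_params`.
#' @param x competitor cover, in `[0, 1]`.
#' @param y1 polyp density (so `delta * y1` is polyp cover).
#' @return named vector (dx, dy1).
#' @export
dyn_rhs <- function(params, x, y1) {
  d <- params$delta
  F <- 1 - x - d * y1
  a0 <- params$a0; a1 <- params$a1; a2 <- params$a2
  dx <- switch(params$variant,
    basic = a0 * F + a1 * x * F + a2 * x,
    settlement_facilitation = (a0 + params$extra * d * y1) * F + a1 * x * F + a2 * x,
    growth_facilitation = a0 * F + (a1 + params$extra * d * y1) * x * F + a2 * x,
    overgrowth = a0 * F + a1 * x * F + params$extra * x * y1 + a2 * x,
    protection = a0 * F + a1 * x * F + a2 * exp(-params$extra * d * y1) * x)
  dy1 <- params$b0 * F + params$b1 * y1 * F + params$b2 * y1
  if (params$variant == "overgrowth")
    dy1 <- dy1 - params$extra / d * x * y1
  c(dx = dx, dy1 = dy1)
}

# build the checkpoint matrix (time, action) for a schedule data.frame
# (week, action in {"A","O"}) and output times
.checkpoints <- function(times, schedule) {
  act <- integer(length(times))
  if (nrow(schedule)) {
    m <- match(times, schedule$week)
    hit <- !is.na(m)
    act[hit] <- ifelse(schedule$action[m[hit]] == "A", 1L, 2L)
  }
  cbind(time = times, action = act)
}

#' Solve a space-competition model with removal events
#'
#' Integrates the ODE system with an adaptive Dormand-Prince RK45 method
#' (relative tolerance 1e-8). At each scheduled application the state is
#' reduced instantaneously: an "A" action multiplies the polyp density by
#' (1 - r_A), an "O" action multiplies competitor cover by (1 - r_O). Both
#' the pre- and post-event states are reported at event times.
#'
#' @param params a `dyn_params`.
#' @param schedule data.frame with columns `week` and `action` ("A"/"O");
#'   empty for a control panel.
#' @param times output times (weeks since deployment), sorted, > 0.
#' @param init initial state c(x, y1) at t = 0 (deployment: empty panel).
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `phase` ("pre"/"post"; post rows
#'   only at event times), `x`, `y1`.
#' @export
solve_dynamics <- function(params, schedule = NULL, times = 1:8,
                           init = c(0, 0), rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "dyn_params"))
  if (is.null(schedule))
    schedule <- data.frame(week = integer(0), action = character(0))
  if (is.unsorted(times)) stop("times must be sorted")
  cp <- .checkpoints(times, schedule)
  u0 <- c(init[1], params$delta * init[2])
  st <- solve_dyn_cpp(.variant_id(params$variant), .upar(params), cp,
                      params$r_A, params$r_O, u0[1], u0[2], rtol, atol)
  pre <- data.frame(time = times, phase = "pre", x = st[, 1],
                    y1 = st[, 2] / params$delta)
  ev <- cp[, 2] > 0
  if (any(ev)) {
    post <- data.frame(time = times[ev], phase = "post", x = st[ev, 3],
                       y1 = st[ev, 4] / params$delta)
    out <- rbind(pre, post)
    out <- out[order(out$time, out$phase != "pre"), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  pre
}

#' Community matrix of interaction strengths
#'
#' Analytic partial derivatives of the proportional rates of change of the
#' relative abundances u1 = x (competitors) and u2 = delta * y1 (polyps)
#' with respect to (u1, u2), at an interior state. Entry (1,2) is the
#' effect of polyps on the proportional growth rate of competitors; in the
#' basic model all four entries are negative.
#'
#' @param params a `dyn_params`.
#' @param x,y1 interior state (x > 0, y1 > 0, x + delta*y1 < 1).
#' @return 2 x 2 matrix, rows/columns ordered (competitors, polyps).
#' @export
community_matrix <- function(params, x, y1) {
  d <- params$delta
  u1 <- x; u2 <- d * y1
  if (!(u1 > 0 && u2 > 0 && u1 + u2 < 1))
    stop("community matrix requires an interior state")
  F <- 1 - u1 - u2
  a0 <- params$a0; a1 <- params$a1; a2 <- params$a2
  B0 <- d * params$b0; b1 <- params$b1; b2 <- params$b2
  ex <- params$extra
  # competitor row
  M11 <- -a0 * (F + u1) / u1^2 - a1
  M12 <- -a0 / u1 - a1
  if (params$variant == "settlement_facilitation") {
    M11 <- -(a0 + ex * u2) * (F + u1) / u1^2 - a1
    M12 <- ex * F / u1 - (a0 + ex * u2) / u1 - a1
  } else if (params$variant == "growth_facilitation") {
    M11 <- -a0 * (F + u1) / u1^2 - (a1 + ex * u2)
    M12 <- -a0 / u1 - (a1 + ex * u2) + ex * F
  } else if (params$variant == "overgrowth") {
    M12 <- -a0 / u1 - a1 + ex / d
  } else if (params$variant == "protection") {
    M12 <- -a0 / u1 - a1 - ex * a2 * exp(-ex * u2)
  }
  # polyp row
  M21 <- -B0 / u2 - b1
  M22 <- -B0 * (F + u2) / u2^2 - b1
  if (params$variant == "overgrowth") M21 <- M21 - ex / d
  matrix(c(M11, M21, M12, M22), 2, 2,
         dimnames = list(c("competitors", "polyps"),
                         c("competitors", "polyps")))
}

#' Effect of polyps on competitors over the composition simplex
#'
#' Evaluates community-matrix entry (1,2) -- the effect of polyp cover on
#' the proportional growth rate of potential competitors -- on a grid over
#' the 2-simplex of (competitor cover, polyp cover, free space), excluding a
#' boundary margin.
#'
#' @param params a `dyn_params`.
#' @param resolution grid steps along each axis.
#' @param eps boundary exclusion margin (default 1e-3).
#' @return data.frame with columns `u1`, `u2`, `free`, `effect`.
#' @export
polyp_effect_field <- function(params, resolution = 40, eps = 1e-3) {
  s <- seq(eps, 1 - eps, length.out = resolution)
  grid <- expand.grid(u1 = s, u2 = s)
  grid <- grid[grid$u1 + grid$u2 <= 1 - eps, ]
  grid$free <- 1 - grid$u1 - grid$u2
  grid$effect <- vapply(seq_len(nrow(grid)), function(i)
    community_matrix(params, grid$u1[i], grid$u2[i] / params$delta)[1, 2],
    numeric(1))
  rownames(grid) <- NULL
  grid
}
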