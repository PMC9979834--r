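#' Point-count category vocabulary
#'
#' The nine fixed categories recorded at each of the ~100 random points per
#' photograph. Polyps growing on potential competitors are recorded separately
#' from those growing directly on the panel.
#' @return character vector of category names, in canonical order.
#' @export
panel_categories <- function() {
  c("aurita_panel", "aurita_competitor", "bare", "botrylloides", "bugula",
    "molgula", "ascidiella", "botryllus", "other")
}

# categories counted as potential competitors in the dynamics aggregation
.competitor_categories <- function() {
  c("botrylloides", "bugula", "molgula", "ascidiella", "botryllus", "other")
}

#' Assemble an experiment table from its components
#'
#' @param counts long-format data.frame with columns `panel`, `week`, `phase`
#'   ("pre"/"post"), `category`, `count`. One row per category per
#'   panel-week-phase; totals per observation should equal the number of
#'   points counted (100 for full photographs).
#' @param meta data.frame with columns `panel`, `block` (1..B), `depth`
#'   (metres, two levels), `treatment` ("C", "A", "O"), and optional
#'   `mistaken_week` (NA except for a control panel mistakenly treated once).
#' @param env data.frame with columns `week`, `depth`, `dissolved_oxygen`,
#'   `temperature`, `salinity` (NA where not measured).
#' @param applications optional data.frame (`panel`, `week`) of actual
#'   treatment applications; derived from the typical schedules and
#'   `mistaken_week` when omitted.
#' @param validate check invariants (default TRUE).
#' @param points points per full photograph (validation bound, default 100).
#' @return object of class `experiment_table`.
#' @export
experiment_table <- function(counts, meta, env, applications = NULL,
                             validate = TRUE, points = 100) {
  counts$panel <- as.character(counts$panel)
  meta$panel <- as.character(meta$panel)
  if (is.null(meta$mistaken_week)) meta$mistaken_week <- NA_integer_
  if (is.null(applications))
    applications <- derive_schedule(meta, max(counts$week))
  applications$panel <- as.character(applications$panel)
  tbl <- structure(list(counts = counts, meta = meta, env = env,
                        applications = applications, points = points),
                   class = "experiment_table")
  if (validate) validate_experiment(tbl, points)
  tbl
}

#' Typical treatment schedules
#'
#' Removal applications begin in the second sampling week for the potential
#' competitor removal (O) and the third week for the polyp removal (A);
#' controls receive none apart from any recorded mistaken application.
#'
#' @param meta panel metadata (see [experiment_table()]).
#' @param n_weeks number of weekly samplings.
#' @return data.frame with columns `panel`, `week`, `action` ("A": polyp
#'   removal, applied to the polyp density; "O": competitor removal, applied
#'   to competitor cover). A mistaken application on a control panel is an
#'   "A" action.
#' @export
derive_schedule <- function(meta, n_weeks = 8) {
  out <- list()
  for (i in seq_len(nrow(meta))) {
    wk <- switch(meta$treatment[i],
                 C = integer(0),
                 A = seq(3L, n_weeks),
                 O = seq(2L, n_weeks),
                 stop("unknown treatment ", meta$treatment[i]))
    act <- rep(meta$treatment[i], length(wk))
    if (!is.na(meta$mistaken_week[i]) && !(meta$mistaken_week[i] %in% wk)) {
      wk <- c(wk, meta$mistaken_week[i])
      act <- c(act, "A")
      ord <- order(wk); wk <- wk[ord]; act <- act[ord]
    }
    if (length(wk))
      out[[length(out) + 1L]] <- data.frame(panel = meta$panel[i], week = wk,
                                            action = act)
  }
  if (!length(out))
    return(data.frame(panel = character(0), week = integer(0),
                      action = character(0)))
  do.call(rbind, out)
}

#' Validate an experiment table
#'
#' Checks the schemas and invariants: known categories; counts nonnegative
#' integers; referential integrity between counts and metadata; one panel per
#' block x depth x treatment; post-phase counts equal to pre-phase counts in
#' weeks with no treatment application; totals constant within a
#' panel-week-phase.
#'
#' @param tbl an `experiment_table`.
#' @param points_per_photo maximum total per photograph (default: the table's
#'   recorded `points`, or 100).
#' @param warn_other warn when the residual "other" category exceeds
#'   `other_threshold` points on any photograph (in the study no other taxon
#'   contributed more than seven points; off by default so synthetic tables
#'   validate silently).
#' @param other_threshold threshold for the "other" warning.
#' @return invisibly TRUE; stops with a message listing offending rows.
#' @export
validate_experiment <- function(tbl, points_per_photo = NULL,
                                warn_other = FALSE, other_threshold = 7) {
  points_per_photo <- points_per_photo %||% tbl$points %||% 100
  if (warn_other) {
    oth <- tbl$counts[tbl$counts$category == "other", ]
    if (any(oth$count > other_threshold))
      warning("'other' exceeds ", other_threshold, " points on: ",
              paste(head(unique(oth$panel[oth$count > other_threshold])),
                    collapse = ", "))
  }
  counts <- tbl$counts; meta <- tbl$meta
  need <- c("panel", "week", "phase", "category", "count")
  if (!all(need %in% names(counts)))
    stop("counts table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(counts$category), panel_categories())
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be nonnegative integers")
  if (!all(counts$phase %in% c("pre", "post"))) stop("phase must be pre/post")
  orphan <- setdiff(unique(counts$panel), meta$panel)
  if (length(orphan)) stop("count rows for unknown panels: ",
                           paste(orphan, collapse = ", "))
  dup <- duplicated(meta[, c("block", "depth", "treatment")])
  if (any(dup)) stop("more than one panel per block x depth x treatment: ",
                     paste(meta$panel[dup], collapse = ", "))
  # totals: every panel-week-phase must have one row per category
  key <- interaction(counts$panel, counts$week, counts$phase, drop = TRUE)
  sizes <- tapply(counts$count, key, length)
  if (any(sizes != length(panel_categories())))
    stop("observations with missing category rows: ",
         paste(head(names(sizes)[sizes != length(panel_categories())]), collapse = ", "))
  totals <- tapply(counts$count, key, sum)
  if (any(totals > points_per_photo))
    stop("observations with more than ", points_per_photo, " points: ",
         paste(head(names(totals)[totals > points_per_photo]), collapse = ", "))
  # post == pre when no application that week
  W <- counts_wide(tbl)
  app_key <- paste(tbl$applications$panel, tbl$applications$week)
  pre <- W[W$phase == "pre", ]
  post <- W[W$phase == "post", ]
  m <- match(paste(post$panel, post$week), paste(pre$panel, pre$week))
  applied <- paste(post$panel, post$week) %in% app_key
  cats <- panel_categories()
  if (any(!applied)) {
    same <- rowSums(abs(as.matrix(post[!applied, cats]) -
                        as.matrix(pre[m[!applied], cats]))) == 0
    if (any(!same))
      stop("post-phase counts differ from pre-phase in weeks without application: ",
           paste(head(paste(post$panel[!applied][!same], post$week[!applied][!same])),
                 collapse = ", "))
  }
  invisible(TRUE)
}

#' Counts in wide form
#'
#' One row per panel-week-phase with one column per category plus the total.
#' @param tbl an `experiment_table`.
#' @return data.frame with columns panel, week, phase, one per category, n.
#' @export
counts_wide <- function(tbl) {
  counts <- tbl$counts
  cats <- panel_categories()
  key <- paste(counts$panel, counts$week, counts$phase, sep = "\r")
  ids <- !duplicated(key)
  out <- counts[ids, c("panel", "week", "phase")]
  M <- matrix(0L, sum(ids), length(cats), dimnames = list(NULL, cats))
  row_i <- match(key, key[ids])
  col_i <- match(counts$category, cats)
  M[cbind(row_i, col_i)] <- as.integer(counts$count)
  out <- cbind(out, as.data.frame(M))
  out$n <- rowSums(M)
  out[order(out$panel, out$week, out$phase != "pre"), , drop = FALSE]
}

#' Read an experiment from CSV files
#'
#' @param count_path,meta_path,env_path CSV files matching the documented
#'   schemas (see [experiment_table()]).
#' @param applications_path optional CSV of actual applications.
#' @return validated `experiment_table`.
#' @export
read_experiment <- function(count_path, meta_path, env_path,
                            applications_path = NULL) {
  counts <- read.csv(count_path, stringsAsFactors = FALSE)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  env <- read.csv(env_path, stringsAsFactors = FALSE)
  app <- if (!is.null(applications_path))
    read.csv(applications_path, stringsAsFactors = FALSE) else NULL
  experiment_table(counts, meta, env, app)
}

#' Write an experiment to CSV files
#' @param tbl an `experiment_table`.
#' @param dir output directory (created if needed).
#' @return invisibly the paths written.
#' @export
write_experiment <- function(tbl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "meta.csv", "env.csv", "applications.csv"))
  write.csv(tbl$counts, paths[1], row.names = FALSE)
  write.csv(tbl$meta, paths[2], row.names = FALSE)
  write.csv(tbl$env, paths[3], row.names = FALSE)
  write.csv(tbl$applications, paths[4], row.names = FALSE)
  invisible(paths)
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("Settlement-panel experiment:", nrow(x$meta), "panels,",
      length(unique(x$counts$week)), "weekly samplings\n")
  cat("  depths:", paste(sort(unique(x$meta$depth)), collapse = ", "),
      "m; treatments:", paste(sort(unique(x$meta$treatment)), collapse = ", "), "\n")
  cat("  treatment applications recorded:", nrow(x$applications), "\n")
  invisible(x)
}

#' Final-composition dataset for the compositional MANOVA
#'
#' Takes the pre-treatment counts from the final sampling week and restricts
#' to five parts: polyps directly on the panel, bare panel, and the taxa
#' contributing at least `min_points` points on at least one panel (in the
#' study: Botrylloides spp., Bugula spp., M. tubifera). The panel that
#' mistakenly received a removal application while assigned to the control is
#' treated as a control here. Polyps on competitors and taxa below the
#' threshold are excluded; totals are the sums of the retained parts.
#'
#' @param tbl an `experiment_table`.
#' @param min_points inclusion threshold for named taxa (default 20).
#' @return object of class `manova_data`: list with `counts` (panels x 5
#'   matrix), `n` totals, `design` (panel, block, depth, treatment),
#'   `parts` (part names).
#' @export
manova_subset <- function(tbl, min_points = 20) {
  W <- counts_wide(tbl)
  wk <- max(W$week)
  W <- W[W$week == wk & W$phase == "pre", ]
  missing_p <- setdiff(tbl$meta$panel, W$panel)
  if (length(missing_p))
    stop("no final-week pre-treatment data for panels: ",
         paste(missing_p, collapse = ", "))
  taxa <- setdiff(panel_categories(),
                  c("aurita_panel", "aurita_competitor", "bare", "other"))
  keep_taxa <- taxa[vapply(taxa, function(tx) any(W[[tx]] >= min_points), logical(1))]
  parts <- c("aurita_panel", "bare", keep_taxa)
  M <- as.matrix(W[, parts, drop = FALSE])
  # assigned treatment labels: the mistakenly-treated control keeps label C,
  # i.e. it is analysed as a control in the final-composition model
  design <- tbl$meta[match(W$panel, tbl$meta$panel),
                     c("panel", "block", "depth", "treatment")]
  rownames(M) <- design$panel
  structure(list(counts = M, n = rowSums(M), design = design, parts = parts,
                 week = wk),
            class = "manova_data")
}

#' @export
print.manova_data <- function(x, ...) {
  cat("Final-composition dataset: ", nrow(x$counts), " panels x ",
      ncol(x$counts), " parts (week ", x$week, ", pre-treatment)\n", sep = "")
  cat("  parts:", paste(x$parts, collapse = ", "), "\n")
  cat("  totals:", min(x$n), "-", max(x$n), "points\n")
  invisible(x)
}

#' Three-category time series for the dynamic models
#'
#' Aggregates each observation to (polyps on panel, bare panel, potential
#' competitors), where competitors comprise all remaining sessile taxa
#' including "other". Points recording polyps on competitors are excluded
#' from all three categories (they were very few), so the observation total
#' is the photograph total minus those points. Control panels contribute one
#' record per week (their post phase duplicates the pre phase); treated
#' panels contribute the post phase only in weeks when the removal was
#' actually applied.
#'
#' @param tbl an `experiment_table`.
#' @return object of class `dynamics_data`: list with `obs` (data.frame:
#'   panel, week, phase, aurita, bare, competitors, n, depth, treatment,
#'   block, applied), `schedules` (named list of application weeks per
#'   panel), `meta`.
#' @export
dynamics_dataset <- function(tbl) {
  W <- counts_wide(tbl)
  comp <- rowSums(as.matrix(W[, .competitor_categories()]))
  obs <- data.frame(panel = W$panel, week = W$week, phase = W$phase,
                    aurita = W$aurita_panel, bare = W$bare, competitors = comp,
                    n = W$aurita_panel + W$bare + comp,
                    stringsAsFactors = FALSE)
  mi <- match(obs$panel, tbl$meta$panel)
  obs$depth <- tbl$meta$depth[mi]
  obs$treatment <- tbl$meta$treatment[mi]
  obs$block <- tbl$meta$block[mi]
  app_key <- paste(tbl$applications$panel, tbl$applications$week)
  obs$applied <- paste(obs$panel, obs$week) %in% app_key
  keep <- obs$phase == "pre" | obs$applied
  obs <- obs[keep, , drop = FALSE]
  obs <- obs[order(obs$panel, obs$week, obs$phase != "pre"), , drop = FALSE]
  rownames(obs) <- NULL
  app <- tbl$applications
  if (is.null(app$action)) {
    app$action <- tbl$meta$treatment[match(app$panel, tbl$meta$panel)]
    app$action[app$action == "C"] <- "A"
  }
  schedules <- split(app[, c("week", "action")], app$panel)
  schedules <- lapply(schedules, function(s) s[order(s$week), , drop = FALSE])
  empty <- setdiff(tbl$meta$panel, names(schedules))
  schedules[empty] <- list(data.frame(week = integer(0), action = character(0)))
  structure(list(obs = obs, schedules = schedules, meta = tbl$meta),
            class = "dynamics_data")
}

#' @export
print.dynamics_data <- function(x, ...) {
  cat("Dynamics dataset:", nrow(x$obs), "observations on",
      length(unique(x$obs$panel)), "panels\n")
  cat("  categories: polyps on panel / bare / potential competitors\n")
  invisible(x)
}
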