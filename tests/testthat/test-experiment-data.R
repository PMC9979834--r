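test_that("experiment tables validate and round-trip through CSV", {
  tbl <- tiny_experiment()
  expect_true(validate_experiment(tbl))
  W <- counts_wide(tbl)
  expect_equal(nrow(W[W$phase == "pre", ]), 4)  # 2 panels x 2 weeks
  expect_true(all(W$n == 100))
  dir <- tempfile()
  write_experiment(tbl, dir)
  tbl2 <- read_experiment(file.path(dir, "counts.csv"),
                          file.path(dir, "meta.csv"),
                          file.path(dir, "env.csv"),
                          file.path(dir, "applications.csv"))
  expect_equal(counts_wide(tbl2), counts_wide(tbl))
  expect_equal(tbl2$applications$week, tbl$applications$week)
})

test_that("validation rejects malformed tables with informative errors", {
  tbl <- tiny_experiment()
  bad <- tbl
  bad$counts$category[1] <- "kraken"
  expect_error(validate_experiment(bad), "unknown categories")
  bad <- tbl
  bad$counts$count[1] <- -1
  expect_error(validate_experiment(bad), "nonnegative")
  bad <- tbl
  bad$counts <- bad$counts[-1, ]  # missing category row
  expect_error(validate_experiment(bad), "missing category")
  # post differing from pre in a week without application
  bad <- tiny_experiment()
  i <- with(bad$counts, which(panel == "p1" & week == 1 & phase == "post" &
                                category == "bare"))
  j <- with(bad$counts, which(panel == "p1" & week == 1 & phase == "post" &
                                category == "molgula"))
  bad$counts$count[i] <- bad$counts$count[i] - 1
  bad$counts$count[j] <- bad$counts$count[j] + 1
  expect_error(validate_experiment(bad), "without application")
  # duplicated design cell
  bad <- tiny_experiment()
  bad$meta$depth[2] <- 1
  bad$meta$treatment[2] <- "C"
  expect_error(validate_experiment(bad), "more than one panel")
})

test_that("synthetic full design round-trips write/read identically", {
  sim <- generate_dynamics_experiment(seed = 99,
                                      design = design_spec(n_blocks = 2))
  dir <- tempfile()
  write_experiment(sim$table, dir)
  tbl2 <- read_experiment(file.path(dir, "counts.csv"),
                          file.path(dir, "meta.csv"),
                          file.path(dir, "env.csv"),
                          file.path(dir, "applications.csv"))
  expect_identical(counts_wide(tbl2), counts_wide(sim$table))
})

test_that("manova subset selects the five analysis parts from final-week data", {
  sim <- generate_dynamics_experiment(seed = 4)
  md <- manova_subset(sim$table)
  expect_s3_class(md, "manova_data")
  expect_equal(nrow(md$counts), 60)
  # the named taxa reaching 20 points on some panel are included for all
  W <- counts_wide(sim$table)
  W <- W[W$week == 8 & W$phase == "pre", ]
  taxa <- c("botrylloides", "bugula", "molgula", "ascidiella", "botryllus")
  expected <- taxa[vapply(taxa, function(tx) any(W[[tx]] >= 20), logical(1))]
  expect_setequal(md$parts, c("aurita_panel", "bare", expected))
  # totals equal the sum of retained parts and stay within the photo total
  expect_equal(md$n, rowSums(md$counts))
  expect_true(all(md$n <= 100))
  # the mistakenly treated control keeps its control label
  mk <- sim$table$meta$panel[!is.na(sim$table$meta$mistaken_week)]
  expect_equal(md$design$treatment[md$design$panel == mk], "C")
  # idempotent under category reordering of the long table
  shuf <- sim$table
  set.seed(1)
  shuf$counts <- shuf$counts[sample(nrow(shuf$counts)), ]
  md2 <- manova_subset(shuf)
  expect_equal(md2$counts[rownames(md$counts), md$parts], md$counts)
})

test_that("manova subset reproduces the worked selection example", {
  tbl <- tiny_experiment()
  ex <- c(aurita_panel = 5, bare = 40, botrylloides = 10, bugula = 20,
          molgula = 20, other = 5)
  ex2 <- c(aurita_panel = 5, bare = 40, botrylloides = 25, bugula = 15,
           molgula = 10, other = 5)
  tbl$counts <- rbind(
    tiny_counts_row("p1", 1, "pre", ex), tiny_counts_row("p1", 1, "post", ex),
    tiny_counts_row("p2", 1, "pre", ex2), tiny_counts_row("p2", 1, "post", ex2))
  md <- manova_subset(tbl)
  # botrylloides reaches 20 points on p2, so it is included for all panels
  expect_equal(md$parts, c("aurita_panel", "bare", "botrylloides", "bugula",
                           "molgula"))
  expect_equal(unname(md$counts["p1", ]), c(5, 40, 10, 20, 20))
  expect_equal(unname(md$n["p1"]), 95)
})

test_that("dynamics dataset aggregates to three categories and drops duplicate posts", {
  tbl <- tiny_experiment()
  dd <- dynamics_dataset(tbl)
  # control panel p1 contributes once per week
  expect_equal(sum(dd$obs$panel == "p1"), 2)
  expect_true(all(dd$obs$phase[dd$obs$panel == "p1"] == "pre"))
  # treated panel p2 contributes the post phase only at its application week
  expect_equal(dd$obs$week[dd$obs$panel == "p2" & dd$obs$phase == "post"], 2)
  # aggregation: week 2 pre counts (5 aurita, 55 bare, 40 competitors)
  r <- dd$obs[dd$obs$panel == "p2" & dd$obs$week == 2 & dd$obs$phase == "pre", ]
  expect_equal(c(r$aurita, r$bare, r$competitors, r$n), c(5, 55, 40, 100))
})

test_that("polyps on competitors are excluded from the three categories", {
  tbl <- tiny_experiment()
  w <- c(aurita_panel = 3, aurita_competitor = 2, bare = 57,
         botrylloides = 10, bugula = 10, molgula = 16, other = 2)
  tbl$counts <- rbind(
    tiny_counts_row("p1", 1, "pre", w), tiny_counts_row("p1", 1, "post", w),
    tiny_counts_row("p2", 1, "pre", w), tiny_counts_row("p2", 1, "post", w))
  tbl$applications <- data.frame(panel = character(0), week = integer(0),
                                 action = character(0))
  dd <- dynamics_dataset(tbl)
  r <- dd$obs[dd$obs$panel == "p1", ]
  expect_equal(c(r$aurita, r$bare, r$competitors), c(3, 57, 38))
  expect_equal(r$n, 98)
  # conservation: three-category total plus excluded polyps = photo total
  expect_equal(r$n + 2, 100)
})
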