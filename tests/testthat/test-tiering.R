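test_that("RPKM values bin into left-closed tiers", {
  expect_equal(rpkm_to_tier(150), 5L)
  expect_equal(rpkm_to_tier(0), 1L)
  expect_equal(rpkm_to_tier(c(19.99, 20, 40, 60, 100)), 1:5)
  expect_error(rpkm_to_tier(-1), "non-negative")
  # monotone, and every value maps to exactly one tier
  v <- sort(c(runif(200, 0, 200), 20, 40, 60, 100))
  t <- rpkm_to_tier(v)
  expect_true(all(diff(t) >= 0))
  expect_true(all(t %in% 1:5))
})

test_that("tier scheme validates its thresholds", {
  expect_error(tier_scheme(boundaries = c(40, 20)), "strictly increasing")
  expect_error(tier_scheme(detection_threshold = 25), "below the first")
  expect_error(tier_scheme(high_threshold = 61), "one of the tier boundaries")
  s <- tier_scheme(boundaries = c(10, 50), high_threshold = 50)
  expect_equal(s$n_tiers, 3L)
})

test_that("per-region tiers use the maximum across time points", {
  # the worked example: 150 RPKM at 24wg, 80 at all other time points
  ages <- c("24wg", "35wg", "4mo", "1y")
  at <- toy_atlas(matrix(c(150, 80, 80, 80,
                           0, 0, 0, 0,
                           0.5, 59.9, 1, 1), 3, byrow = TRUE),
                  rep("Hipp", 4), ages, genes = c("EX", "ZERO", "MID"))
  a <- assign_region_tiers(at)
  ex <- a[a$gene == "EX", ]
  expect_equal(ex$tier, 5L)
  expect_true(ex$detected && ex$highly_expressed)
  z <- a[a$gene == "ZERO", ]
  expect_equal(z$tier, 1L)
  expect_false(z$detected || z$highly_expressed)
  md <- a[a$gene == "MID", ]
  expect_equal(md$tier, 3L)
  expect_true(md$detected)
  expect_false(md$highly_expressed)
})

test_that("tier of the max equals the max of per-sample tiers", {
  gen <- generate_atlas(atlas_spec(n_genes = 40, n_housekeeping = 8,
                                   n_high = 6, n_silent = 4,
                                   n_pan_region_high = 2, seed = 5))
  at <- gen$atlas
  a <- assign_region_tiers(at)
  for (r in unique(a$region)) {
    cols <- at$samples$region == r
    sample_tier_max <- apply(
      matrix(rpkm_to_tier(at$values[, cols, drop = FALSE]),
             nrow = nrow(at$values)), 1, max)
    expect_equal(a$tier[a$region == r][match(at$genes, a$gene[a$region == r])],
                 unname(sample_tier_max))
  }
})

test_that("span reports count consecutive tiers on per-sample values", {
  at <- toy_atlas(matrix(c(10, 30, 55,
                           10, 120, 10,
                           25, 25, 25), 3, byrow = TRUE),
                  rep("Hipp", 3), c("24wg", "1y", "4y"),
                  genes = c("HK", "DIFF", "CONST"))
  sr <- span_report(at)
  expect_equal(sr$span[sr$gene == "HK"], 3L)
  expect_false(sr$differential[sr$gene == "HK"])
  expect_equal(sr$span[sr$gene == "DIFF"], 5L)
  expect_true(sr$differential[sr$gene == "DIFF"])
  expect_equal(sr$span[sr$gene == "CONST"], 1L)
  expect_error(span_report(at, genes = "NOPE"), "NOPE")
})

test_that("differential flag ignores samples inside the existing tier range", {
  base <- toy_atlas(matrix(c(10, 120), 1), rep("Hipp", 2), c("24wg", "1y"),
                    genes = "G")
  more <- toy_atlas(matrix(c(10, 120, 30, 70), 1), rep("Hipp", 4),
                    c("24wg", "1y", "4y", "8y"), genes = "G")
  expect_equal(span_report(base)$differential, span_report(more)$differential)
  expect_equal(span_report(base)$span, span_report(more)$span)
})

test_that("housekeeping calibration flags genes exceeding the span limit", {
  gen <- generate_atlas(atlas_spec(n_genes = 60, n_housekeeping = 21,
                                   n_high = 5, n_silent = 5,
                                   n_pan_region_high = 0, seed = 9))
  hk <- gen$truth$gene[gen$truth$class == "housekeeping"]
  cal <- housekeeping_calibration(gen$atlas, hk)
  expect_equal(cal$n_within_limit, 21L)
  expect_length(cal$offending, 0L)
  expect_true(cal$passed)
  # one wide-span gene lands in the offending list
  wide <- toy_atlas(matrix(c(5, 150, 30, 30), 2, byrow = TRUE),
                    rep("Hipp", 2), c("24wg", "1y"),
                    genes = c("WIDE", "FLAT"))
  cal2 <- housekeeping_calibration(wide, c("WIDE", "FLAT"))
  expect_equal(cal2$offending, "WIDE")
  expect_false(cal2$passed)
  # a single constant gene passes
  expect_true(housekeeping_calibration(wide, "FLAT")$passed)
  expect_error(housekeeping_calibration(wide, character(0)), "empty")
})

test_that("tier heatmaps export deterministically and round-trip", {
  at <- toy_atlas(matrix(c(150, 3), 1), c("Cere", "Hipp"), c("1y", "1y"),
                  genes = "G01")
  a <- assign_region_tiers(at)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap(a, path)
  lines <- readLines(path)
  expect_equal(lines[1], "gene\tHipp\tCere")  # canonical region order
  expect_equal(lines[2], "G01\t1\t5")
  # empty assignments give a header-only file
  export_heatmap(a[0, ], path)
  expect_length(readLines(path), 1L)
  # round-trip reproduces the tier matrix of a larger atlas
  gen <- generate_atlas(atlas_spec(n_genes = 30, n_housekeeping = 5,
                                   n_high = 4, n_silent = 3,
                                   n_pan_region_high = 1, seed = 2))
  a2 <- assign_region_tiers(gen$atlas)
  export_heatmap(a2, path)
  back <- read_heatmap(path)
  for (r in unique(a2$region))
    expect_equal(back[[r]], a2$tier[a2$region == r][match(back$gene, a2$gene[a2$region == r])])
})

test_that("region summaries report counts and half-up percentages", {
  # printed-arithmetic convention: 46/219 -> 21%
  expect_equal(round_half_up(100 * 46 / 219), 21)
  ages <- c("24wg", "1y")
  vals <- rbind(c(0, 0), c(0.2, 0.4), c(5, 10), c(70, 10), c(120, 80),
                c(30, 20), c(2, 3), c(0.5, 8), c(61, 2), c(15, 25))
  at <- toy_atlas(vals, rep("Hipp", 2), ages)
  a <- assign_region_tiers(at)
  s <- summarize_region(rownames(at$values), a)
  expect_equal(s$n_genes, 10L)
  expect_equal(s$n_highly_expressed, 3L)
  expect_equal(s$pct_highly_expressed, 30)
  expect_equal(s$n_not_detected, 2L)
  expect_equal(s$pct_not_detected, 20)
  # three tier categories partition the set
  expect_equal(s$n_below_20 + s$n_mid + s$n_highly_expressed, s$n_genes)
  expect_true(all(c(s$pct_below_20, s$pct_mid, s$pct_highly_expressed) >= 0))
  expect_true(all(c(s$pct_below_20, s$pct_mid, s$pct_highly_expressed) <= 100))
  expect_equal(s$pct_below_20 + s$pct_mid + s$pct_highly_expressed, 100,
               tolerance = 0.2)
  # degenerate set: everything at zero
  at0 <- toy_atlas(matrix(0, 2, 2), rep("Hipp", 2), ages, genes = c("A", "B"))
  s0 <- summarize_region(c("A", "B"), assign_region_tiers(at0))
  expect_equal(s0$pct_below_20, 100)
  expect_equal(s0$pct_highly_expressed, 0)
  expect_error(summarize_region(character(0), a), "empty")
})
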