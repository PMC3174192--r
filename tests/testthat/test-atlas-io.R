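test_that("age labels parse, order chronologically, and round-trip", {
  a <- parse_age(c("24wg", "21wg", "6mo", "4mo", "1y", "23y"))
  expect_equal(format_age(a), c("24wg", "21wg", "6mo", "4mo", "1y", "23y"))
  # gestational before postnatal, numeric within stage
  o <- order(a$order_key)
  expect_equal(a$label[o], c("21wg", "24wg", "4mo", "6mo", "1y", "23y"))
  expect_true(all(a$order_key[a$stage == "gestational"] <
                    min(a$order_key[a$stage == "postnatal"])))
  expect_error(parse_age("24weeks"), "unparseable")
  expect_error(parse_age("wg24"), "unparseable")
})

test_that("atlas constructor enforces its invariants", {
  m <- matrix(c(10, 0, 20, 5), 2, dimnames = list(c("A", "B"), NULL))
  at <- expression_atlas(m, regions = c("Hipp", "Hipp"), ages = c("24wg", "1y"))
  expect_equal(dim(at), c(2L, 2L))
  expect_equal(unname(at$values["A", ]), c(10, 20))
  neg <- m; neg[2, 1] <- -1
  expect_error(expression_atlas(neg, c("Hipp", "Hipp"), c("24wg", "1y")),
               "negative RPKM.*B")
  dup <- m; rownames(dup) <- c("A", "A")
  expect_error(expression_atlas(dup, c("Hipp", "Hipp"), c("24wg", "1y")),
               "duplicate gene")
  expect_error(expression_atlas(m, c("Hipp", "Hipp"), c("24wg", "24wg")),
               "duplicate \\(region, age\\)")
})

test_that("expression matrix round-trips through CSV and TSV", {
  at <- toy_atlas(matrix(c(10, 0, 20, 5), 2), c("Hipp", "Hipp"),
                  c("24wg", "1y"), genes = c("A", "B"))
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_expression_matrix(at, path)
    back <- read_expression_matrix(path)
    expect_equal(back$values, at$values)
    expect_equal(back$samples$region, at$samples$region)
    expect_equal(back$samples$age, at$samples$age)
  }
  # a full synthetic atlas round-trips exactly
  gen <- generate_atlas(atlas_spec(n_genes = 60, n_housekeeping = 10,
                                   n_high = 8, n_silent = 5,
                                   n_pan_region_high = 2, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(gen$atlas, path)
  expect_equal(read_expression_matrix(path)$values, gen$atlas$values)
})

test_that("unknown region codes are rejected by name, aliases map them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,XXQ.24wg", "A,1.0"), path)
  expect_error(read_expression_matrix(path), "XXQ")
  expect_silent(at <- read_expression_matrix(path, aliases = c(XXQ = "Hipp")))
  expect_equal(at$samples$region, "Hipp")
  # malformed header without the REGION.AGE dot
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,Hipp24wg", "A,1.0"), path2)
  expect_error(read_expression_matrix(path2), "Hipp24wg")
})

test_that("age filtering keeps everything up to the cutoff", {
  at <- toy_atlas(matrix(1:4, 1), rep("Hipp", 4), c("24wg", "1y", "30y", "40y"),
                  genes = "A")
  f <- filter_ages(at, "23y")
  expect_equal(sort(unique(f$samples$age)), c("1y", "24wg"))
  expect_equal(f$genes, at$genes)
  # beyond all ages: no-op
  expect_equal(filter_ages(at, "50y")$values, at$values)
  # before all ages: empty result rejected
  expect_error(filter_ages(at, "20wg"), "removes every sample")
})

test_that("region subsetting keeps requested regions, rejects unknown", {
  extras <- c("V1C", "A1C", "M1C", "S1C", "IPC")
  regions16 <- c(canonical_regions(), extras)
  at <- toy_atlas(matrix(seq_len(2 * 16), 2), regions16, rep("1y", 16))
  s <- subset_regions(at, canonical_regions())
  expect_setequal(unique(s$samples$region), canonical_regions())
  expect_equal(subset_regions(at, regions16)$values[, order(colnames(at$values))],
               at$values[, order(colnames(at$values))])
  expect_error(subset_regions(at, c("Hipp", "XYZ")), "XYZ")
})

test_that("age filtering and region subsetting commute", {
  gen <- generate_atlas(atlas_spec(n_genes = 30, n_housekeeping = 5,
                                   n_high = 4, n_silent = 3,
                                   n_pan_region_high = 1, seed = 3))
  at <- gen$atlas
  ab <- subset_regions(filter_ages(at, "2y"), c("Hipp", "Cere"))
  ba <- filter_ages(subset_regions(at, c("Hipp", "Cere")), "2y")
  expect_equal(ab$values, ba$values)
  expect_equal(ab$samples, ba$samples)
})

test_that("gene lists parse against the atlas with an exclusion report", {
  at <- toy_atlas(matrix(1:2, 2), "Hipp", "1y", genes = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A", "B", "C"), path)
  res <- parse_gene_list(path, at)
  expect_equal(res$set$members, c("A", "B"))
  expect_equal(res$excluded, "C")
  # duplicates collapse with a message, and the size identity holds
  writeLines(c("A", "a", "B", "C"), path)
  expect_message(res <- parse_gene_list(path, at), "1 duplicate")
  expect_equal(length(res$set$members) + length(res$excluded), 3L)
  expect_equal(res$n_duplicates, 1L)
  writeLines(character(0), path)
  expect_error(parse_gene_list(path, at), "empty")
})

test_that("the synthetic disease list parses complete against its atlas", {
  sc <- generate_disease_scenario(seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(sc$sets$ASD$members, path)
  res <- parse_gene_list(path, sc$atlas)
  expect_length(res$set$members, 219L)
  expect_length(res$excluded, 0L)
})

test_that("GMT files round-trip", {
  sets <- list(gene_set("S1", c("A", "B", "C")), gene_set("S2", c("B", "D")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$S1$members, c("A", "B", "C"))
  expect_equal(back$S2$members, c("B", "D"))
  expect_error(read_gmt(withr::local_tempfile(fileext = ".gmt")), "not found")
})
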