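test_that("venn counts are exact and satisfy inclusion-exclusion", {
  A <- gene_set("A", c("a", "b", "c"))
  B <- gene_set("B", c("b", "c", "d"))
  C <- gene_set("C", c("c", "d", "e"))
  v <- venn_counts(list(A, B, C))
  expect_equal(v$triple, 1L)
  expect_equal(unname(v$pairwise["A&B"]), 2L)
  expect_equal(v$regions[["A"]], "A")
  expect_equal(v$regions[["A&B&C"]], "C")
  # union two ways: region sum and inclusion-exclusion
  expect_equal(sum(vapply(v$regions, length, 0L)), v$union_size)
  expect_equal(sum(v$sizes) - sum(v$pairwise) + v$triple, v$union_size)
  # permutation invariance up to relabeling
  v2 <- venn_counts(list(C, A, B))
  expect_equal(v2$triple, v$triple)
  expect_equal(v2$union_size, v$union_size)
  expect_equal(sort(unname(v2$sizes)), sort(unname(v$sizes)))
  # identical sets: full triple, no exclusive members
  v3 <- venn_counts(list(gene_set("X", letters[1:4]), gene_set("Y", letters[1:4]),
                         gene_set("Z", letters[1:4])))
  expect_equal(v3$triple, 4L)
  expect_equal(names(v3$regions), "X&Y&Z")
  expect_error(venn_counts(list(A)), "two or three")
})

test_that("highly expressed subsets require the 60 RPKM threshold somewhere", {
  ages <- c("24wg", "1y")
  vals <- rbind(c(70, 1), c(2, 61), c(59.9, 10), c(0, 0), c(20, 30))
  at <- toy_atlas(vals, rep("Hipp", 2), ages,
                  genes = c("H1", "H2", "NO1", "NO2", "NO3"))
  a <- assign_region_tiers(at)
  hs <- highly_expressed_subset(gene_set("toy", c("H1", "H2", "NO1", "NO2", "NO3")), a)
  expect_equal(hs$members, c("H1", "H2"))
  low <- gene_set("low", c("NO1", "NO2", "NO3"))
  expect_error(highly_expressed_subset(low, a), "highly expressed")
  expect_length(highly_expressed_subset(low, a, allow_empty = TRUE), 0L)
})

test_that("pan-region calls demand every region, unique calls exactly one", {
  regions <- canonical_regions()
  # PAN high everywhere; TEN high in 10 of 11; CERE high only in Cere;
  # CH high in Cere and Hipp
  vals <- do.call(cbind, lapply(regions, function(r) {
    c(PAN = 80, TEN = if (r == "Amyg") 10 else 90,
      CERE = if (r == "Cere") 100 else 5,
      CH = if (r %in% c("Cere", "Hipp")) 70 else 5)
  }))
  at <- toy_atlas(vals, regions, rep("1y", length(regions)),
                  genes = c("PAN", "TEN", "CERE", "CH"))
  a <- assign_region_tiers(at)
  gs <- gene_set("toy", c("PAN", "TEN", "CERE", "CH"))
  expect_equal(pan_region_high(gs, a), "PAN")
  expect_equal(region_unique_high(gs, a, "Cere"), "CERE")
  for (r in setdiff(regions, "Cere"))
    expect_false("CERE" %in% region_unique_high(gs, a, r))
  expect_length(region_unique_high(gs, a, "Hipp"), 0L)  # CH high in two regions
  expect_error(region_unique_high(gs, a, "XYZ"), "XYZ")
  # containment and disjointness properties
  high <- highly_expressed_subset(gs, a)$members
  expect_true(all(pan_region_high(gs, a) %in% high))
  uniques <- lapply(regions, function(r) region_unique_high(gs, a, r))
  expect_true(all(unlist(uniques) %in% high))
  expect_equal(anyDuplicated(unlist(uniques)), 0L)
  # missing region is an error naming it
  a_sub <- a[a$region != "Amyg", ]
  expect_error(pan_region_high(gs, a_sub, regions = regions), "Amyg")
})

test_that("overlap fractions reproduce the printed percent style", {
  q130 <- sprintf("d%03d", 1:130)
  ref <- c(q130[1:4], "OTHER1", "OTHER2")
  ov <- overlap_fraction(q130, ref)
  expect_equal(ov$n_overlap, 4L)
  expect_equal(format(ov), "4/130 (3%)")
  expect_equal(overlap_fraction(sprintf("x%d", 1:5), "y1")$percent_text, "0%")
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c"))$fraction, 1)
  expect_error(overlap_fraction(character(0), "a"), "empty")
})

test_that("scenario recovery: planted disease-set structure is exact", {
  sc <- generate_disease_scenario(seed = 4)
  a <- assign_region_tiers(sc$atlas)
  ex <- sc$truth$expected
  hs <- lapply(sc$sets, function(s) highly_expressed_subset(s, a)$members)
  expect_length(hs$ASD, ex$high_asd)
  expect_length(hs$Epilepsy, ex$high_epi)
  expect_length(hs$Schizophrenia, ex$high_sz)
  expect_equal(venn_counts(sc$sets)$triple, ex$triple)
  expect_length(pan_region_high(sc$sets$ASD, a), ex$pan_region_asd)
  expect_length(intersect(hs$ASD, intersect(sc$sets$ASD$members,
                                            sc$sets$Schizophrenia$members)),
                ex$asd_sz_high)
  # the recovered high set is exactly the planted one
  expect_equal(sort(unique(c(hs$ASD, hs$Epilepsy, hs$Schizophrenia))),
               sort(intersect(unique(unlist(lapply(sc$sets, `[[`, "members"))),
                              c(sc$truth$high, sc$truth$pan_region))))
})
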