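test_that("binomial VAF test keeps cluster-consistent candidates", {
  # alt 10/100 with expected VAF theta/2 = 0.1: perfectly consistent
  bt <- binomial_vaf_test(10, 100, theta = 0.2, g_T = "AB")
  expect_true(bt$keep)
  expect_equal(bt$p_value, binom.test(10, 100, 0.1)$p.value)

  # alt 3/100 against p0 = 0.25: wildly inconsistent
  bt2 <- binomial_vaf_test(3, 100, theta = 0.5, g_T = "AB", alpha = 1e-4)
  expect_false(bt2$keep)
  expect_lt(bt2$p_value, 1e-6)

  # homozygous tumor genotype doubles the expectation
  expect_equal(binomial_vaf_test(20, 100, 0.2, "BB")$p_value,
               binom.test(20, 100, 0.2)$p.value)

  # the exact expected count is kept at any alpha < 1
  expect_true(binomial_vaf_test(25, 100, 0.5, "AB", alpha = 0.99)$keep)

  # zero depth is undefined -> reject
  expect_false(binomial_vaf_test(0, 0, 0.2)$keep)
})

test_that("binomial keep-region is contiguous in the alt count", {
  for (p0th in list(c(0.2, "AB"), c(0.1, "BB"))) {
    theta <- as.numeric(p0th[1])
    keep <- vapply(0:100, function(k)
      binomial_vaf_test(k, 100, theta, p0th[2], alpha = 1e-3)$keep, TRUE)
    runs <- rle(keep)
    expect_equal(sum(runs$values), 1L)  # a single TRUE run
  }
})

mk_stats <- function(mean_bq = 30, mean_mq = 50, depth = 100, alt = 10,
                     strand_counts = NULL, galt = 0, indel = FALSE,
                     rep_ctx = FALSE) {
  if (is.null(strand_counts)) {
    strand_counts <- c(ref_fwd = (depth - alt) %/% 2,
                       ref_rev = depth - alt - (depth - alt) %/% 2,
                       alt_fwd = alt %/% 2, alt_rev = alt - alt %/% 2)
  }
  structure(list(mean_base_qual = mean_bq, mean_map_qual = mean_mq,
                 strand_counts = strand_counts, depth = depth,
                 alt_count = alt, vaf = alt / depth, nearby_indel = indel,
                 repeat_context = rep_ctx, germline_alt_count = galt),
            class = "site_stats")
}

test_that("pass / hold / reject partition follows essential vs non-essential", {
  # clean candidate passes everything
  v <- apply_site_filters(mk_stats(), theta = 0.2)
  expect_equal(v$category, "pass")
  expect_length(v$failed_filters, 0)

  # low mean base quality is an essential failure
  v2 <- apply_site_filters(mk_stats(mean_bq = 15), theta = 0.2)
  expect_equal(v2$category, "reject")
  expect_true(v2$essential_failed)
  expect_true("mean_base_qual" %in% v2$failed_filters)

  # all essential pass but depth 60 < 80 -> hold
  v3 <- apply_site_filters(mk_stats(depth = 60, alt = 6), theta = 0.2)
  expect_equal(v3$category, "hold")
  expect_false(v3$essential_failed)
  expect_equal(v3$failed_filters, "depth")

  # two germline alt reads -> essential reject
  v4 <- apply_site_filters(mk_stats(galt = 2), theta = 0.2)
  expect_equal(v4$category, "reject")
  expect_true("germline_alt" %in% v4$failed_filters)

  # strong strand bias on the alt reads -> essential reject
  sc <- c(ref_fwd = 45, ref_rev = 45, alt_fwd = 10, alt_rev = 0)
  v5 <- apply_site_filters(mk_stats(strand_counts = sc), theta = 0.2)
  expect_equal(v5$category, "reject")
  expect_true("strand_bias" %in% v5$failed_filters)

  # the partition is exhaustive and exclusive
  for (v in list(v, v2, v3, v4, v5)) {
    expect_true(v$category %in% c("pass", "hold", "reject"))
    expect_equal(v$category == "reject", v$essential_failed)
  }
})

test_that("co-occurrence filter flags exclusively shared mismatches only", {
  # candidate A: all 5 alt reads share 3 extra mismatches absent in refs
  varA <- replicate(5, c(11L, 57L, 90L), simplify = FALSE)
  refA <- replicate(20, integer(), simplify = FALSE)
  # candidate B: alt reads clean (clustered read position is NOT penalized)
  varB <- replicate(5, integer(), simplify = FALSE)
  refB <- replicate(20, integer(), simplify = FALSE)
  # candidate C: one mismatch shared equally by ref and alt reads
  varC <- replicate(5, 33L, simplify = FALSE)
  refC <- replicate(20, 33L, simplify = FALSE)
  flags <- misalignment_cooccurrence_filter(list(varA, varB, varC),
                                            list(refA, refB, refC))
  expect_equal(flags, c(TRUE, FALSE, FALSE))

  # a single co-occurring mismatch is below the >= 2 requirement
  varD <- replicate(5, 44L, simplify = FALSE)
  expect_false(misalignment_cooccurrence_filter(list(varD), list(refA)))
})

test_that("co-occurrence filter rescues fragment-hotspot mutations that a
           clustered-position filter would kill", {
  # non-random fragmentation: every alt read starts at the same position, so
  # the variant sits at a constant read offset -- yet reads are clean
  sim <- simulate_mutation_pileup(0.1, 120, seed = 31)
  alt_obs <- sim$plasma$obs[sim$plasma$obs$base == sim$plasma$alt, ]
  alt_obs$d5p <- 17L  # preferred fragment start
  clustered_pos_filter <- function(d5p) stats::var(d5p) < 1  # conventional rule
  expect_true(clustered_pos_filter(alt_obs$d5p))             # would be killed
  keep <- !misalignment_cooccurrence_filter(
    list(replicate(nrow(alt_obs), integer(), simplify = FALSE)),
    list(replicate(40, integer(), simplify = FALSE)))
  expect_true(keep)                                          # rescued here
})
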