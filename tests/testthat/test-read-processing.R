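# 10 bp mates with a 4 bp overlap on positions 7-10
mk_pair <- function(b1 = "ACGTACGTAC", q1 = rep(30, 10),
                    b2 = "GTACGTACGT", q2 = rep(30, 10),
                    start2 = 7L) {
  read_pair(b1, q1, b2, q2, mapq1 = 50, mapq2 = 55,
            start1 = 1L, start2 = start2, read_id = "f1")
}

test_that("concordant overlap bases are confirmed with boosted quality", {
  # mate2 copies mate1's bases over the 4-bp overlap
  p <- mk_pair(b2 = paste0(substr("ACGTACGTAC", 7, 10), "GTACGT"))
  m <- merge_read_pair(p, min_overlap = 4)
  expect_s3_class(m, "merged_read")
  ov <- 7:10
  expect_true(all(m$confirmed[ov]))
  expect_equal(m$quals[ov], rep(60, 4))  # min(30 + 30, 60)
  expect_equal(m$fragment_length, 16L)
  expect_false(any(m$confirmed[-ov]))
})

test_that("discordant overlap bases go to the higher-quality call", {
  # read1 overlap bases (positions 7-10): G T A C
  q2 <- c(10, 40, 30, 30, rep(30, 6))
  b2 <- paste0("TCTA", "GTACGT")  # all four overlap calls disagree
  p <- mk_pair(b2 = b2, q2 = q2)
  m <- merge_read_pair(p, min_overlap = 4, max_mismatch_density = 1)
  # read1 G (q30) beats read2 T (q10); quality of the winner retained
  expect_equal(m$bases[7], "G")
  expect_equal(m$quals[7], 30)
  # read2 C (q40) beats read1 T (q30)
  expect_equal(m$bases[8], "C")
  expect_equal(m$quals[8], 40)
  # quality ties are unresolvable
  expect_equal(m$bases[9], "N")
  expect_equal(m$quals[9], 2)
  expect_equal(m$bases[10], "N")
  expect_false(any(m$confirmed[7:10]))
})

test_that("short overlaps and high mismatch density leave the pair unmerged", {
  p <- mk_pair()
  expect_s3_class(merge_read_pair(p, min_overlap = 10), "read_pair")
  # 4 discordant bases out of 4 overlap -> density 1 > 0.25
  p2 <- mk_pair(b2 = paste0("TTTT", "GTACGT"))
  expect_s3_class(merge_read_pair(p2, min_overlap = 4), "read_pair")
})

test_that("merging is idempotent", {
  p <- mk_pair(b2 = paste0(substr("ACGTACGTAC", 7, 10), "GTACGT"))
  m <- merge_read_pair(p, min_overlap = 4)
  expect_identical(merge_read_pair(m), m)
})

test_that("mismatched base/quality lengths are an input error", {
  expect_error(read_pair("ACGT", c(30, 30), "ACGT", rep(30, 4),
                         50, 50, 1L, 3L), "equal length")
})

test_that("pileups count each fragment once and pick the majority alt", {
  # ten merged fragments, all reference
  frags <- lapply(1:10, function(i) {
    p <- mk_pair(b2 = paste0(substr("ACGTACGTAC", 7, 10), "GTACGT"))
    m <- merge_read_pair(p, min_overlap = 4)
    m$read_id <- paste0("f", i)
    m
  })
  pu <- build_pileup(frags, "chr1", 3L, ref = "G")
  expect_equal(nrow(pu$obs), 10L)
  expect_equal(sum(pu$obs$base != "G"), 0L)
  expect_true(is.na(pu$alt))

  # a merged fragment covering the locus in the old overlap contributes once
  pu2 <- build_pileup(frags, "chr1", 8L, ref = "T")
  expect_equal(nrow(pu2$obs), 10L)

  # an unmerged pair covering the locus in both mates still contributes once
  p <- mk_pair()  # unmergeable defaults stay a read_pair after merge attempt
  pu3 <- build_pileup(list(merge_read_pair(p, min_overlap = 99)), "chr1", 8L,
                      ref = "T")
  expect_equal(nrow(pu3$obs), 1L)

  # majority non-reference base becomes the alternate allele
  obs_frags <- lapply(1:100, function(i) {
    b <- if (i <= 7) "T" else if (i <= 9) "G" else "A"
    structure(list(chrom = "chr1", bases = b, quals = 30, mapq = 60,
                   strand = "+", span = c(5L, 5L), fragment_length = 1L,
                   confirmed = FALSE, read_id = paste0("x", i),
                   mapq1 = 60, mapq2 = 60),
              class = "merged_read")
  })
  pu4 <- build_pileup(obs_frags, "chr1", 5L, ref = "A")
  expect_equal(pu4$alt, "T")
  expect_equal(sum(pu4$obs$base == "T"), 7L)

  # uncovered locus yields an empty pileup, not an error
  expect_equal(nrow(build_pileup(frags, "chr1", 999L, ref = "A")$obs), 0L)
})

test_that("pileup dump TSV round-trips observations", {
  sim <- simulate_mutation_pileup(0.2, 25, cfg = simulation_config(seed = 9))
  f <- tempfile(fileext = ".tsv")
  write_pileup_tsv(list(sim$plasma), f)
  back <- read_pileup_tsv(f)[[1]]
  expect_equal(nrow(back$obs), nrow(sim$plasma$obs))
  expect_equal(sort(back$obs$base), sort(sim$plasma$obs$base))
  expect_equal(back$pos, sim$plasma$pos)
})
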