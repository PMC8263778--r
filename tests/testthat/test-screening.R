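clean_pileup <- function(n, n_alt, ref = "A", alt = "T", role = "plasma",
                         bq = 35, mq = 60) {
  base <- c(rep(alt, n_alt), rep(ref, n - n_alt))
  locus_pileup("sim1", 100L, ref,
               data.frame(base = base, bq = bq, mq = mq,
                          strand = rep_len(c("+", "-"), n),
                          d5p = 5L, d3p = 150L, flen = 166L,
                          confirmed = FALSE, merged = TRUE,
                          read_id = paste0(role, seq_len(n)),
                          stringsAsFactors = FALSE),
               alt = alt, sample_role = role)
}

test_that("MAP joint genotype recovers the canonical cases", {
  # all reads reference in both samples -> (AA, AA, AA)
  post <- map_joint_genotype(clean_pileup(100, 0), clean_pileup(50, 0), 0.1)
  expect_equal(unname(post$g_map), c("AA", "AA", "AA"))
  expect_equal(post$classification, "reference")

  # heterozygous germline and plasma -> germline call
  post2 <- map_joint_genotype(clean_pileup(100, 48),
                              clean_pileup(50, 26, role = "germline"), 0.1)
  expect_equal(unname(post2$g_map["g_N"]), "AB")
  expect_equal(unname(post2$g_map["g_W"]), "AB")
  expect_equal(post2$classification, "germline")

  # 5% plasma alt with a clean germline at theta = 0.1 -> somatic het
  post3 <- map_joint_genotype(clean_pileup(200, 10), clean_pileup(50, 0), 0.1)
  expect_equal(unname(post3$g_map), c("AB", "AA", "AA"))
  expect_equal(post3$classification, "somatic")
})

test_that("MAP equals exhaustive 27-triplet enumeration on random pileups", {
  set.seed(42)
  prior <- default_prior_table()
  for (i in 1:60) {
    pp <- random_pileup_pair(depth_p = sample(20:60, 1),
                             depth_g = sample(15:40, 1),
                             p_alt = sample(c(0, 0.05, 0.3, 0.5), 1))
    theta <- runif(1, 0.02, 0.6)
    got <- map_joint_genotype(pp$plasma, pp$germline, theta, prior)
    want <- oracle_map_genotype(pp$plasma, pp$germline, theta, prior)
    expect_equal(unname(got$g_map), unname(want))
  }
})

test_that("posterior is invariant to read order", {
  pp <- random_pileup_pair(40, 30, 0.2)
  post1 <- map_joint_genotype(pp$plasma, pp$germline, 0.3)
  shuf <- pp$plasma
  shuf$obs <- shuf$obs[sample(nrow(shuf$obs)), ]
  post2 <- map_joint_genotype(shuf, pp$germline, 0.3)
  expect_equal(sort(post1$table$log_post), sort(post2$table$log_post))
  expect_equal(post1$g_map, post2$g_map)
})

test_that("triplet classification covers somatic, germline, LOH, reference", {
  expect_equal(classify_locus("AB", "AA", "AA"), "somatic")
  expect_equal(classify_locus("BB", "AA", "AA"), "somatic")
  expect_equal(classify_locus("AB", "AB", "AB"), "germline")
  expect_equal(classify_locus("AA", "AB", "AB"), "LOH")
  expect_equal(classify_locus("BB", "AB", "AB"), "LOH")
  expect_equal(classify_locus("AA", "AA", "AA"), "reference")
  expect_error(classify_locus("AA", "AB", "AA"))
})

test_that("fitness ratio prefers the mixture for low-frequency mutations", {
  # strong heterozygous germline signal: non-somatic explanation wins
  pl <- clean_pileup(100, 50)
  gl <- clean_pileup(60, 30, role = "germline")
  fr <- fitness_ratio(pl, gl, theta = 0.5)
  expect_lt(fr$log_ratio, 0)

  # all-reference plasma: no variant evidence at any theta
  pl0 <- clean_pileup(100, 0)
  gl0 <- clean_pileup(50, 0, role = "germline")
  for (th in c(0.05, 0.3, 0.9)) {
    expect_lte(fitness_ratio(pl0, gl0, th)$log_ratio, 0)
  }

  # a 3% VAF mutation at depth 200: theta = VAF fits far better than
  # the conventional pure-tumor assumption (theta = 1)
  sim <- simulate_mutation_pileup(0.03, 200, seed = 12)
  f_vaf <- fitness_ratio(sim$plasma, sim$germline, 0.03)
  f_one <- fitness_ratio(sim$plasma, sim$germline, 1)
  expect_gt(f_vaf$log_ratio - f_one$log_ratio, log(40))
})

test_that("the fitness ratio peaks near the mutation's cfDNA frequency", {
  sim <- simulate_mutation_pileup(0.04, 300, seed = 77)
  th <- seq(0.01, 0.5, by = 0.01)
  lr <- vapply(th, function(t)
    fitness_ratio(sim$plasma, sim$germline, t)$log_ratio, 0)
  peak <- th[which.max(lr)]
  # best theta tracks the mutation's frequency: ~VAF for a homozygous tumor
  # genotype, ~2 x VAF for a heterozygous one
  expect_gte(peak, 0.02)
  expect_lte(peak, 0.12)
  # and the ratio decays far from the mutation frequency
  expect_gt(max(lr), lr[length(lr)])
})
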