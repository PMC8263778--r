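test_that("error probability follows the Phred closed form", {
  expect_equal(error_probability(20, 20), 1 - 0.99^2)
  expect_equal(error_probability(20, 20), 0.0199)
  # symmetric in mapping and base quality
  for (pair in list(c(10, 30), c(7, 55), c(0, 12))) {
    expect_equal(error_probability(pair[1], pair[2]),
                 error_probability(pair[2], pair[1]))
  }
  # q = 0 means a certainly-wrong call regardless of mapping quality
  expect_equal(error_probability(50, 0), 1)
  # perfect qualities drive the error to zero
  expect_lt(error_probability(1e6, 1e6), 1e-12)
  expect_error(error_probability(-1, 20), "non-negative")
})

test_that("base likelihood matches the genotype table", {
  expect_equal(base_likelihood("A", "AB", 0, "A", "T"), 0.5)
  expect_equal(base_likelihood("A", "BB", 0, "A", "T"), 0)
  expect_equal(base_likelihood("A", "AA", 0.03, "A", "T"), 0.97)
  # off-genotype base gets eps/3 under every genotype
  expect_equal(base_likelihood("G", "AB", 0.3, "A", "T"), 0.1)
  # N calls are uninformative
  expect_equal(base_likelihood("N", "BB", 0.01, "A", "T"), 1)
  # matches the scalar oracle across bases, genotypes and error rates
  set.seed(11)
  for (i in 1:50) {
    eps <- runif(1, 0, 0.7)
    b <- sample(c("A", "C", "G", "T"), 1)
    g <- sample(c("AA", "AB", "BB"), 1)
    expect_equal(base_likelihood(b, g, eps, "A", "C"),
                 oracle_base_lik(b, g, eps, "A", "C"))
  }
})

test_that("base likelihoods over the four bases sum to one for every genotype", {
  set.seed(5)
  eps <- runif(200, 0, 0.74)
  L <- plasmasnv:::base_likelihood_matrix(
    rep(c("A", "C", "G", "T"), each = 200), rep(eps, 4), "A", "T")
  sums <- rowsum(L, rep(seq_along(eps), 4))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("joint prior honours the WBC = normal constraint and normalizes", {
  tab <- default_prior_table()
  expect_equal(joint_prior("AB", "AA", "AB", tab), 0)
  total <- 0
  for (gT in c("AA", "AB", "BB")) for (gN in c("AA", "AB", "BB"))
    for (gW in c("AA", "AB", "BB"))
      total <- total + joint_prior(gT, gN, gW, tab)
  expect_equal(total, 1)
  # a heterozygous somatic event is more probable a priori than homozygous
  expect_gt(joint_prior("AB", "AA", "AA", tab),
            joint_prior("BB", "AA", "AA", tab))
})

test_that("prior table round-trips through TSV and JSON config files", {
  tab <- default_prior_table()
  df <- expand.grid(g_N = c("AA", "AB", "BB"), g_T = c("AA", "AB", "BB"),
                    stringsAsFactors = FALSE)
  df$p <- unclass(tab)[cbind(df$g_N, df$g_T)]
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_prior_table(tsv))[cbind(df$g_N, df$g_T)], df$p)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(setNames(as.list(df$p), paste(df$g_N, df$g_T, sep = ",")),
                       js, auto_unbox = TRUE, digits = NA)
  expect_equal(unclass(read_prior_table(js))[cbind(df$g_N, df$g_T)], df$p)
  # unnormalized tables are rejected at load time
  df$p[1] <- df$p[1] + 0.5
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_prior_table(tsv), "sum to 1")
})

test_that("mixture read likelihood interpolates between genotype densities", {
  # theta = 0 and 1 recover the pure component densities
  expect_equal(read_likelihood_mixture("T", 40, 30, "AB", "AA", 0, "A", "T"),
               base_likelihood("T", "AA", error_probability(40, 30), "A", "T"))
  expect_equal(read_likelihood_mixture("T", 40, 30, "AB", "AA", 1, "A", "T"),
               base_likelihood("T", "AB", error_probability(40, 30), "A", "T"))
  # hand-evaluated mixture at eps = 0.0199 (m = q = 20), theta = 0.1
  val <- read_likelihood_mixture("T", 20, 20, "AB", "AA", 0.1, "A", "T")
  expect_equal(val, 0.1 * (0.5 * 0.9801 + 0.0199 / 6) + 0.9 * (0.0199 / 3),
               tolerance = 1e-12)
  # linear and monotone in theta between the endpoints
  th <- seq(0, 1, 0.1)
  vals <- sapply(th, function(t)
    read_likelihood_mixture("T", 30, 30, "AB", "AA", t, "A", "T"))
  expect_true(all(diff(vals) > 0))
  expect_equal(max(abs(diff(diff(vals)))), 0, tolerance = 1e-12)
})
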