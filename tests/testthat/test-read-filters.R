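# small labeled set shared across classifier tests
labeled_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        clusters = data.frame(target_vaf = c(0.25, 0.1),
                              n_mutations = c(50L, 50L)),
        depth = 180, n_background = 3000L, n_germline_het = 80L, seed = 202L)
      s <- simulate_sample(cfg, replicates = 2)
      cache <<- label_reads_for_training(s$plasma_replicates)
    }
    cache
  }
})

test_that("feature extraction is deterministic with fixed dimensionality", {
  obs <- data.frame(bq = c(30, 60), mq = c(60, 40), d5p = c(5L, 80L),
                    d3p = c(160L, 85L), flen = 166L, mate_mq = c(60, 60),
                    read_mm = c(0L, 3L), mate_mm = 0L, softclip = c(0L, 8L),
                    strand = c("+", "-"), confirmed = c(TRUE, FALSE))
  X1 <- extract_read_features(obs, c("ACG", "TGT"), c("T", "A"), "overlapping")
  X2 <- extract_read_features(obs, c("ACG", "TGT"), c("T", "A"), "overlapping")
  expect_identical(X1, X2)
  expect_equal(nrow(X1), 2L)
  # one-hot groups each sum to one
  for (grp in c("strand", "ctx5_", "ref", "ctx3_", "alt")) {
    cols <- grep(paste0("^", grp), colnames(X1))
    expect_equal(unname(rowSums(X1[, cols, drop = FALSE])), c(1, 1))
  }
  expect_equal(unname(X1[, "overlap_confirmed"]), c(1, 0))
  # the non-overlapping set drops the overlap feature, keeps the rest
  Xn <- extract_read_features(obs, c("ACG", "TGT"), c("T", "A"),
                              "nonoverlapping")
  expect_false("overlap_confirmed" %in% colnames(Xn))
  # missing mate columns fall back to the read's own values
  obs2 <- obs[, setdiff(names(obs), c("mate_mq", "mate_mm"))]
  Xf <- extract_read_features(obs2, c("ACG", "TGT"), c("T", "A"),
                              "nonoverlapping")
  expect_equal(unname(Xf[, "mate_map_qual"]), obs$mq)
})

test_that("replicate concordance labels variants and singleton errors", {
  lab <- labeled_fixture()
  expect_true(all(c("true_variant", "error") %in% lab$label))
  expect_gt(sum(lab$label == "error"), 50)
  # labeled error reads obey the high-quality singleton definition
  err <- lab[lab$label == "error", ]
  expect_true(all(err$bq >= 20 & err$mq >= 40))
  # true-variant reads come from sites supported in both replicates
  expect_gt(sum(lab$label == "true_variant"), 1000)
})

test_that("error-site labeling demands depth and a single non-reference read", {
  loci <- data.table::data.table(locus_id = 1:3, chrom = "sim1",
                                 pos = c(10L, 20L, 30L), ref = "A",
                                 context = "CAG")
  shallow <- function(n, n_alt) {
    data.frame(base = c(rep("T", n_alt), rep("A", n - n_alt)),
               bq = 30, mq = 60, strand = "+", d5p = 1L, d3p = 160L,
               flen = 166L, confirmed = FALSE, merged = TRUE,
               pair_overlap = TRUE, mate_mq = 60, read_mm = 0L,
               mate_mm = 0L, softclip = 0L,
               read_id = paste0("r", seq_len(n)), origin = "normal",
               stringsAsFactors = FALSE)
  }
  reps <- lapply(1:2, function(i) {
    obs <- data.table::rbindlist(list(
      data.table::data.table(locus_id = 1L, shallow(50, 1)),   # depth 50
      data.table::data.table(locus_id = 2L, shallow(100, 5)),  # variant site
      data.table::data.table(locus_id = 3L, shallow(100, 1))   # error site
    ))
    pileup_set(obs, loci, "plasma")
  })
  lab <- label_reads_for_training(reps)
  # the depth-50 singleton site is not used for error labeling
  expect_false(any(lab$site_id == 1L))
  # the 5-read site is concordant -> true variants
  expect_true(all(lab$label[lab$site_id == 2L] == "true_variant"))
  # the deep singleton high-quality non-reference read is the error class
  expect_true(all(lab$label[lab$site_id == 3L] == "error"))
  expect_equal(sum(lab$site_id == 3L), 2L)  # one read per replicate
})

test_that("training is seed-reproducible and beats a permutation null", {
  lab <- labeled_fixture()
  set.seed(1)
  sites <- unique(lab$site_id)
  tr_sites <- sample(sites, floor(length(sites) * 0.6))
  tr <- lab[lab$site_id %in% tr_sites, ]
  te <- lab[!lab$site_id %in% tr_sites, ]

  clf1 <- train_read_classifier(tr, seed = 9)
  clf2 <- train_read_classifier(tr, seed = 9)
  p1 <- predict_read_probs(clf1, te)
  p2 <- predict_read_probs(clf2, te)
  expect_identical(p1, p2)

  auc <- auc_rank(p1, te$label == "true_variant")
  expect_gt(auc, 0.8)
  # agreement with an established AUC implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = te$label == "true_variant", predictor = p1, quiet = TRUE,
    direction = "<")))
  expect_equal(auc, proc_auc, tolerance = 1e-9)

  # label permutation destroys the signal
  perm <- data.table::copy(tr)
  set.seed(2)
  perm$label <- sample(perm$label)
  clfp <- train_read_classifier(perm, seed = 9)
  aucp <- auc_rank(predict_read_probs(clfp, te), te$label == "true_variant")
  expect_lt(abs(aucp - 0.5), 0.06)

  # single-class data cannot be trained
  expect_error(train_read_classifier(tr[tr$label == "error", ], seed = 1),
               "both labels")
})

test_that("confirmed-supporting-read rule keeps and drops candidates", {
  lab <- labeled_fixture()
  clf <- train_read_classifier(lab, seed = 3)
  # fabricate candidates from known supporting reads
  sup_true <- lab[lab$label == "true_variant", ][1:5, ]
  res <- filter_candidate_by_reads(sup_true, clf, min_confirmed = 3L)
  expect_equal(res$n_supporting, 5L)
  expect_true(res$n_confirmed >= 0 && res$n_confirmed <= 5)
  expect_equal(res$keep, res$n_confirmed >= 3L)

  # anti-monotone in min_confirmed
  kept <- vapply(1:5, function(k)
    filter_candidate_by_reads(sup_true, clf, min_confirmed = k)$keep, TRUE)
  expect_true(all(diff(as.integer(kept)) <= 0))

  # without a model the filter is disabled with a warning
  expect_warning(res0 <- filter_candidate_by_reads(sup_true, NULL, 3L),
                 "disabled")
  expect_true(res0$keep)
  expect_equal(res0$n_confirmed, 5L)
})
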