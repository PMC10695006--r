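test_that("filter stages fire in the documented order", {
  ref <- cage_key(0L, "[Lr]c1ccc([Lr])cc1", 0L)

  bad_smiles <- cage_records(0L, "CCO", 0L)       # placeholder row
  bad_smiles$bb2_smiles <- "c1ccc"                # force invalid string
  expect_identical(filter_cage(bad_smiles, ref)$failed_stage, "validity")

  known <- cage_records(0L, "c1cc([Lr])ccc1[Lr]", 0L)  # same cage, reordered
  expect_identical(filter_cage(known, ref)$failed_stage, "novelty")

  no_sites <- cage_records(0L, "CCO", 0L)
  expect_identical(filter_cage(no_sites, ref)$failed_stage,
                   "precursor_validity")

  one_site <- cage_records(0L, "[Lr]CC", 0L)
  expect_identical(filter_cage(one_site, ref)$failed_stage,
                   "reaction_sites")

  lopsided <- cage_records(0L, "[Lr]Cc1ccc(C(=O)[Lr])cc1", 0L)
  expect_identical(filter_cage(lopsided, ref)$failed_stage, "symmetry")

  good <- cage_records(1L, "[Lr]c1ccc([Lr])cc1", 0L)  # novel bb1
  out <- filter_cage(good, ref)
  expect_true(out$passed)
  expect_identical(out$failed_stage, "none")
})

test_that("filter feedback loop resamples until the budget or the quota", {
  good <- cage_records(1L, "[Lr]c1ccc([Lr])cc1", 0L)
  always_good <- function(n, seed) {
    good[rep(1L, n), , drop = FALSE]
  }
  res <- generate_with_filter(always_good, character(0), n_required = 5)
  expect_identical(nrow(res$cages), 5L)
  expect_identical(nrow(res$log), 5L)
  expect_false(res$exhausted)

  bad <- cage_records(0L, "[Lr]CC", 0L)
  always_bad <- function(n, seed) bad[rep(1L, n), , drop = FALSE]
  res2 <- generate_with_filter(always_bad, character(0), n_required = 3,
                               max_attempts = 12)
  expect_null(res2$cages)
  expect_true(res2$exhausted)
  expect_identical(nrow(res2$log), 12L)
  # conservation: passes + failures == attempts
  expect_identical(sum(res2$log$passed) + sum(!res2$log$passed), 12L)
})

test_that("metric rates equal hand counts on a constructed batch", {
  # 10 candidates: 1 invalid; among the 9 valid: 2 copies of a reference
  # cage (not novel, duplicated), 1 with no sites, 1 with one site,
  # 1 asymmetric with two sites, 4 symmetric-novel (one repeated once
  # more via a reordered SMILES)
  ref_cage <- "[Lr]c1ccc([Lr])cc1"
  batch <- cage_records(
    bb1_id = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L),
    bb2_smiles = c("X_invalid_placeholder", ref_cage, ref_cage,
                   "CCO", "[Lr]CC",
                   "[Lr]Cc1ccc(C(=O)[Lr])cc1",
                   "[Lr]C#Cc1ccc(C#C[Lr])cc1",
                   "c1cc(C#C[Lr])ccc1C#C[Lr]",  # same as previous, reordered
                   "[Lr]CCC[Lr]",
                   "[Lr]c1cccc([Lr])c1"),
    reaction_id = rep(0L, 10))
  batch$bb2_smiles[1] <- "c1ccc"   # bypass constructor validation
  ref_orig <- cage_key(0L, ref_cage, 0L)
  ref_comb <- c(ref_orig, cage_key(1L, "[Lr]CCC[Lr]", 0L))
  rep_ <- compute_metrics(batch, ref_orig, ref_comb)

  expect_identical(rep_$n_sampled, 10L)
  expect_equal(rep_$validity, 9 / 10)
  expect_equal(rep_$novelty_original_given_valid, 7 / 9)
  expect_equal(rep_$novelty_combined_given_valid, 6 / 9)
  # distinct keys among the 9 valid: ref(x2 -> 1), CCO, LrCC, lopsided,
  # diyne (x2 -> 1), chain, meta = 7
  expect_equal(rep_$uniqueness_given_valid, 7 / 9)
  # precursor-valid among valid: ref x2, lopsided, diyne x2, chain, meta = 7
  expect_equal(rep_$precursor_validity_given_valid, 7 / 9)
  # symmetric among precursor-valid: all but the lopsided one
  expect_equal(rep_$symmetry_given_precursor_valid, 6 / 7)

  # shuffling the batch leaves every rate unchanged
  set.seed(1)
  shuf <- batch[sample.int(10), , drop = FALSE]
  rep2 <- compute_metrics(shuf, ref_orig, ref_comb)
  expect_equal(unclass(rep2), unclass(rep_))
})

test_that("PCA projection is centered with sane variance ratios", {
  # points on a line: first component carries all the variance
  t <- seq(-2, 2, length.out = 40)
  line <- cbind(t, 2 * t, -t) + matrix(rnorm(120, sd = 1e-8), 40)
  pc <- pca_latent(line, 2)
  expect_gt(pc$explained_variance_ratio[1], 0.999)
  expect_identical(dim(pc$coords), c(40L, 2L))
  # projection of the mean point is the origin (centering)
  expect_lt(max(abs(colMeans(pc$coords))), 1e-10)
  # isotropic cloud: roughly equal ratios
  set.seed(2)
  cloud <- matrix(rnorm(4000), 1000, 4)
  pc2 <- pca_latent(cloud, 4)
  expect_true(all(abs(pc2$explained_variance_ratio - 0.25) < 0.05))
  expect_error(pca_latent(matrix(1, 1, 3), 2), "nrow")
})
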