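test_that("fragment-ion counts: identity, disjointness, empty prediction", {
  gt <- parse_peptide("PEPTIDEK")
  ions <- enumerate_theoretical_ions(gt, charges = 1L, losses = "none")
  s <- spectrum_at(sort(ions$mz))            # every singly charged b/y present
  r <- evaluate_fragment_ions(s, gt, gt)
  expect_gt(r$gt_matched, 0L)
  expect_identical(r$shared_matched, r$gt_matched)   # dn = gt shares all

  r0 <- evaluate_fragment_ions(s, gt, new_peptide())
  expect_identical(r0$dn_matched, 0L)
  expect_identical(r0$shared_matched, 0L)
  expect_identical(r0$gt_matched, r$gt_matched)

  # a de novo peptide whose ions live far from every gt-matched peak
  dn_far <- parse_peptide("WWWWWWWW")
  r_far <- evaluate_fragment_ions(spectrum_at(sort(ions$mz[1:5])), gt, dn_far)
  expect_lte(r_far$shared_matched, min(r_far$gt_matched, r_far$dn_matched))
})

test_that("a shared peak counts once even when several ions hit it", {
  # one peak satisfied by a b ion of gt and of dn: peak-level counting
  gt <- parse_peptide("AGK")
  s <- spectrum_at(c(72.04439))              # b1 of A...
  r <- evaluate_fragment_ions(s, gt, parse_peptide("AGR"))
  expect_identical(r$gt_matched, 1L)
  expect_identical(r$dn_matched, 1L)
  expect_identical(r$shared_matched, 1L)
  # ion-level counting reports ions, not peaks
  r_ion <- evaluate_fragment_ions(s, gt, parse_peptide("AGR"),
                                  count = "ions")
  expect_gte(r_ion$gt_matched, r$gt_matched)
})

test_that("amino-acid alignment follows the mass-cursor rule", {
  al <- align_amino_acids(parse_peptide("PEPTIDE"), parse_peptide("PEPTIDE"))
  expect_identical(al$aa_matched, 7L)
  expect_true(al$peptide_match)

  # transposed residues shift every cumulative mass: nothing matches
  al <- align_amino_acids(parse_peptide("GA"), parse_peptide("AG"))
  expect_identical(al$aa_matched, 0L)
  expect_false(al$peptide_match)

  # empty prediction
  al <- align_amino_acids(new_peptide(), parse_peptide("AGK"))
  expect_identical(al$aa_matched, 0L)
  expect_false(al$peptide_match)

  # a shorter prediction can have all residues matched yet counts as a
  # peptide match only through its own residues
  al <- align_amino_acids(parse_peptide("AG"), parse_peptide("AGK"))
  expect_identical(al$aa_matched, 2L)
})

test_that("isobaric substitutions match at the same position", {
  pairs <- list(c("L", "I"), c("I", "L"), c("K", "Q"), c("Q", "K"),
                c("Q(Deamidation)", "E"), c("M(Oxidation)", "F"),
                c("N(Deamidation)", "D"))
  set.seed(31)
  for (pr in pairs) {
    base <- random_peptide(9, tryptic = FALSE)
    pos <- sample(1:9, 1)
    # gt has pr[2], dn has pr[1] at `pos`, otherwise identical
    aa <- base$aa
    gt_txt <- paste0(c(aa[seq_len(pos - 1)], pr[2],
                       if (pos < 9) aa[(pos + 1):9]), collapse = "")
    dn_txt <- paste0(c(aa[seq_len(pos - 1)], pr[1],
                       if (pos < 9) aa[(pos + 1):9]), collapse = "")
    al <- align_amino_acids(parse_peptide(dn_txt), parse_peptide(gt_txt))
    expect_identical(al$aa_matched, 9L)
    expect_true(al$peptide_match)
  }
})

test_that("greedy cursor alignment equals the DP maximizer", {
  alphabet <- c("G", "A", "S", "P", "V")
  strings <- all_strings(alphabet, 3)
  peps <- lapply(strings, parse_peptide)
  idx <- seq_along(peps)
  set.seed(32)
  # exhaustive over a subsample here; the full grid runs in the
  # acceptance suite
  sub <- sample(idx, 40)
  for (i in sub) for (j in sub) {
    expect_identical(align_amino_acids(peps[[i]], peps[[j]])$aa_matched,
                     dp_max_aa_matches(peps[[i]], peps[[j]]))
  }
})

test_that("aggregation micro-averages numerators over denominators", {
  evals <- data.frame(scan_id = c("a", "b"), gt_len = c(10, 10),
                      gt_matched = c(10, 10), dn_matched = c(9, 8),
                      shared_matched = c(9, 7), aa_total_gt = c(10, 10),
                      aa_matched = c(9, 7), peptide_match = c(TRUE, FALSE))
  rep <- aggregate_accuracy(evals)
  expect_equal(rep$fragment_ion_accuracy, 16 / 20)
  expect_equal(rep$amino_acid_accuracy, 16 / 20)
  expect_equal(rep$peptide_accuracy, 1 / 2)
  expect_error(aggregate_accuracy(evals[0, ]), "empty")
})

test_that("abstentions dilute accuracy; 3-of-4 plus one empty gives 0.8", {
  set.seed(33)
  fx <- generate_fixture_dataset(5, config = spectrum_sim_config(
    dropout = 0, noise_peaks = 0, mz_jitter = 0))
  dn <- fx$truth[, c("scan_id", "peptide")]
  dn$peptide[5] <- ""                         # tool returned nothing
  dn$score <- 100
  evals <- evaluate_psms(fx$spectra, dn, fx$truth)
  rep <- aggregate_accuracy(evals)
  expect_equal(rep$peptide_accuracy, 4 / 5)
  expect_lt(rep$amino_acid_accuracy, 1)
  expect_identical(evals$dn_matched[5], 0L)

  dn$peptide <- fx$truth$peptide              # all identical -> all 1.0
  rep1 <- aggregate_accuracy(evaluate_psms(fx$spectra, dn, fx$truth))
  expect_equal(rep1$fragment_ion_accuracy, 1)
  expect_equal(rep1$amino_acid_accuracy, 1)
  expect_equal(rep1$peptide_accuracy, 1)
})

test_that("micro-averages are conserved across any partition of PSMs", {
  set.seed(34)
  fx <- generate_fixture_dataset(30)
  dn <- mock_denovo(fx$spectra, fx$truth)
  evals <- evaluate_psms(fx$spectra, dn, fx$truth)
  whole <- aggregate_accuracy(evals)
  part <- sample(1:3, nrow(evals), replace = TRUE)
  tot <- colSums(do.call(rbind, lapply(1:3, function(g)
    unlist(aggregate_accuracy(evals[part == g, ])$totals))))
  expect_equal(tot[["shared_matched"]] / tot[["gt_matched"]],
               whole$fragment_ion_accuracy)
  expect_equal(tot[["aa_matched"]] / tot[["aa_total_gt"]],
               whole$amino_acid_accuracy)
  expect_equal(tot[["peptides_matched"]] / tot[["peptides_total"]],
               whole$peptide_accuracy)
  expect_true(all(c(whole$fragment_ion_accuracy, whole$amino_acid_accuracy,
                    whole$peptide_accuracy) >= 0))
  expect_true(all(c(whole$fragment_ion_accuracy, whole$amino_acid_accuracy,
                    whole$peptide_accuracy) <= 1))
})

test_that("length stratification conserves totals and flags bad bins", {
  set.seed(35)
  fx <- generate_fixture_dataset(40)
  dn <- mock_denovo(fx$spectra, fx$truth)
  evals <- evaluate_psms(fx$spectra, dn, fx$truth)

  one <- stratify_by_length(evals, breaks = c(7, 20))
  whole <- aggregate_accuracy(evals)
  expect_identical(nrow(one), 1L)
  expect_equal(one$fragment_ion_accuracy, whole$fragment_ion_accuracy)

  two <- stratify_by_length(evals, breaks = c(7, 12, 20))
  expect_identical(sum(two$n_psms), nrow(evals))
  expect_identical(sum(two$gt_matched), whole$totals$gt_matched)
  expect_identical(sum(two$aa_matched), whole$totals$aa_matched)

  expect_error(stratify_by_length(evals, breaks = c(7, 7, 20)),
               "strictly increasing")
  expect_error(stratify_by_length(evals, breaks = c(10, 20)), "cover")

  # empty bin reports undefined ratios, zero denominators
  empty <- stratify_by_length(evals[evals$gt_len >= 10, ],
                              breaks = c(1, 5, 25))
  expect_identical(empty$n_psms[1], 0L)
  expect_true(is.nan(empty$fragment_ion_accuracy[1]))
})
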