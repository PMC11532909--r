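hamming <- function(a, b) sum(a$aa != b$aa)

test_that("mutation introduces exactly k substitutions", {
  set.seed(61)
  p <- parse_peptide("M(Oxidation)AGDESTVKLR")
  expect_identical(hamming(mutate_peptide(p, 0), p), 0L)
  for (k in c(1, 3, 7, length(p))) {
    for (rep in 1:10) {
      m <- mutate_peptide(p, k)
      expect_identical(hamming(m, p), as.integer(k))
      expect_identical(length(attr(m, "mutated_positions")), as.integer(k))
      # modifications dropped at mutated positions
      expect_true(all(is.na(m$mod[attr(m, "mutated_positions")])))
    }
  }
  m_all <- mutate_peptide(p, length(p))
  expect_true(all(m_all$aa != p$aa))
  expect_error(mutate_peptide(p, length(p) + 1), "between 0 and")
})

test_that("mutation datasets cover each k once, skipping short peptides", {
  peps <- c("AGSTVLKDER", "AGK", "PEPTIDESRVVK")
  ds <- generate_mutation_datasets(peps, 1:10, seed = 62)
  expect_length(ds, 10L)
  expect_identical(names(ds)[1], "k=1")
  expect_identical(nrow(ds[["k=1"]]), 3L)
  expect_identical(nrow(ds[["k=5"]]), 2L)              # "AGK" too short
  expect_identical(attr(ds[["k=5"]], "n_skipped"), 1L)
  for (k in c(2L, 8L)) {
    d <- ds[[paste0("k=", k)]]
    for (r in seq_len(nrow(d))) {
      expect_identical(hamming(parse_peptide(d$mutated[r]),
                               parse_peptide(d$original[r])), k)
      expect_identical(length(strsplit(d$positions[r], ",")[[1]]),
                       as.integer(k))
    }
  }
  ds2 <- generate_mutation_datasets(peps, 1:10, seed = 62)
  expect_identical(ds, ds2)                            # seed determinism
})

test_that("noise-free in-silico spectra are closed under the ion model", {
  set.seed(63)
  cfg0 <- spectrum_sim_config(dropout = 0, noise_peaks = 0, mz_jitter = 0)
  p <- random_peptide(12)
  s <- predict_spectrum_simple(p, "X1", config = cfg0)
  expect_identical(nrow(s$peaks), 2L * (length(p) - 1L))
  ions <- enumerate_theoretical_ions(p, charges = 1L, losses = "none")
  expect_identical(match_ions(s, ions)$matched_ion_count, nrow(ions))
  expect_equal(precursor_neutral_mass(s$precursor_mz, s$precursor_charge),
               peptide_neutral_mass(p), tolerance = 1e-4)
  expect_error(predict_spectrum_simple(parse_peptide("K"), "X2"),
               "shorter than 2")
})

test_that("peak dropout thins spectra at the configured binomial rate", {
  set.seed(64)
  p <- random_peptide(11)                              # 20 b/y ions
  cfg <- spectrum_sim_config(dropout = 0.5, noise_peaks = 0, mz_jitter = 0)
  counts <- vapply(1:1000, function(i)
    nrow(predict_spectrum_simple(p, paste0("D", i), config = cfg)$peaks),
    integer(1))
  # mean within 4 standard errors of 20 * 0.5
  se <- sqrt(20 * 0.25 / 1000)
  expect_lt(abs(mean(counts) - 10), 4 * se)
})

test_that("fixture datasets are deterministic and self-consistent", {
  cfg0 <- spectrum_sim_config(dropout = 0, noise_peaks = 0, mz_jitter = 0)
  fx <- generate_fixture_dataset(50, seed = 65, config = cfg0)
  expect_length(fx$spectra, 50L)
  expect_identical(nrow(fx$truth), 50L)
  expect_true(all(fx$truth$length >= 7 & fx$truth$length <= 20))
  # tryptic-like C-terminus
  last <- vapply(fx$truth$peptide, function(t) {
    p <- parse_peptide(t); p$aa[length(p)]
  }, character(1))
  expect_true(all(last %in% c("K", "R")))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_mgf(generate_fixture_dataset(50, seed = 65, config = cfg0)$spectra, f1)
  write_mgf(generate_fixture_dataset(50, seed = 65, config = cfg0)$spectra, f2)
  expect_identical(readLines(f1), readLines(f2))

  # evaluating the truth against itself is perfect when nothing is dropped
  dn <- fx$truth[, c("scan_id", "peptide")]
  rep <- aggregate_accuracy(evaluate_psms(fx$spectra, dn, fx$truth))
  expect_equal(rep$fragment_ion_accuracy, 1)
  expect_equal(rep$peptide_accuracy, 1)
})

test_that("zero-error engine reproduces the ground truth exactly", {
  set.seed(66)
  fx <- generate_fixture_dataset(25, config = spectrum_sim_config(
    dropout = 0, noise_peaks = 0, mz_jitter = 0))
  eng0 <- mock_engine_config(residue_error_rate = 0, swap_rate = 0,
                             missing_site_swap_rate = 0, score_noise_sd = 0)
  psms <- mock_denovo(fx$spectra, fx$truth, eng0)
  expect_identical(psms$peptide, fx$truth$peptide)
  expect_equal(psms$score, rep(100, 25))
})

test_that("residue errors lower peptide accuracy near the closed form", {
  set.seed(67)
  peps <- replicate(2000, format_peptide(random_peptide(10)))
  ids <- sprintf("E%04d", 1:2000)
  truth <- data.frame(scan_id = ids, peptide = peps,
                      stringsAsFactors = FALSE)
  cfg0 <- spectrum_sim_config(dropout = 0, noise_peaks = 0, mz_jitter = 0)
  spectra <- lapply(1:2000, function(i)
    predict_spectrum_simple(parse_peptide(peps[i]), ids[i], config = cfg0))
  eng <- mock_engine_config(residue_error_rate = 0.02, swap_rate = 0,
                            missing_site_swap_rate = 0)
  psms <- mock_denovo(spectra, truth, eng)
  acc <- aggregate_accuracy(evaluate_psms(spectra, psms, truth))
  # (1 - e)^L plus a small excess from isobaric substitutions
  expect_lt(abs(acc$peptide_accuracy - 0.98^10), 0.03)
})

test_that("engine scores fall on heavily degraded decoy spectra", {
  set.seed(68)
  fx <- generate_fixture_dataset(500)
  dec <- generate_decoy_dataset(fx$spectra, "random", 0.9, seed = 680)
  psms_t <- mock_denovo(fx$spectra, fx$truth)
  psms_d <- mock_denovo(dec$decoys, fx$truth)
  w <- stats::wilcox.test(psms_d$score, psms_t$score,
                          alternative = "less")
  expect_lt(w$p.value, 1e-10)
  expect_lt(stats::median(psms_d$score), stats::median(psms_t$score))
})

test_that("positional accuracy classes isolate where errors occur", {
  set.seed(69)
  # all-correct predictions: every class at 1.0
  peps <- replicate(40, format_peptide(random_peptide(15)))
  ids <- sprintf("P%03d", 1:40)
  pos <- sample(1:15, 40, replace = TRUE)
  truth <- data.frame(scan_id = ids, peptide = peps,
                      positions = as.character(pos),
                      stringsAsFactors = FALSE)
  dn <- data.frame(scan_id = ids, peptide = peps, stringsAsFactors = FALSE)
  pa <- positional_accuracy(dn, truth, fixed_length = 15)
  expect_true(all(pa$classes$accuracy[pa$classes$n > 0] == 1))
  expect_identical(nrow(pa$by_position), 15L)

  # break position 1 in every prediction: first-3 falls, middle intact
  dn_bad <- dn
  dn_bad$peptide <- vapply(dn$peptide, function(t) {
    p <- parse_peptide(t)
    p$aa[1] <- if (p$aa[1] == "G") "W" else "G"
    format_peptide(p)
  }, character(1))
  pa2 <- positional_accuracy(dn_bad, truth)
  first3 <- pa2$classes[pa2$classes$class == "first3", ]
  middle3 <- pa2$classes[pa2$classes$class == "middle3", ]
  if (first3$n > 0 && middle3$n > 0)
    expect_lte(first3$accuracy, middle3$accuracy)

  # peptides too short for disjoint classes are excluded and counted
  short <- data.frame(scan_id = "S1", peptide = "AGSTVLK", positions = "2",
                      stringsAsFactors = FALSE)
  pa3 <- positional_accuracy(data.frame(scan_id = "S1", peptide = "AGSTVLK",
                                        stringsAsFactors = FALSE), short)
  expect_identical(pa3$n_excluded_short, 1L)
  expect_true(all(pa3$classes$n == 0L))
})
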