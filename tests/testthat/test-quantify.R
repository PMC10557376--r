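lay2 <- generate_layout(generator_config(n_sets = 2L))

test_that("protein abundances are exact sums of peptide evidence", {
  ev <- aggregate_to_peptides(dplyr::bind_rows(
    make_psm("a", 1, "AAK", "P1", c(1, 2, rep(0, 8))),
    make_psm("b", 1, "CCK", "P1", c(3, 4, rep(0, 8))),
    make_psm("c", 1, "DDK", "P2", c(5, 0, 1, rep(0, 7)))
  ), lay2)
  q <- protein_group_abundance(ev)
  p1 <- q[q$protein_accession == "P1" & q$set_id == 1, ]
  expect_equal(p1$abundance[p1$channel_index == 1], 4)
  expect_equal(p1$abundance[p1$channel_index == 2], 6)
  expect_equal(unique(p1$n_peptides), 2L)
  p2 <- q[q$protein_accession == "P2" & q$set_id == 1, ]
  expect_equal(p2$abundance[p2$channel_index == 1], 5)
  # conservation on simulated data
  cfg <- generator_config(n_sets = 2L, n_proteins = 20L, seed = 13L)
  evs <- aggregate_to_peptides(simulate_psm_table(cfg), generate_layout(cfg))
  expect_equal(sum(protein_group_abundance(evs)$abundance),
               sum(evs$abundance))
})

test_that("single-mean normalization makes the single class read as 1", {
  reporters <- rep(0, 10)
  # layout order: C C S D S D S D E E
  reporters[c(3, 5, 7)] <- 1     # singles
  reporters[c(4, 6, 8)] <- 1.6   # doubles
  reporters[c(1, 2)] <- 100      # carriers
  ev <- aggregate_to_peptides(make_psm("a", 1, "AAK", "P1", reporters), lay2)
  q <- normalize_per_protein(protein_group_abundance(ev), lay2)
  s1 <- q[q$set_id == 1, ]
  expect_equal(s1$norm_abundance[s1$channel_class == "SINGLE"], rep(1, 3))
  expect_equal(s1$norm_abundance[s1$channel_class == "DOUBLE"], rep(1.6, 3))
  expect_equal(s1$norm_abundance[s1$channel_class == "CARRIER"], rep(100, 2))
  # set 2 has no signal at all: normalized values are NA, not imputed
  expect_true(all(is.na(q$norm_abundance[q$set_id == 2])))
})

test_that("all-zero proteins keep zero vectors and null normalized values", {
  ev <- aggregate_to_peptides(make_psm("a", 1, "AAK", "P1", rep(0, 10)), lay2)
  q <- normalize_per_protein(protein_group_abundance(ev), lay2)
  expect_true(all(q$abundance == 0))
  expect_true(all(is.na(q$norm_abundance)))
})

test_that("clean-limit class comparison hits the theoretical ratios", {
  cfg <- clean_config()
  lay <- generate_layout(cfg)
  ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
  q <- normalize_per_protein(protein_group_abundance(ev), lay)
  for (est in c("geometric", "arithmetic")) {
    cs <- class_comparison(q, lay, ratio_estimator = est, n_boot = 50L)
    expect_equal(cs$enrichment_double_vs_single, 100)
    expect_equal(cs$carrier_factor, 250)
  }
})

test_that("noise-free enrichment recovers 100(1 - c) across compression grid", {
  for (c in c(0, 0.25, 0.4, 0.8)) {
    cfg <- clean_config(n_sets = 1L, n_proteins = 6L, compression_c = c)
    lay <- generate_layout(cfg)
    ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
    q <- normalize_per_protein(protein_group_abundance(ev), lay)
    cs <- class_comparison(q, lay, n_boot = 10L)
    expect_equal(cs$enrichment_double_vs_single, 100 * (1 - c))
  }
})

test_that("enrichment decreases in compression and carrier factor stays below 250", {
  enr <- carr <- numeric(0)
  for (c in c(0.1, 0.5, 0.9)) {
    cfg <- clean_config(n_sets = 1L, n_proteins = 6L, compression_c = c)
    lay <- generate_layout(cfg)
    ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
    cs <- class_comparison(normalize_per_protein(protein_group_abundance(ev),
                                                 lay), lay, n_boot = 10L)
    enr <- c(enr, cs$enrichment_double_vs_single)
    carr <- c(carr, cs$carrier_factor)
  }
  expect_true(all(diff(enr) < 0))
  expect_true(all(carr < 250))
  # attenuated carrier also stays below the theoretical limit
  cfg <- clean_config(n_sets = 1L, n_proteins = 6L, carrier_attenuation = 0.5)
  lay <- generate_layout(cfg)
  ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
  cs <- class_comparison(normalize_per_protein(protein_group_abundance(ev),
                                               lay), lay, n_boot = 10L)
  expect_equal(cs$carrier_factor, 125)
})

test_that("class summaries are invariant to rescaling one set", {
  cfg <- generator_config(n_sets = 2L, n_proteins = 20L,
                          contaminant_fraction = 0, seed = 29L)
  lay <- generate_layout(cfg)
  psms <- simulate_psm_table(cfg)
  scaled <- psms
  k <- 7.3
  idx <- scaled$set_id == 2L
  for (col in reporter_cols()) scaled[[col]][idx] <- scaled[[col]][idx] * k
  summarize <- function(p) {
    ev <- aggregate_to_peptides(p, lay)
    q <- normalize_per_protein(protein_group_abundance(ev), lay)
    withr::with_seed(1, class_comparison(q, lay, n_boot = 50L))
  }
  a <- summarize(psms)
  b <- summarize(scaled)
  expect_equal(b$enrichment_double_vs_single, a$enrichment_double_vs_single)
  expect_equal(b$carrier_factor, a$carrier_factor)
  expect_equal(b$class_stats, a$class_stats)
})

test_that("mean enrichment recovers the compression model across seeds", {
  enr <- vapply(1:8, function(s) {
    cfg <- generator_config(n_sets = 4L, n_proteins = 60L, seed = 200L + s)
    lay <- generate_layout(cfg)
    fl <- filter_pipeline(simulate_psm_table(cfg), lay,
                          simulate_bulk_table(cfg))
    q <- normalize_per_protein(protein_group_abundance(fl$evidence), lay)
    class_comparison(q, lay, n_boot = 10L)$enrichment_double_vs_single
  }, numeric(1))
  se <- stats::sd(enr) / sqrt(length(enr))
  expect_lt(abs(mean(enr) - 60), 3 * se + 1e-9)
})

test_that("empty-channel test distinguishes carry-over from clean background", {
  cfg <- clean_config()
  lay <- generate_layout(cfg)
  ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
  q <- normalize_per_protein(protein_group_abundance(ev), lay)
  et <- empty_background_test(q, lay, n_boot = 100L)
  expect_true(et$indistinguishable)
  expect_equal(et$mean, 0)

  # empties at the single-cell level: clearly distinguishable
  cfg2 <- generator_config(n_sets = 2L, n_proteins = 15L, empty_floor = 1,
                           contaminant_fraction = 0, seed = 15L)
  lay2b <- generate_layout(cfg2)
  ev2 <- aggregate_to_peptides(simulate_psm_table(cfg2), lay2b)
  q2 <- normalize_per_protein(protein_group_abundance(ev2), lay2b)
  et2 <- withr::with_seed(1, empty_background_test(q2, lay2b, n_boot = 200L))
  expect_false(et2$indistinguishable)
  expect_lt(et2$p_value, 0.001)
  expect_error(empty_background_test(q2[0, ], lay2b), ">= 2 observations")
})

test_that("labeling efficiency is the percent of flagged PSMs", {
  psms <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_psm(paste0("p", i), 1, paste0("PE", LETTERS[i], "K"), "P1",
             rep(1, 10), labeled = i <= 3)
  }))
  expect_equal(labeling_efficiency(psms), 75)
  expect_equal(labeling_efficiency(dplyr::mutate(psms, is_labeled = TRUE)),
               100)
  expect_error(labeling_efficiency(psms[0, ]), "empty")
  # binomial recovery at a different completeness setting
  cfg <- generator_config(n_sets = 4L, n_proteins = 250L,
                          labeling_prob = 0.85, seed = 77L)
  psms_sim <- simulate_psm_table(cfg)
  expect_gte(nrow(psms_sim), 2000L)
  expect_lt(abs(labeling_efficiency(psms_sim) - 85), 2)
})
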