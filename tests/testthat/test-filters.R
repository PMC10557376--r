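two_set_layout <- function() generate_layout(generator_config(n_sets = 2L))

test_that("fdr_filter implements the four validator rules inclusively", {
  psms <- dplyr::bind_rows(
    make_psm("a", 1, "AAK", "P1", rep(1, 10), q_perc = 0.01, q_td = 0.2),
    make_psm("b", 1, "CCK", "P1", rep(1, 10), q_perc = 0.2, q_td = 0.01),
    make_psm("c", 1, "DDK", "P1", rep(1, 10), q_perc = 0.2, q_td = 0.2),
    make_psm("d", 1, "EEK", "P1", rep(1, 10), q_perc = 0.05, q_td = 0.05)
  )
  expect_equal(fdr_filter(psms, 0.05, "either")$psm_id, c("a", "b", "d"))
  expect_equal(fdr_filter(psms, 0.05, "both")$psm_id, "d")
  expect_equal(fdr_filter(psms, 0.05, "percolator")$psm_id, c("a", "d"))
  expect_equal(fdr_filter(psms, 0.05, "targetdecoy")$psm_id, c("b", "d"))
  expect_error(fdr_filter(psms[, setdiff(names(psms), "q_targetdecoy")],
                          0.05, "either"), "q_targetdecoy")
  expect_error(fdr_filter(psms, 1.5), "\\[0, 1\\]")
})

test_that("contaminant removal drops listed accessions and reports them", {
  keratins <- c("P04264", "P13645", "P35527")
  psms <- dplyr::bind_rows(
    lapply(1:7, function(i) make_psm(paste0("t", i), 1,
                                     paste0("PEP", LETTERS[i], "K"),
                                     paste0("TARG", i), rep(1, 10))),
    lapply(1:3, function(i) make_psm(paste0("k", i), 1,
                                     paste0("KER", LETTERS[i], "K"),
                                     keratins[i], rep(1, 10),
                                     contaminant = TRUE))
  )
  out <- remove_contaminants(psms)
  expect_equal(nrow(out), 7L)
  expect_setequal(attr(out, "removed_accessions"), keratins)
  expect_equal(nrow(remove_contaminants(psms, character(0))), 10L)
  all_contam <- psms[psms$is_contaminant, ]
  expect_equal(nrow(remove_contaminants(all_contam)), 0L)
})

test_that("aggregation sums PSM intensities and conserves total signal", {
  lay <- two_set_layout()
  psms <- dplyr::bind_rows(
    make_psm("a", 1, "AAK", "P1", c(0, 0, 3, rep(0, 7))),
    make_psm("b", 1, "AAK", "P1", c(0, 0, 4, rep(0, 7))),
    make_psm("c", 2, "AAK", "P1", c(rep(0, 4), 5, rep(0, 5)))
  )
  ev <- aggregate_to_peptides(psms, lay)
  expect_equal(ev$abundance[ev$set_id == 1 & ev$channel_index == 3], 7)
  expect_equal(unique(ev$psm_count), 3L)
  expect_equal(sum(ev$abundance), sum(as.matrix(psms[, reporter_cols()])))

  one <- aggregate_to_peptides(psms[1, ], lay)
  expect_equal(unique(one$psm_count), 1L)
})

test_that("aggregation conserves signal on simulated data", {
  cfg <- generator_config(n_sets = 2L, n_proteins = 30L, seed = 19L)
  psms <- simulate_psm_table(cfg)
  ev <- aggregate_to_peptides(psms, generate_layout(cfg))
  expect_equal(sum(ev$abundance), sum(as.matrix(psms[, reporter_cols()])))
  expect_error(aggregate_to_peptides(psms,
                                     generate_layout(generator_config(n_sets = 1L))),
               "absent from layouts")
})

test_that("channel occupancy matches the printed examples", {
  lay <- generate_layout(generator_config(n_sets = 16L))
  cells <- lay[lay$channel_class %in% c("SINGLE", "DOUBLE"), ]
  expect_equal(nrow(cells), 96L)
  # peptide seen in 90 of 96 cell channels
  reporters90 <- lapply(1:16, function(s) {
    hit <- cells[cells$set_id == s, ]
    r <- rep(0, 10)
    n_hit <- if (s == 1) 0L else 6L  # miss all 6 channels of set 1
    if (n_hit > 0) r[hit$channel_index[seq_len(n_hit)]] <- 1
    make_psm(paste0("p", s), s, "AAK", "P1", r)
  })
  ev <- aggregate_to_peptides(dplyr::bind_rows(reporters90), lay)
  expect_equal(unique(ev$occupancy_percent), 93.75)
  # peptide seen in 6 of 96
  reporters6 <- make_psm("q", 1, "CCK", "P1", {
    r <- rep(0, 10); r[cells$channel_index[cells$set_id == 1]] <- 1; r
  })
  ev6 <- aggregate_to_peptides(reporters6, lay)
  expect_equal(unique(ev6$occupancy_percent), 6.25)
  # all-zero cell channels
  ev0 <- aggregate_to_peptides(make_psm("z", 1, "DDK", "P1", rep(0, 10)), lay)
  expect_equal(unique(ev0$occupancy_percent), 0)
})

test_that("vectorized occupancy equals brute-force scan on random instances", {
  withr::local_seed(101)
  for (i in 1:60) {
    n_sets <- sample(1:3, 1)
    cfg <- generator_config(n_sets = n_sets, n_proteins = sample(2:5, 1),
                            peptides_per_protein_lambda = 0.5,
                            detection_rate_per_cell_channel = stats::runif(1, 0.1, 0.9),
                            labeling_prob = stats::runif(1, 0.5, 1),
                            contaminant_fraction = 0,
                            seed = sample.int(1e6, 1))
    lay <- generate_layout(cfg)
    ev <- aggregate_to_peptides(simulate_psm_table(cfg), lay)
    fast <- unique(tibble::as_tibble(ev)[, c("peptide_key",
                                             "protein_accession",
                                             "occupancy_percent")])
    slow <- occupancy_oracle(ev, lay)
    merged <- dplyr::inner_join(fast, slow,
                                by = c("peptide_key", "protein_accession"),
                                suffix = c("_fast", "_slow"))
    expect_equal(nrow(merged), nrow(fast))
    expect_equal(merged$occupancy_percent_fast, merged$occupancy_percent_slow)
  }
})

test_that("occupancy filter is inclusive at the threshold and idempotent", {
  lay <- two_set_layout()
  cells1 <- lay[lay$set_id == 1 & lay$channel_class %in% c("SINGLE", "DOUBLE"), ]
  # 3 of 12 cell channels -> exactly 25%
  r <- rep(0, 10); r[cells1$channel_index[1:3]] <- 1
  at25 <- make_psm("a", 1, "AAK", "P1", r)
  r6 <- rep(0, 10); r6[cells1$channel_index[1]] <- 1
  below <- make_psm("b", 1, "CCK", "P2", r6)  # 1/12 = 8.33%
  ev <- aggregate_to_peptides(dplyr::bind_rows(at25, below), lay)
  kept <- occupancy_filter(ev, 25)
  expect_setequal(unique(kept$peptide_key), "AAK")
  expect_equal(occupancy_filter(kept, 25), kept)
  expect_equal(nrow(occupancy_filter(ev, 0)), nrow(ev))
})

test_that("bulk-rank filter applies the inclusive top-percentile rule", {
  lay <- two_set_layout()
  ev <- aggregate_to_peptides(dplyr::bind_rows(
    make_psm("a", 1, "AAK", "GAPA", rep(1, 10)),
    make_psm("b", 1, "CCK", "TOLA", rep(1, 10)),
    make_psm("c", 1, "DDK", "UNKNOWN", rep(1, 10))
  ), lay)
  bulk <- tibble::tibble(
    protein_accession = c("GAPA", "TOLA", sprintf("X%04d", 1:1130)),
    is_ribosomal = FALSE, is_membrane = FALSE,
    freeze_thaw_1 = 1, sonication_1 = 1,
    bulk_rank = c(1L, 1001L, setdiff(2:1132, 1001L))
  )
  kept <- bulk_rank_filter(ev, bulk, 0.25, absent_policy = "fail")
  expect_setequal(unique(kept$protein_accession), "GAPA")
  # rank 1001 of 1132 is percentile 88.4%, removed
  expect_false("TOLA" %in% kept$protein_accession)
  exempt <- bulk_rank_filter(ev, bulk, 0.25, absent_policy = "exempt")
  expect_setequal(unique(exempt$protein_accession), c("GAPA", "UNKNOWN"))
  expect_true(all(is.na(exempt$bulk_rank[exempt$protein_accession == "UNKNOWN"])))
  # idempotent
  expect_equal(bulk_rank_filter(kept, bulk, 0.25), kept)
  # empty bulk table with exempt policy is the identity on peptides
  none <- bulk_rank_filter(ev, bulk[0, ], 0.25, absent_policy = "exempt")
  expect_equal(nrow(none), nrow(ev))
})

test_that("identification counting distinguishes multi-peptide proteins", {
  lay <- two_set_layout()
  ev0 <- aggregate_to_peptides(
    simulate_psm_table(generator_config(n_sets = 2L, n_proteins = 3L,
                                        seed = 1L))[0, ], lay)
  expect_equal(count_identifications(ev0),
               list(n_peptides = 0L, n_proteins = 0L,
                    n_proteins_min2_peptides = 0L))
  ev <- aggregate_to_peptides(dplyr::bind_rows(
    make_psm("a", 1, "VGEEVEIVGIK", "TUFB", rep(1, 10)),
    make_psm("b", 1, "ALEGDAEWEAK", "TUFB", rep(1, 10)),
    make_psm("c", 1, "DAIHAAK", "TRMD", rep(1, 10))
  ), lay)
  counts <- count_identifications(ev)
  expect_equal(counts$n_peptides, 3L)
  expect_equal(counts$n_proteins, 2L)
  expect_equal(counts$n_proteins_min2_peptides, 1L)
})

test_that("filter report counts telescope and permissive chain is identity", {
  cfg <- generator_config(n_sets = 2L, n_proteins = 25L, seed = 37L)
  lay <- generate_layout(cfg)
  psms <- simulate_psm_table(cfg)
  bulk <- simulate_bulk_table(cfg)
  fl <- filter_pipeline(psms, lay, bulk)
  rep <- fl$report
  expect_equal(rep$n_in[-1][rep$unit[-1] == rep$unit[-nrow(rep)]],
               rep$n_out[-nrow(rep)][rep$unit[-1] == rep$unit[-nrow(rep)]])
  expect_equal(rep$n_in[1], nrow(psms))

  permissive <- filter_pipeline(psms, lay, bulk, fdr_threshold = 1,
                                contaminants = character(0),
                                min_occupancy = 0, max_rank_percentile = 1,
                                absent_policy = "exempt")
  base <- aggregate_to_peptides(psms, lay)
  expect_equal(nrow(permissive$evidence), nrow(base))
  expect_setequal(unique(permissive$evidence$peptide_key),
                  unique(base$peptide_key))
  expect_equal(permissive$evidence$abundance, base$abundance)
})
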