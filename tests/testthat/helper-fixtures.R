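# Small deterministic fixtures built in code.

# One hand-built PSM row; reporters is a numeric vector of length 10.
make_psm <- function(psm_id, set_id, peptide, protein,
                     reporters = rep(0, 10),
                     q_perc = 0.01, q_td = 0.01,
                     labeled = TRUE, contaminant = FALSE,
                     prev = "K", nxt = "A") {
  row <- tibble::tibble(
    psm_id = psm_id, set_id = as.integer(set_id),
    peptide_key = peptide,
    annotated_sequence = sprintf("[%s].%s.[%s]", prev, peptide, nxt),
    protein_accession = protein, charge = 2L,
    retention_time = 30, observed_mz = 500.5
  )
  for (i in 1:10) row[[reporter_cols()[i]]] <- reporters[i]
  row$q_percolator <- q_perc
  row$q_targetdecoy <- q_td
  row$is_labeled <- labeled
  row$is_contaminant <- contaminant
  row
}

# Tiny clean-limit config used by several deterministic checks; any
# generator_config argument can be overridden through `...`.
clean_config <- function(n_sets = 2L, n_proteins = 12L, seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_sets = n_sets, n_proteins = n_proteins, noise_cv = 0,
         compression_c = 0, detection_rate_per_cell_channel = 1,
         labeling_prob = 1, contaminant_fraction = 0, decoy_rate = 0,
         validator_miss_rate = 0, seed = seed),
    list(...))
  do.call(generator_config, args)
}

# Brute-force channel-occupancy oracle: per-peptide scan over every
# single/double channel of every set.
occupancy_oracle <- function(evidence, layouts, noise_threshold = 0) {
  peps <- unique(evidence[, c("peptide_key", "protein_accession")])
  cells <- layouts[layouts$channel_class %in% c("SINGLE", "DOUBLE"), ]
  res <- lapply(seq_len(nrow(peps)), function(i) {
    hits <- 0L
    for (j in seq_len(nrow(cells))) {
      ab <- evidence$abundance[
        evidence$peptide_key == peps$peptide_key[i] &
          evidence$protein_accession == peps$protein_accession[i] &
          evidence$set_id == cells$set_id[j] &
          evidence$channel_index == cells$channel_index[j]]
      if (length(ab) == 1L && ab > noise_threshold) hits <- hits + 1L
    }
    tibble::tibble(peptide_key = peps$peptide_key[i],
                   protein_accession = peps$protein_accession[i],
                   occupancy_percent = 100 * hits / nrow(cells))
  })
  dplyr::bind_rows(res)
}
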