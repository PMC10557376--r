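#' Filter PSMs by validator q-values
#'
#' Retains PSMs whose q-value passes the FDR threshold under the requested
#' rule: `"percolator"` or `"targetdecoy"` use a single validator's column;
#' `"either"` (the default, matching the study's consensus rule) keeps a PSM
#' if at least one validator passes; `"both"` requires both.
#'
#' @param psms PSM tibble with `q_percolator` and/or `q_targetdecoy`.
#' @param threshold FDR threshold (default 0.05); the comparison is
#'   inclusive (`q <= threshold`).
#' @param mode One of `"either"`, `"both"`, `"percolator"`, `"targetdecoy"`.
#' @return The retained PSM rows.
#' @export
fdr_filter <- function(psms, threshold = 0.05,
                       mode = c("either", "both", "percolator", "targetdecoy")) {
  mode <- match.arg(mode)
  need <- switch(mode,
                 percolator = "q_percolator",
                 targetdecoy = "q_targetdecoy",
                 c("q_percolator", "q_targetdecoy"))
  missing <- setdiff(need, names(psms))
  if (length(missing) > 0L) {
    stop("fdr_filter mode '", mode, "' requires column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  keep <- switch(
    mode,
    percolator = psms$q_percolator <= threshold,
    targetdecoy = psms$q_targetdecoy <= threshold,
    either = psms$q_percolator <= threshold | psms$q_targetdecoy <= threshold,
    both = psms$q_percolator <= threshold & psms$q_targetdecoy <= threshold
  )
  psms[keep, , drop = FALSE]
}

#' Remove contaminant PSMs
#'
#' Drops PSMs whose protein accession is on the contaminant list (keratins,
#' trypsin and similar; see [default_contaminants()]).
#'
#' @param psms PSM tibble.
#' @param contaminant_accessions Character vector of accessions to remove
#'   (default: the packaged list).
#' @return The retained PSM rows, with the removed accessions recorded in
#'   the `removed_accessions` attribute.
#' @export
remove_contaminants <- function(psms,
                                contaminant_accessions = default_contaminants()) {
  drop <- psms$protein_accession %in% contaminant_accessions
  out <- psms[!drop, , drop = FALSE]
  attr(out, "removed_accessions") <- unique(psms$protein_accession[drop])
  out
}

#' Aggregate PSMs to peptide evidence
#'
#' Sums reporter intensities over all PSMs of each (peptide, protein) pair
#' per set and channel, on the full grid of sets and channels given by
#' `layouts` (a channel in which no PSM was observed is an explicit 0).
#' Computes the per-peptide PSM count, the channel-occupancy statistic (via
#' [channel_occupancy()]) and per-validator pass flags (minimum q over the
#' peptide's PSMs at `fdr_threshold`).
#'
#' @param psms PSM tibble (typically after [fdr_filter()] and
#'   [remove_contaminants()]).
#' @param layouts Layout tibble from [generate_layout()]; must cover every
#'   set referenced by the PSMs.
#' @param noise_threshold Intensity above which a channel counts as occupied
#'   (default 0, i.e. any nonzero abundance).
#' @param fdr_threshold Threshold used for the informational
#'   `passed_percolator` / `passed_targetdecoy` flags (default 0.05).
#' @return A `peptide_evidence` tibble, one row per (peptide_key,
#'   protein_accession, set_id, channel_index), with columns `channel_class`,
#'   `abundance`, and peptide-level `psm_count`, `occupancy_percent`,
#'   `passed_percolator`, `passed_targetdecoy`.
#' @export
aggregate_to_peptides <- function(psms, layouts, noise_threshold = 0,
                                  fdr_threshold = 0.05) {
  validate_psm_table(psms)
  bad_sets <- setdiff(unique(psms$set_id), unique(layouts$set_id))
  if (length(bad_sets) > 0L) {
    stop("PSMs reference set(s) absent from layouts: ",
         paste(bad_sets, collapse = ", "), call. = FALSE)
  }
  peptide_stats <- psms |>
    dplyr::group_by(.data$peptide_key, .data$protein_accession) |>
    dplyr::summarise(
      psm_count = dplyr::n(),
      passed_percolator = any(.data$q_percolator <= fdr_threshold),
      passed_targetdecoy = any(.data$q_targetdecoy <= fdr_threshold),
      .groups = "drop"
    )
  long <- psms |>
    dplyr::select(dplyr::all_of(c("peptide_key", "protein_accession",
                                  "set_id", reporter_cols()))) |>
    tidyr::pivot_longer(dplyr::all_of(reporter_cols()),
                        names_to = "channel_index",
                        values_to = "abundance") |>
    dplyr::mutate(channel_index = match(.data$channel_index, reporter_cols())) |>
    dplyr::group_by(.data$peptide_key, .data$protein_accession,
                    .data$set_id, .data$channel_index) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  grid <- tidyr::expand_grid(
    peptide_stats[, c("peptide_key", "protein_accession")],
    layouts[, c("set_id", "channel_index", "channel_class")]
  )
  ev <- grid |>
    dplyr::left_join(long, by = c("peptide_key", "protein_accession",
                                  "set_id", "channel_index")) |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0)) |>
    dplyr::left_join(peptide_stats, by = c("peptide_key", "protein_accession"))
  occ <- channel_occupancy(ev, layouts, noise_threshold)
  ev <- dplyr::left_join(ev, occ[, c("peptide_key", "protein_accession",
                                     "occupancy_percent")],
                         by = c("peptide_key", "protein_accession"))
  class(ev) <- c("peptide_evidence", class(ev))
  ev
}

#' Channel occupancy of peptide evidence
#'
#' The study's occupancy statistic: the percentage of single- and
#' double-cell channels (across all sets of the experiment) in which a
#' peptide shows abundance above `noise_threshold`. Carrier and empty
#' channels enter neither numerator nor denominator; the denominator is
#' `n_sets * (n_single + n_double)` taken from `layouts` (96 in the default
#' 16-set design), regardless of where the peptide was observed.
#'
#' @param evidence Long evidence tibble with `peptide_key`,
#'   `protein_accession`, `set_id`, `channel_index`, `abundance`.
#' @param layouts Layout tibble covering all sets referenced by `evidence`.
#' @param noise_threshold Occupancy counts channels with
#'   `abundance > noise_threshold` (default 0, the "nonzero abundance" rule).
#' @return A tibble per (peptide_key, protein_accession):
#'   `n_occupied`, `n_cell_channels`, `occupancy_percent`.
#' @examples
#' # a peptide seen in 90 of 96 cell channels has occupancy 93.75%
#' @export
channel_occupancy <- function(evidence, layouts, noise_threshold = 0) {
  bad_sets <- setdiff(unique(evidence$set_id), unique(layouts$set_id))
  if (length(bad_sets) > 0L) {
    stop("evidence references set(s) absent from layouts: ",
         paste(bad_sets, collapse = ", "), call. = FALSE)
  }
  cells <- layouts[layouts$channel_class %in% c("SINGLE", "DOUBLE"),
                   c("set_id", "channel_index")]
  n_cell <- nrow(cells)
  if (n_cell == 0L) stop("layouts contain no single/double cell channels",
                         call. = FALSE)
  occ <- evidence |>
    dplyr::inner_join(cells, by = c("set_id", "channel_index")) |>
    dplyr::group_by(.data$peptide_key, .data$protein_accession) |>
    dplyr::summarise(
      n_occupied = sum(.data$abundance > noise_threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_cell_channels = n_cell,
                  occupancy_percent = 100 * .data$n_occupied / n_cell)
  occ
}

peptide_level <- function(evidences) {
  dplyr::distinct(tibble::as_tibble(evidences), .data$peptide_key,
                  .data$protein_accession, .keep_all = FALSE)
}

#' Filter peptide evidence by channel occupancy
#'
#' Retains peptides whose occupancy is at least `min_occupancy` percent
#' (inclusive, mirroring the study's ">= 25%" rule).
#'
#' @param evidences `peptide_evidence` tibble with `occupancy_percent`.
#' @param min_occupancy Minimum occupancy in percent (default 25).
#' @return The retained evidence rows.
#' @export
occupancy_filter <- function(evidences, min_occupancy = 25) {
  evidences[evidences$occupancy_percent >= min_occupancy, , drop = FALSE]
}

#' Filter peptide evidence by bulk abundance rank
#'
#' Retains peptides whose matched bulk-proteome entry lies in the top
#' `max_percentile` fraction of the bulk abundance ranking (inclusive,
#' mirroring the study's "<= 25%" rule); the percentile of a protein with
#' dense rank `r` in a bulk table of `n` entries is `r / n`. Matching is at
#' protein level by default (the bulk table's ranks are protein ranks); a
#' peptide-level mode joins on `peptide_key` when the bulk table carries one.
#'
#' @param evidences `peptide_evidence` tibble.
#' @param bulk_table Bulk table with `bulk_rank` (dense, 1 = most abundant).
#' @param max_percentile Maximum rank percentile as a fraction (default 0.25).
#' @param absent_policy What to do with evidence unmatched in the bulk table:
#'   `"fail"` (default) removes it, `"exempt"` retains and flags it.
#' @param match_on `"protein"` (default) or `"peptide"`.
#' @return The retained evidence rows with `bulk_rank` and
#'   `bulk_rank_percentile` columns added (NA for exempted rows).
#' @export
bulk_rank_filter <- function(evidences, bulk_table, max_percentile = 0.25,
                             absent_policy = c("fail", "exempt"),
                             match_on = c("protein", "peptide")) {
  absent_policy <- match.arg(absent_policy)
  match_on <- match.arg(match_on)
  key <- if (match_on == "protein") "protein_accession" else "peptide_key"
  if (nrow(bulk_table) == 0L) {
    ev <- dplyr::mutate(evidences, bulk_rank = NA_integer_,
                        bulk_rank_percentile = NA_real_)
    return(if (absent_policy == "exempt") ev else ev[0L, , drop = FALSE])
  }
  if (!key %in% names(bulk_table)) {
    stop("bulk table has no '", key, "' column for match_on = '", match_on,
         "'", call. = FALSE)
  }
  n_total <- nrow(bulk_table)
  ranks <- bulk_table[, c(key, "bulk_rank")]
  ev <- evidences |>
    dplyr::select(-dplyr::any_of(c("bulk_rank", "bulk_rank_percentile"))) |>
    dplyr::left_join(ranks, by = key) |>
    dplyr::mutate(bulk_rank_percentile = .data$bulk_rank / n_total)
  keep <- !is.na(ev$bulk_rank_percentile) &
    ev$bulk_rank_percentile <= max_percentile
  if (absent_policy == "exempt") keep <- keep | is.na(ev$bulk_rank_percentile)
  ev[keep, , drop = FALSE]
}

#' Count identifications in peptide evidence
#'
#' @param evidences `peptide_evidence` tibble.
#' @return A list with `n_peptides` (distinct peptide keys), `n_proteins`
#'   (distinct accessions) and `n_proteins_min2_peptides` (accessions with at
#'   least two distinct peptides).
#' @export
count_identifications <- function(evidences) {
  pep <- peptide_level(evidences)
  per_prot <- table(pep$protein_accession)
  list(
    n_peptides = length(unique(pep$peptide_key)),
    n_proteins = length(per_prot),
    n_proteins_min2_peptides = sum(per_prot >= 2L)
  )
}

#' Run the full three-layer validation filter chain
#'
#' Applies, in order: validator FDR filtering ([fdr_filter()]), contaminant
#' removal ([remove_contaminants()]), aggregation to peptide evidence
#' ([aggregate_to_peptides()]), the channel-occupancy cutoff
#' ([occupancy_filter()]) and the bulk-abundance-rank cutoff
#' ([bulk_rank_filter()]), while recording a stage-by-stage filter report
#' whose counts telescope exactly.
#'
#' @param psms PSM tibble.
#' @param layouts Layout tibble.
#' @param bulk_table Bulk table (for the rank filter).
#' @param fdr_threshold,fdr_mode Passed to [fdr_filter()].
#' @param contaminants Passed to [remove_contaminants()].
#' @param noise_threshold Passed to [aggregate_to_peptides()].
#' @param min_occupancy Passed to [occupancy_filter()].
#' @param max_rank_percentile,absent_policy Passed to [bulk_rank_filter()].
#' @return A list with `evidence` (the retained `peptide_evidence`),
#'   `report` (a `filter_report` tibble: stage, unit, n_in, n_out, with
#'   removed identifiers in the `removed` attribute and parameters in the
#'   `parameters` attribute).
#' @export
filter_pipeline <- function(psms, layouts, bulk_table,
                            fdr_threshold = 0.05, fdr_mode = "either",
                            contaminants = default_contaminants(),
                            noise_threshold = 0,
                            min_occupancy = 25,
                            max_rank_percentile = 0.25,
                            absent_policy = "fail") {
  stages <- list()
  removed <- list()
  add_stage <- function(stage, unit, n_in, n_out, removed_ids) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, unit = unit, n_in = n_in, n_out = n_out)
    removed[[stage]] <<- removed_ids
  }

  f1 <- fdr_filter(psms, fdr_threshold, fdr_mode)
  add_stage("fdr", "PSM", nrow(psms), nrow(f1),
            setdiff(psms$psm_id, f1$psm_id))
  f2 <- remove_contaminants(f1, contaminants)
  add_stage("contaminants", "PSM", nrow(f1), nrow(f2),
            attr(f2, "removed_accessions"))

  ev <- aggregate_to_peptides(f2, layouts, noise_threshold, fdr_threshold)
  n_pep <- function(e) nrow(peptide_level(e))
  add_stage("aggregate", "peptide", n_pep(ev), n_pep(ev), character(0))

  ev_occ <- occupancy_filter(ev, min_occupancy)
  add_stage("occupancy", "peptide", n_pep(ev), n_pep(ev_occ),
            setdiff(peptide_level(ev)$peptide_key,
                    peptide_level(ev_occ)$peptide_key))
  ev_rank <- bulk_rank_filter(ev_occ, bulk_table, max_rank_percentile,
                              absent_policy)
  add_stage("bulk_rank", "peptide", n_pep(ev_occ), n_pep(ev_rank),
            setdiff(peptide_level(ev_occ)$peptide_key,
                    peptide_level(ev_rank)$peptide_key))

  report <- dplyr::bind_rows(stages)
  attr(report, "removed") <- removed
  attr(report, "parameters") <- list(
    fdr_threshold = fdr_threshold, fdr_mode = fdr_mode,
    noise_threshold = noise_threshold, min_occupancy = min_occupancy,
    max_rank_percentile = max_rank_percentile, absent_policy = absent_policy,
    n_contaminant_accessions = length(contaminants)
  )
  class(report) <- c("filter_report", class(report))
  list(evidence = ev_rank, report = report)
}
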