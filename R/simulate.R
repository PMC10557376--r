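#' @importFrom rlang .data
NULL

#' Names of the ten reporter-intensity columns
#'
#' PSM tables carry reporter-ion intensities in wide columns
#' `reporter_01` .. `reporter_10`, aligned to `channel_index` 1..10 of the
#' set layout.
#' @return Character vector of length 10.
#' @export
reporter_cols <- function() sprintf("reporter_%02d", 1:10)

amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, min_len = 6L, max_len = 18L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  peps <- vapply(lens, function(l) {
    paste0(sample(amino_acids, l, replace = TRUE), collapse = "")
  }, character(1))
  # collisions are vanishingly rare at these lengths; regenerate if any
  while (anyDuplicated(peps) > 0L) {
    dup <- duplicated(peps)
    peps[dup] <- vapply(lens[dup], function(l) {
      paste0(sample(amino_acids, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  peps
}

#' Generate a synthetic proteome
#'
#' Draws a proteome of `n_proteins` with log-normal true per-cell abundances,
#' flags a subset as ribosomal and (disjointly) a configured fraction as
#' membrane proteins, and assigns each protein `1 + Poisson(lambda)` unique
#' synthetic peptide sequences. Ribosomal abundances are rescaled so their
#' share of total abundance equals `ribosomal_share` exactly.
#'
#' @param config A [generator_config()].
#' @return A list with `proteins` (tibble: `protein_accession`,
#'   `true_abundance`, `is_ribosomal`, `is_membrane`) and `peptides` (tibble:
#'   `peptide_key`, `protein_accession`), deterministic given `config$seed`.
#' @export
simulate_proteome <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    acc <- sprintf("SYNP%04d", seq_len(n))
    ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$bulk_abundance_sdlog)
    n_ribo <- if (config$ribosomal_share > 0 && n > 0) {
      max(1L, round(0.08 * n))
    } else 0L
    is_ribo <- seq_len(n) %in% sample.int(n, n_ribo)
    n_mem <- round(config$membrane_fraction * n)
    non_ribo <- which(!is_ribo)
    is_mem <- seq_len(n) %in% sample(non_ribo, min(n_mem, length(non_ribo)))
    if (n_ribo > 0L && config$ribosomal_share < 1) {
      # rescale ribosomal abundances so their share is exact
      target <- config$ribosomal_share
      alpha <- target / (1 - target) * sum(ab[!is_ribo]) / sum(ab[is_ribo])
      ab[is_ribo] <- ab[is_ribo] * alpha
    }
    n_pep <- 1L + stats::rpois(n, config$peptides_per_protein_lambda)
    peptides <- tibble::tibble(
      peptide_key = random_peptides(sum(n_pep)),
      protein_accession = rep(acc, times = n_pep)
    )
    list(
      proteins = tibble::tibble(
        protein_accession = acc,
        true_abundance = ab,
        is_ribosomal = is_ribo,
        is_membrane = is_mem
      ),
      peptides = peptides
    )
  })
}

# Fixed per-peptide observables (flanks, charge, RT, m/z, response factor).
peptide_observables <- function(peptide_keys) {
  n <- length(peptide_keys)
  prev <- sample(c(amino_acids, "-"), n, replace = TRUE, prob = c(rep(1, 20), 2))
  nxt <- sample(c(amino_acids, "-"), n, replace = TRUE, prob = c(rep(1, 20), 2))
  tibble::tibble(
    peptide_key = peptide_keys,
    annotated_sequence = sprintf("[%s].%s.[%s]", prev, peptide_keys, nxt),
    charge = sample(2:4, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    retention_time = round(stats::runif(n, 20, 95), 2),
    observed_mz = round(stats::runif(n, 350, 1000), 4),
    response = stats::rlnorm(n, 0, 0.5)
  )
}

# Two partially dependent validator q-value columns.
simulate_q_values <- function(n, config) {
  is_decoy <- stats::runif(n) < config$decoy_rate
  draw_one <- function() {
    q <- stats::rbeta(n, 1, config$q_true_shape2)
    miss <- stats::runif(n) < config$validator_miss_rate
    q[miss] <- stats::runif(sum(miss))
    q[is_decoy] <- stats::runif(sum(is_decoy))
    q
  }
  list(q_percolator = draw_one(), q_targetdecoy = draw_one(),
       is_decoy = is_decoy)
}

#' Simulate a PSM table for a multi-set SCoPE-MS experiment
#'
#' Generates one PSM per (peptide, set). For labeled PSMs, the intensity in
#' channel `j` is
#' `response * true_abundance * compressed_load_ratio_j * noise`, where load
#' ratios are relative to the single-cell load and compressed by
#' [apply_compression()] with `config$compression_c`; carrier channels are
#' additionally multiplied by `carrier_attenuation`. Single/double-cell
#' channels are independently zeroed with probability
#' `1 - detection_rate_per_cell_channel` (a missed detection is stored as an
#' explicit 0); carrier channels are always detected. Empty channels carry
#' only `empty_floor` background (on the peptide's single-cell intensity
#' scale), never compressed signal. With probability `1 - labeling_prob` a
#' PSM is unlabeled and all ten reporter intensities are 0. A configured
#' fraction of PSMs is assigned to contaminant accessions (keratins,
#' trypsin) with ambient, layout-independent intensities. Two validator
#' q-value columns are simulated with partial dependence.
#'
#' @param config A [generator_config()].
#' @param layouts Layout tibble from [generate_layout()]; defaults to the
#'   layout implied by `config`.
#' @param proteome Proteome from [simulate_proteome()]; defaults to the one
#'   implied by `config`.
#' @return A PSM tibble with columns `psm_id`, `set_id`, `peptide_key`,
#'   `annotated_sequence`, `protein_accession`, `charge`, `retention_time`,
#'   `observed_mz`, `reporter_01`..`reporter_10`, `q_percolator`,
#'   `q_targetdecoy`, `is_labeled`, `is_contaminant`. Deterministic given
#'   `config$seed`.
#' @export
simulate_psm_table <- function(config,
                               layouts = generate_layout(config),
                               proteome = simulate_proteome(config)) {
  validate_generator_config(config)
  if (config$n_sets == 0L) return(empty_psm_table())

  withr::with_seed(config$seed + 1L, {
    target <- proteome$peptides
    n_target <- nrow(target)
    n_contam_pep <- round(config$contaminant_fraction /
                            max(1 - config$contaminant_fraction, 1e-12) *
                            n_target)
    contam_acc <- default_contaminants()
    contam <- tibble::tibble(
      peptide_key = random_peptides(n_contam_pep),
      protein_accession = sample(contam_acc, n_contam_pep, replace = TRUE)
    )
    peptides <- dplyr::bind_rows(
      dplyr::mutate(target, is_contaminant = FALSE),
      dplyr::mutate(contam, is_contaminant = TRUE)
    )
    obs <- peptide_observables(peptides$peptide_key)
    peptides <- dplyr::left_join(peptides, obs, by = "peptide_key")
    # single-cell intensity scale for target peptides; ambient scale for
    # contaminants (present regardless of channel load)
    base <- dplyr::left_join(peptides,
                             proteome$proteins[, c("protein_accession",
                                                   "true_abundance")],
                             by = "protein_accession")
    base$true_abundance[base$is_contaminant] <-
      stats::rlnorm(sum(base$is_contaminant), 0, config$bulk_abundance_sdlog)
    base$single_level <- 1e4 * base$true_abundance * base$response

    psms <- tidyr::expand_grid(set_id = seq_len(config$n_sets),
                               base[, c("peptide_key", "protein_accession",
                                        "annotated_sequence", "charge",
                                        "retention_time", "observed_mz",
                                        "is_contaminant", "single_level")])
    n <- nrow(psms)

    # per-channel observed load ratios (identical across sets)
    one_set <- layouts[layouts$set_id == layouts$set_id[1L], ]
    one_set <- one_set[order(one_set$channel_index), ]
    cls <- one_set$channel_class
    ratio <- apply_compression(one_set$nominal_load / config$single_cells,
                               config$compression_c)
    ratio[cls == "CARRIER"] <- ratio[cls == "CARRIER"] * config$carrier_attenuation
    ratio[cls == "EMPTY"] <- config$empty_floor

    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- if (config$noise_cv > 0) {
      matrix(stats::rlnorm(n * 10L, -sdlog^2 / 2, sdlog), nrow = n)
    } else {
      matrix(1, nrow = n, ncol = 10L)
    }
    intens <- psms$single_level * noise *
      matrix(ratio, nrow = n, ncol = 10L, byrow = TRUE)
    # contaminants are ambient: same expected level in every channel
    if (any(psms$is_contaminant)) {
      ci <- which(psms$is_contaminant)
      intens[ci, ] <- psms$single_level[ci] * noise[ci, ]
    }
    # stochastic detection in cell channels only (explicit zeros)
    cell_cols <- which(cls %in% c("SINGLE", "DOUBLE"))
    detect <- matrix(stats::runif(n * length(cell_cols)) <
                       config$detection_rate_per_cell_channel,
                     nrow = n)
    intens[, cell_cols] <- intens[, cell_cols] * detect
    if (config$empty_floor == 0) intens[, cls == "EMPTY"] <- 0

    is_labeled <- stats::runif(n) < config$labeling_prob
    intens[!is_labeled, ] <- 0

    qv <- simulate_q_values(n, config)
    colnames(intens) <- reporter_cols()

    out <- dplyr::bind_cols(
      tibble::tibble(psm_id = sprintf("PSM%06d", seq_len(n))),
      psms[, c("set_id", "peptide_key", "annotated_sequence",
               "protein_accession", "charge", "retention_time",
               "observed_mz")],
      tibble::as_tibble(intens),
      tibble::tibble(q_percolator = qv$q_percolator,
                     q_targetdecoy = qv$q_targetdecoy,
                     is_labeled = is_labeled,
                     is_contaminant = psms$is_contaminant)
    )
    out
  })
}

empty_psm_table <- function() {
  cols <- c(list(psm_id = character(), set_id = integer(),
                 peptide_key = character(), annotated_sequence = character(),
                 protein_accession = character(), charge = integer(),
                 retention_time = numeric(), observed_mz = numeric()),
            stats::setNames(rep(list(numeric()), 10L), reporter_cols()),
            list(q_percolator = numeric(), q_targetdecoy = numeric(),
                 is_labeled = logical(), is_contaminant = logical()))
  tibble::as_tibble(cols)
}

#' Simulate a bulk-proteome abundance table
#'
#' Produces per-protein abundances for two extraction methods
#' (`freeze_thaw`, `sonication`) with `bulk_replicates` replicates each.
#' Each protein is detected by a method with that method's detection rate
#' (undetected means 0 in every replicate of that method); detected
#' replicate values are `true_abundance * effect * noise`, where membrane
#' proteins get `membrane_sonication_effect` in the sonication columns.
#' A dense abundance rank (1 = most abundant, computed from mean
#' freeze-and-thaw abundance) is included.
#'
#' @param config A [generator_config()].
#' @param proteome Proteome from [simulate_proteome()]; defaults to the one
#'   implied by `config`.
#' @return A tibble with columns `protein_accession`, `is_ribosomal`,
#'   `is_membrane`, `freeze_thaw_1..k`, `sonication_1..k`, `bulk_rank`.
#'   Deterministic given `config$seed`.
#' @export
simulate_bulk_table <- function(config, proteome = simulate_proteome(config)) {
  validate_generator_config(config)
  withr::with_seed(config$seed + 2L, {
    prot <- proteome$proteins
    n <- nrow(prot)
    k <- config$bulk_replicates
    det_ft <- stats::runif(n) < config$ft_detection_rate
    det_son <- stats::runif(n) < config$sonication_detection_rate
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    rep_vals <- function(detected, effect) {
      m <- matrix(prot$true_abundance * effect, nrow = n, ncol = k)
      if (config$noise_cv > 0) {
        m <- m * matrix(stats::rlnorm(n * k, -sdlog^2 / 2, sdlog), nrow = n)
      }
      m * detected
    }
    eff_son <- ifelse(prot$is_membrane, config$membrane_sonication_effect, 1)
    ft <- rep_vals(det_ft, 1)
    son <- rep_vals(det_son, eff_son)
    colnames(ft) <- sprintf("freeze_thaw_%d", seq_len(k))
    colnames(son) <- sprintf("sonication_%d", seq_len(k))
    out <- dplyr::bind_cols(
      prot[, c("protein_accession", "is_ribosomal", "is_membrane")],
      tibble::as_tibble(ft), tibble::as_tibble(son)
    )
    out$bulk_rank <- dplyr::dense_rank(dplyr::desc(rowMeans(ft)))
    out
  })
}
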