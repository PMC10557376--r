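#' Configuration for the synthetic TMT-10plex SCoPE-MS data generator
#'
#' Bundles every knob of the simulation: the multiplexing design (how many
#' carrier, single-cell, double-cell and empty channels per set, and how many
#' sets), the synthetic proteome (size, ribosomal abundance share, membrane
#' fraction, peptides per protein), and the measurement model (labeling
#' completeness, isobaric ratio compression, carrier attenuation, per-channel
#' detection probability, multiplicative noise, empty-channel background,
#' q-value simulation and contaminant rate).
#'
#' The defaults reproduce the study design this package models: 16 TMT-10plex
#' sets, each with two 250-cell carrier channels, three single-cell and three
#' double-cell channels in alternating order, and two empty channels; ~75%
#' complete TMT labeling; ribosomal proteins carrying 12.1% of total bulk
#' abundance.
#'
#' @param n_sets Number of TMT-10plex sets (default 16).
#' @param n_carrier,n_single,n_double,n_empty Channels per class in each set
#'   (defaults 2/3/3/2; must sum to 10).
#' @param carrier_cells Cells loaded in each carrier channel (default 250).
#' @param single_cells Cells per single-cell channel (default 1).
#' @param double_cells Cells per double-cell channel (default 2).
#' @param n_proteins Number of proteins in the synthetic proteome (default 300).
#' @param ribosomal_share Fraction of total true abundance carried by
#'   ribosome-flagged proteins (default 0.121).
#' @param membrane_fraction Fraction of proteins flagged as membrane-associated
#'   (default 0.15).
#' @param peptides_per_protein_lambda Peptides per protein are drawn as
#'   `1 + Poisson(lambda)`; default lambda 1.5 (mean 2.5 peptides).
#' @param labeling_prob Per-PSM probability of complete TMT labeling
#'   (default 0.75). Unlabeled PSMs carry zero in all reporter channels.
#' @param compression_c Isobaric ratio-compression coefficient in [0, 1]
#'   (default 0.4): observed load ratios are `1 + (r - 1) * (1 - c)` relative
#'   to the single-cell load.
#' @param carrier_attenuation Multiplicative factor on carrier-channel observed
#'   signal, in (0, 1] (default 1 = off). Separate from `compression_c` because
#'   the observed carrier suppression exceeds what a single compression
#'   coefficient explains.
#' @param detection_rate_per_cell_channel Probability that a peptide yields
#'   nonzero signal in a given single/double-cell channel (default 0.3).
#'   Carrier channels are always detected for labeled PSMs.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (default 0.2; 0 turns noise off).
#' @param empty_floor Additive background level in empty channels, on the
#'   single-cell intensity scale (default 0 = no carry-over).
#' @param contaminant_fraction Fraction of PSMs assigned to contaminant
#'   accessions such as keratins and trypsin (default 0.10).
#' @param decoy_rate Fraction of non-contaminant PSMs that are decoy-like
#'   (their q-values are drawn uniform on [0, 1]; default 0.10).
#' @param q_true_shape2 Beta(1, shape2) second parameter for confident-PSM
#'   q-values (default 99; mean q = 0.01).
#' @param validator_miss_rate Probability that one validator independently
#'   fails a confident PSM (its q drawn uniform), emulating two validators
#'   that agree on only a subset of identifications (default 0.15).
#' @param bulk_replicates Replicates per extraction method in the bulk table
#'   (default 3).
#' @param ft_detection_rate,sonication_detection_rate Per-protein detection
#'   probability in the freeze-and-thaw and probe-sonication bulk preparations
#'   (defaults 1 and 0.654; the latter reproduces, in expectation, the
#'   observed ~53% detection advantage of freeze-and-thaw).
#' @param membrane_sonication_effect Fold-change applied to membrane proteins
#'   in the sonication columns (default 1 = no method effect).
#' @param bulk_abundance_sdlog Standard deviation (log scale) of the log-normal
#'   true protein abundance distribution (default 1.5).
#' @param seed Integer seed; every generator function is deterministic given
#'   the config (default 1L).
#'
#' @return An object of class `generator_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_sets = 2, n_proteins = 20)
#' cfg$labeling_prob
#' @export
generator_config <- function(n_sets = 16L,
                             n_carrier = 2L,
                             n_single = 3L,
                             n_double = 3L,
                             n_empty = 2L,
                             carrier_cells = 250,
                             single_cells = 1,
                             double_cells = 2,
                             n_proteins = 300L,
                             ribosomal_share = 0.121,
                             membrane_fraction = 0.15,
                             peptides_per_protein_lambda = 1.5,
                             labeling_prob = 0.75,
                             compression_c = 0.4,
                             carrier_attenuation = 1,
                             detection_rate_per_cell_channel = 0.3,
                             noise_cv = 0.2,
                             empty_floor = 0,
                             contaminant_fraction = 0.10,
                             decoy_rate = 0.10,
                             q_true_shape2 = 99,
                             validator_miss_rate = 0.15,
                             bulk_replicates = 3L,
                             ft_detection_rate = 1,
                             sonication_detection_rate = 0.654,
                             membrane_sonication_effect = 1,
                             bulk_abundance_sdlog = 1.5,
                             seed = 1L) {
  cfg <- list(
    n_sets = as.integer(n_sets),
    n_carrier = as.integer(n_carrier),
    n_single = as.integer(n_single),
    n_double = as.integer(n_double),
    n_empty = as.integer(n_empty),
    carrier_cells = as.numeric(carrier_cells),
    single_cells = as.numeric(single_cells),
    double_cells = as.numeric(double_cells),
    n_proteins = as.integer(n_proteins),
    ribosomal_share = as.numeric(ribosomal_share),
    membrane_fraction = as.numeric(membrane_fraction),
    peptides_per_protein_lambda = as.numeric(peptides_per_protein_lambda),
    labeling_prob = as.numeric(labeling_prob),
    compression_c = as.numeric(compression_c),
    carrier_attenuation = as.numeric(carrier_attenuation),
    detection_rate_per_cell_channel = as.numeric(detection_rate_per_cell_channel),
    noise_cv = as.numeric(noise_cv),
    empty_floor = as.numeric(empty_floor),
    contaminant_fraction = as.numeric(contaminant_fraction),
    decoy_rate = as.numeric(decoy_rate),
    q_true_shape2 = as.numeric(q_true_shape2),
    validator_miss_rate = as.numeric(validator_miss_rate),
    bulk_replicates = as.integer(bulk_replicates),
    ft_detection_rate = as.numeric(ft_detection_rate),
    sonication_detection_rate = as.numeric(sonication_detection_rate),
    membrane_sonication_effect = as.numeric(membrane_sonication_effect),
    bulk_abundance_sdlog = as.numeric(bulk_abundance_sdlog),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the TMT-10plex channel-count invariant and all probability/fraction
#' domains. Called by [generator_config()]; exported so configs read from YAML
#' can be re-validated.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n_chan <- cfg$n_carrier + cfg$n_single + cfg$n_double + cfg$n_empty
  if (n_chan != 10L) {
    stop("channel class counts must sum to 10 (TMT-10plex), got ", n_chan,
         call. = FALSE)
  }
  if (cfg$n_sets < 0L) stop("n_sets must be >= 0", call. = FALSE)
  for (nm in c("ribosomal_share", "labeling_prob", "compression_c",
               "detection_rate_per_cell_channel", "membrane_fraction",
               "contaminant_fraction", "decoy_rate", "validator_miss_rate",
               "ft_detection_rate", "sonication_detection_rate")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single value in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$carrier_attenuation <= 0 || cfg$carrier_attenuation > 1) {
    stop("carrier_attenuation must be in (0, 1]", call. = FALSE)
  }
  if (any(c(cfg$carrier_cells, cfg$single_cells, cfg$double_cells) < 0)) {
    stop("cell loads must be >= 0", call. = FALSE)
  }
  if (cfg$single_cells < 1) stop("single_cells must be >= 1", call. = FALSE)
  if (cfg$carrier_cells < cfg$single_cells) {
    stop("carrier_cells must be >= single_cells", call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$empty_floor < 0) stop("empty_floor must be >= 0", call. = FALSE)
  if (cfg$bulk_replicates < 1L) stop("bulk_replicates must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  design: %d sets x [%dC/%dS/%dD/%dE], loads %g/%g/%g cells\n",
              x$n_sets, x$n_carrier, x$n_single, x$n_double, x$n_empty,
              x$carrier_cells, x$single_cells, x$double_cells))
  cat(sprintf("  proteome: %d proteins, ribosomal share %.3f, membrane %.2f\n",
              x$n_proteins, x$ribosomal_share, x$membrane_fraction))
  cat(sprintf("  model: labeling %.2f, compression %.2f, detection %.2f, noise CV %.2f, seed %d\n",
              x$labeling_prob, x$compression_c,
              x$detection_rate_per_cell_channel, x$noise_cv, x$seed))
  invisible(x)
}
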