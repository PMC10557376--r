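#' Channel classes of a TMT-10plex SCoPE-MS set
#'
#' Channel classes in the fixed within-set order used by the generator:
#' two carrier-proteome channels first, then single- and double-cell channels
#' alternating, then the two empty channels. The alternation matches a design
#' with three single and three double cells per set; carrier and empty
#' channels sit at the edges of the plex.
#' @keywords internal
channel_classes <- c("CARRIER", "SINGLE", "DOUBLE", "EMPTY")

#' Generate the channel layout of every TMT set
#'
#' Expands a [generator_config()] into one row per (set, channel) giving the
#' channel class and its nominal cell load. For the default class counts
#' (2 carrier / 3 single / 3 double / 2 empty) the within-set order is
#' `CARRIER, CARRIER, SINGLE, DOUBLE, SINGLE, DOUBLE, SINGLE, DOUBLE, EMPTY,
#' EMPTY`; other counts keep the carrier-first, alternating-cells,
#' empty-last scheme (interleaving singles and doubles until one class is
#' exhausted).
#'
#' @param config A `generator_config`.
#' @return A tibble with columns `set_id` (integer), `channel_index` (1..10),
#'   `channel_class` (`"CARRIER"`, `"SINGLE"`, `"DOUBLE"`, `"EMPTY"`) and
#'   `nominal_load` (cells: `carrier_cells` / `single_cells` / `double_cells`
#'   / 0). `n_sets = 0` yields a zero-row tibble.
#' @examples
#' layout <- generate_layout(generator_config())
#' table(layout$channel_class)  # 32 CARRIER, 48 SINGLE, 48 DOUBLE, 32 EMPTY
#' @export
generate_layout <- function(config) {
  validate_generator_config(config)
  order <- set_channel_order(config)
  loads <- c(CARRIER = config$carrier_cells,
             SINGLE = config$single_cells,
             DOUBLE = config$double_cells,
             EMPTY = 0)
  if (config$n_sets == 0L) {
    return(tibble::tibble(set_id = integer(), channel_index = integer(),
                          channel_class = character(), nominal_load = numeric()))
  }
  tibble::tibble(
    set_id = rep(seq_len(config$n_sets), each = 10L),
    channel_index = rep(1:10, times = config$n_sets),
    channel_class = rep(order, times = config$n_sets),
    nominal_load = unname(loads[rep(order, times = config$n_sets)])
  )
}

# Within-set channel order: carriers, alternating single/double, empties.
set_channel_order <- function(config) {
  cells <- character(0)
  s <- config$n_single
  d <- config$n_double
  while (s > 0L || d > 0L) {
    if (s > 0L) { cells <- c(cells, "SINGLE"); s <- s - 1L }
    if (d > 0L) { cells <- c(cells, "DOUBLE"); d <- d - 1L }
  }
  c(rep("CARRIER", config$n_carrier), cells, rep("EMPTY", config$n_empty))
}

#' Apply isobaric ratio compression to a load ratio
#'
#' Models the co-isolation interference of isobaric (TMT) quantification as a
#' linear shrinkage of between-channel ratios toward 1:
#' `observed = 1 + (true_ratio - 1) * (1 - c)`, with ratios expressed relative
#' to the single-cell load. `c = 0` is the interference-free identity;
#' `c = 1` collapses every ratio to 1. With the default `c = 0.4` a true
#' double/single ratio of 2 is observed as 1.6, i.e. a 60% enrichment.
#'
#' @param true_ratio Non-negative true abundance ratio(s) relative to the
#'   single-cell channel load.
#' @param c Compression coefficient in [0, 1].
#' @return The compressed ratio(s), same length as `true_ratio`.
#' @examples
#' apply_compression(2, 0.4)   # 1.6
#' apply_compression(250, 0)   # 250
#' @export
apply_compression <- function(true_ratio, c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop("compression coefficient c must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (any(true_ratio < 0, na.rm = TRUE)) {
    stop("true_ratio must be >= 0", call. = FALSE)
  }
  1 + (true_ratio - 1) * (1 - c)
}
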