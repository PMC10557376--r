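#' Default contaminant accession list
#'
#' Accessions of common laboratory contaminant proteins (human keratins,
#' trypsin, BSA) shipped with the package. Used by [remove_contaminants()]
#' and, in the generator, as the accession pool for simulated contaminant
#' PSMs.
#'
#' @param path Optional path to a custom list (one accession per line,
#'   `#` comments allowed).
#' @return Character vector of accessions.
#' @export
default_contaminants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "contaminants.txt", package = "scopebac",
                        mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Parse an annotated peptide sequence
#'
#' Splits search-engine annotated sequences of the form `"[R].DAIHAAK.[A]"`
#' into the preceding flanking residue, the bare peptide sequence (the
#' peptide key) and the following flanking residue. A flank of `-` (or an
#' empty bracket) denotes a protein terminus.
#'
#' @param text Character vector of annotated sequences.
#' @return A tibble with columns `prev_flank`, `peptide_key`, `next_flank`
#'   (flanks are `""` for empty brackets). Malformed input raises an error
#'   naming the offending token.
#' @examples
#' parse_annotated_sequence("[R].DAIHAAK.[A]")
#' parse_annotated_sequence("[-].MQGKALQDFVIDK.[I]")
#' @export
parse_annotated_sequence <- function(text) {
  pattern <- "^\\[([A-Za-z-]?)\\]\\.([A-Za-z]+)\\.\\[([A-Za-z-]?)\\]$"
  ok <- grepl(pattern, text)
  if (!all(ok)) {
    bad <- text[!ok][1L]
    stop("malformed annotated sequence: '", bad, "'", call. = FALSE)
  }
  tibble::tibble(
    prev_flank = sub(pattern, "\\1", text),
    peptide_key = toupper(sub(pattern, "\\2", text)),
    next_flank = sub(pattern, "\\3", text)
  )
}

psm_required_cols <- function() {
  c("psm_id", "set_id", "peptide_key", "annotated_sequence",
    "protein_accession", "charge", "retention_time", "observed_mz",
    reporter_cols(), "q_percolator", "q_targetdecoy", "is_labeled",
    "is_contaminant")
}

validate_psm_table <- function(psms) {
  missing <- setdiff(psm_required_cols(), names(psms))
  if (length(missing) > 0L) {
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rep_mat <- as.matrix(psms[, reporter_cols()])
  if (nrow(psms) > 0L) {
    bad <- which(!stats::complete.cases(rep_mat) | apply(rep_mat < 0, 1, any))
    if (length(bad) > 0L) {
      stop("negative or missing reporter intensity at row ", bad[1L],
           call. = FALSE)
    }
    for (qc in c("q_percolator", "q_targetdecoy")) {
      q <- psms[[qc]]
      if (any(is.na(q) | q < 0 | q > 1)) {
        stop(qc, " must lie in [0, 1]", call. = FALSE)
      }
    }
    key <- parse_annotated_sequence(psms$annotated_sequence)$peptide_key
    if (!all(key == toupper(psms$peptide_key))) {
      stop("peptide_key does not match annotated_sequence middle segment",
           call. = FALSE)
    }
  }
  invisible(psms)
}

#' Write a PSM table as tab-separated text
#'
#' Writes the documented TSV dialect (one row per PSM, reporter intensities
#' in `reporter_01`..`reporter_10`). The file is re-read losslessly by
#' [read_psm_table()].
#'
#' @param psms PSM tibble (see [simulate_psm_table()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' Read a PSM table
#'
#' Reads either the package's TSV dialect or the minimal mzTab subset
#' written by [write_mztab_subset()]. Required columns are validated;
#' unknown columns are retained. Empty reporter cells are read as explicit
#' zeros (the number of such cells is reported in the `n_blank_reporters`
#' attribute), because channel-occupancy semantics require explicit zeros.
#' A non-numeric reporter cell is an error naming the data line.
#'
#' @param path Input file path.
#' @param dialect `"tsv"` (default) or `"mztab"`.
#' @return A validated PSM tibble.
#' @export
read_psm_table <- function(path, dialect = c("tsv", "mztab")) {
  dialect <- match.arg(dialect)
  if (dialect == "mztab") return(read_mztab_subset(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # skip leading provenance/comment lines
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", skip = n_skip,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  psms <- tibble::as_tibble(raw)
  missing <- setdiff(psm_required_cols(), names(psms))
  if (length(missing) > 0L) {
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_blank <- 0L
  for (col in reporter_cols()) {
    v <- psms[[col]]
    blank <- !nzchar(trimws(v)) | toupper(trimws(v)) == "NA"
    n_blank <- n_blank + sum(blank)
    v[blank] <- "0"
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num))) {
      line <- which(is.na(num))[1L] + 1L + n_skip  # +1 for the header line
      stop("non-numeric reporter value '", v[is.na(num)][1L], "' in column ",
           col, " at line ", line, " of ", path, call. = FALSE)
    }
    psms[[col]] <- num
  }
  psms$set_id <- as.integer(psms$set_id)
  psms$charge <- as.integer(psms$charge)
  for (col in c("retention_time", "observed_mz", "q_percolator",
                "q_targetdecoy")) {
    psms[[col]] <- as.numeric(psms[[col]])
  }
  for (col in c("is_labeled", "is_contaminant")) {
    psms[[col]] <- as.logical(psms[[col]])
  }
  validate_psm_table(psms)
  attr(psms, "n_blank_reporters") <- n_blank
  psms
}

mztab_psm_cols <- function() {
  c("sequence", "PSM_ID", "accession", "charge", "retention_time",
    "exp_mass_to_charge", "opt_set_id", "opt_annotated_sequence",
    "opt_q_percolator", "opt_q_targetdecoy", "opt_is_labeled",
    "opt_is_contaminant", sprintf("opt_reporter_intensity[%d]", 1:10))
}

#' Write a minimal mzTab-style PSM section
#'
#' Emits a small mzTab-like file: `MTD` metadata lines, a `PSH` header line
#' and one `PSM` line per record, with the ten reporter intensities and the
#' two validator q-values as `opt_` columns. Re-readable with
#' `read_psm_table(path, dialect = "mztab")`.
#'
#' @param psms PSM tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mztab_subset <- function(psms, path) {
  validate_psm_table(psms)
  mtd <- c(
    "MTD\tmzTab-version\t1.0",
    "MTD\tmzTab-mode\tSummary",
    "MTD\tmzTab-type\tQuantification",
    paste0("MTD\tdescription\tscopebac PSM export (",
           nrow(psms), " PSMs)")
  )
  psh <- paste(c("PSH", mztab_psm_cols()), collapse = "\t")
  lines <- c(mtd, psh)
  if (nrow(psms) > 0L) {
    body <- cbind(
      "PSM", psms$peptide_key, psms$psm_id, psms$protein_accession,
      psms$charge, psms$retention_time, psms$observed_mz, psms$set_id,
      psms$annotated_sequence,
      format(psms$q_percolator, digits = 17, trim = TRUE, scientific = FALSE),
      format(psms$q_targetdecoy, digits = 17, trim = TRUE, scientific = FALSE),
      psms$is_labeled, psms$is_contaminant,
      apply(as.matrix(psms[, reporter_cols()]), 2, format,
            digits = 17, trim = TRUE, scientific = FALSE)
    )
    lines <- c(lines, apply(body, 1, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

read_mztab_subset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  psh <- lines[startsWith(lines, "PSH")]
  if (length(psh) != 1L) {
    stop("mzTab file must contain exactly one PSH header line", call. = FALSE)
  }
  header <- strsplit(psh, "\t", fixed = TRUE)[[1]][-1]
  missing <- setdiff(mztab_psm_cols(), header)
  if (length(missing) > 0L) {
    stop("mzTab PSM section missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lines[startsWith(lines, "PSM\t")]
  if (length(rows) == 0L) return(empty_psm_table())
  mat <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))[, -1, drop = FALSE]
  colnames(mat) <- header
  df <- tibble::as_tibble(mat)
  rep_src <- sprintf("opt_reporter_intensity[%d]", 1:10)
  out <- tibble::tibble(
    psm_id = df$PSM_ID,
    set_id = as.integer(df$opt_set_id),
    peptide_key = df$sequence,
    annotated_sequence = df$opt_annotated_sequence,
    protein_accession = df$accession,
    charge = as.integer(df$charge),
    retention_time = as.numeric(df$retention_time),
    observed_mz = as.numeric(df$exp_mass_to_charge)
  )
  for (i in 1:10) out[[reporter_cols()[i]]] <- as.numeric(df[[rep_src[i]]])
  out$q_percolator <- as.numeric(df$opt_q_percolator)
  out$q_targetdecoy <- as.numeric(df$opt_q_targetdecoy)
  out$is_labeled <- as.logical(df$opt_is_labeled)
  out$is_contaminant <- as.logical(df$opt_is_contaminant)
  validate_psm_table(out)
  out
}

#' Write / read the bulk-proteome table
#'
#' TSV round-trip for the bulk table produced by [simulate_bulk_table()]:
#' per-protein abundances for two extraction methods across replicates,
#' ribosomal/membrane flags and the dense bulk abundance rank.
#'
#' @param bulk Bulk tibble.
#' @param path File path.
#' @return `write_bulk_table()`: `path` invisibly; `read_bulk_table()`:
#'   the bulk tibble.
#' @export
write_bulk_table <- function(bulk, path) {
  readr::write_tsv(bulk, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_bulk_table
#' @export
read_bulk_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bulk <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  need <- c("protein_accession", "is_ribosomal", "is_membrane", "bulk_rank")
  missing <- setdiff(need, names(bulk))
  if (length(missing) > 0L) {
    stop("bulk table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bulk
}
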