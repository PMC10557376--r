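bulk_method_cols <- function(bulk, method) {
  cols <- grep(paste0("^", method, "_\\d+$"), names(bulk), value = TRUE)
  if (length(cols) == 0L) {
    stop("bulk table has no replicate columns for method '", method, "'",
         call. = FALSE)
  }
  cols
}

bulk_detected <- function(bulk, method, min_replicates = 1L) {
  m <- as.matrix(bulk[, bulk_method_cols(bulk, method)])
  rowSums(m > 0) >= min_replicates
}

#' Detection-count difference between extraction methods
#'
#' Percent more proteins detected by the freeze-and-thaw preparation than by
#' probe sonication: `100 * (n_ft - n_son) / n_son`, where a protein counts
#' as detected by a method when it has nonzero abundance in at least
#' `min_replicates` of that method's replicates.
#'
#' @param bulk_table Bulk tibble (see [simulate_bulk_table()]).
#' @param min_replicates Minimum nonzero replicates for detection (default 1).
#' @return Percent difference (positive when freeze-and-thaw detects more).
#' @export
detection_count_delta <- function(bulk_table, min_replicates = 1L) {
  n_ft <- sum(bulk_detected(bulk_table, "freeze_thaw", min_replicates))
  n_son <- sum(bulk_detected(bulk_table, "sonication", min_replicates))
  if (n_son == 0L) {
    stop("sonication detects no proteins; detection delta undefined",
         call. = FALSE)
  }
  100 * (n_ft - n_son) / n_son
}

#' Per-protein extraction-method enrichment test
#'
#' Two-sample t-test on log2 abundances (freeze-and-thaw vs sonication
#' replicates) per protein, Benjamini-Hochberg adjusted across tested
#' proteins. Only proteins with at least `min_replicates` nonzero replicate
#' values in both methods are tested. Zero-variance comparisons are resolved
#' exactly: equal means give p = 1, unequal means with no within-group
#' variance give p = 0. Reports, per enrichment direction, the fraction of
#' significant proteins that are membrane, ribosomal or other.
#'
#' @param bulk_table Bulk tibble.
#' @param alpha FDR level for the significance call (default 0.05).
#' @param min_replicates Minimum nonzero replicates per method (default 2).
#' @param adjust Multiple-testing adjustment (only `"BH"`).
#' @return A `method_comparison` list: `per_protein` tibble
#'   (`protein_accession`, `log2_ratio` (freeze-thaw over sonication),
#'   `p_value`, `adj_p_value`, `significant`, `direction`, flags) and
#'   `aggregate` (detection delta, counts and per-direction category
#'   fractions).
#' @export
method_enrichment_test <- function(bulk_table, alpha = 0.05,
                                   min_replicates = 2L, adjust = "BH") {
  adjust <- match.arg(adjust, "BH")
  ft_cols <- bulk_method_cols(bulk_table, "freeze_thaw")
  son_cols <- bulk_method_cols(bulk_table, "sonication")
  if (length(ft_cols) < 2L || length(son_cols) < 2L) {
    stop("method enrichment test needs >= 2 replicates per method",
         call. = FALSE)
  }
  ft <- as.matrix(bulk_table[, ft_cols])
  son <- as.matrix(bulk_table[, son_cols])
  n <- nrow(bulk_table)
  res <- lapply(seq_len(n), function(i) {
    a <- ft[i, ][ft[i, ] > 0]
    b <- son[i, ][son[i, ] > 0]
    if (length(a) < min_replicates || length(b) < min_replicates) {
      return(c(NA_real_, NA_real_))
    }
    la <- log2(a); lb <- log2(b)
    ratio <- mean(la) - mean(lb)
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else {
      stats::t.test(la, lb)$p.value
    }
    c(ratio, p)
  })
  res <- do.call(rbind, res)
  per_protein <- tibble::tibble(
    protein_accession = bulk_table$protein_accession,
    is_ribosomal = bulk_table$is_ribosomal,
    is_membrane = bulk_table$is_membrane,
    log2_ratio = res[, 1],
    p_value = res[, 2]
  )
  per_protein$adj_p_value <- NA_real_
  tested <- !is.na(per_protein$p_value)
  per_protein$adj_p_value[tested] <-
    stats::p.adjust(per_protein$p_value[tested], method = "BH")
  per_protein$significant <- !is.na(per_protein$adj_p_value) &
    per_protein$adj_p_value <= alpha
  per_protein$direction <- dplyr::case_when(
    !per_protein$significant ~ NA_character_,
    per_protein$log2_ratio > 0 ~ "freeze_thaw",
    TRUE ~ "sonication"
  )
  category_fractions <- function(dir) {
    s <- per_protein[per_protein$significant &
                       per_protein$direction == dir, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(list(n = 0L, membrane = NA_real_, ribosomal = NA_real_,
                  other = NA_real_))
    }
    mem <- mean(s$is_membrane)
    rib <- mean(s$is_ribosomal)
    list(n = nrow(s), membrane = mem, ribosomal = rib,
         other = 1 - mem - rib)
  }
  out <- list(
    per_protein = per_protein,
    aggregate = list(
      alpha = alpha,
      n_tested = sum(tested),
      n_significant = sum(per_protein$significant),
      detection_delta_percent = detection_count_delta(bulk_table),
      freeze_thaw_enriched = category_fractions("freeze_thaw"),
      sonication_enriched = category_fractions("sonication")
    )
  )
  class(out) <- "method_comparison"
  out
}

#' Ribosomal share of total protein abundance
#'
#' Percent of total bulk protein abundance carried by ribosome-flagged
#' proteins: `100 * sum(abundance[ribosomal]) / sum(abundance)`. By default
#' the freeze-and-thaw columns are used (the preparation adopted for the
#' single-cell workflow); the statistic is invariant to global abundance
#' rescaling.
#'
#' @param bulk_table Bulk tibble with `is_ribosomal`.
#' @param method `"freeze_thaw"` (default), `"sonication"` or `"both"`.
#' @return Percent share.
#' @export
ribosomal_share <- function(bulk_table,
                            method = c("freeze_thaw", "sonication", "both")) {
  method <- match.arg(method)
  cols <- if (method == "both") {
    c(bulk_method_cols(bulk_table, "freeze_thaw"),
      bulk_method_cols(bulk_table, "sonication"))
  } else {
    bulk_method_cols(bulk_table, method)
  }
  m <- as.matrix(bulk_table[, cols])
  if (any(m < 0, na.rm = TRUE)) stop("abundances must be >= 0", call. = FALSE)
  total <- sum(m)
  if (total <= 0) stop("total abundance is zero; share undefined",
                       call. = FALSE)
  100 * sum(m[bulk_table$is_ribosomal, , drop = FALSE]) / total
}
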