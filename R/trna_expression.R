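#' Count reads per tRNA under the exclusive-mapping rule
#'
#' Consumes a per-read hit table (`read_id`, `target`, `score`,
#' `target_class` in `{"mature", "genomic"}`; at most the aligner's
#' best-alignment set, <= 50 hits per read) and applies the counting
#' policy for small-RNA reads aligned jointly to the genome and to mature
#' tRNA sequences:
#' \itemize{
#'   \item only hits at the read's best score survive;
#'   \item if the best-score hits include both genomic loci and mature
#'     tRNAs, the genomic hits are dropped (reads are mapped exclusively to
#'     mature tRNAs);
#'   \item a read with one surviving mature hit adds 1 to that tRNA; a read
#'     tied across `k` mature tRNAs adds `1/k` to each, so total counts are
#'     conserved;
#'   \item reads whose best hits are all genomic are not counted.
#' }
#'
#' @param hits Hit table (data frame).
#' @param reference Mature-tRNA reference tibble (`trna_id`, `length`).
#' @return A tibble `trna_id`, `read_count` (fractional allowed),
#'   `length_nt`, covering every reference tRNA; the numbers of counted and
#'   skipped reads are attached as attributes `n_counted` / `n_skipped`.
#' @export
count_trna_reads <- function(hits, reference) {
  stopifnot(all(c("read_id", "target", "score", "target_class") %in%
                  names(hits)))
  bad <- setdiff(unique(hits$target_class), c("mature", "genomic"))
  if (length(bad) > 0L) {
    stop("unknown target_class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  surviving <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(if (any(.data$target_class == "mature"))
      .data$target_class == "mature" else FALSE) |>
    dplyr::mutate(weight = 1 / dplyr::n()) |>
    dplyr::ungroup()
  per_trna <- surviving |>
    dplyr::group_by(trna_id = .data$target) |>
    dplyr::summarise(read_count = sum(.data$weight), .groups = "drop")
  unknown <- setdiff(per_trna$trna_id, reference$trna_id)
  if (length(unknown) > 0L) {
    stop("hits reference unknown mature tRNAs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(trna_id = reference$trna_id,
                        length_nt = reference$length) |>
    dplyr::left_join(per_trna, by = "trna_id") |>
    dplyr::mutate(read_count = ifelse(is.na(.data$read_count), 0,
                                      .data$read_count)) |>
    dplyr::select("trna_id", "read_count", "length_nt")
  n_counted <- length(unique(surviving$read_id))
  attr(out, "n_counted") <- n_counted
  attr(out, "n_skipped") <- length(unique(hits$read_id)) - n_counted
  out
}

#' RPKM normalisation and the expressed-tRNA filter
#'
#' `RPKM = read_count / (length_nt / 1000 * total_reads / 1e6)`. The
#' expression filter marks a tRNA as expressed iff its RPKM strictly
#' exceeds `expressed_threshold` (default 10,000).
#'
#' @param counts Tibble with `trna_id`, `read_count`, `length_nt` (e.g.
#'   from [count_trna_reads()] or the expression simulator).
#' @param total_reads Total mapped reads of the library; defaults to the
#'   sum of `read_count` (appropriate when the table covers the whole
#'   library).
#' @param expressed_threshold RPKM threshold for the expressed flag.
#' @return The input tibble with `rpkm` and logical `expressed` columns.
#' @export
rpkm <- function(counts, total_reads = NULL,
                 expressed_threshold = 10000) {
  total_reads <- total_reads %||% sum(counts$read_count)
  if (total_reads <= 0) {
    stop("cannot normalise: library total is zero", call. = FALSE)
  }
  if (any(counts$length_nt <= 0)) {
    stop("tRNA lengths must be positive", call. = FALSE)
  }
  dplyr::mutate(counts,
                rpkm = .data$read_count /
                  (.data$length_nt / 1000 * total_reads / 1e6),
                expressed = .data$rpkm > expressed_threshold)
}

#' Per-tRNA expression fold change between knockdown and control
#'
#' `FC = RPKM_knockdown / RPKM_control`, reported per tRNA with its m7G
#' class. The analysis set is defined on the control condition (tRNAs
#' expressed in control), so knockdown-induced losses are not filtered
#' away.
#'
#' @param kd,ctrl [rpkm()] outputs for knockdown and control.
#' @param m7g_trnas Character vector of m7G-modified tRNA ids (defines the
#'   `"modified"` class).
#' @param filter_expressed Restrict to tRNAs expressed in control
#'   (default `TRUE`).
#' @return A tibble `trna_id`, `rpkm_ctrl`, `rpkm_kd`, `fold_change`,
#'   `m7g_class`; `fold_change` is `NA` (flagged) when the control RPKM is
#'   zero.
#' @export
expression_fold_change <- function(kd, ctrl, m7g_trnas = character(0),
                                   filter_expressed = TRUE) {
  if (!setequal(kd$trna_id, ctrl$trna_id)) {
    stop("knockdown and control do not share the tRNA set", call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(ctrl, "trna_id", rpkm_ctrl = "rpkm",
                  expressed_ctrl = "expressed"),
    dplyr::select(kd, "trna_id", rpkm_kd = "rpkm"),
    by = "trna_id"
  )
  if (filter_expressed) out <- out[out$expressed_ctrl, , drop = FALSE]
  out |>
    dplyr::mutate(
      fold_change = ifelse(.data$rpkm_ctrl > 0,
                           .data$rpkm_kd / .data$rpkm_ctrl, NA_real_),
      m7g_class = ifelse(.data$trna_id %in% m7g_trnas, "modified",
                         "unmodified")) |>
    dplyr::select("trna_id", "rpkm_ctrl", "rpkm_kd", "fold_change",
                  "m7g_class")
}

#' Relative quantification by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each sample, `ddCt = dCt_test -
#' dCt_calibrator`, and relative expression `2^-ddCt`. Serves both plain
#' qRT-PCR (reference beta-actin, calibrator the control sample) and
#' MeRIP-qPCR enrichment (reference U6, calibrator the input sample). All
#' arguments are vectorised.
#'
#' @param target_ct,reference_ct Ct values of the test sample.
#' @param calibrator_target_ct,calibrator_reference_ct Ct values of the
#'   calibrator sample.
#' @return Relative expression value(s), `2^-ddCt`.
#' @export
relative_expression_ddct <- function(target_ct, reference_ct,
                                     calibrator_target_ct,
                                     calibrator_reference_ct) {
  cts <- c(target_ct, reference_ct, calibrator_target_ct,
           calibrator_reference_ct)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  dct_test <- target_ct - reference_ct
  dct_cal <- calibrator_target_ct - calibrator_reference_ct
  2^-(dct_test - dct_cal)
}

#' Modification percentage from LC-MS nucleoside peak areas
#'
#' The percentage of a tRNA modification is `100 * area_modification / sum
#' of all normalised nucleoside peak areas` in the sample.
#'
#' @param peaks Named numeric vector of normalised peak areas (>= 0).
#' @param modification Name of the modified nucleoside (e.g. `"m7G"`).
#' @return The modification percentage.
#' @export
modification_fraction <- function(peaks, modification) {
  if (!modification %in% names(peaks)) {
    stop("modification '", modification, "' not present in the peak table",
         call. = FALSE)
  }
  if (any(peaks < 0)) stop("peak areas must be >= 0", call. = FALSE)
  total <- sum(peaks)
  if (total == 0) {
    stop("degenerate input: all peak areas are zero", call. = FALSE)
  }
  100 * unname(peaks[modification]) / total
}
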