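#' Per-position read depth and read-start counts over mature tRNAs
#'
#' For every mature tRNA, counts at each 1-based position `i` the number of
#' reads overlapping `i` (`depth`) and the number of reads whose alignment
#' begins exactly at `i` (`starts`) -- the two quantities the cleavage
#' statistics are built from. Input is either the simulator's alignment
#' table (`trna_id`, `start`, `end`; 1-based closed) or a path to a SAM/BAM
#' file, in which case unmapped, secondary and supplementary records are
#' excluded and the reported (post-soft-clip) alignment start is used.
#'
#' @param alignments A data frame of alignments or a SAM/BAM path.
#' @param reference Mature-tRNA reference tibble (needs `trna_id`,
#'   `length`).
#' @return A tibble with columns `trna_id`, `position`, `depth`, `starts`,
#'   one row per position of every tRNA in `reference`.
#' @export
compute_pileup <- function(alignments, reference) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignment_file(alignments)
  }
  stopifnot(is.data.frame(alignments),
            all(c("trna_id", "start", "end") %in% names(alignments)))
  unknown <- setdiff(unique(alignments$trna_id), reference$trna_id)
  if (length(unknown) > 0L) {
    stop("alignments reference unknown tRNAs: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (any(alignments$end < alignments$start)) {
    stop("malformed alignment record: end < start", call. = FALSE)
  }
  lens <- stats::setNames(reference$length, reference$trna_id)
  if (any(alignments$start < 1L) ||
      any(alignments$end > lens[alignments$trna_id])) {
    stop("alignment outside the mature tRNA bounds", call. = FALSE)
  }
  by_trna <- split(alignments[c("start", "end")], alignments$trna_id)
  pieces <- lapply(reference$trna_id, function(id) {
    len <- lens[[id]]
    a <- by_trna[[id]]
    if (is.null(a)) {
      starts <- depth <- integer(len)
    } else {
      starts <- tabulate(a$start, nbins = len)
      delta <- starts - tabulate(a$end + 1L, nbins = len + 1L)[seq_len(len)]
      depth <- cumsum(delta)
    }
    tibble::tibble(trna_id = id, position = seq_len(len),
                   depth = depth, starts = starts)
  })
  dplyr::bind_rows(pieces)
}

# Read primary alignments from a SAM or BAM file into the package's
# alignment-table form. Requires Rsamtools/GenomicAlignments.
read_alignment_file <- function(path) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("reading SAM/BAM requires the ", pkg, " package", call. = FALSE)
    }
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags))
  tibble::tibble(
    trna_id = as.character(GenomicAlignments::seqnames(ga)),
    start = BiocGenerics::start(ga),
    end = BiocGenerics::end(ga)
  )
}

#' Per-site cleavage ratio
#'
#' The cleavage ratio at site `i` is the number of reads starting at `i`
#' divided by the read depth at `i`. Positions with depth below `min_depth`
#' are masked (`NA`), never reported as 0: absence of coverage is absence
#' of evidence.
#'
#' @param pileup Output of [compute_pileup()].
#' @param min_depth Minimum depth for a position to be scored
#'   (default 20).
#' @return The pileup tibble with an added `ratio` column.
#' @export
cleavage_ratio <- function(pileup, min_depth = 20) {
  if (min_depth < 1) stop("min_depth must be >= 1", call. = FALSE)
  dplyr::mutate(pileup,
                ratio = ifelse(.data$depth >= min_depth,
                               .data$starts / .data$depth, NA_real_))
}

#' Per-site cleavage score
#'
#' The cleavage score contrasts the treated and non-treated arms at each
#' site: `score_i = log2(max(r_treated, epsilon) / max(r_control,
#' epsilon))`. The pseudo-ratio `epsilon` prevents infinite scores when one
#' arm has zero read starts and sits far below any ratio observable at the
#' depth floor, so real signals are unperturbed. `literal = TRUE` instead
#' computes the ratio of logs, `log2(r_treated) / log2(r_control)`, an
#' alternative reading of the score definition that is provided for
#' comparison (it is bounded near [0, 1] at enriched sites).
#'
#' @param treated,non_treated [cleavage_ratio()] outputs for the two arms
#'   of the same sample, covering the same tRNAs and positions.
#' @param epsilon Pseudo-ratio floor (default 1e-4).
#' @param literal Use the ratio-of-logs form (default `FALSE`).
#' @return A tibble `trna_id`, `position`, `depth_treated`,
#'   `starts_treated`, `ratio_treated`, `depth_control`, `starts_control`,
#'   `ratio_control`, `score`; `score` is `NA` where either arm is masked.
#' @export
cleavage_score <- function(treated, non_treated, epsilon = 1e-4,
                           literal = FALSE) {
  if (!setequal(unique(treated$trna_id), unique(non_treated$trna_id)) ||
      nrow(treated) != nrow(non_treated)) {
    stop("treated and non-treated profiles do not cover the same tRNAs ",
         "and positions", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    dplyr::rename(treated, depth_treated = "depth",
                  starts_treated = "starts", ratio_treated = "ratio"),
    dplyr::rename(non_treated, depth_control = "depth",
                  starts_control = "starts", ratio_control = "ratio"),
    by = c("trna_id", "position")
  )
  if (nrow(merged) != nrow(treated)) {
    stop("treated and non-treated profiles do not share positions",
         call. = FALSE)
  }
  rt <- merged$ratio_treated
  rc <- merged$ratio_control
  score <- if (literal) {
    log2(rt) / log2(rc)
  } else {
    log2(pmax(rt, epsilon) / pmax(rc, epsilon))
  }
  score[is.na(rt) | is.na(rc)] <- NA_real_
  merged$score <- score
  merged
}

#' Call m7G sites in the variable-loop window
#'
#' A site is called when it lies in the variable-loop window (mature
#' positions 46-48), its cleavage score strictly exceeds `min_score` and
#' its treated-arm cleavage ratio strictly exceeds `min_ratio`. A tRNA is
#' m7G-modified iff it has at least one passing call.
#'
#' @param scores Output of [cleavage_score()].
#' @param window Candidate positions (default `46:48`).
#' @param min_score Score threshold, strict (default 4).
#' @param min_ratio Treated-ratio threshold, strict (default 0.1).
#' @return A tibble of all in-window sites with `trna_id`, `position`,
#'   `cleavage_score`, `treated_ratio` and logical `passed`.
#' @export
call_m7g_sites <- function(scores, window = 46:48, min_score = 4,
                           min_ratio = 0.1) {
  calls <- scores |>
    dplyr::filter(.data$position %in% window) |>
    dplyr::transmute(.data$trna_id, .data$position,
                     cleavage_score = .data$score,
                     treated_ratio = .data$ratio_treated,
                     passed = !is.na(.data$score) &
                       !is.na(.data$ratio_treated) &
                       .data$score > min_score &
                       .data$treated_ratio > min_ratio)
  calls
}

#' tRNA ids with at least one passing m7G call
#' @param calls Output of [call_m7g_sites()].
#' @return Character vector of modified tRNA ids.
#' @export
m7g_trnas <- function(calls) sort(unique(calls$trna_id[calls$passed]))

#' Per-tRNA methylation level
#'
#' Summarises a score track into one methylation level per tRNA: the
#' maximum cleavage score over the variable-loop window. This package-level
#' definition makes condition comparisons (e.g. knockdown vs control)
#' paired by tRNA.
#'
#' @param scores Output of [cleavage_score()].
#' @param window Positions summarised (default `46:48`).
#' @param condition Optional condition label attached to the output.
#' @return A tibble `trna_id`, `level`, `condition`; `level` is `NA` when
#'   every window position is masked.
#' @export
methylation_levels <- function(scores, window = 46:48, condition = NA) {
  scores |>
    dplyr::filter(.data$position %in% window) |>
    dplyr::group_by(.data$trna_id) |>
    dplyr::summarise(
      level = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(condition = condition)
}

#' Paired comparison of methylation levels between conditions
#'
#' Wilcoxon signed-rank test on per-tRNA methylation levels paired by tRNA.
#' The null distribution is exact (enumeration over sign assignments) when
#' n <= 15 and there are no zero differences or ties; a normal
#' approximation with continuity correction is used otherwise.
#'
#' @param control,knockdown Numeric vectors of levels over the same tRNA
#'   set, or [methylation_levels()] tibbles (paired by `trna_id`).
#' @param alternative Test sidedness (default two-sided).
#' @return A list with `statistic` (V), `p_value`, `n` and `method`.
#' @export
compare_methylation_paired <- function(control, knockdown,
                                       alternative = "two.sided") {
  if (is.data.frame(control)) {
    m <- dplyr::inner_join(control, knockdown, by = "trna_id",
                           suffix = c("_ctrl", "_kd"))
    if (nrow(m) < nrow(control) || nrow(m) < nrow(knockdown)) {
      stop("conditions do not cover the same tRNA set", call. = FALSE)
    }
    control <- m$level_ctrl
    knockdown <- m$level_kd
  }
  keep <- !is.na(control) & !is.na(knockdown)
  control <- control[keep]
  knockdown <- knockdown[keep]
  n <- length(control)
  if (n < 5) stop("need at least 5 paired levels", call. = FALSE)
  d <- control - knockdown
  if (all(d == 0)) {
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  }
  exact <- n <= 15 && !any(d == 0) && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(control, knockdown, paired = TRUE,
                       alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Sequence motif around called m7G sites
#'
#' Builds a base-frequency matrix over a window of `2 * flank + 1`
#' positions centred on every passing call. Windows truncated by the
#' sequence ends contribute only their covered columns; each column is
#' normalised by the number of sites contributing to it.
#'
#' @param calls Output of [call_m7g_sites()] (only `passed` rows are used).
#' @param reference Mature-tRNA reference tibble with `sequence`.
#' @param flank Flank size in nt (default 5).
#' @return A 4 x (2 * flank + 1) matrix of base frequencies (rows A, C, G,
#'   T; column sums 1), with the raw counts in `attr(, "counts")`.
#' @export
site_motif <- function(calls, reference, flank = 5) {
  if (flank < 1) stop("flank must be >= 1", call. = FALSE)
  hits <- calls[calls$passed, , drop = FALSE]
  if (nrow(hits) == 0L) {
    stop("no passing m7G calls: cannot build a motif", call. = FALSE)
  }
  width <- 2L * flank + 1L
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(bases, as.character(-flank:flank)))
  seqs <- stats::setNames(reference$sequence, reference$trna_id)
  for (i in seq_len(nrow(hits))) {
    s <- seqs[[hits$trna_id[i]]]
    for (k in seq_len(width)) {
      pos <- hits$position[i] + k - flank - 1L
      if (pos >= 1L && pos <= nchar(s)) {
        b <- substr(s, pos, pos)
        counts[b, k] <- counts[b, k] + 1L
      }
    }
  }
  freq <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  attr(freq, "counts") <- counts
  freq
}
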