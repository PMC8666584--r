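#' FPKM normalisation
#'
#' `FPKM = count / (length_nt / 1000 * total_fragments / 1e6)`. Fractional
#' fragment counts are accepted (consistent with the fractional
#' multi-mapper policy of the tRNA counting stage).
#'
#' @param counts Numeric vector of fragment counts.
#' @param length_nt Transcript lengths in nucleotides.
#' @param total_fragments Library total; defaults to `sum(counts)`.
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(counts, length_nt, total_fragments = NULL) {
  total_fragments <- total_fragments %||% sum(counts)
  if (total_fragments <= 0) {
    stop("cannot normalise: library total is zero", call. = FALSE)
  }
  if (any(length_nt <= 0)) {
    stop("transcript lengths must be positive", call. = FALSE)
  }
  counts / (length_nt / 1000 * total_fragments / 1e6)
}

#' Translation efficiency from polysome and input FPKM
#'
#' `TE = FPKM_polysome / FPKM_input`. Genes with input FPKM below
#' `min_input_fpkm` are masked (`NA`) and excluded from downstream
#' statistics: TE ratios on weakly expressed genes are dominated by
#' counting noise.
#'
#' @param poly_fpkm,input_fpkm Matched FPKM vectors.
#' @param min_input_fpkm Expression floor on the input library (default 1).
#' @return Numeric vector of TE values, `NA` where masked.
#' @export
translation_efficiency <- function(poly_fpkm, input_fpkm,
                                   min_input_fpkm = 1) {
  stopifnot(length(poly_fpkm) == length(input_fpkm))
  ifelse(is.na(input_fpkm) | input_fpkm < min_input_fpkm, NA_real_,
         poly_fpkm / input_fpkm)
}

#' Translation ratio between knockdown and control
#'
#' The translation ratio of a gene is `TE_knockdown / TE_control`; defined
#' only where both TEs are defined.
#'
#' @param te_kd,te_ctrl Matched TE vectors.
#' @return A tibble with `ratio` and `log2_ratio`.
#' @export
translation_ratio <- function(te_kd, te_ctrl) {
  stopifnot(length(te_kd) == length(te_ctrl))
  ratio <- ifelse(is.na(te_kd) | is.na(te_ctrl) | te_ctrl == 0, NA_real_,
                  te_kd / te_ctrl)
  tibble::tibble(ratio = ratio, log2_ratio = log2(ratio))
}

#' m7G-codon frequency of coding sequences
#'
#' Counts in-frame codons (frame fixed at 0) and reports per gene the
#' fraction `f` of codons that belong to the m7G codon set. A terminal
#' stop codon is excluded from both numerator and denominator; internal
#' stop codons are counted but trigger a warning.
#'
#' @param cds Character vector (or [Biostrings::DNAStringSet]) of CDS
#'   sequences; lengths must be divisible by 3.
#' @param codon_set Character vector of m7G codons, or the list returned by
#'   [build_m7g_codon_set()].
#' @param gene_id Optional gene identifiers (defaults to names or index).
#' @return A tibble `gene_id`, `n_codons` (terminal stop excluded), `f`,
#'   with the 64-column in-frame codon count matrix (terminal stop
#'   removed) in `attr(, "codon_counts")`.
#' @export
m7g_codon_frequency <- function(cds, codon_set, gene_id = NULL) {
  if (is.list(codon_set) && !is.null(codon_set$codon_set)) {
    codon_set <- codon_set$codon_set
  }
  if (!inherits(cds, "DNAStringSet")) {
    gene_id <- gene_id %||% names(cds)
    cds <- Biostrings::DNAStringSet(toupper(gsub("U", "T", cds)))
  }
  gene_id <- gene_id %||% names(cds) %||% as.character(seq_along(cds))
  w <- Biostrings::width(cds)
  if (any(w %% 3 != 0)) {
    stop("CDS length not divisible by 3 for: ",
         paste(utils::head(gene_id[w %% 3 != 0], 5), collapse = ", "),
         call. = FALSE)
  }
  counts <- Biostrings::trinucleotideFrequency(cds, step = 3)
  stops <- c("TAA", "TAG", "TGA")
  last <- substr(as.character(Biostrings::subseq(cds, start = w - 2)), 1, 3)
  has_term_stop <- last %in% stops
  for (s in stops) {
    i <- which(has_term_stop & last == s)
    counts[i, s] <- counts[i, s] - 1L
  }
  if (any(rowSums(counts[, stops, drop = FALSE]) > 0)) {
    warning("internal stop codons found; counted as ordinary codons")
  }
  n_codons <- rowSums(counts)
  f <- if (length(codon_set) == 0L) rep(0, length(n_codons)) else
    rowSums(counts[, codon_set, drop = FALSE]) / n_codons
  out <- tibble::tibble(gene_id = gene_id, n_codons = n_codons, f = f)
  attr(out, "codon_counts") <- counts
  out
}

#' Pearson correlation between codon frequency and translation
#'
#' Pairs genes by `gene_id` and computes the Pearson correlation (with the
#' two-sided p-value from the t transform) between the m7G-codon frequency
#' and a translation statistic (TE or log2 translation ratio). Masked
#' genes (NA) are dropped.
#'
#' @param profiles Tibble with `gene_id` and `f` (see
#'   [m7g_codon_frequency()]).
#' @param te_values Tibble with `gene_id` and a `value` column, or a named
#'   numeric vector.
#' @return A list with `r`, `p_value` and `n`.
#' @export
correlate_freq_te <- function(profiles, te_values) {
  if (!is.data.frame(te_values)) {
    te_values <- tibble::tibble(gene_id = names(te_values),
                                value = unname(te_values))
  }
  m <- dplyr::inner_join(profiles, te_values, by = "gene_id")
  m <- m[is.finite(m$f) & is.finite(m$value), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(m$f) == 0 || stats::sd(m$value) == 0) {
    stop("degenerate correlation: zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(m$f, m$value, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = nrow(m))
}

#' Classify genes by translation-ratio change
#'
#' `decreased` if the log2 translation ratio is `<= -threshold`,
#' `increased` if `>= +threshold`, `other` otherwise (boundaries inclusive
#' toward the extreme classes). The default threshold is a 1.5-fold change.
#'
#' @param log2_ratio Numeric vector of log2 translation ratios.
#' @param threshold Positive log2 fold-change cutoff (default
#'   `log2(1.5)`).
#' @return A factor with levels `decreased`, `increased`, `other`; `NA`
#'   where the ratio is undefined.
#' @export
classify_te_genes <- function(log2_ratio, threshold = log2(1.5)) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  cls <- ifelse(log2_ratio <= -threshold, "decreased",
                ifelse(log2_ratio >= threshold, "increased", "other"))
  factor(cls, levels = c("decreased", "increased", "other"))
}

#' Split genes into low and high codon-frequency groups
#'
#' Takes the bottom and top `q` quantile tails by m7G-codon frequency
#' (default quartiles), with ties broken deterministically by `gene_id`
#' order so the groups have exactly equal size `floor(q * n)`.
#'
#' @param profiles Tibble with `gene_id` and `f`.
#' @param q Tail proportion, in (0, 0.5] (default 0.25).
#' @return A list with `low` and `high` gene-id vectors and `n_per_group`.
#' @export
split_by_codon_frequency <- function(profiles, q = 0.25) {
  if (q <= 0 || q > 0.5) stop("q must be in (0, 0.5]", call. = FALSE)
  p <- profiles[is.finite(profiles$f), , drop = FALSE]
  n_grp <- floor(q * nrow(p))
  if (n_grp < 1L) {
    stop("too few genes for a ", q, "-quantile split", call. = FALSE)
  }
  ord <- order(p$f, p$gene_id)
  list(low = p$gene_id[ord[seq_len(n_grp)]],
       high = p$gene_id[ord[seq(nrow(p) - n_grp + 1L, nrow(p))]],
       n_per_group = n_grp)
}

#' Mann-Whitney U comparison of two gene groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The null distribution
#' is exact by enumeration when `n_a + n_b <= 12` and there are no ties; a
#' normal approximation with tie correction is used otherwise.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param labels Optional length-2 group labels.
#' @return A list with `statistic` (U for group a), `p_value`, `n_a`,
#'   `n_b`, `direction` (sign of `median(a) - median(b)`) and `method`.
#' @export
compare_groups <- function(values_a, values_b,
                           labels = c("a", "b")) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs at least 3 finite values", call. = FALSE)
  }
  exact <- (length(values_a) + length(values_b) <= 12) &&
    !anyDuplicated(c(values_a, values_b))
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(values_a), n_b = length(values_b),
       labels = labels,
       direction = sign(stats::median(values_a) - stats::median(values_b)),
       method = if (exact) "exact" else "normal approximation")
}

#' Mean per-codon frequency profile of a TE class
#'
#' For the genes of one translation-efficiency class (default
#' `decreased`), computes each gene's per-codon frequency vector (terminal
#' stop excluded) and averages across genes, returning codons ranked by
#' mean frequency with m7G-set membership flagged.
#'
#' @param profiles Output of [m7g_codon_frequency()] (must carry the
#'   `codon_counts` attribute).
#' @param te_class Factor from [classify_te_genes()], aligned with
#'   `profiles` rows.
#' @param codon_set m7G codon set (vector or [build_m7g_codon_set()]
#'   output).
#' @param class Which class to profile (default `"decreased"`).
#' @return A tibble `codon`, `mean_freq`, `in_m7g_set`, sorted by
#'   decreasing mean frequency.
#' @export
te_class_codon_profile <- function(profiles, te_class, codon_set,
                                   class = "decreased") {
  if (is.list(codon_set) && !is.null(codon_set$codon_set)) {
    codon_set <- codon_set$codon_set
  }
  counts <- attr(profiles, "codon_counts")
  if (is.null(counts)) {
    stop("profiles lack the codon_counts attribute; use ",
         "m7g_codon_frequency()", call. = FALSE)
  }
  stopifnot(length(te_class) == nrow(profiles))
  sel <- which(!is.na(te_class) & te_class == class)
  if (length(sel) == 0L) {
    stop("no genes in TE class '", class, "'", call. = FALSE)
  }
  freq <- counts[sel, , drop = FALSE] / rowSums(counts[sel, , drop = FALSE])
  mean_freq <- colMeans(freq)
  codon <- names(mean_freq)
  out <- tibble::tibble(codon = codon,
                        mean_freq = unname(mean_freq),
                        in_m7g_set = codon %in% codon_set)
  out[order(-out$mean_freq, out$codon), , drop = FALSE]
}
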