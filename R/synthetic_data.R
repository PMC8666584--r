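#' @importFrom rlang %||% .data
NULL

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all64), c("TAA", "TAG", "TGA"))
}

# Default codon set used by the TE simulator to implant codon-frequency
# effects: reverse complements of anticodons of variable-loop-modified tRNA
# families (Lys-CTT -> AAG etc.); synthetic stand-in, not a measured set.
DEFAULT_M7G_CODONS <- c("AAG", "AGA", "TGC", "GAA", "GTG", "ATC", "CCT",
                        "ACA")

#' Configuration for the TRAC-seq simulator
#'
#' Models the reduction/aniline cleavage chemistry as a per-molecule
#' Bernoulli event: in the treated arm a modified molecule is cleaved at its
#' m7G site with probability `p_cleave_treated`; everywhere else (the
#' non-treated arm, and unmodified molecules in either arm) cleavage occurs
#' at the background rate `p_cleave_background`. A cleaved molecule yields
#' the downstream fragment, i.e. a read that starts exactly at the cleavage
#' position; an uncleaved molecule yields a full-length read starting at
#' position 1.
#'
#' @param n_trnas Number of mature tRNAs to simulate.
#' @param reads_per_trna Source molecules per tRNA per library.
#' @param modified_fraction Fraction of tRNAs carrying an m7G site.
#' @param m7g_positions Candidate site positions (variable loop, 46-48).
#' @param p_cleave_treated Cleavage probability at an m7G site in the
#'   treated arm.
#' @param p_cleave_background Background cleavage probability (non-treated
#'   arm and unmodified molecules).
#' @param read_length Maximum read length in nt, or `NULL` for full
#'   fragments.
#' @param length_range Mature tRNA length range in nt (CCA included).
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @return A `trac_sim_config` list.
#' @export
trac_sim_config <- function(n_trnas = 20, reads_per_trna = 2000,
                            modified_fraction = 0.5,
                            m7g_positions = 46:48,
                            p_cleave_treated = 0.3,
                            p_cleave_background = 0.01,
                            read_length = NULL,
                            length_range = c(70, 90),
                            seed = 1) {
  if (n_trnas < 1) stop("n_trnas must be >= 1", call. = FALSE)
  if (reads_per_trna < 1) stop("reads_per_trna must be >= 1", call. = FALSE)
  if (modified_fraction < 0 || modified_fraction > 1) {
    stop("modified_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!(p_cleave_background >= 0 && p_cleave_background < p_cleave_treated &&
        p_cleave_treated <= 1)) {
    stop("need 0 <= p_cleave_background < p_cleave_treated <= 1",
         call. = FALSE)
  }
  if (any(m7g_positions >= min(length_range))) {
    stop("m7g_positions must lie inside the shortest mature tRNA",
         call. = FALSE)
  }
  structure(list(n_trnas = as.integer(n_trnas),
                 reads_per_trna = as.integer(reads_per_trna),
                 modified_fraction = modified_fraction,
                 m7g_positions = as.integer(m7g_positions),
                 p_cleave_treated = p_cleave_treated,
                 p_cleave_background = p_cleave_background,
                 read_length = read_length,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "trac_sim_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 19e7) * 10 + offset)
}

#' Simulate a mature tRNA reference with implanted m7G sites
#'
#' Generates `n_trnas` mature sequences (random body, canonical anticodon
#' placed at positions 34-36, `CCA` 3' tail) of which `modified_fraction`
#' carry a designated `G` at a position drawn from `m7g_positions`.
#'
#' @param config A [trac_sim_config()].
#' @return A list with `reference` (mature-tRNA tibble, see
#'   [build_mature_reference()]) and `truth` (tibble: `trna_id`, `modified`,
#'   `m7g_position`).
#' @export
simulate_trna_reference <- function(config) {
  stopifnot(inherits(config, "trac_sim_config"))
  withr::with_seed(derive_seed(config$seed, 0L), {
    n <- config$n_trnas
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   n, replace = TRUE)
    n_mod <- round(n * config$modified_fraction)
    modified <- rep(c(TRUE, FALSE), c(n_mod, n - n_mod))
    pos_pool <- config$m7g_positions
    m7g_pos <- ifelse(modified,
                      pos_pool[sample.int(length(pos_pool), n,
                                          replace = TRUE)],
                      NA_integer_)
    anticodons <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- vapply(seq_len(n), function(i) {
      body <- sample(c("A", "C", "G", "T"), lens[i] - 3L, replace = TRUE)
      body[34:36] <- strsplit(anticodons[i], "")[[1]]
      if (modified[i]) body[m7g_pos[i]] <- "G"
      paste0(paste(body, collapse = ""), "CCA")
    }, character(1))
    ids <- sprintf("tRNA-%s-%s-sim%02d", anticodon_isotype(anticodons),
                   anticodons, seq_len(n))
    list(
      reference = tibble::tibble(
        trna_id = ids, sequence = seqs, anticodon = anticodons,
        isotype = anticodon_isotype(anticodons), length = nchar(seqs),
        source_ids = as.list(ids)
      ),
      truth = tibble::tibble(trna_id = ids, modified = modified,
                             m7g_position = m7g_pos)
    )
  })
}

#' Simulate one TRAC-seq library (treated or non-treated arm)
#'
#' See [trac_sim_config()] for the generative model. The returned alignment
#' table (1-based, closed coordinates on the mature sequence) makes the
#' whole calling pipeline testable without an external aligner; FASTQ export
#' is available through [write_fixtures()].
#'
#' @param reference,truth Output of [simulate_trna_reference()].
#' @param config The [trac_sim_config()].
#' @param arm `"treated"` or `"non_treated"`.
#' @param p_site Optional override of the cleavage probability at m7G sites
#'   (e.g. to emulate a methyltransferase knockdown by halving it);
#'   defaults to the arm's configured probability.
#' @param seed_offset Extra offset added to the derived seed so paired
#'   conditions can be simulated independently from one config.
#' @return A tibble of alignments: `read_id`, `trna_id`, `start`, `end`,
#'   plus a `realized_cleavage` attribute (per-tRNA realized site-cleavage
#'   fraction).
#' @export
simulate_trac_library <- function(reference, truth, config,
                                  arm = c("treated", "non_treated"),
                                  p_site = NULL, seed_offset = 0L) {
  arm <- match.arg(arm)
  stopifnot(inherits(config, "trac_sim_config"))
  p_mod <- p_site %||% switch(arm,
                              treated = config$p_cleave_treated,
                              non_treated = config$p_cleave_background)
  arm_off <- switch(arm, treated = 1L, non_treated = 2L)
  withr::with_seed(derive_seed(config$seed, arm_off + 10L * seed_offset), {
    n_reads <- config$reads_per_trna
    pieces <- vector("list", nrow(reference))
    realized <- numeric(nrow(reference))
    for (i in seq_len(nrow(reference))) {
      len <- reference$length[i]
      if (isTRUE(truth$modified[i])) {
        cleaved <- stats::rbinom(n_reads, 1L, p_mod) == 1L
        start <- ifelse(cleaved, truth$m7g_position[i], 1L)
        realized[i] <- mean(cleaved)
      } else {
        cleaved <- stats::rbinom(n_reads, 1L, config$p_cleave_background) == 1L
        pos <- sample(2:(len - 1L), n_reads, replace = TRUE)
        start <- ifelse(cleaved, pos, 1L)
        realized[i] <- mean(cleaved)
      }
      end <- rep(len, n_reads)
      if (!is.null(config$read_length)) {
        end <- pmin(end, start + config$read_length - 1L)
      }
      pieces[[i]] <- tibble::tibble(trna_id = reference$trna_id[i],
                                    start = as.integer(start),
                                    end = as.integer(end))
    }
    out <- dplyr::bind_rows(pieces)
    out <- tibble::tibble(
      read_id = sprintf("%s_%s_%07d", arm, out$trna_id, seq_len(nrow(out))),
      out
    )
    attr(out, "realized_cleavage") <-
      tibble::tibble(trna_id = reference$trna_id, arm = arm,
                     realized_fraction = realized)
    out
  })
}

#' Configuration for the tRNA expression simulator
#'
#' Emulates demethylase(ALKB)-treated small-RNA expression libraries:
#' per-tRNA absolute abundances are log-normal, sequenced counts are Poisson
#' around them, and in the knockdown arm the abundance of every
#' m7G-modified tRNA is scaled by `kd_factor`. tRNA reads are a minority of
#' a small-RNA library, so `total_mapped_reads` (the RPKM denominator) is a
#' library property held equal across arms rather than the tRNA-count sum.
#'
#' @param mean_log_abundance,sd_log_abundance Log-normal parameters of the
#'   expected per-tRNA read count.
#' @param kd_factor Abundance scaling of modified tRNAs under knockdown.
#' @param total_mapped_reads Total mapped reads per library (RPKM
#'   denominator).
#' @param seed Integer seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(mean_log_abundance = log(1e5),
                            sd_log_abundance = 0.5,
                            kd_factor = 0.6,
                            total_mapped_reads = 2e7,
                            seed = 1) {
  if (kd_factor < 0) stop("kd_factor must be >= 0", call. = FALSE)
  if (total_mapped_reads <= 0) {
    stop("total_mapped_reads must be > 0", call. = FALSE)
  }
  structure(list(mean_log_abundance = mean_log_abundance,
                 sd_log_abundance = sd_log_abundance,
                 kd_factor = kd_factor,
                 total_mapped_reads = total_mapped_reads,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate paired control/knockdown tRNA expression count tables
#'
#' @param reference,truth Output of [simulate_trna_reference()].
#' @param config An [expr_sim_config()].
#' @return A list with `control` and `knockdown` count tibbles (`trna_id`,
#'   `read_count`, `length_nt`), `totals` (named total mapped reads), and
#'   `truth` (per-tRNA abundances and modification flags).
#' @export
simulate_expression_counts <- function(reference, truth, config) {
  stopifnot(inherits(config, "expr_sim_config"))
  withr::with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(reference)
    abundance <- exp(stats::rnorm(n, config$mean_log_abundance,
                                  config$sd_log_abundance))
    mu_kd <- abundance * ifelse(truth$modified, config$kd_factor, 1)
    ctrl <- stats::rpois(n, abundance)
    kd <- stats::rpois(n, mu_kd)
    list(
      control = tibble::tibble(trna_id = reference$trna_id,
                               read_count = as.numeric(ctrl),
                               length_nt = reference$length),
      knockdown = tibble::tibble(trna_id = reference$trna_id,
                                 read_count = as.numeric(kd),
                                 length_nt = reference$length),
      totals = c(control = config$total_mapped_reads,
                 knockdown = config$total_mapped_reads),
      truth = tibble::tibble(trna_id = reference$trna_id,
                             abundance = abundance,
                             modified = truth$modified)
    )
  })
}

#' Configuration for the translation-efficiency simulator
#'
#' Per gene, an m7G-codon frequency `f` is drawn uniformly from
#' `codon_freq_range` and implanted exactly into a synthetic CDS by mixing
#' codons from the designated m7G codon set with other sense codons. The
#' true knockdown effect on translation is linear in `f`:
#' `log2 TE ratio = -beta * f + Normal(0, sigma)`. Sequenced fragment counts
#' for the four libraries (input/polysome x control/knockdown) are negative
#' binomial around means consistent with the gene's abundance and TE.
#'
#' @param n_genes Number of genes.
#' @param cds_length_range CDS length range in codons (stop excluded).
#' @param codon_freq_range Range of the implanted m7G-codon frequency.
#' @param beta Log2 TE decrease per unit `f` under knockdown (>= 0).
#' @param sigma Gene-level noise SD on the true log2 TE ratio.
#' @param dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param mean_log_counts,sd_log_counts Log-normal parameters of the
#'   expected input fragment count per gene.
#' @param te_log2_sd SD of the control-condition log2 TE across genes.
#' @param m7g_codons Codon set used to implant `f`.
#' @param seed Integer seed.
#' @return A `te_sim_config` list.
#' @export
te_sim_config <- function(n_genes = 8000,
                          cds_length_range = c(100, 500),
                          codon_freq_range = c(0.2, 0.6),
                          beta = 2, sigma = 0.2, dispersion = 0.1,
                          mean_log_counts = log(500), sd_log_counts = 1,
                          te_log2_sd = 0.3,
                          m7g_codons = DEFAULT_M7G_CODONS,
                          seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (diff(cds_length_range) < 0 || cds_length_range[1] < 10) {
    stop("cds_length_range must be non-degenerate and >= 10 codons",
         call. = FALSE)
  }
  if (codon_freq_range[1] < 0 || codon_freq_range[2] > 1 ||
      diff(codon_freq_range) <= 0) {
    stop("codon_freq_range must be a non-degenerate interval in [0, 1]",
         call. = FALSE)
  }
  if (beta < 0 || sigma < 0 || dispersion < 0) {
    stop("beta, sigma and dispersion must be >= 0", call. = FALSE)
  }
  m7g_codons <- vapply(m7g_codons, normalize_dna, character(1),
                       USE.NAMES = FALSE)
  if (!all(m7g_codons %in% SENSE_CODONS)) {
    stop("m7g_codons must be sense codons", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 cds_length_range = as.integer(cds_length_range),
                 codon_freq_range = codon_freq_range,
                 beta = beta, sigma = sigma, dispersion = dispersion,
                 mean_log_counts = mean_log_counts,
                 sd_log_counts = sd_log_counts,
                 te_log2_sd = te_log2_sd,
                 m7g_codons = sort(unique(m7g_codons)),
                 seed = as.integer(seed)),
            class = "te_sim_config")
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a polysome/input translation-efficiency experiment
#'
#' @param config A [te_sim_config()].
#' @return A list with `cds` (tibble `gene_id`, `cds`; stop codon `TAA`
#'   appended), `counts` (tibble `gene_id`, `length_nt`, `input_ctrl`,
#'   `poly_ctrl`, `input_kd`, `poly_kd`), `truth` (realized `f`, true log2
#'   TE ratio and the four library means per gene) and `codon_set`.
#' @export
simulate_te_experiment <- function(config) {
  stopifnot(inherits(config, "te_sim_config"))
  withr::with_seed(derive_seed(config$seed, 4L), {
    n <- config$n_genes
    n_codons <- sample(seq(config$cds_length_range[1],
                           config$cds_length_range[2]), n, replace = TRUE)
    f_target <- stats::runif(n, config$codon_freq_range[1],
                             config$codon_freq_range[2])
    n_set <- round(f_target * n_codons)
    f <- n_set / n_codons

    gene_idx <- rep.int(seq_len(n), n_codons)
    in_set <- sequence(n_codons) <= rep.int(n_set, n_codons)
    ord <- order(gene_idx, stats::runif(length(gene_idx)))
    in_set <- in_set[ord]
    nonset <- setdiff(SENSE_CODONS, config$m7g_codons)
    codons <- character(length(gene_idx))
    codons[in_set] <- sample(config$m7g_codons, sum(in_set), replace = TRUE)
    codons[!in_set] <- sample(nonset, sum(!in_set), replace = TRUE)
    cds <- vapply(split(codons, gene_idx), paste, character(1),
                  collapse = "")
    cds <- paste0(cds, "TAA")
    gene_id <- sprintf("gene%05d", seq_len(n))

    mu_input <- exp(stats::rnorm(n, config$mean_log_counts,
                                 config$sd_log_counts))
    te_ctrl <- 2^stats::rnorm(n, 0, config$te_log2_sd)
    true_l2r <- -config$beta * f + stats::rnorm(n, 0, config$sigma)
    mu <- cbind(input_ctrl = mu_input,
                poly_ctrl = mu_input * te_ctrl,
                input_kd = mu_input,
                poly_kd = mu_input * te_ctrl * 2^true_l2r)
    counts <- apply(mu, 2, function(m) rnbinom_mu(n, m, config$dispersion))

    list(
      cds = tibble::tibble(gene_id = gene_id, cds = cds),
      counts = tibble::tibble(gene_id = gene_id,
                              length_nt = 3L * (n_codons + 1L),
                              input_ctrl = as.numeric(counts[, "input_ctrl"]),
                              poly_ctrl = as.numeric(counts[, "poly_ctrl"]),
                              input_kd = as.numeric(counts[, "input_kd"]),
                              poly_kd = as.numeric(counts[, "poly_kd"])),
      truth = tibble::tibble(gene_id = gene_id, f = f,
                             true_log2_te_ratio = true_l2r,
                             mu_input_ctrl = mu[, "input_ctrl"],
                             mu_poly_ctrl = mu[, "poly_ctrl"],
                             mu_input_kd = mu[, "input_kd"],
                             mu_poly_kd = mu[, "poly_kd"]),
      codon_set = config$m7g_codons
    )
  })
}

#' Closed-form correlation between codon frequency and measured TE ratio
#'
#' Under the simulator's linear model the measured per-gene log2 TE ratio is
#' `-beta * f + Normal(0, sigma)` plus counting noise from the four
#' negative-binomial libraries. By the delta method the counting noise
#' contributes `sum over libraries of (1/mu + dispersion) / ln(2)^2` to the
#' variance, so the expected Pearson correlation with `f` is
#' `-beta * sd(f) / sqrt(beta^2 var(f) + sigma^2 + v_meas)`. With
#' `dispersion = 0` and large counts this reduces to the pure
#' linear-plus-noise form.
#'
#' @param config The [te_sim_config()].
#' @param truth The simulator's truth table (supplies the realized `f` and
#'   per-library means); if `NULL`, the experiment is regenerated from
#'   `config`.
#' @return Expected Pearson r (a negative number when `beta > 0`).
#' @export
expected_freq_te_correlation <- function(config, truth = NULL) {
  stopifnot(inherits(config, "te_sim_config"))
  if (is.null(truth)) truth <- simulate_te_experiment(config)$truth
  mu <- as.matrix(truth[, c("mu_input_ctrl", "mu_poly_ctrl",
                            "mu_input_kd", "mu_poly_kd")])
  v_meas <- mean(rowSums(1 / mu + config$dispersion)) / log(2)^2
  var_f <- stats::var(truth$f)
  -config$beta * sqrt(var_f) /
    sqrt(config$beta^2 * var_f + config$sigma^2 + v_meas)
}

#' Write synthetic fixtures to disk with a manifest
#'
#' Materialises a complete synthetic study: mature tRNA reference (FASTA +
#' table), treated/non-treated TRAC-seq libraries (FASTQ + alignment TSV),
#' control/knockdown expression count tables, CDS FASTA, the four-library
#' TE count table, both truth tables, and a JSON manifest recording seeds
#' and per-file MD5 checksums. Re-running with the same configs is
#' byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param trac_config,expr_config,te_config Simulator configurations.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_fixtures <- function(outdir,
                           trac_config = trac_sim_config(),
                           expr_config = expr_sim_config(),
                           te_config = te_sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trna_reference(trac_config)
  paths <- character(0)

  p <- file.path(outdir, "mature_trnas.fa")
  write_mature_reference(sim$reference, fasta_path = p,
                         table_path = file.path(outdir, "mature_trnas.tsv"))
  paths <- c(paths, p, file.path(outdir, "mature_trnas.tsv"))

  p <- file.path(outdir, "truth_trnas.tsv")
  utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  for (arm in c("treated", "non_treated")) {
    aln <- simulate_trac_library(sim$reference, sim$truth, trac_config, arm)
    ap <- file.path(outdir, paste0("trac_", arm, ".alignments.tsv"))
    utils::write.table(aln, ap, sep = "\t", quote = FALSE, row.names = FALSE)
    fq <- file.path(outdir, paste0("trac_", arm, ".fastq"))
    write_alignment_fastq(aln, sim$reference, fq)
    paths <- c(paths, ap, fq)
  }

  expr <- simulate_expression_counts(sim$reference, sim$truth, expr_config)
  for (cond in c("control", "knockdown")) {
    p <- file.path(outdir, paste0("trna_counts_", cond, ".tsv"))
    utils::write.table(expr[[cond]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }

  te <- simulate_te_experiment(te_config)
  cds_set <- Biostrings::DNAStringSet(te$cds$cds)
  names(cds_set) <- te$cds$gene_id
  p <- file.path(outdir, "cds.fa")
  Biostrings::writeXStringSet(cds_set, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "te_counts.tsv")
  utils::write.table(te$counts, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "truth_genes.tsv")
  utils::write.table(te$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "m7g_codon_set.tsv")
  utils::write.table(data.frame(codon = te$codon_set), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  manifest <- list(
    seeds = list(trac = trac_config$seed, expression = expr_config$seed,
                 te = te_config$seed),
    truth_tables = list(trnas = "truth_trnas.tsv", genes = "truth_genes.tsv"),
    files = lapply(stats::setNames(paths, basename(paths)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Emit reads of an alignment table as FASTQ (constant high quality; the
# pipeline never uses quality strings).
write_alignment_fastq <- function(alignments, reference, path) {
  seqs <- substr(reference$sequence[match(alignments$trna_id,
                                          reference$trna_id)],
                 alignments$start, alignments$end)
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- alignments$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
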