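#' Construct a tRNA gene record
#'
#' A `trna_gene` holds the unspliced genomic sequence of a tRNA gene together
#' with its predicted intron intervals, anticodon and isotype (amino-acid
#' identity). Intron coordinates are 1-based closed intervals on the gene
#' sequence. `U` is normalised to `T` so that all sequence spaces in the
#' package are DNA-alphabet.
#'
#' @param gene_id Gene identifier.
#' @param genomic_sequence Unspliced gene sequence (A/C/G/T; U accepted and
#'   converted to T).
#' @param anticodon 3-mer anticodon as written 5'->3' in the tRNA.
#' @param isotype Amino-acid code (e.g. `"Lys"`); if `NULL`, derived from the
#'   anticodon via the standard genetic code.
#' @param intron_intervals A list of length-2 integer vectors `c(start, end)`
#'   (1-based, closed) on the gene sequence; possibly empty.
#' @return An object of class `trna_gene`.
#' @export
trna_gene <- function(gene_id, genomic_sequence, anticodon, isotype = NULL,
                      intron_intervals = list()) {
  genomic_sequence <- normalize_dna(genomic_sequence, what = gene_id)
  anticodon <- normalize_dna(anticodon, what = paste0(gene_id, " anticodon"))
  if (nchar(anticodon) != 3L) {
    stop("anticodon for '", gene_id, "' must be a 3-mer, got '", anticodon, "'",
         call. = FALSE)
  }
  intron_intervals <- lapply(intron_intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2]) {
      stop("malformed intron interval for gene '", gene_id, "'", call. = FALSE)
    }
    iv
  })
  validate_introns(intron_intervals, nchar(genomic_sequence), gene_id)
  if (is.null(isotype)) isotype <- anticodon_isotype(anticodon)
  spliced <- excise_intervals(genomic_sequence, intron_intervals)
  if (!grepl(anticodon, spliced, fixed = TRUE)) {
    stop("anticodon '", anticodon, "' not found in the spliced sequence of '",
         gene_id, "'", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, genomic_sequence = genomic_sequence,
         intron_intervals = intron_intervals, anticodon = anticodon,
         isotype = isotype),
    class = "trna_gene"
  )
}

normalize_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  if (grepl("[^ACGT]", x)) {
    stop("non-ACGT characters in ", what, call. = FALSE)
  }
  x
}

validate_introns <- function(intervals, seq_len, gene_id) {
  if (length(intervals) == 0L) return(invisible(TRUE))
  m <- do.call(rbind, intervals)
  if (any(m[, 1] < 1L) || any(m[, 2] > seq_len)) {
    stop("reference construction failed for gene '", gene_id,
         "': intron interval outside the gene sequence", call. = FALSE)
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
    stop("reference construction failed for gene '", gene_id,
         "': overlapping intron intervals", call. = FALSE)
  }
  invisible(TRUE)
}

excise_intervals <- function(sequence, intervals) {
  if (length(intervals) == 0L) return(sequence)
  keep <- rep(TRUE, nchar(sequence))
  for (iv in intervals) keep[iv[1]:iv[2]] <- FALSE
  paste(strsplit(sequence, "")[[1]][keep], collapse = "")
}

#' Build a mature tRNA from a gene model
#'
#' Excises the predicted introns from the gene sequence and appends the
#' post-transcriptional `CCA` tail to the 3' end, yielding the mature tRNA
#' sequence that sequencing reads are aligned against.
#'
#' @param gene A [trna_gene()].
#' @return A one-row [tibble::tibble] with columns `trna_id`, `sequence`,
#'   `anticodon`, `isotype`, `length` (nucleotides, CCA included) and
#'   `source_ids` (list column of contributing gene ids).
#' @examples
#' g <- trna_gene("tRNA-Xxx", "AAAGGGTTT", anticodon = "AAA",
#'                intron_intervals = list(c(4, 6)))
#' build_mature_trna(g)$sequence  # "AAATTTCCA"
#' @export
build_mature_trna <- function(gene) {
  stopifnot(inherits(gene, "trna_gene"))
  mature <- paste0(excise_intervals(gene$genomic_sequence,
                                    gene$intron_intervals), "CCA")
  tibble::tibble(
    trna_id = gene$gene_id,
    sequence = mature,
    anticodon = gene$anticodon,
    isotype = gene$isotype,
    length = nchar(mature),
    source_ids = list(gene$gene_id)
  )
}

#' Build a mature tRNA reference from gene models
#'
#' Applies [build_mature_trna()] to every gene and, by default, collapses
#' distinct gene loci that yield an identical mature sequence into a single
#' reference entry carrying all contributing gene ids (reads cannot
#' distinguish identical mature sequences, so keeping duplicates would only
#' split counts arbitrarily). The collapse is recorded in `source_ids` and is
#' therefore reversible.
#'
#' @param genes List of [trna_gene()] objects.
#' @param collapse_duplicates Collapse identical mature sequences
#'   (default `TRUE`).
#' @return A tibble, one row per mature tRNA (see [build_mature_trna()]).
#' @export
build_mature_reference <- function(genes, collapse_duplicates = TRUE) {
  ref <- dplyr::bind_rows(lapply(genes, build_mature_trna))
  if (collapse_duplicates && anyDuplicated(ref$sequence)) {
    ref <- ref |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(
        trna_id = .data$trna_id[1],
        anticodon = .data$anticodon[1],
        isotype = .data$isotype[1],
        length = .data$length[1],
        source_ids = list(unlist(.data$source_ids)),
        .groups = "drop"
      ) |>
      dplyr::select("trna_id", "sequence", "anticodon", "isotype",
                    "length", "source_ids")
  }
  ref[order(ref$trna_id), , drop = FALSE]
}

#' Read tRNA gene models from an annotated FASTA file
#'
#' The header dialect is `>gene_id isotype=Xxx anticodon=NNN
#' [introns=a-b,c-d]` with 1-based closed intron intervals on the gene
#' sequence. A plain mature-tRNA FASTA (sequences already ending in `CCA`,
#' headers carrying at least `anticodon=`) can instead be read with
#' [load_mature_fasta()].
#'
#' @param path Path to the FASTA file.
#' @return A list of [trna_gene()] objects (empty list for an empty file).
#' @export
load_trna_genes <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- parse_trna_header(names(seqs)[i])
    trna_gene(hdr$id, as.character(seqs[[i]]), anticodon = hdr$anticodon,
              isotype = hdr$isotype, intron_intervals = hdr$introns)
  })
}

parse_trna_header <- function(header) {
  fields <- strsplit(trimws(header), "\\s+")[[1]]
  if (length(fields) < 1L || !nzchar(fields[1])) {
    stop("malformed FASTA header: '", header, "'", call. = FALSE)
  }
  kv <- fields[-1]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"anticodon" %in% keys) {
    stop("FASTA header for record '", fields[1],
         "' lacks an anticodon= field", call. = FALSE)
  }
  introns <- list()
  if ("introns" %in% keys && nzchar(vals[["introns"]])) {
    introns <- lapply(strsplit(vals[["introns"]], ",")[[1]], function(iv) {
      parts <- as.integer(strsplit(iv, "-")[[1]])
      if (length(parts) != 2L || anyNA(parts)) {
        stop("malformed introns= field in record '", fields[1], "'",
             call. = FALSE)
      }
      parts
    })
  }
  list(id = fields[1],
       anticodon = vals[["anticodon"]],
       isotype = if ("isotype" %in% keys) vals[["isotype"]] else NULL,
       introns = introns)
}

#' Read a pre-built mature tRNA FASTA
#'
#' Accepts sequences as-is (they must already end in `CCA`). Headers follow
#' the same `key=value` dialect as [load_trna_genes()] minus `introns=`.
#'
#' @param path Path to the FASTA file.
#' @return A mature-tRNA reference tibble.
#' @export
load_mature_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  rows <- lapply(seq_along(seqs), function(i) {
    hdr <- parse_trna_header(names(seqs)[i])
    s <- normalize_dna(as.character(seqs[[i]]), what = hdr$id)
    if (!endsWith(s, "CCA")) {
      stop("mature tRNA '", hdr$id, "' does not end in CCA", call. = FALSE)
    }
    ac <- normalize_dna(hdr$anticodon)
    tibble::tibble(
      trna_id = hdr$id, sequence = s, anticodon = ac,
      isotype = if (is.null(hdr$isotype)) anticodon_isotype(ac) else
        hdr$isotype,
      length = nchar(s), source_ids = list(hdr$id)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a mature tRNA reference as FASTA and as a TSV table
#'
#' The FASTA is suitable for indexing by an external aligner; the TSV records
#' `trna_id`, `isotype`, `anticodon`, `length` and the comma-joined source
#' gene ids so both gene-level and anticodon-level roll-ups stay computable.
#'
#' @param reference Mature-tRNA reference tibble.
#' @param fasta_path,table_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_mature_reference <- function(reference, fasta_path = NULL,
                                   table_path = NULL) {
  if (!is.null(fasta_path)) {
    set <- Biostrings::DNAStringSet(reference$sequence)
    names(set) <- sprintf("%s isotype=%s anticodon=%s",
                          reference$trna_id, reference$isotype,
                          reference$anticodon)
    Biostrings::writeXStringSet(set, fasta_path)
  }
  if (!is.null(table_path)) {
    tab <- data.frame(
      trna_id = reference$trna_id,
      isotype = reference$isotype,
      anticodon = reference$anticodon,
      length = reference$length,
      source_ids = vapply(reference$source_ids, paste, "", collapse = ",")
    )
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta_path, table_path))
}

anticodon_isotype <- function(anticodon) {
  codon <- revcomp(anticodon)
  aa <- as.character(Biostrings::GENETIC_CODE[codon])
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", `*` = "Sup")
  unname(aa3[aa])
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Codons decoded by a tRNA anticodon
#'
#' With `wobble = FALSE` (the default) decoding is strict Watson-Crick: the
#' single decoded codon is the reverse complement of the anticodon (e.g.
#' anticodon `CTT` decodes `AAG`, the Lys codon read by tRNA-Lys-CTT). With
#' `wobble = TRUE` the classic wobble rules at the codon third position /
#' anticodon position 34 are added: G34 also reads codons ending in T (G:U
#' pair) and T34 also reads codons ending in G; A34 and C34 stay strict.
#'
#' @param anticodon 3-mer anticodon (DNA alphabet; U converted).
#' @param wobble Enable wobble expansion (default `FALSE`).
#' @return Character vector of decoded codons, sorted.
#' @export
decoded_codons <- function(anticodon, wobble = FALSE) {
  anticodon <- normalize_dna(anticodon, what = "anticodon")
  if (nchar(anticodon) != 3L) {
    stop("anticodon must be a 3-mer", call. = FALSE)
  }
  codons <- revcomp(anticodon)
  if (wobble) {
    stem <- substr(codons, 1, 2)
    extra <- switch(substr(anticodon, 1, 1),
                    G = paste0(stem, "T"),
                    T = paste0(stem, "G"),
                    character(0))
    codons <- union(codons, extra)
  }
  sort(codons)
}

#' Codons decoded by the m7G-modified tRNA set
#'
#' Takes site calls (see [call_m7g_sites()]) and the mature reference and
#' returns the union of codons decoded by every tRNA with at least one
#' passing m7G call, plus the contributing tRNA ids. Stop codons can only
#' arise through wobble expansion and are flagged.
#'
#' @param calls Tibble of site calls with columns `trna_id` and `passed`.
#' @param reference Mature-tRNA reference tibble.
#' @param wobble Passed to [decoded_codons()].
#' @return A list with `codon_set` (sorted character vector),
#'   `source_trnas`, and `stop_codons` (any stop codons in the set, e.g.
#'   from suppressor anticodons or wobble expansion).
#' @export
build_m7g_codon_set <- function(calls, reference, wobble = FALSE) {
  ids <- unique(calls$trna_id[calls$passed])
  missing <- setdiff(ids, reference$trna_id)
  if (length(missing) > 0L) {
    stop("m7G calls reference tRNAs absent from the reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  acs <- reference$anticodon[match(ids, reference$trna_id)]
  codons <- sort(unique(unlist(lapply(acs, decoded_codons, wobble = wobble))))
  stops <- intersect(codons, c("TAA", "TAG", "TGA"))
  list(codon_set = codons, source_trnas = ids, stop_codons = stops)
}
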