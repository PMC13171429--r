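# Shared I/O and data-model conventions.
#
# Sequences are plain uppercase character strings held in named character
# vectors; nucleotide alphabets are {A,C,G,T,N} (N = assembly gap, excluded
# from every composition count), amino-acid alphabets are the 20 standard
# residues plus '-' (gap), 'X' and '*'. Coordinates are 0-based half-open
# internally; GFF3 (1-based inclusive) is converted at the boundary. Trees
# are ape "phylo" objects.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-", "*")

check_alphabet <- function(seqs, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  legal <- if (alphabet == "dna") NUC_ALPHABET else AA_ALPHABET
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, legal)
    if (length(bad) > 0) {
      abort(sprintf(
        "record '%s' contains characters outside the %s alphabet: %s",
        names(seqs)[i] %||% as.character(i), alphabet,
        paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(seqs)
}

#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase sequences,
#' preserving file order. Record ids are the first whitespace-delimited
#' token of each header. Duplicate ids, empty records and characters outside
#' the declared alphabet (`{A,C,G,T,N}` for DNA, standard residues plus
#' `X`/`-`/`*` for protein) are rejected.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (length(seqs) == 0) abort("FASTA file contains no records")
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty record(s): %s",
                  paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate record id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  check_alphabet(seqs, alphabet)
  seqs
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then re-reading recovers identical ids
#' and sequences.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read gene loci from GFF3 or BED-like TSV
#'
#' Returns one row per locus with internal 0-based half-open coordinates.
#' GFF3 coordinates (1-based inclusive) are converted at the boundary; a
#' BED-like TSV (`chrom start end [name] [score] [strand]`, no header) is
#' passed through. Strand defaults to `"+"` when absent.
#'
#' @param path Path to the loci file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param genomes Optional named character vector of genome sequences; when
#'   supplied, loci referencing unknown genomes or exceeding sequence bounds
#'   are rejected.
#' @return A tibble with columns `genome_id`, `gene_id`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_loci <- function(path, dialect = c("gff3", "bed"), genomes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "gff3") {
    gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    ids <- if ("ID" %in% names(gr)) as.character(gr$ID) else
      rep(NA_character_, nrow(gr))
    if ("Name" %in% names(gr)) ids <- dplyr::coalesce(ids, as.character(gr$Name))
    ids[is.na(ids)] <- paste0("locus", seq_len(nrow(gr)))[is.na(ids)]
    strand <- as.character(gr$strand)
    strand[!strand %in% c("+", "-")] <- "+"
    loci <- tibble(
      genome_id = as.character(gr$seqnames),
      gene_id = ids,
      start = as.integer(gr$start) - 1L,  # 1-based incl -> 0-based half-open
      end = as.integer(gr$end),
      strand = strand
    )
  } else {
    df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE, comment = "#")
    if (ncol(df) < 3) abort("BED-like TSV needs at least 3 columns")
    loci <- tibble(
      genome_id = as.character(df[[1]]),
      gene_id = if (ncol(df) >= 4) as.character(df[[4]]) else
        paste0("locus", seq_len(nrow(df))),
      start = as.integer(df[[2]]),
      end = as.integer(df[[3]]),
      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+"
    )
    loci$strand[!loci$strand %in% c("+", "-")] <- "+"
  }
  bad <- loci$start >= loci$end | loci$start < 0
  if (any(bad)) {
    abort(sprintf("invalid interval(s) (start >= end after conversion): %s",
                  paste(loci$gene_id[bad], collapse = ", ")))
  }
  if (anyDuplicated(paste(loci$genome_id, loci$gene_id))) {
    abort("gene_id values must be unique within a genome")
  }
  if (!is.null(genomes)) {
    unknown <- setdiff(unique(loci$genome_id), names(genomes))
    if (length(unknown) > 0) {
      abort(sprintf("loci reference unknown genome id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    glen <- nchar(genomes)[loci$genome_id]
    if (any(loci$end > glen)) {
      abort(sprintf("locus end beyond genome length: %s",
                    paste(loci$gene_id[loci$end > glen], collapse = ", ")))
    }
  }
  loci
}

#' Write loci as a BED-like TSV
#'
#' @param loci Tibble as returned by [read_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  readr::write_tsv(
    tibble(loci$genome_id, loci$start, loci$end, loci$gene_id, 0L, loci$strand),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the package's validity checks: a single
#' tree per file, unique tip labels, non-negative finite branch lengths.
#' Missing branch lengths default to zero with a warning; a basal polytomy
#' is flagged (warning) when `require_rooted` is set.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param require_rooted Warn on an unrooted basal polytomy.
#' @param text Optional Newick string, read instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, require_rooted = TRUE, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    ape::read.tree(path)
  }
  if (is.null(tr)) abort("unparseable Newick input")
  if (inherits(tr, "multiPhylo")) abort("expected a single tree per file")
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicate tip label(s): %s",
                  paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                        collapse = ", ")))
  }
  if (is.null(tr$edge.length)) {
    warn("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    abort("branch lengths must be finite and non-negative")
  }
  if (require_rooted && !ape::is.rooted(tr)) {
    warn("tree has a basal polytomy (not strictly rooted)")
  }
  tr
}

#' Read a binary trait table
#'
#' Two-column TSV `tip<TAB>state` with states 0 (absent) / 1 (present),
#' no header.
#'
#' @param path Path to the TSV.
#' @return Named integer vector of 0/1 states.
#' @export
read_trait_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("tip", "state"),
                        col_types = "ci", progress = FALSE)
  if (any(!df$state %in% c(0L, 1L))) abort("trait states must be 0 or 1")
  if (anyDuplicated(df$tip)) abort("duplicate tip in trait table")
  setNames(df$state, df$tip)
}
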