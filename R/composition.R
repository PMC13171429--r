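# GC-content screen: a laterally acquired gene typically deviates from its
# host genome's composition, so the gene-vs-genome GC deviation per strain
# is the first line of evidence.

#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator.
#'
#' @param sequence Uppercase nucleotide string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  b <- strsplit(sequence, "")[[1]]
  n <- sum(b %in% c("A", "C", "G", "T"))
  if (n == 0) abort("sequence has no non-N bases")
  sum(b %in% c("G", "C")) / n
}

# Pooled-count GC over several contigs (not a mean of per-contig fractions).
gc_content_pooled <- function(contigs) {
  b <- strsplit(paste(contigs, collapse = ""), "")[[1]]
  n <- sum(b %in% c("A", "C", "G", "T"))
  if (n == 0) abort("genome has no non-N bases")
  sum(b %in% c("G", "C")) / n
}

#' Gene vs genome GC content across strains
#'
#' For each locus, computes the GC fraction of the gene (sliced from its
#' genome unless an explicit CDS set is supplied) and of the whole genome
#' (all contigs pooled by base counting), and the deviation gene - genome.
#' Genomes may span several contigs: supply `contig_map` naming, for each
#' strain, its contig ids in `genomes`; by default each locus' `genome_id`
#' is taken as a single-contig strain.
#'
#' @param loci Tibble of loci (see [read_loci()]); one locus per strain.
#' @param genomes Named character vector of contig sequences.
#' @param gene_seqs Optional named character vector of gene CDS, indexed by
#'   `gene_id`; overrides slicing.
#' @param contig_map Optional named list: strain id -> character vector of
#'   contig ids.
#' @return Object of class `"gc_screen"`: tibble with `strain`, `gene_gc`,
#'   `genome_gc`, `deviation`, `z` plus a `summary` attribute; [tidy()]
#'   returns the table, [glance()] the per-group means/s.d.
#' @export
gene_vs_genome_gc <- function(loci, genomes, gene_seqs = NULL,
                              contig_map = NULL) {
  recs <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    loc <- loci[i, ]
    strain <- loc$genome_id
    contigs <- if (!is.null(contig_map)) {
      if (!strain %in% names(contig_map)) {
        abort(sprintf("no contigs mapped for strain '%s'", strain))
      }
      genomes[contig_map[[strain]]]
    } else {
      if (!strain %in% names(genomes)) {
        abort(sprintf("missing genome for locus '%s'", loc$gene_id))
      }
      genomes[strain]
    }
    if (anyNA(contigs)) abort(sprintf("missing contig(s) for strain '%s'", strain))
    gene_seq <- if (!is.null(gene_seqs)) {
      if (!loc$gene_id %in% names(gene_seqs)) {
        abort(sprintf("no CDS supplied for gene '%s'", loc$gene_id))
      }
      gene_seqs[[loc$gene_id]]
    } else {
      substr(genomes[[strain]], loc$start + 1L, loc$end)
    }
    tibble(strain = strain, gene_id = loc$gene_id,
           gene_gc = gc_content(gene_seq),
           genome_gc = gc_content_pooled(contigs))
  })
  recs$deviation <- recs$gene_gc - recs$genome_gc
  recs$z <- if (nrow(recs) >= 2 && sd(recs$gene_gc) > 0) {
    (recs$gene_gc - mean(recs$gene_gc)) / sd(recs$gene_gc)
  } else NA_real_
  structure(recs, class = c("gc_screen", class(recs)))
}

#' @export
#' @exportS3Method generics::tidy
tidy.gc_screen <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
#' @exportS3Method generics::glance
glance.gc_screen <- function(x, ...) {
  n <- nrow(x)
  tibble(
    n = n,
    gene_gc_mean = mean(x$gene_gc),
    gene_gc_sd = if (n >= 2) sd(x$gene_gc) else NA_real_,
    genome_gc_mean = mean(x$genome_gc),
    genome_gc_sd = if (n >= 2) sd(x$genome_gc) else NA_real_,
    deviation_mean = mean(x$deviation),
    deviation_sd = if (n >= 2) sd(x$deviation) else NA_real_
  )
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.gc_screen <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("gene_gc", "genome_gc"),
                              names_to = "which", values_to = "gc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = 100 * .data$gc,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "GC (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Z-score of a gene's GC against a background of gene GC values
#'
#' `(gene_gc - mean(background)) / sd(background)` with the sample (n-1)
#' standard deviation.
#'
#' @param gene_gc GC fraction of the focal gene.
#' @param background_gene_gcs Numeric vector (n >= 2) of background GC
#'   fractions.
#' @return The z-score.
#' @export
gc_deviation_z <- function(gene_gc, background_gene_gcs) {
  if (length(background_gene_gcs) < 2) abort("background needs n >= 2")
  s <- sd(background_gene_gcs)
  if (s == 0) abort("zero-variance background")
  (gene_gc - mean(background_gene_gcs)) / s
}
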