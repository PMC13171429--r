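# Gene-neighbourhood synteny around a focal locus. A neighbourhood profile
# is the ordered list of gene-family labels within a window of the focal
# gene; families come from any caller-supplied orthology labelling.

#' Build a gene-neighbourhood profile around a focal locus
#'
#' Collects the loci whose intervals intersect the window
#' `[focal_start - window_bp, focal_end + window_bp)` on the focal gene's
#' genome, ordered by start coordinate, and attaches their family labels.
#'
#' @param loci Tibble of loci (see [read_loci()]).
#' @param focal_gene_id `gene_id` of the focal locus.
#' @param families Named character vector: `gene_id` -> family label.
#' @param window_bp Window on each side of the focal locus (default
#'   10000).
#' @return Object of class `"neighborhood_profile"`: tibble with
#'   `gene_id`, `family`, `strand`, `offset` (bp from the focal-gene
#'   start, signed), plus attributes `focal` and `window_bp`.
#' @export
neighborhood_profile <- function(loci, focal_gene_id, families,
                                 window_bp = 10000) {
  focal <- loci[loci$gene_id == focal_gene_id, ]
  if (nrow(focal) != 1) abort(sprintf("focal gene '%s' not found uniquely",
                                      focal_gene_id))
  win_lo <- focal$start - window_bp
  win_hi <- focal$end + window_bp
  nb <- loci[loci$genome_id == focal$genome_id &
               loci$end > win_lo & loci$start < win_hi, ]
  nb <- nb[order(nb$start), ]
  missing <- setdiff(nb$gene_id, names(families))
  if (length(missing) > 0) {
    abort(sprintf("no family label for gene(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(gene_id = nb$gene_id,
                family = unname(families[nb$gene_id]),
                strand = nb$strand,
                offset = nb$start - focal$start)
  structure(out, focal = focal_gene_id, window_bp = window_bp,
            class = c("neighborhood_profile", class(out)))
}

#' Synteny score between two gene neighbourhoods
#'
#' `score = J/2 + ADJ/2` where `J` is the Jaccard index of the two family
#' sets and `ADJ` is the fraction of adjacent ordered family pairs of `A`
#' (after restricting both profiles to the shared families) that appear as
#' adjacent ordered pairs of `B`. Identical profiles score 1,
#' disjoint family sets score 0. Profiles must be built with the same
#' window.
#'
#' @param profileA,profileB [neighborhood_profile()] results (or tibbles
#'   with a `family` column in neighbourhood order).
#' @return Synteny score in `[0, 1]` (`NA` with a warning for empty
#'   profiles).
#' @export
neighborhood_synteny <- function(profileA, profileB) {
  wA <- attr(profileA, "window_bp"); wB <- attr(profileB, "window_bp")
  if (!is.null(wA) && !is.null(wB) && wA != wB) {
    abort("profiles built with different windows")
  }
  famA <- profileA$family
  famB <- profileB$family
  if (length(famA) == 0 || length(famB) == 0) {
    warn("empty neighbourhood profile: synteny undefined")
    return(NA_real_)
  }
  setA <- unique(famA); setB <- unique(famB)
  J <- length(intersect(setA, setB)) / length(union(setA, setB))
  shared <- intersect(setA, setB)
  if (length(shared) == 0) return(0)
  a <- famA[famA %in% shared]
  b <- famB[famB %in% shared]
  adj_pairs <- function(v) {
    if (length(v) < 2) return(character(0))
    paste(v[-length(v)], v[-1], sep = "\r")
  }
  pa <- adj_pairs(a)
  if (length(pa) == 0) {
    adj <- 1  # a single shared family has no order to violate
  } else {
    adj <- mean(pa %in% adj_pairs(b))
  }
  J / 2 + adj / 2
}
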