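# Protein-variant identity analysis and subtype clustering, plus MSA
# trimming. Pairwise identity uses mutually ungapped columns as the
# denominator, so fragments are not penalised for missing termini.

#' Trim columns from a protein MSA
#'
#' Removes a poorly aligned N-terminal block and/or an explicit 1-based
#' inclusive column range from every row.
#'
#' @param msa Named character vector of equal-length aligned rows (gap
#'   `-`).
#' @param drop_nterm_cols Number of leading columns to drop (default 30).
#' @param drop_range Length-2 1-based inclusive column range to drop
#'   (default `c(475, 549)`), or `NULL`.
#' @return The trimmed MSA (named character vector).
#' @export
trim_alignment <- function(msa, drop_nterm_cols = 30,
                           drop_range = c(475, 549)) {
  stopifnot(length(unique(nchar(msa))) == 1)
  width <- nchar(msa[[1]])
  drop <- integer(0)
  if (drop_nterm_cols > 0) {
    if (drop_nterm_cols > width) abort("N-terminal drop exceeds alignment width")
    drop <- seq_len(drop_nterm_cols)
  }
  if (!is.null(drop_range) && length(drop_range) == 2) {
    if (drop_range[1] > drop_range[2]) abort("invalid drop range (start > end)")
    if (drop_range[2] > width) abort("drop range beyond alignment width")
    rng <- seq.int(drop_range[1], drop_range[2])
    if (length(intersect(rng, drop)) > 0) abort("overlapping drop ranges")
    drop <- c(drop, rng)
  }
  if (length(drop) == 0) return(msa)
  keep <- setdiff(seq_len(width), drop)
  vapply(msa, function(row) {
    paste(strsplit(row, "")[[1]][keep], collapse = "")
  }, character(1))
}

#' Pairwise percent-identity matrix of an MSA
#'
#' `identity(i, j) = 100 * identical residues / columns ungapped in both
#' rows`; columns gapped in either row are excluded from numerator and
#' denominator. Pairs with no mutually ungapped columns get `NA`.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @return Symmetric numeric matrix (diagonal 100) with row/column names,
#'   of class `"identity_matrix"`.
#' @export
identity_matrix <- function(msa) {
  if (length(msa) < 2) abort("need at least 2 rows")
  stopifnot(length(unique(nchar(msa))) == 1)
  chars <- do.call(rbind, strsplit(unname(msa), ""))
  ungapped <- chars != "-"
  n <- length(msa)
  m <- matrix(100, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ungapped[i, ] & ungapped[j, ]
      m[i, j] <- m[j, i] <- if (!any(both)) NA_real_ else
        100 * sum(chars[i, both] == chars[j, both]) / sum(both)
    }
  }
  structure(m, class = c("identity_matrix", "matrix", "array"))
}

#' @export
#' @exportS3Method generics::tidy
tidy.identity_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "identity",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(id1 = "Var1", id2 = "Var2")
}

#' Cluster protein variants into subtypes by identity
#'
#' Single-linkage clustering of the identity matrix: two variants share a
#' subtype iff they are connected by a chain of pairs with identity at or
#' above `threshold`. Subtypes are numbered by decreasing size (ties by
#' first appearance in the input); variants are numbered within each
#' subtype by input order, producing `"subtype.variant"` labels such as
#' `"1.1"`.
#'
#' @param identity_matrix An [identity_matrix()] (no `NA` entries among the
#'   clustered ids).
#' @param threshold Percent-identity threshold (default 85).
#' @return A tibble with `id`, `subtype`, `variant`, `label`.
#' @export
cluster_subtypes <- function(identity_matrix, threshold = 85) {
  m <- unclass(identity_matrix)
  if (anyNA(m)) abort("identity matrix has undefined entries")
  n <- nrow(m)
  ids <- rownames(m)
  cl <- if (n == 1) 1L else {
    d <- stats::as.dist(100 - m)
    hc <- stats::hclust(d, method = "single")
    # single linkage merges exactly the chains of pairs with distance
    # <= h, i.e. identity >= threshold
    stats::cutree(hc, h = 100 - threshold)
  }
  sizes <- table(cl)
  first_seen <- vapply(names(sizes), function(k) min(which(cl == as.integer(k))),
                       integer(1))
  rank <- order(-as.integer(sizes), first_seen)
  subtype <- match(as.character(cl), names(sizes)[rank])
  variant <- stats::ave(seq_len(n), subtype, FUN = seq_along)
  tibble(id = ids, subtype = subtype, variant = variant,
         label = paste(subtype, variant, sep = "."))
}
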