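# Pairwise Nei-Gojobori (1986) dN/dS on protein-guided codon alignments.
#
# Sites: each sense codon contributes s = sum over its three positions of
# the synonymous fraction among single-base changes (changes to stop codons
# excluded, reducing that position's denominator) and n = 3 - s.
# Differences: codons differing at k positions are resolved by averaging
# the synonymous/nonsynonymous step counts over all k! mutational pathways
# with equal weight; pathways passing through a stop codon are excluded and
# the weights renormalised. Proportions are Jukes-Cantor corrected:
# d = -(3/4) log(1 - (4/3) p).

genetic_code <- function(code = "standard") {
  if (!identical(code, "standard")) {
    gc <- Biostrings::getGeneticCode(code)
  } else {
    gc <- Biostrings::GENETIC_CODE
  }
  gc
}

is_sense <- function(codon, gc) {
  !is.na(gc[codon]) & gc[codon] != "*"
}

#' Translate a CDS under a genetic code
#'
#' @param cds Nucleotide string with length divisible by 3.
#' @param code Genetic code id (`"standard"` or a Biostrings code name).
#' @return Amino-acid string; stop codons translate to `*`.
#' @export
translate_cds <- function(cds, code = "standard") {
  gc <- genetic_code(code)
  if (nchar(cds) %% 3 != 0) abort("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- gc[codons]
  if (anyNA(aa)) {
    abort(sprintf("untranslatable codon(s): %s",
                  paste(unique(codons[is.na(aa)]), collapse = ", ")))
  }
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Maps each aligned amino-acid column of `protein_msa` onto its source
#' codon from `cds_set`; protein gaps become the gap codon `"---"`. A
#' terminal stop codon on a CDS is tolerated and stripped. The translated
#' CDS must equal the ungapped protein row exactly.
#'
#' @param protein_msa Named character vector of aligned protein rows (equal
#'   lengths, gap `-`).
#' @param cds_set Named character vector of unaligned CDS, ids matching the
#'   MSA.
#' @param code Genetic code id.
#' @return Object of class `"codon_alignment"`: named character vector of
#'   aligned codon rows with attribute `code`.
#' @export
backtranslate <- function(protein_msa, cds_set, code = "standard") {
  stopifnot(length(unique(nchar(protein_msa))) == 1)
  rows <- purrr::imap_chr(protein_msa, function(prow, id) {
    if (!id %in% names(cds_set)) abort(sprintf("no CDS for id '%s'", id))
    cds <- cds_set[[id]]
    if (nchar(cds) %% 3 != 0) {
      abort(sprintf("CDS length of '%s' not divisible by 3", id))
    }
    aa <- translate_cds(cds, code)
    if (endsWith(aa, "*")) {  # strip terminal stop
      aa <- substr(aa, 1, nchar(aa) - 1)
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    ungapped <- gsub("-", "", prow, fixed = TRUE)
    if (nchar(aa) != nchar(ungapped)) {
      abort(sprintf("CDS of '%s' translates to %d aa but protein row has %d",
                    id, nchar(aa), nchar(ungapped)))
    }
    mism <- which(strsplit(aa, "")[[1]] != strsplit(ungapped, "")[[1]])
    if (length(mism) > 0) {
      abort(sprintf("translation mismatch for '%s' at protein position %d",
                    id, mism[1]))
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- character(nchar(prow))
    pchars <- strsplit(prow, "")[[1]]
    out[pchars == "-"] <- "---"
    out[pchars != "-"] <- codons
    paste(out, collapse = "")
  })
  structure(rows, code = code, class = "codon_alignment")
}

#' Synonymous/nonsynonymous site fractions of one codon
#'
#' Enumerates the nine single-base changes of a sense codon; changes to
#' stop codons are excluded and that position's denominator reduced. The
#' synonymous site count is `s = sum over positions of (synonymous
#' changes / non-stop changes)` and `n = 3 - s`.
#'
#' @param codon Sense codon (3 letters over ACGT).
#' @param code Genetic code id.
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
codon_site_counts <- function(codon, code = "standard") {
  gc <- genetic_code(code)
  if (is.na(gc[codon]) || gc[codon] == "*") {
    abort(sprintf("'%s' is not a sense codon", codon))
  }
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      alt_aa <- gc[[alt]]
      if (alt_aa == "*") next
      nonstop <- nonstop + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# Average (Sd, Nd) over equally weighted mutational pathways between two
# sense codons; pathways crossing a stop codon are dropped (renormalised).
# Returns NULL when every pathway crosses a stop.
pathway_counts <- function(c1, c2, gc) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diff_pos) else {
    if (k == 2) {
      list(diff_pos, rev(diff_pos))
    } else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) diff_pos[o])
    }
  }
  tallies <- purrr::map(perms, function(order) {
    cur <- c1
    sd <- 0L; nd <- 0L
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  })
  tallies <- purrr::compact(tallies)
  if (length(tallies) == 0) return(NULL)
  Reduce(`+`, tallies) / length(tallies)
}

#' Pairwise NG86 dN/dS for two rows of a codon alignment
#'
#' Compares only columns where both codons are ungapped sense codons. Site
#' counts `S`, `N` are averaged over the two sequences; difference counts
#' `Sd`, `Nd` are pathway-averaged per column (see [codon_site_counts()]
#' and the module notes). `pS = Sd/S`, `pN = Nd/N`, and `dS`, `dN` are the
#' Jukes-Cantor corrections. The `status` field applies the reporting
#' filters: `"undefined_pS0"` when `pS = 0`, `"saturated"` when
#' `(4/3) p >= 1` for either proportion, `"filtered_dN0_or_dS0"` when
#' `dN = 0` or `dS = 0`, else `"ok"`; `omega` is reported only for
#' `"ok"` pairs.
#'
#' @param row1,row2 Equal-length codon-alignment rows (strings, length
#'   divisible by 3, gap codon `"---"`).
#' @param code Genetic code id.
#' @param id1,id2 Optional sequence labels carried into the result.
#' @return One-row tibble: `id1`, `id2`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega`, `status`, `n_codons` (compared columns).
#' @export
ng86_pair <- function(row1, row2, code = "standard",
                      id1 = "seq1", id2 = "seq2") {
  if (nchar(row1) != nchar(row2)) abort("rows differ in length")
  if (nchar(row1) %% 3 != 0) abort("row length not divisible by 3")
  gc <- genetic_code(code)
  starts <- seq(1, nchar(row1), 3)
  cods1 <- substring(row1, starts, starts + 2)
  cods2 <- substring(row2, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", cods1) & grepl("^[ACGT]{3}$", cods2)
  comparable <- clean & is_sense(cods1, gc) & is_sense(cods2, gc)
  # site fractions computed once per distinct codon in the pair
  uniq <- unique(c(cods1[comparable], cods2[comparable]))
  site_tab <- vapply(uniq, function(cod) codon_site_counts(cod, code)[["s"]],
                     numeric(1))
  # pathway-averaged differences once per distinct codon pair; NULL entries
  # mark columns where every pathway crosses a stop (column skipped)
  idx <- which(comparable & cods1 != cods2)
  keys <- paste(cods1[idx], cods2[idx])
  path_tab <- lapply(setNames(unique(keys), unique(keys)), function(k) {
    cc <- strsplit(k, " ")[[1]]
    pathway_counts(cc[1], cc[2], gc)
  })
  skipped <- idx[vapply(keys, function(k) is.null(path_tab[[k]]), logical(1))]
  usable <- setdiff(which(comparable), skipped)
  used <- length(usable)
  if (used == 0L) abort("empty comparable region")
  s_cols <- (site_tab[cods1[usable]] + site_tab[cods2[usable]]) / 2
  S <- sum(s_cols)
  N <- 3 * used - S
  diffs <- lapply(keys[!idx %in% skipped], function(k) path_tab[[k]])
  Sd <- sum(vapply(diffs, `[[`, numeric(1), "sd"))
  Nd <- sum(vapply(diffs, `[[`, numeric(1), "nd"))
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if ((4 / 3) * p >= 1) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  dS <- jc(pS); dN <- jc(pN)
  status <- if (pS == 0) {
    "undefined_pS0"
  } else if (is.na(dS) || is.na(dN)) {
    "saturated"
  } else if (dN == 0 || dS == 0) {
    "filtered_dN0_or_dS0"
  } else "ok"
  omega <- if (status == "ok") dN / dS else NA_real_
  tibble(id1 = id1, id2 = id2, S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
         status = status, n_codons = used)
}

#' All pairwise NG86 comparisons of a codon alignment
#'
#' Computes [ng86_pair()] for every unordered pair of rows. The retained
#' omega set excludes every status other than `"ok"`, reproducing the
#' reporting convention of discarding undefined (`pS = 0`) pairs and pairs
#' with `dN = 0` or `dS = 0`.
#'
#' @param codon_alignment A [backtranslate()] result, or a named character
#'   vector of codon rows.
#' @param label Group label carried into the result (e.g. gene name).
#' @param code Genetic code id (defaults to the alignment's own).
#' @return Object of class `"dnds_matrix"`: tibble of all pairs (class
#'   keeps the `label`); `tidy()` returns the pair table, `glance()` the
#'   retained-omega summary, `retained_omegas()` the filtered vector.
#' @export
pairwise_matrix <- function(codon_alignment, label = "gene",
                            code = NULL) {
  code <- code %||% attr(codon_alignment, "code") %||% "standard"
  rows <- unclass(codon_alignment)
  attr(rows, "code") <- NULL
  if (length(rows) < 2) abort("need at least 2 rows")
  ids <- names(rows)
  pairs <- utils::combn(length(rows), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ng86_pair(rows[[i]], rows[[j]], code = code, id1 = ids[i], id2 = ids[j])
  })
  out$label <- label
  structure(out, class = c("dnds_matrix", class(out)))
}

#' @export
#' @exportS3Method generics::tidy
tidy.dnds_matrix <- function(x, ...) as_tibble(unclass(x))

#' Retained omega values of a dN/dS pair table
#'
#' @param x A `dnds_matrix`.
#' @return Numeric vector of `omega` for pairs with status `"ok"`.
#' @export
retained_omegas <- function(x) {
  x$omega[x$status == "ok"]
}

#' @export
#' @exportS3Method generics::glance
glance.dnds_matrix <- function(x, ...) {
  om <- retained_omegas(x)
  tibble(label = x$label[1], n_pairs = nrow(x), n_retained = length(om),
         mean_omega = if (length(om)) mean(om) else NA_real_,
         median_omega = if (length(om)) stats::median(om) else NA_real_)
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.dnds_matrix <- function(object, ...) {
  df <- tibble(omega = retained_omegas(object), label = object$label[1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$omega)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(d[N] / d[S])) +
    ggplot2::theme_minimal()
}
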