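# Synthetic-data generators. Each generator is a pure function of its
# arguments including the seed, and returns machine-readable ground truth
# alongside the data so pipeline tests can be scored against it.

#' Simulate a genome with compositionally distinct islands
#'
#' Background bases are drawn i.i.d. from `background_freqs`; each island
#' interval is overwritten with i.i.d. draws from its own composition
#' (sharp boundaries, emulating an integrated element such as a prophage).
#'
#' @param length Genome length in bp.
#' @param background_freqs Probability vector over `A,C,G,T`.
#' @param islands List of islands, each a list with `start`, `end`
#'   (0-based half-open) and `freqs` (probability vector over `A,C,G,T`).
#'   Islands must be disjoint and within bounds.
#' @param seed Integer seed.
#' @param id Genome id.
#' @return List with `genome` (named character vector of one sequence) and
#'   `truth` (tibble of island intervals and their compositions, plus the
#'   background as attribute `background_freqs`).
#' @export
sim_genome_with_islands <- function(length, background_freqs, islands = list(),
                                    seed, id = "synthetic_genome") {
  stopifnot(length >= 1, abs(sum(background_freqs) - 1) < 1e-8)
  bases <- c("A", "C", "G", "T")
  if (length(islands) > 0) {
    iv <- purrr::map_dfr(islands, function(isl) {
      tibble(start = isl$start, end = isl$end)
    })
    if (any(iv$start < 0 | iv$end > length | iv$start >= iv$end)) {
      abort("island out of bounds")
    }
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort("overlapping islands")
    }
  }
  seq <- withr::with_seed(seed, {
    s <- sample(bases, length, replace = TRUE, prob = background_freqs)
    for (isl in islands) {
      n <- isl$end - isl$start
      s[(isl$start + 1):isl$end] <- sample(bases, n, replace = TRUE,
                                           prob = isl$freqs)
    }
    s
  })
  truth <- purrr::map_dfr(islands, function(isl) {
    tibble(start = isl$start, end = isl$end,
           freq_A = isl$freqs[1], freq_C = isl$freqs[2],
           freq_G = isl$freqs[3], freq_T = isl$freqs[4])
  })
  attr(truth, "background_freqs") <- background_freqs
  list(genome = setNames(paste(seq, collapse = ""), id), truth = truth)
}

# --- codon-pair simulation ---------------------------------------------------

# Rate graph over the 61 sense codons: single-base changes only, weight
# kappa for transitions, omega for nonsynonymous changes, stop codons
# disallowed. Rates are normalised so that the expected number of
# substitutions per codon site equals 1 per unit time for a uniform
# stationary start (neutral baseline omega = kappa = 1).
codon_rate_graph <- function(omega, kappa, code = "standard") {
  gc <- genetic_code(code)
  sense <- names(gc)[gc != "*"]
  gc_named <- gc
  is_transition <- function(b1, b2) {
    (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
      (b1 %in% c("C", "T") && b2 %in% c("C", "T"))
  }
  edges <- purrr::map(sense, function(cod) {
    to <- character(0); w <- numeric(0)
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (gc_named[[alt]] == "*") next
        wt <- 1
        if (is_transition(substr(cod, pos, pos), b)) wt <- wt * kappa
        if (gc_named[[alt]] != gc_named[[cod]]) wt <- wt * omega
        to <- c(to, alt); w <- c(w, wt)
      }
    }
    syn <- gc_named[to] == gc_named[[cod]]
    list(to = to, w = w, syn = unname(syn))
  })
  names(edges) <- sense
  # neutral normalisation: mean total neutral leaving weight per codon
  neutral <- codon_neutral_rate_scale(code)
  for (i in seq_along(edges)) edges[[i]]$w <- edges[[i]]$w / neutral
  edges
}

codon_neutral_rate_scale <- function(code = "standard") {
  gc <- genetic_code(code)
  sense <- names(gc)[gc != "*"]
  tot <- vapply(sense, function(cod) {
    cnt <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (gc[[alt]] != "*") cnt <- cnt + 1
      }
    }
    cnt
  }, numeric(1))
  mean(tot)
}

#' Simulate a diverged codon-sequence pair at a known omega
#'
#' Draws an ancestor uniformly over sense codons and evolves two lineages
#' for `t/2` each under a continuous-time process on codons in which
#' single-base changes carry weight `kappa` when they are transitions and
#' `omega` when they are nonsynonymous; multi-base instantaneous changes
#' and stop codons are disallowed. Substitutions are simulated event by
#' event and every event's class is recorded. The process is scaled so
#' that `t` is the expected number of substitutions per codon site along
#' the whole pair path at `omega = kappa = 1`.
#'
#' @param L Number of codons.
#' @param t Divergence (expected substitutions per codon site along the
#'   pair path, neutral scaling).
#' @param omega dN/dS of the generating process.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @param code Genetic code id.
#' @return List with `cds1`, `cds2` (codon strings), `ancestor`, and
#'   `truth`: tibble of realised substitutions (`lineage`, `site`, `from`,
#'   `to`, `synonymous`).
#' @export
sim_codon_pair <- function(L, t, omega, kappa = 1, seed, code = "standard") {
  stopifnot(L >= 1, t >= 0, omega >= 0, kappa > 0)
  graph <- codon_rate_graph(omega, kappa, code)
  sense <- names(graph)
  withr::with_seed(seed, {
    anc <- sample(sense, L, replace = TRUE)
    events <- list()
    evolve <- function(codons, lineage, duration) {
      for (site in seq_len(L)) {
        time <- 0
        repeat {
          g <- graph[[codons[site]]]
          rate <- sum(g$w)
          if (rate == 0) break
          time <- time + rexp(1, rate)
          if (time > duration) break
          k <- sample.int(length(g$to), 1, prob = g$w)
          events[[length(events) + 1L]] <<- tibble(
            lineage = lineage, site = site,
            from = codons[site], to = g$to[k], synonymous = g$syn[k])
          codons[site] <- g$to[k]
        }
      }
      codons
    }
    c1 <- evolve(anc, 1L, t / 2)
    c2 <- evolve(anc, 2L, t / 2)
    truth <- if (length(events)) dplyr::bind_rows(events) else
      tibble(lineage = integer(0), site = integer(0), from = character(0),
             to = character(0), synonymous = logical(0))
    list(cds1 = paste(c1, collapse = ""), cds2 = paste(c2, collapse = ""),
         ancestor = paste(anc, collapse = ""), truth = truth)
  })
}

#' Simulate a Yule (pure-birth) tree
#'
#' Standard forward construction: starting from two lineages, while `k`
#' lineages are active the next split waits an `Exp(k * birth_rate)` time
#' and splits a uniformly chosen lineage; after the n-th lineage appears a
#' final `Exp(n * birth_rate)` period elapses. Expected root depth is
#' `sum_{k=2..n} 1/(k * birth_rate)`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] with tip labels `t1..tn`.
#' @export
sim_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  withr::with_seed(seed, {
    root <- n_tips + 1L
    next_internal <- root + 1L
    # active lineages: open edges hanging from `parent` since `start`
    active <- data.frame(parent = c(root, root), start = c(0, 0))
    edge_par <- integer(0); edge_chi <- integer(0); edge_len <- numeric(0)
    now <- 0
    while (nrow(active) < n_tips) {
      k <- nrow(active)
      now <- now + rexp(1, k * birth_rate)
      i <- sample.int(k, 1)
      u <- next_internal
      next_internal <- next_internal + 1L
      edge_par <- c(edge_par, active$parent[i])
      edge_chi <- c(edge_chi, u)
      edge_len <- c(edge_len, now - active$start[i])
      active <- rbind(active[-i, , drop = FALSE],
                      data.frame(parent = c(u, u), start = c(now, now)))
    }
    t_end <- now + rexp(1, n_tips * birth_rate)
    for (j in seq_len(n_tips)) {
      edge_par <- c(edge_par, active$parent[j])
      edge_chi <- c(edge_chi, j)
      edge_len <- c(edge_len, t_end - active$start[j])
    }
    tr <- structure(
      list(edge = cbind(edge_par, edge_chi, deparse.level = 0),
           edge.length = edge_len,
           tip.label = paste0("t", seq_len(n_tips)),
           Nnode = n_tips - 1L),
      class = "phylo", order = NULL)
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Simulate a binary trait along a tree
#'
#' Evolves a two-state trait edge by edge under the Mk process with gain
#' rate `q01` and loss rate `q10`, drawing exponential waiting times and
#' recording every state flip.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param q01,q10 Gain (0 to 1) and loss (1 to 0) rates, per unit branch
#'   length.
#' @param root_state State at the root (0 or 1).
#' @param seed Integer seed.
#' @return List with `traits` (named 0/1 vector over tips), `node_states`
#'   (states at every node, ape numbering) and `events` tibble (`parent`,
#'   `child`, `time_on_edge`, `from`, `to`).
#' @export
sim_trait_on_tree <- function(tree, q01, q10, root_state = 0, seed) {
  stopifnot(q01 >= 0, q10 >= 0, root_state %in% c(0, 1))
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    states <- integer(ntip + tree$Nnode)
    states[ntip + 1L] <- as.integer(root_state)
    events <- list()
    eo <- reorder(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
      len <- eo$edge.length[k]
      s <- states[par]
      time <- 0
      repeat {
        rate <- if (s == 0L) q01 else q10
        if (rate == 0) break
        time <- time + rexp(1, rate)
        if (time > len) break
        events[[length(events) + 1L]] <- tibble(
          parent = par, child = chi, time_on_edge = time,
          from = s, to = 1L - s)
        s <- 1L - s
      }
      states[chi] <- s
    }
    events <- if (length(events)) dplyr::bind_rows(events) else
      tibble(parent = integer(0), child = integer(0),
             time_on_edge = numeric(0), from = integer(0), to = integer(0))
    list(traits = setNames(states[seq_len(ntip)], tree$tip.label),
         node_states = states, events = events)
  })
}

#' Engineer a lateral transfer by regrafting a tip
#'
#' Prunes `recipient_tip` and regrafts it as sister to `donor_tip`,
#' attaching at the midpoint of the donor's pendant edge (the recipient's
#' new pendant edge gets the same half-length). All other relationships
#' are preserved.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param donor_tip,recipient_tip Distinct tip labels.
#' @return The modified tree.
#' @export
apply_transfer <- function(tree, donor_tip, recipient_tip) {
  if (donor_tip == recipient_tip) abort("donor and recipient must differ")
  stopifnot(donor_tip %in% tree$tip.label, recipient_tip %in% tree$tip.label)
  pruned <- ape::drop.tip(tree, recipient_tip)
  d <- which(pruned$tip.label == donor_tip)
  half <- pruned$edge.length[pruned$edge[, 2] == d] / 2
  phytools::bind.tip(pruned, recipient_tip, edge.length = half,
                     where = d, position = half)
}

#' Simulate protein variant sets with controlled identity structure
#'
#' Builds `n_subtypes` subtype ancestors by mutating a random base protein
#' and, within each subtype, `variants_per_subtype` variants by mutating
#' the ancestor, with mutation loads chosen so that pairwise identities
#' hit `within_identity` inside a subtype and `between_identity` across
#' subtypes (at the variant level), each within a few points. Mutated
#' positions are disjoint within a subtype, making within-subtype
#' identities exact.
#'
#' @param base_length Protein length (residues).
#' @param n_subtypes Number of subtypes.
#' @param variants_per_subtype Variants per subtype.
#' @param within_identity,between_identity Percent-identity targets with
#'   `0 <= between < within <= 100`.
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector, ids
#'   `s<subtype>v<variant>`) and `truth` tibble (`id`, `subtype`,
#'   `variant`).
#' @export
sim_variant_proteins <- function(base_length, n_subtypes, variants_per_subtype,
                                 within_identity, between_identity, seed) {
  stopifnot(between_identity >= 0, within_identity <= 100,
            between_identity < within_identity)
  w <- within_identity / 100
  b <- between_identity / 100
  # within-subtype pairs: both variants carry m_w disjoint mutations
  m_w <- round(base_length * (1 - w) / 2)
  if (m_w * variants_per_subtype > base_length) {
    abort("infeasible identity combination: too many within-subtype mutations")
  }
  # between-subtype variant pairs compound ancestor and variant mutations;
  # aim ancestor-level identity at b / w so the variant level lands on b
  anc_ident <- min(1, b / w)
  m_b <- round(base_length * (1 - sqrt(anc_ident)))
  if (m_b > base_length) abort("infeasible identity combination")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    base <- sample(aa, base_length, replace = TRUE)
    mutate_at <- function(seqv, pos) {
      for (p in pos) seqv[p] <- sample(setdiff(aa, seqv[p]), 1)
      seqv
    }
    proteins <- character(0)
    truth <- list()
    for (s in seq_len(n_subtypes)) {
      anc <- mutate_at(base, sample.int(base_length, m_b))
      var_pos <- if (m_w > 0) {
        split(sample.int(base_length, m_w * variants_per_subtype),
              rep(seq_len(variants_per_subtype), each = m_w))
      } else rep(list(integer(0)), variants_per_subtype)
      for (v in seq_len(variants_per_subtype)) {
        id <- sprintf("s%dv%d", s, v)
        proteins[id] <- paste(mutate_at(anc, var_pos[[v]]), collapse = "")
        truth[[length(truth) + 1L]] <- tibble(id = id, subtype = s,
                                              variant = v)
      }
    }
    list(proteins = proteins, truth = dplyr::bind_rows(truth))
  })
}
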