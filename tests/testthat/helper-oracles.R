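# Independent brute-force oracles. These deliberately recompute everything
# from scratch (re-scanning counts, enumerating pathways or state
# assignments) rather than sharing code paths with the package.

# --- segmentation oracle -----------------------------------------------------

# Quadratic divergence recomputed from raw substring scans.
oracle_delta <- function(seq_chars, s, e, i) {
  count4 <- function(v) {
    c(sum(v == "A"), sum(v == "C"), sum(v == "G"), sum(v == "T"))
  }
  left <- count4(seq_chars[(s + 1):i])
  right <- count4(seq_chars[(i + 1):e])
  nl <- sum(left); nr <- sum(right)
  if (nl == 0 || nr == 0) return(NA_real_)
  pl <- left / nl; pr <- right / nr
  n <- nl + nr
  a <- nl / n
  pooled <- a * pl + (1 - a) * pr
  n * (a * sum(pl^2) + (1 - a) * sum(pr^2) - sum(pooled^2))
}

# Recursive brute-force segmentation that re-scans counts at every
# candidate split.
oracle_segmentation <- function(sequence, t0, min_len) {
  seq_chars <- strsplit(sequence, "")[[1]]
  recurse <- function(s, e) {
    if (e - s < 2 * min_len) return(integer(0))
    cand <- seq.int(s + min_len, e - min_len)
    delta <- vapply(cand, function(i) oracle_delta(seq_chars, s, e, i),
                    numeric(1))
    if (all(is.na(delta))) return(integer(0))
    best <- which.max(delta)
    if (is.na(delta[best]) || delta[best] < t0) return(integer(0))
    bp <- cand[best]
    c(recurse(s, bp), bp, recurse(bp, e))
  }
  recurse(0L, nchar(sequence))
}

# --- NG86 oracle -------------------------------------------------------------

oracle_code <- Biostrings::GENETIC_CODE

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_codon_sites <- function(codon) {
  aa <- oracle_code[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- character(0)
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (oracle_code[[alt]] != "*") alts <- c(alts, alt)
    }
    if (length(alts) > 0) {
      s <- s + mean(vapply(alts, function(a) oracle_code[[a]] == aa, logical(1)))
    }
  }
  c(s = s, n = 3 - s)
}

oracle_pathways <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  acc <- list()
  for (ord in oracle_permutations(dpos)) {
    cur <- c1; sd <- 0; nd <- 0; dead <- FALSE
    for (pos in ord) {
      nxt <- paste0(substr(cur, 1, pos - 1), substr(c2, pos, pos),
                    substr(cur, pos + 1, 3))
      if (oracle_code[[nxt]] == "*") { dead <- TRUE; break }
      if (oracle_code[[nxt]] == oracle_code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!dead) acc[[length(acc) + 1]] <- c(sd = sd, nd = nd)
  }
  if (length(acc) == 0) return(NULL)
  Reduce(`+`, acc) / length(acc)
}

oracle_ng86 <- function(row1, row2) {
  starts <- seq(1, nchar(row1), 3)
  c1 <- substring(row1, starts, starts + 2)
  c2 <- substring(row2, starts, starts + 2)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(c1)) {
    ok1 <- grepl("^[ACGT]{3}$", c1[i]) && oracle_code[[c1[i]]] != "*"
    ok2 <- grepl("^[ACGT]{3}$", c2[i]) && oracle_code[[c2[i]]] != "*"
    if (!ok1 || !ok2) next
    pw <- oracle_pathways(c1[i], c2[i])
    if (is.null(pw)) next
    s1 <- oracle_codon_sites(c1[i]); s2 <- oracle_codon_sites(c2[i])
    S <- S + (s1[["s"]] + s2[["s"]]) / 2
    N <- N + (s1[["n"]] + s2[["n"]]) / 2
    Sd <- Sd + pw[["sd"]]; Nd <- Nd + pw[["nd"]]
    used <- used + 1
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = used)
}

# random codon row of L sense codons
random_codon_row <- function(L, pool = NULL) {
  if (is.null(pool)) pool <- names(oracle_code)[oracle_code != "*"]
  paste(sample(pool, L, replace = TRUE), collapse = "")
}

# random pair of similar codon rows: start from one row and mutate a few bases
random_codon_pair <- function(L, n_mut) {
  r1 <- random_codon_row(L)
  repeat {
    chars <- strsplit(r1, "")[[1]]
    pos <- sample(length(chars), min(n_mut, length(chars)))
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    r2 <- paste(chars, collapse = "")
    starts <- seq(1, nchar(r2), 3)
    cods <- substring(r2, starts, starts + 2)
    if (all(oracle_code[cods] != "*")) return(c(r1, r2))
  }
}

# --- Mk likelihood oracle ----------------------------------------------------

oracle_pmat <- function(t, q01, q10) {
  q <- q01 + q10
  if (q == 0) return(diag(2))
  e <- exp(-q * t)
  rbind(c((q10 + q01 * e) / q, (q01 - q01 * e) / q),
        c((q10 - q10 * e) / q, (q01 + q10 * e) / q))
}

# Likelihood by exhaustive enumeration of internal-node state assignments.
oracle_mk_loglik <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internals <- (ntip + 1):(ntip + nnode)
  tipst <- states[tree$tip.label]
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  for (g in seq_len(nrow(grid))) {
    assign_state <- c(tipst, grid[g, ])
    lik <- prior[grid[g, 1] + 1]  # first internal is the root (ape numbering)
    for (k in seq_len(nrow(tree$edge))) {
      P <- oracle_pmat(tree$edge.length[k], q01, q10)
      lik <- lik * P[assign_state[tree$edge[k, 1]] + 1,
                     assign_state[tree$edge[k, 2]] + 1]
    }
    total <- total + lik
  }
  log(total)
}

# random rooted binary tree with branch lengths
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
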