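# ML ancestral-state reconstruction of a binary trait under the Mk model.
#
# Two-state continuous-time Markov chain with gain rate q01 and loss rate
# q10 (ER ties them). Transition probabilities over a branch of length t,
# with q = q01 + q10:
#   P(0->1) = q01/q (1 - e^{-qt}),  P(1->0) = q10/q (1 - e^{-qt}),
# diagonal entries as complements. The likelihood is computed by
# Felsenstein pruning; marginal node probabilities combine the downward
# partial likelihoods with an upward (re-rooting) pass.

mk_pmat <- function(t, q01, q10) {
  q <- q01 + q10
  if (q == 0) return(diag(2))
  e <- exp(-q * t)
  matrix(c(
    (q10 + q01 * e) / q, (q01 - q01 * e) / q,
    (q10 - q10 * e) / q, (q01 + q10 * e) / q
  ), nrow = 2, byrow = TRUE)
}

# Downward partial likelihoods; returns list(D = matrix, loglik).
mk_prune <- function(tree, states, q01, q10, prior) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  D <- matrix(0, nrow = ntip + nnode, ncol = 2)
  D[cbind(seq_len(ntip), states[tree$tip.label] + 1L)] <- 1
  D[(ntip + 1):(ntip + nnode), ] <- 1
  eo <- reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
    P <- mk_pmat(eo$edge.length[k], q01, q10)
    D[par, ] <- D[par, ] * as.vector(P %*% D[chi, ])
  }
  root <- ntip + 1L
  lik <- sum(prior * D[root, ])
  list(D = D, loglik = if (lik > 0) log(lik) else -Inf)
}

#' Maximum-likelihood ancestral-state reconstruction (2-state Mk)
#'
#' Fits the rate(s) of a two-state Markov model of trait gain/loss on a
#' rooted tree by bounded maximisation of the pruning likelihood, then
#' computes marginal presence probabilities at every internal node by the
#' standard re-rooting construction. The default (`model = "ER"`, equal
#' root prior) is the common one-rate Mk reconstruction; `"ARD"` frees the
#' gain and loss rates.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param traits Named 0/1 vector covering every tip (1 = present).
#' @param model `"ER"` (single rate) or `"ARD"` (gain rate `q01`, loss
#'   rate `q10`).
#' @param root_prior `"equal"` or `"stationary"`.
#' @param fixed_rates Optional: skip rate optimisation and evaluate at
#'   these rates (a single number for `"ER"`, or `c(q01 = , q10 = )` for
#'   `"ARD"`).
#' @return Object of class `"mk_asr"`: `marginals` tibble (`node`,
#'   `p_absent`, `p_present`; node numbers in ape convention, internal
#'   nodes only), `rates` (`q01`, `q10`), `loglik`, `labels` (max-marginal
#'   node labelling over all nodes, ties inheriting the parent's label),
#'   `gains`/`losses` (edge tibbles), `origin_node`, plus the inputs.
#'   `tidy()` returns the marginal table.
#' @export
mk_asr <- function(tree, traits, model = c("ER", "ARD"),
                   root_prior = c("equal", "stationary"),
                   fixed_rates = NULL) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (all(tree$edge.length == 0)) {
    abort("all branch lengths are zero: likelihood degenerate")
  }
  missing_tips <- setdiff(tree$tip.label, names(traits))
  if (length(missing_tips) > 0) {
    abort(sprintf("missing state(s) for tip(s): %s",
                  paste(missing_tips, collapse = ", ")))
  }
  states <- traits[tree$tip.label]
  if (any(!states %in% c(0, 1))) abort("states must be 0/1")

  prior_of <- function(q01, q10) {
    if (root_prior == "equal" || q01 + q10 == 0) c(0.5, 0.5)
    else c(q10, q01) / (q01 + q10)
  }
  lb <- log(1e-8); ub <- log(1e3)
  if (!is.null(fixed_rates)) {
    if (model == "ER") {
      q01 <- q10 <- fixed_rates[[1]]
    } else {
      q01 <- fixed_rates[["q01"]]; q10 <- fixed_rates[["q10"]]
    }
  } else if (model == "ER") {
    f <- function(lq) {
      q <- exp(lq)
      mk_prune(tree, states, q, q, prior_of(q, q))$loglik
    }
    opt <- optimize(f, interval = c(lb, ub), maximum = TRUE, tol = 1e-8)
    q01 <- q10 <- exp(opt$maximum)
  } else {
    f <- function(lq) {
      q <- exp(lq)
      -mk_prune(tree, states, q[1], q[2], prior_of(q[1], q[2]))$loglik
    }
    opt <- optim(c(log(0.1), log(0.1)), f, method = "L-BFGS-B",
                 lower = lb, upper = ub)
    q01 <- exp(opt$par[1]); q10 <- exp(opt$par[2])
  }
  prior <- prior_of(q01, q10)
  pr <- mk_prune(tree, states, q01, q10, prior)
  D <- pr$D

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # upward pass (preorder over edges)
  U <- matrix(NA_real_, nrow = ntip + nnode, ncol = 2)
  U[root, ] <- prior
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(k) mk_pmat(tree$edge.length[k], q01, q10))
  # downward message through each edge: M_k[s_par] = sum_s P_k[s_par,s] D[child,s]
  M <- t(vapply(seq_len(nrow(tree$edge)),
                function(k) as.vector(Pm[[k]] %*% D[tree$edge[k, 2], ]),
                numeric(2)))
  eo <- reorder(tree, "cladewise")
  ord <- match(paste(eo$edge[, 1], eo$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in ord) {
    par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
    sib <- which(tree$edge[, 1] == par & tree$edge[, 2] != chi)
    above <- U[par, ]
    for (s in sib) above <- above * M[s, ]
    U[chi, ] <- as.vector(above %*% Pm[[k]])
  }
  marg <- U * D
  marg <- marg / rowSums(marg)
  marginals <- tibble(node = (ntip + 1L):(ntip + nnode),
                      p_absent = marg[(ntip + 1L):(ntip + nnode), 1],
                      p_present = marg[(ntip + 1L):(ntip + nnode), 2])

  res <- structure(
    list(marginals = marginals, rates = c(q01 = q01, q10 = q10),
         loglik = pr$loglik, model = model, root_prior = root_prior,
         tree = tree, traits = states,
         p_present_all = c(as.numeric(states), marginals$p_present)),
    class = "mk_asr"
  )
  res$labels <- max_marginal_labels(res)
  trans <- count_transitions(res, tree)
  res$gains <- trans$gains
  res$losses <- trans$losses
  res$origin_node <- if (any(states == 1)) {
    # the fallback warning is for interactive origin_node() calls
    suppressWarnings(origin_node(res, tree))
  } else NA_integer_
  res
}

# Max-marginal state labelling of every node; ties inherit the parent's
# label (a root tie takes state 0). Tips keep their observed state.
max_marginal_labels <- function(asr) {
  tree <- asr$tree
  ntip <- length(tree$tip.label)
  lab <- integer(ntip + tree$Nnode)
  lab[seq_len(ntip)] <- asr$traits
  p <- asr$p_present_all
  root <- ntip + 1L
  lab[root] <- if (p[root] > 0.5) 1L else 0L
  eo <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    chi <- eo$edge[k, 2]
    if (chi <= ntip) next
    lab[chi] <- if (p[chi] > 0.5) 1L else if (p[chi] < 0.5) 0L else
      lab[eo$edge[k, 1]]
  }
  lab
}

#' @export
print.mk_asr <- function(x, ...) {
  cat(sprintf(
    "Mk ancestral-state reconstruction (%s, %s root prior)\n  q01 = %.4g, q10 = %.4g, logLik = %.4f\n  gains = %d, losses = %d, origin node = %s\n",
    x$model, x$root_prior, x$rates[["q01"]], x$rates[["q10"]], x$loglik,
    nrow(x$gains), nrow(x$losses),
    ifelse(is.na(x$origin_node), "none", x$origin_node)))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.mk_asr <- function(x, ...) x$marginals

#' @export
#' @exportS3Method generics::glance
glance.mk_asr <- function(x, ...) {
  tibble(model = x$model, q01 = x$rates[["q01"]], q10 = x$rates[["q10"]],
         loglik = x$loglik, n_gains = nrow(x$gains),
         n_losses = nrow(x$losses), origin_node = x$origin_node)
}

#' Count gain and loss edges of a reconstructed trait history
#'
#' Labels every node with its max-marginal state (ties inherit the parent's
#' label) and counts edges whose parent/child labels differ: `0 -> 1` is a
#' gain, `1 -> 0` a loss.
#'
#' @param asrresult A [mk_asr()] result.
#' @param tree The tree the reconstruction was computed on (defaults to the
#'   one stored in `asrresult`).
#' @return List with tibbles `gains` and `losses` (`parent`, `child` node
#'   numbers).
#' @export
count_transitions <- function(asrresult, tree = asrresult$tree) {
  lab <- max_marginal_labels(asrresult)
  par <- lab[tree$edge[, 1]]
  chi <- lab[tree$edge[, 2]]
  gains <- tree$edge[par == 0L & chi == 1L, , drop = FALSE]
  losses <- tree$edge[par == 1L & chi == 0L, , drop = FALSE]
  list(gains = tibble(parent = gains[, 1], child = gains[, 2]),
       losses = tibble(parent = losses[, 1], child = losses[, 2]))
}

# number of edges from the root for every node
node_depths_topo <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- integer(ntip + tree$Nnode)
  eo <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    depth[eo$edge[k, 2]] <- depth[eo$edge[k, 1]] + 1L
  }
  depth
}

# tip-descendant sets (by tip number) for every node
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  sets
}

#' Inferred origin node of a present trait
#'
#' The deepest node (closest to the root) whose marginal presence
#' probability reaches `threshold` and from which every present tip
#' descends. If no node qualifies, the MRCA of the present tips is
#' returned with a warning.
#'
#' @param asrresult A [mk_asr()] result.
#' @param tree Tree of the reconstruction.
#' @param threshold Marginal presence probability cutoff (default 0.5).
#' @return Node number (ape convention; may be a tip when a single tip is
#'   present).
#' @export
origin_node <- function(asrresult, tree = asrresult$tree, threshold = 0.5) {
  states <- asrresult$traits
  present <- which(states[tree$tip.label] == 1)
  if (length(present) == 0) abort("no present tips")
  p <- asrresult$p_present_all
  sets <- node_tip_sets(tree)
  covers <- vapply(sets, function(s) all(present %in% s), logical(1))
  ok <- which(covers & p >= threshold)
  if (length(ok) == 0) {
    warn("no covering node reaches the marginal threshold; returning the MRCA of present tips")
    if (length(present) == 1) return(present)
    return(ape::getMRCA(tree, tree$tip.label[present]))
  }
  depth <- node_depths_topo(tree)
  ok[which.min(depth[ok])]
}
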