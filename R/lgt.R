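# Gene-tree / species-tree incongruence flagging of candidate transfers.
#
# For each tip, its "sister set" in a tree is the set of tip labels of its
# sibling subtree(s). A tip is *incongruent* when its sister set differs
# between the gene tree and the species tree (pruned to the shared tips).
# Raw sister-set incongruence implicates every tip touching an affected
# cherry (a regrafted recipient changes the sister sets of its donor and
# of its former sisters too), so the *flagged* call is refined to the
# minimal explanation: among incongruent tips, those whose single-tip
# removal restores full topological congruence. When no single tip
# explains the conflict, all incongruent tips stay flagged.

sister_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  out <- vector("list", ntip)
  names(out) <- tree$tip.label
  for (i in seq_len(ntip)) {
    par <- tree$edge[tree$edge[, 2] == i, 1]
    sibs <- tree$edge[tree$edge[, 1] == par & tree$edge[, 2] != i, 2]
    out[[i]] <- sort(tree$tip.label[unlist(sets[sibs])])
  }
  out
}

same_topology <- function(t1, t2) {
  isTRUE(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE))
}

#' Flag candidate lateral transfers by tree incongruence
#'
#' Compares, tip by tip, the sister set in the gene tree with the sister
#' set in the species tree restricted to the shared tips. `incongruent`
#' marks every tip whose sister sets differ; `flagged` refines this to
#' tips whose removal alone restores topological congruence (falling back
#' to all incongruent tips when no single tip explains the conflict). The
#' proposed donor lineage of a flagged tip is its gene-tree sister set.
#'
#' @param gene_tree,species_tree Rooted [ape::phylo] objects; gene-tree
#'   tips must be a subset of species-tree tips.
#' @return A tibble with columns `tip`, `incongruent`, `flagged`,
#'   `species_sisters`, `gene_sisters`, `proposed_donor` (list columns).
#' @export
lgt_flags <- function(gene_tree, species_tree) {
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) == 0) abort("empty tip intersection")
  extra <- setdiff(gene_tree$tip.label, species_tree$tip.label)
  if (length(extra) > 0) {
    abort(sprintf("gene-tree tip(s) not in species tree: %s",
                  paste(extra, collapse = ", ")))
  }
  sp <- if (length(shared) < length(species_tree$tip.label)) {
    ape::keep.tip(species_tree, shared)
  } else species_tree
  ss_sp <- sister_sets(sp)
  ss_gn <- sister_sets(gene_tree)
  tips <- gene_tree$tip.label
  incongruent <- vapply(tips, function(t) {
    !setequal(ss_sp[[t]], ss_gn[[t]])
  }, logical(1))
  flagged <- incongruent
  cands <- tips[incongruent]
  if (length(cands) > 0 && length(shared) > 3) {
    restores <- vapply(cands, function(t) {
      same_topology(ape::drop.tip(sp, t), ape::drop.tip(gene_tree, t))
    }, logical(1))
    if (any(restores)) {
      flagged <- tips %in% cands[restores]
      names(flagged) <- tips
    }
  }
  flag_vec <- unname(flagged[tips])
  donors <- purrr::map2(flag_vec, unname(ss_gn[tips]),
                        function(f, s) if (f) s else character(0))
  tibble(
    tip = tips,
    incongruent = unname(incongruent),
    flagged = flag_vec,
    species_sisters = unname(ss_sp[tips]),
    gene_sisters = unname(ss_gn[tips]),
    proposed_donor = donors
  )
}
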