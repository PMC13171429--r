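# Fixture builders for integration tests: codon alignments evolved along a
# tree (reusing the package's codon rate graph) and a complete synthetic
# vertical-inheritance scenario.

sim_codon_msa <- function(tree, L, omega, kappa = 1, seed = 1) {
  graph <- vertitrace:::codon_rate_graph(omega, kappa)
  sense <- names(graph)
  withr::with_seed(seed, {
    ntip <- length(tree$tip.label)
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1]] <- sample(sense, L, replace = TRUE)
    eo <- reorder(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
      len <- eo$edge.length[k]
      codons <- seqs[[par]]
      for (site in seq_len(L)) {
        time <- 0
        repeat {
          g <- graph[[codons[site]]]
          rate <- sum(g$w)
          if (rate == 0) break
          time <- time + rexp(1, rate)
          if (time > len) break
          codons[site] <- g$to[sample.int(length(g$to), 1, prob = g$w)]
        }
      }
      seqs[[chi]] <- codons
    }
    out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    structure(setNames(out, tree$tip.label), code = "standard",
              class = "codon_alignment")
  })
}

# A complete no-transfer scenario: homogeneous genomes, a focal gene with
# genome-matched GC, conserved neighbourhoods, focal and core genes under
# comparable purifying selection, a single trait gain on the species tree
# and a congruent gene tree.
make_vertical_scenario <- function(seed = 101, n_tips = 16,
                                   with_transfer = FALSE) {
  sp <- sim_yule_tree(n_tips, 1, seed = seed)
  sp$edge.length <- sp$edge.length / max(ape::node.depth.edgelength(sp))

  # single-gain trait: all tips of one mid-sized clade are present
  sets <- vertitrace:::node_tip_sets(sp)
  ntip <- n_tips
  sizes <- lengths(sets)
  cand <- which(sizes >= 4 & sizes <= ntip / 2 & seq_along(sizes) > ntip)
  gain_node <- cand[which.max(sizes[cand])]
  present <- sp$tip.label[sets[[gain_node]]]
  traits <- setNames(as.integer(sp$tip.label %in% present), sp$tip.label)

  gene_tree <- ape::keep.tip(sp, present)
  recipient <- NULL
  if (with_transfer) {
    pair <- withr::with_seed(seed + 1, sample(present, 2))
    sis <- vertitrace:::sister_sets(gene_tree)
    # avoid the degenerate already-sisters case
    if (identical(sis[[pair[2]]], pair[1])) pair <- rev(pair)
    gene_tree <- apply_transfer(gene_tree, pair[1], pair[2])
    recipient <- pair[2]
  }

  # genomes: homogeneous high-GC background, focal gene sliced from genome
  bg <- c(0.14, 0.36, 0.36, 0.14)  # GC 0.72
  genomes <- character(0)
  loci <- list()
  nb <- list()
  fam_order <- c("f1", "f2", "tox", "f3", "f4")
  for (i in seq_along(present)) {
    gsim <- sim_genome_with_islands(30000, bg, seed = seed + 10 + i,
                                    id = present[i])
    genomes <- c(genomes, gsim$genome)
    strain_loci <- tibble::tibble(
      genome_id = present[i],
      gene_id = paste0(fam_order, "_", present[i]),
      start = as.integer(seq(8000, by = 2000, length.out = 5)),
      end = as.integer(seq(8000, by = 2000, length.out = 5) + 1500),
      strand = "+")
    loci[[i]] <- strain_loci
    fams <- setNames(fam_order, strain_loci$gene_id)
    nb[[present[i]]] <- neighborhood_profile(strain_loci,
                                             paste0("tox_", present[i]),
                                             fams, window_bp = 10000)
  }
  loci <- dplyr::bind_rows(loci)
  focal_loci <- loci[startsWith(loci$gene_id, "tox_"), ]

  focal_aln <- sim_codon_msa(gene_tree, 200, omega = 0.2, seed = seed + 2)
  core_alns <- lapply(1:3, function(k) {
    sim_codon_msa(sp, 150, omega = 0.2, seed = seed + 100 + k)
  })
  names(core_alns) <- paste0("core", 1:3)

  calibrations <- list(list(tips = sp$tip.label, age = 382, ci = c(250, 514)))

  list(
    species_tree = sp, gene_tree = gene_tree, traits = traits,
    present = present, gain_node = gain_node, recipient = recipient,
    genomes = genomes, loci = focal_loci, neighborhoods = nb,
    focal_codon_aln = focal_aln, core_codon_alns = core_alns,
    calibrations = calibrations,
    config = list(
      seed = seed,
      genomes = genomes, loci = focal_loci,
      focal_gene_id = focal_loci$gene_id[1],
      focal_codon_aln = focal_aln, core_codon_alns = core_alns,
      species_tree = sp, gene_tree = gene_tree, traits = traits,
      calibrations = calibrations, neighborhoods = nb
    )
  )
}
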