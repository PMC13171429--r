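test_that("island genomes honour composition, bounds and the seed", {
  g <- sim_genome_with_islands(2000, c(0.25, 0.25, 0.25, 0.25),
                               list(list(start = 500, end = 800,
                                         freqs = c(1, 0, 0, 0))), seed = 1)
  isl <- substr(g$genome[[1]], 501, 800)
  expect_identical(isl, strrep("A", 300))
  g2 <- sim_genome_with_islands(2000, c(0.25, 0.25, 0.25, 0.25),
                                list(list(start = 500, end = 800,
                                          freqs = c(1, 0, 0, 0))), seed = 1)
  expect_identical(g$genome, g2$genome)

  # realised background composition within a binomial tolerance
  g3 <- sim_genome_with_islands(50000, c(0.4, 0.1, 0.2, 0.3), seed = 2)
  b <- strsplit(g3$genome[[1]], "")[[1]]
  freq <- table(factor(b, c("A", "C", "G", "T"))) / 50000
  expect_equal(as.numeric(freq), c(0.4, 0.1, 0.2, 0.3), tolerance = 0.02)

  expect_error(sim_genome_with_islands(
    1000, rep(0.25, 4),
    list(list(start = 0, end = 600, freqs = rep(0.25, 4)),
         list(start = 500, end = 900, freqs = rep(0.25, 4))), seed = 1),
    "overlap")
})

test_that("codon-pair simulation respects omega, t and the seed", {
  cp0 <- sim_codon_pair(50, 0, 1, seed = 3)
  expect_identical(cp0$cds1, cp0$cds2)
  expect_equal(nrow(cp0$truth), 0)

  cp <- sim_codon_pair(100, 0.5, 0, seed = 4)
  expect_false(any(!cp$truth$synonymous))

  a <- sim_codon_pair(60, 0.3, 0.5, seed = 5)
  b <- sim_codon_pair(60, 0.3, 0.5, seed = 5)
  expect_identical(a$cds1, b$cds1)
  expect_identical(a$truth, b$truth)
})

test_that("realised substitution classes match the rate-graph expectation", {
  # expected syn fraction from summing rates over the codon graph at the
  # uniform ancestor distribution
  graph <- vertitrace:::codon_rate_graph(omega = 0.3, kappa = 2)
  syn_rate <- mean(vapply(graph, function(g) sum(g$w[g$syn]), numeric(1)))
  tot_rate <- mean(vapply(graph, function(g) sum(g$w), numeric(1)))
  expected <- syn_rate / tot_rate
  cp <- sim_codon_pair(8000, 0.5, 0.3, kappa = 2, seed = 6)
  realised <- mean(cp$truth$synonymous)
  expect_equal(realised, expected, tolerance = 0.05)
})

test_that("Yule trees have the right shape, depth and determinism", {
  t2 <- sim_yule_tree(2, 1, seed = 7)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(ape::is.rooted(t2))

  t1 <- sim_yule_tree(20, 1, seed = 8)
  t1b <- sim_yule_tree(20, 1, seed = 8)
  expect_identical(ape::write.tree(t1), ape::write.tree(t1b))
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))

  depths <- vapply(1:300, function(s) {
    tr <- sim_yule_tree(8, 2, seed = 10000 + s)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- sum(1 / (2 * (2:8)))
  expect_equal(mean(depths), expected, tolerance = 0.08)
})

test_that("trait simulation follows the two-state process", {
  tr <- sim_yule_tree(10, 1, seed = 9)
  s0 <- sim_trait_on_tree(tr, 0, 0, root_state = 1, seed = 10)
  expect_true(all(s0$traits == 1))
  expect_equal(nrow(s0$events), 0)

  s1 <- sim_trait_on_tree(tr, 0.5, 0.2, root_state = 0, seed = 11)
  s2 <- sim_trait_on_tree(tr, 0.5, 0.2, root_state = 0, seed = 11)
  expect_identical(s1$events, s2$events)

  # empirical flip fraction on fixed-length edges vs closed-form P(t)
  star <- ape::stree(2000, type = "star")
  star$edge.length <- rep(0.8, nrow(star$edge))
  sim <- sim_trait_on_tree(star, 0.4, 0.7, root_state = 0, seed = 12)
  p01 <- vertitrace:::mk_pmat(0.8, 0.4, 0.7)[1, 2]
  expect_equal(mean(sim$traits), p01, tolerance = 0.03)
})

test_that("tip regrafting preserves the tip set and sisters the recipient", {
  tr <- sim_yule_tree(12, 1, seed = 13)
  out <- apply_transfer(tr, "t3", "t9")
  expect_setequal(out$tip.label, tr$tip.label)
  # recipient is now sister to the donor
  ss <- vertitrace:::sister_sets(out)
  expect_identical(ss[["t9"]], "t3")
  expect_error(apply_transfer(tr, "t1", "t1"), "differ")

  # transferring a tip already sister to the donor keeps the topology
  cherry_parent <- vapply(tr$tip.label, function(t) {
    sibs <- vertitrace:::sister_sets(tr)[[t]]
    length(sibs) == 1
  }, logical(1))
  t_a <- names(cherry_parent)[cherry_parent][1]
  t_b <- vertitrace:::sister_sets(tr)[[t_a]]
  out2 <- apply_transfer(tr, t_a, t_b)
  expect_true(isTRUE(ape::all.equal.phylo(out2, tr, use.edge.length = FALSE)))
})

test_that("variant simulation hits its identity targets", {
  vp <- sim_variant_proteins(250, 3, 4, within_identity = 100,
                             between_identity = 60, seed = 14)
  expect_identical(vp$proteins[["s1v1"]], vp$proteins[["s1v2"]])

  vp2 <- sim_variant_proteins(300, 4, 3, 94, 60, seed = 15)
  im <- unclass(identity_matrix(vp2$proteins))
  truth <- vp2$truth
  within <- im[truth$subtype[1] == truth$subtype &
                 seq_len(nrow(truth)) != 1, "s1v1"]
  expect_true(all(abs(within[c("s1v2", "s1v3")] - 94) <= 3))
  between <- im["s1v1", c("s2v1", "s3v2", "s4v3")]
  expect_true(all(abs(between - 60) <= 4))

  vp3 <- sim_variant_proteins(300, 4, 3, 94, 60, seed = 15)
  expect_identical(vp2$proteins, vp3$proteins)
  expect_error(sim_variant_proteins(300, 3, 3, 60, 94, seed = 1),
               "between_identity < within")
})
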