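test_that("pruning likelihood matches exhaustive state enumeration", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    tr <- random_tree(n)
    traits <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    q01 <- runif(1, 0.05, 1); q10 <- runif(1, 0.05, 1)
    mine <- vertitrace:::mk_prune(tr, traits, q01, q10, c(0.5, 0.5))$loglik
    orc <- oracle_mk_loglik(tr, traits, q01, q10, c(0.5, 0.5))
    expect_equal(mine, orc, tolerance = 1e-10)
  }
})

test_that("the two-tip root marginal matches the closed form", {
  tr <- read_newick(text = "(A:0.7,B:0.7);")
  q <- 0.3
  asr <- mk_asr(tr, c(A = 1, B = 0), model = "ER", fixed_rates = q)
  P <- vertitrace:::mk_pmat(0.7, q, q)
  num <- c(0.5 * P[1, 2] * P[1, 1],   # root absent: A present, B absent
           0.5 * P[2, 2] * P[2, 1])   # root present
  expect_equal(asr$marginals$p_present, num[2] / sum(num), tolerance = 1e-10)
  expect_equal(asr$loglik, log(sum(num)), tolerance = 1e-10)
})

test_that("marginals are proper probabilities and a constant trait needs no change", {
  tr <- sim_yule_tree(16, 1, seed = 3)
  asr <- mk_asr(tr, setNames(rep(1L, 16), tr$tip.label))
  expect_true(all(asr$marginals$p_present > 0.5))
  expect_lt(asr$rates[["q01"]], 1e-6)  # rate driven to the lower bound
  expect_equal(asr$marginals$p_absent + asr$marginals$p_present,
               rep(1, nrow(asr$marginals)))
  expect_equal(nrow(asr$gains) + nrow(asr$losses), 0)
})

test_that("ER likelihood is invariant under 0/1 relabelling with equal prior", {
  tr <- sim_yule_tree(12, 1, seed = 4)
  traits <- setNames(sample(0:1, 12, replace = TRUE), tr$tip.label)
  a1 <- mk_asr(tr, traits, model = "ER", fixed_rates = 0.2)
  a2 <- mk_asr(tr, 1L - traits, model = "ER", fixed_rates = 0.2)
  expect_equal(a1$loglik, a2$loglik, tolerance = 1e-12)
})

test_that("a single present clade under an absent root counts one gain", {
  tr <- read_newick(text = paste0(
    "((((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1):1,",
    "(i:1,(j:1,k:1):1):2);"))
  traits <- c(a = 1, b = 1, c = 1, d = 1, e = 0, f = 0, g = 0, h = 0,
              i = 0, j = 0, k = 0)
  asr <- mk_asr(tr, traits)
  tc <- count_transitions(asr, tr)
  expect_equal(nrow(tc$gains), 1)
  expect_equal(nrow(tc$losses), 0)
  # origin node is the MRCA of the present clade
  expect_equal(asr$origin_node, ape::getMRCA(tr, c("a", "b", "c", "d")))
})

test_that("an unattainable origin threshold falls back to the MRCA with a warning", {
  tr <- sim_yule_tree(10, 1, seed = 6)
  traits <- setNames(c(1L, 1L, rep(0L, 8)), tr$tip.label)
  asr <- mk_asr(tr, traits)
  expect_warning(on <- origin_node(asr, tr, threshold = 1.01), "MRCA")
  expect_equal(on, ape::getMRCA(tr, tr$tip.label[1:2]))
})

test_that("degenerate ASR inputs are rejected", {
  tr <- sim_yule_tree(4, 1, seed = 7)
  traits <- setNames(c(1L, 0L, 1L, 0L), tr$tip.label)
  expect_error(mk_asr(tr, traits[1:3]), "missing state")
  tr0 <- tr
  tr0$edge.length[] <- 0
  expect_error(mk_asr(tr0, traits), "degenerate")
  expect_error(mk_asr(ape::unroot(tr), traits), "rooted")
})

test_that("simulated traits are reconstructed with sensible rate and states", {
  ok_rate <- 0; ok_state <- 0; n_rep <- 10
  for (r in seq_len(n_rep)) {
    tr <- sim_yule_tree(48, 1, seed = 900 + r)
    sim <- sim_trait_on_tree(tr, 0.3, 0.3, root_state = 0, seed = 950 + r)
    if (length(unique(sim$traits)) < 2) next
    asr <- mk_asr(tr, sim$traits)
    ok_rate <- ok_rate + (asr$rates[["q01"]] < 0.3 * 4 && asr$rates[["q01"]] > 0.3 / 4)
    lab <- vertitrace:::max_marginal_labels(asr)
    ntip <- 48
    acc <- mean(lab[(ntip + 1):(ntip + tr$Nnode)] ==
                  sim$node_states[(ntip + 1):(ntip + tr$Nnode)])
    ok_state <- ok_state + (acc > 0.7)
  }
  expect_gte(ok_rate, 6)
  expect_gte(ok_state, 8)
})

test_that("dating recovers a single root calibration exactly on a clock tree", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")  # ultrametric, depth 2
  dat <- date_nodes(tr, list(list(tips = c("A", "B", "C", "D"), age = 200)))
  root_row <- tidy(dat)[tidy(dat)$node == 5, ]
  expect_equal(root_row$age_ma, 200)
  expect_equal(dat$rate, 2 / 200)
  # tips at age 0
  expect_equal(tidy(dat)$age_ma[1:4], rep(0, 4))
})

test_that("two clock-consistent calibrations are both dated at their ages", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cal <- list(list(tips = c("A", "B", "C", "D"), age = 400, ci = c(300, 500)),
              list(tips = c("A", "B"), age = 200, ci = c(150, 250)))
  dat <- date_nodes(tr, cal)
  ages <- tidy(dat)
  expect_equal(ages$age_ma[ages$node == 5], 400, tolerance = 1e-10)
  expect_equal(ages$age_ma[ages$node == 6], 200, tolerance = 1e-10)
  expect_true(all(ages$age_lo <= ages$age_ma & ages$age_ma <= ages$age_hi))
})

test_that("child ages never exceed parent ages", {
  set.seed(15)
  for (i in 1:20) {
    tr <- random_tree(sample(5:25, 1))
    dat <- date_nodes(tr, list(list(tips = sample(tr$tip.label, 3), age = 100)))
    ages <- dat$ages$age_ma
    for (k in seq_len(nrow(tr$edge))) {
      expect_lte(ages[tr$edge[k, 2]], ages[tr$edge[k, 1]] + 1e-12)
    }
  }
})

test_that("dating rejects tip calibrations", {
  tr <- sim_yule_tree(6, 1, seed = 8)
  expect_error(date_nodes(tr, list(list(tips = "t1", age = 10))), "tip")
})

test_that("identical topologies yield no transfer flags", {
  tr <- sim_yule_tree(12, 1, seed = 16)
  fl <- lgt_flags(tr, tr)
  expect_false(any(fl$incongruent))
  expect_false(any(fl$flagged))
})

test_that("a fully swapped quartet flags all four tips", {
  sp <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  gn <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  fl <- lgt_flags(gn, sp)
  expect_true(all(fl$incongruent))
  expect_true(all(fl$flagged))
})

test_that("an engineered transfer flags the recipient with the donor as sister", {
  # transfers between lineages that are not already neighbours: a "transfer"
  # into a tip's own sister group is topologically unidentifiable
  tested <- 0
  for (s in 1:8) {
    tr <- sim_yule_tree(16, 1, seed = 20 + s)
    pick <- withr::with_seed(30 + s, sample(tr$tip.label, 2))
    sis <- vertitrace:::sister_sets(tr)
    if (pick[1] %in% sis[[pick[2]]] || pick[2] %in% sis[[pick[1]]]) next
    gn <- apply_transfer(tr, donor_tip = pick[1], recipient_tip = pick[2])
    fl <- lgt_flags(gn, tr)
    expect_identical(fl$tip[fl$flagged], pick[2])
    expect_true(pick[1] %in% fl$proposed_donor[fl$flagged][[1]])
    tested <- tested + 1
  }
  expect_gte(tested, 4)
})

test_that("gene trees restricted to a tip subset are compared after pruning", {
  sp <- sim_yule_tree(10, 1, seed = 26)
  gn <- ape::keep.tip(sp, sp$tip.label[1:6])
  fl <- lgt_flags(gn, sp)
  expect_false(any(fl$flagged))
  alien <- sim_yule_tree(4, 1, seed = 1)
  alien$tip.label <- c("t1", "t2", "x3", "x4")  # partial overlap
  expect_error(lgt_flags(alien, sp), "not in species")
  alien$tip.label <- paste0("x", 1:4)
  expect_error(lgt_flags(alien, sp), "empty tip intersection")
})
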