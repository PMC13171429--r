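make_msa <- function(rows) setNames(rows, paste0("v", seq_along(rows)))

test_that("alignment trimming drops the stated columns from every row", {
  msa <- make_msa(rep(strrep("A", 600), 3))
  trimmed <- trim_alignment(msa)  # defaults: 30 N-terminal + 475..549
  expect_equal(unique(nchar(trimmed)), 600 - 30 - 75)

  expect_identical(trim_alignment(msa, drop_nterm_cols = 0, drop_range = NULL),
                   msa)
  expect_error(trim_alignment(msa, drop_range = c(10, 5)), "invalid")
  expect_error(trim_alignment(msa, drop_nterm_cols = 0, drop_range = c(550, 700)),
               "beyond")
  expect_error(trim_alignment(msa, drop_nterm_cols = 30, drop_range = c(10, 40)),
               "overlap")

  # column content (not just width) is preserved in order
  m2 <- c(a = "ABCDEF")
  expect_identical(unname(trim_alignment(m2, 2, c(5, 5))), "CDF")
})

test_that("pairwise identity uses mutually ungapped columns", {
  m <- c(x = "MK-R", y = "MQ-R")
  im <- identity_matrix(m)
  expect_equal(im["x", "y"], 100 * 2 / 3)
  expect_equal(diag(unclass(im)), c(x = 100, y = 100))
  expect_equal(unclass(im), t(unclass(im)))

  im2 <- identity_matrix(c(a = "M---", b = "---K"))
  expect_true(is.na(im2["a", "b"]))

  im3 <- identity_matrix(c(a = "MKR", b = "MKR"))
  expect_equal(im3["a", "b"], 100)
})

test_that("subtype clustering is single-linkage with size-ranked labels", {
  m <- matrix(60, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  diag(m) <- 100
  m[1:3, 1:3] <- 95; diag(m) <- 100
  m[4:5, 4:5] <- 95; diag(m) <- 100
  cl <- cluster_subtypes(structure(m, class = "identity_matrix"), 85)
  expect_equal(cl$subtype, c(1, 1, 1, 2, 2))
  expect_equal(cl$label, c("1.1", "1.2", "1.3", "2.1", "2.2"))

  expect_equal(unique(cluster_subtypes(structure(m, class = "identity_matrix"),
                                       0)$subtype), 1)
  m100 <- matrix(50, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m100) <- 100
  expect_equal(cluster_subtypes(structure(m100, class = "identity_matrix"),
                                100)$subtype, 1:3)

  mna <- m; mna[1, 2] <- mna[2, 1] <- NA
  expect_error(cluster_subtypes(structure(mna, class = "identity_matrix"), 85),
               "undefined")
})

test_that("raising the identity threshold never merges clusters", {
  set.seed(19)
  for (i in 1:5) {
    vp <- sim_variant_proteins(200, 4, 3, 92, 65, seed = 400 + i)
    im <- identity_matrix(vp$proteins)
    lo <- cluster_subtypes(im, 70)$subtype
    hi <- cluster_subtypes(im, 88)$subtype
    # each high-threshold cluster sits inside one low-threshold cluster
    expect_true(all(tapply(lo, hi, function(v) length(unique(v))) == 1))
  }
})

test_that("simulated variant sets re-cluster perfectly at threshold 85", {
  for (s in 1:10) {
    vp <- sim_variant_proteins(300, 5, 4, within_identity = 92,
                               between_identity = 65, seed = 500 + s)
    im <- identity_matrix(vp$proteins)
    # realised identities land close to their targets
    for (i in 1:3) expect_equal(unclass(im)[1, 2], 92, tolerance = 3.5)
    cl <- cluster_subtypes(im, 85)
    truth <- vp$truth
    joined <- merge(cl, truth, by = "id")
    tab <- table(joined$subtype.x, joined$subtype.y)
    expect_equal(sum(tab > 0), 5)  # one-to-one cluster correspondence
  }
})

test_that("neighbourhood profiles collect ordered windowed loci", {
  loci <- tibble::tibble(
    genome_id = "g", gene_id = c("a", "focal", "b", "far"),
    start = c(1000L, 5000L, 8000L, 40000L),
    end = c(2000L, 6000L, 9000L, 41000L), strand = c("+", "+", "-", "+"))
  fam <- c(a = "f1", focal = "tox", b = "f2", far = "f9")
  prof <- neighborhood_profile(loci, "focal", fam, window_bp = 10000)
  expect_equal(prof$family, c("f1", "tox", "f2"))
  expect_equal(prof$offset, c(-4000L, 0L, 3000L))
  expect_error(neighborhood_profile(loci, "nope", fam), "not found")
})

test_that("synteny scoring combines family overlap and adjacency", {
  pA <- tibble::tibble(family = c("f1", "f2", "f3"))
  pB <- tibble::tibble(family = c("f1", "f3", "f2"))
  expect_equal(neighborhood_synteny(pA, pA), 1)
  expect_equal(neighborhood_synteny(pA,
                                    tibble::tibble(family = c("g1", "g2"))), 0)
  expect_equal(neighborhood_synteny(pA, pB), 0.5)
  expect_warning(sc <- neighborhood_synteny(pA,
                                            tibble::tibble(family = character(0))),
                 "empty")
  expect_true(is.na(sc))
})
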