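.pm <- function(states, taxa, char = "c1") {
  m <- matrix(as.integer(states), ncol = length(char),
              dimnames = list(taxa, char))
  methods::new("PresenceMatrix", states = m)
}

test_that("small frozen cases match brute-force parsimony", {
  # single leaf, state 1: score 0, root = 1
  tr <- readNewickTreeText("(A);")
  rec <- fitchReconstruction(tr, .pm(1L, "A"))
  expect_identical(unname(parsimonyScores(rec)), 0L)
  expect_true(all(nodeStates(rec)[, "c1"] == "1"))

  # ((A,B),C) with A=B=1, C=0: score 1, ambiguous root
  tr <- readNewickTreeText("((A,B),C);")
  rec <- fitchReconstruction(tr, .pm(c(1L, 1L, 0L), c("A", "B", "C")))
  expect_identical(unname(parsimonyScores(rec)), 1L)
  n_tip <- 3L
  root_label <- rownames(nodeStates(rec))[n_tip + 1L]
  expect_identical(unname(nodeStates(rec)[root_label, "c1"]), "ambiguous")

  # all-identical leaves: score 0, every node that state
  rec <- fitchReconstruction(tr, .pm(c(1L, 1L, 1L), c("A", "B", "C")))
  expect_identical(unname(parsimonyScores(rec)), 0L)
  expect_true(all(nodeStates(rec) == "1"))
})

test_that("scores equal brute-force minima on random trees with <= 7 leaves", {
  withr::local_seed(101)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    tr <- randomTree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) states[1] <- 1L - states[1]
    rec <- fitchReconstruction(tr, .pm(states, tr$tip.label))
    oracle <- bruteParsimony(tr, states)
    expect_identical(unname(parsimonyScores(rec)), as.integer(oracle$score))
    # the per-node most-parsimonious state sets agree too
    got_sets <- lapply(nodeStates(rec)[, "c1"], function(s)
      if (s == "ambiguous") 0:1 else as.integer(s))
    for (v in seq_along(oracle$sets))
      expect_identical(sort(unlist(got_sets[[v]])), oracle$sets[[v]])
  }
})

test_that("scores agree with phangorn's parsimony on larger random trees", {
  skip_if_not_installed("phangorn")
  withr::local_seed(102)
  for (i in 1:20) {
    n <- sample(8:16, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    rec <- fitchReconstruction(tr, .pm(states, tr$tip.label))
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_identical(unname(parsimonyScores(rec)),
                     as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("the parsimony score is invariant under rerooting", {
  withr::local_seed(103)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    s0 <- unname(parsimonyScores(
      fitchReconstruction(tr, .pm(states, tr$tip.label))))
    for (tip in sample(tr$tip.label, 2)) {
      tr2 <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      s1 <- unname(parsimonyScores(
        fitchReconstruction(tr2, .pm(states[tr2$tip.label],
                                     tr2$tip.label))))
      expect_identical(s1, s0)
    }
  }
})

test_that("dollo_single_gain places one gain at the presence clade stem", {
  tr <- readNewickTreeText("((A,B),(C,D));")
  pm <- .pm(c(1L, 1L, 0L, 0L), c("A", "B", "C", "D"))
  rec <- fitchReconstruction(tr, pm)
  res <- resolveRoot(rec, "dollo_single_gain", matrix = pm)
  ev <- mapEvents(res)
  gains <- ev[ev$type == "gain", ]
  expect_identical(nrow(gains), 1L)
  # the gain sits on the stem of the (A,B) clade
  mrca <- ape::getMRCA(res@tree, c("A", "B"))
  expect_identical(gains$branch,
                   rownames(nodeStates(res))[mrca])

  # property: exactly one gain per character for clade-confined characters
  withr::local_seed(104)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    # confine presence to a random proper subtree
    internal <- setdiff(unique(tr$edge[, 1]), n + 1L)
    if (!length(internal)) next
    node <- sample(internal, 1)
    tips_in <- ape::extract.clade(tr, node)$tip.label
    states <- stats::setNames(as.integer(tr$tip.label %in% tips_in),
                              tr$tip.label)
    # knock some presences out so losses exist below the gain
    if (length(tips_in) > 2)
      states[sample(tips_in, 1)] <- 0L
    if (sum(states) == 0) next
    pm_i <- .pm(states, tr$tip.label)
    res_i <- resolveRoot(fitchReconstruction(tr, pm_i),
                         "dollo_single_gain", matrix = pm_i)
    ev_i <- mapEvents(res_i)
    expect_identical(sum(ev_i$type == "gain"), 1L)
    # leaves keep their observed states
    st <- nodeStates(res_i)[tr$tip.label, "c1"]
    expect_identical(unname(st), as.character(states[tr$tip.label]))
  }
})

test_that("presence_bias resolves flagged ambiguous roots to present", {
  tr <- readNewickTreeText("((A,B),C);")
  pm <- .pm(c(1L, 1L, 0L), c("A", "B", "C"))
  rec <- fitchReconstruction(tr, pm)
  root_label <- rownames(nodeStates(rec))[4L]
  flagged <- resolveRoot(rec, "presence_bias", biasCharacters = "c1",
                         matrix = pm)
  expect_identical(unname(nodeStates(flagged)[root_label, "c1"]), "1")
  unflagged <- resolveRoot(rec, "presence_bias", matrix = pm)
  expect_identical(unname(nodeStates(unflagged)[root_label, "c1"]), "0")
  # policy none keeps ambiguity, and mapEvents then refuses
  expect_identical(resolveRoot(rec, "none"), rec)
  expect_error(mapEvents(rec), "ambiguous")
})

test_that("the lineage fixture reproduces the stem gains and root set", {
  tr <- loadFixture("superphylum_tree")
  pm <- loadFixture("domain_presence")
  rec <- fitchReconstruction(tr, pm)
  bias <- c("CdvB:Snf7", "CdvB:MIM2", "CdvC:MIT", "CdvC:AAA_ATPase",
            "CdvC:Vps4_C")  # characters with gene-cluster support
  res <- resolveRoot(rec, "presence_bias", biasCharacters = bias,
                     matrix = pm)
  ev <- mapEvents(res)
  gain_of <- function(char) ev$branch[ev$character == char &
                                        ev$type == "gain"]
  expect_identical(gain_of("CdvA:BWI"), "Crenarchaeota")
  expect_identical(gain_of("CdvB:BWH"), "Crenarchaeota")
  expect_identical(gain_of("CdvA:CdvA_alpha"), "TACK")
  expect_identical(gain_of("CdvA:CdvA_beta"), "TACK")
  expect_identical(gain_of("CdvB:ANCHR"), "Asgard")
  expect_identical(gain_of("CdvB:MIM1"), "Asgard")
  # the ancestral machinery: a two-domain CdvB plus a complete CdvC
  root <- ancestralArchitecture(res, "LACA")
  expect_setequal(root$CdvB, c("Snf7", "MIM2"))
  expect_setequal(root$CdvC, c("MIT", "AAA_ATPase", "Vps4_C"))
  expect_null(root$CdvA)
  # leaf query returns the observed set
  leaf <- ancestralArchitecture(res, "Crenarchaeota")
  expect_setequal(leaf$CdvA, c("CdvA_alpha", "CdvA_beta", "BWI"))
})

test_that("missing leaves and unknown nodes are rejected", {
  tr <- readNewickTreeText("((A,B),C);")
  expect_error(fitchReconstruction(tr, .pm(c(1L, 0L), c("A", "B"))),
               "missing")
  pm <- .pm(c(1L, 1L, 0L), c("A", "B", "C"))
  rec <- resolveRoot(fitchReconstruction(tr, pm), "presence_bias",
                     matrix = pm)
  expect_error(ancestralArchitecture(rec, "nope"), "unknown node")
})
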