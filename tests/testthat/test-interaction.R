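test_that("qualitative ancestral networks have the published edge sets", {
  sets <- ancestralProteinSets()
  edge_key <- function(net) {
    e <- edgeTable(net)
    sort(paste(e$node_a, e$node_b, e$domain_a, e$domain_b, sep = "|"))
  }
  thaum <- buildPpiNetwork(sets$Thaumarchaeota, qualitative = TRUE)
  expect_identical(edge_key(thaum), sort(c(
    "CdvA|CdvC|MIM2|MIT", "CdvB|CdvC|MIM2|MIT", "CdvB|CdvB|Snf7|Snf7",
    "CdvC|CdvC|Vps4_C|Vps4_C")))
  cren <- buildPpiNetwork(sets$Crenarchaeota, qualitative = TRUE)
  expect_identical(edge_key(cren), sort(c(
    "CdvA|CdvB|BWH|BWI", "CdvB|CdvB|Snf7|Snf7", "CdvB|CdvC|MIM2|MIT",
    "CdvC|CdvC|Vps4_C|Vps4_C")))
  # empty rule set -> no edges
  empty <- methods::new("InteractionRuleSet", rules = data.frame(
    domain_a = character(), domain_b = character(), status = character(),
    effect = character(), stringsAsFactors = FALSE))
  expect_identical(nrow(edgeTable(buildPpiNetwork(sets$Crenarchaeota,
                                                  empty))), 0L)
})

test_that("every PPI edge is justified by domains on its endpoints", {
  withr::local_seed(11)
  rules <- defaultRuleSet()
  r <- ruleTable(rules)
  for (i in 1:15) {
    ra <- randomArchitectureSet(6)
    net <- buildPpiNetwork(ra, rules, qualitative = FALSE)
    e <- edgeTable(net)
    d <- domainTable(ra)
    for (k in seq_len(nrow(e))) {
      da <- d$domain_type[d$protein_id == e$node_a[k]]
      db <- d$domain_type[d$protein_id == e$node_b[k]]
      ok <- (e$domain_a[k] %in% da && e$domain_b[k] %in% db) ||
        (e$domain_b[k] %in% da && e$domain_a[k] %in% db)
      expect_true(ok)
      # and the rule actually exists, enabled
      expect_true(any((r$domain_a == e$domain_a[k] &
                         r$domain_b == e$domain_b[k]) |
                        (r$domain_a == e$domain_b[k] &
                           r$domain_b == e$domain_a[k])))
    }
  }
})

test_that("qualitative counts are invariant under paralog duplication", {
  sets <- ancestralProteinSets()
  cren <- sets$Crenarchaeota
  p <- proteinTable(cren)
  d <- domainTable(cren)
  # duplicate the CdvB1/2 paralog with identical architecture
  p2 <- rbind(p, within(p[p$protein_id == "CdvB1/2", ],
                        protein_id <- "CdvB1/2-copy"))
  dd <- d[d$protein_id == "CdvB1/2", ]
  dd$protein_id <- "CdvB1/2-copy"
  d2 <- rbind(d, dd)
  dup <- architectureSet(p2, d2)
  n0 <- nrow(edgeTable(buildPpiNetwork(cren, qualitative = TRUE)))
  n1 <- nrow(edgeTable(buildPpiNetwork(dup, qualitative = TRUE)))
  expect_identical(n0, n1)
})

test_that("affinity ranking is the documented total order", {
  cand <- data.frame(
    actor = c("c1", "c2", "c3", "c4"),
    target = "t",
    domain_a = c("Snf7", "MIM2", "BWI", "Vps4_C"),
    domain_b = c("Snf7", "MIT", "BWH", "Vps4_C"),
    proline_count = c(NA, 4, NA, NA), stringsAsFactors = FALSE)
  ranked <- rankAffinity(cand)
  expect_identical(ranked$domain_a,
                   c("BWI", "Snf7", "MIM2", "Vps4_C"))
  # within the MIT tier, more prolines first; MIM1 (no count) after MIM2
  cand2 <- data.frame(
    actor = c("low", "high", "mim1"), target = "t",
    domain_a = c("MIM2", "MIM2", "MIM1"), domain_b = "MIT",
    proline_count = c(2, 4, NA), stringsAsFactors = FALSE)
  expect_identical(rankAffinity(cand2)$actor, c("high", "low", "mim1"))
  # single candidate passes through
  expect_identical(nrow(rankAffinity(cand2[1, ])), 1L)
})

test_that("the Crenarchaeota run reproduces the sequential-enrichment order", {
  sc <- inferMechanism(ancestralProteinSets()$Crenarchaeota)
  expect_length(sc, 1L)
  ev <- eventTable(sc[[1]])
  expect_identical(ev$event, c("membrane_bind", "recruit", "polymerize",
                               "bind", "disassemble", "disassemble"))
  expect_identical(ev$actor[1], "CdvA")
  expect_identical(ev$actor[2], "CdvB")          # BWI-BWH recruitment
  expect_identical(ev$actor[3], "CdvB1/2,CdvB3") # Snf7 ring
  expect_identical(ev$actor[4], "CdvC")
  expect_identical(ev$target[4], "CdvB")         # 4-proline MIM2 preferred
  # CdvB disassembles before CdvB1/2
  expect_identical(ev$target[5], "CdvB")
  expect_identical(ev$target[6], "CdvB1/2")
  expect_identical(unresolvedProteins(sc[[1]]), "CdvB3")
})

test_that("the Thaumarchaeota run forks into exactly two scenarios", {
  sc <- inferMechanism(ancestralProteinSets()$Thaumarchaeota)
  expect_length(sc, 2L)
  ev1 <- eventTable(sc[[1]])
  ev2 <- eventTable(sc[[2]])
  # scenario 1: CdvA itself polymerises into the ring and is disassembled
  expect_true("polymerize" %in% ev1$event &&
                ev1$actor[ev1$event == "polymerize"] == "CdvA")
  expect_identical(ev1$target[ev1$event == "disassemble"], "CdvA")
  # scenario 2: CdvC links CdvA to CdvB; no disassembly is possible
  expect_true(any(ev2$event == "recruit" & ev2$actor == "CdvB"))
  expect_false("disassemble" %in% ev2$event)
  expect_false(any(ev2$actor == "CdvA" & ev2$event == "polymerize"))
})

test_that("the Asgard run starts at CdvBa1 and resolves every protein", {
  sc <- inferMechanism(ancestralProteinSets()$Asgard)
  expect_length(sc, 1L)
  ev <- eventTable(sc[[1]])
  expect_identical(ev$actor[1], "CdvBa1")
  expect_identical(ev$event[2], "polymerize")
  expect_true(any(ev$event == "bind" & ev$actor == "CdvC"))
  expect_true(sum(ev$event == "disassemble") == 2L)
  expect_length(unresolvedProteins(sc[[1]]), 0L)
})

test_that("mechanism inference is deterministic and respects rule status", {
  sets <- ancestralProteinSets()
  a <- inferMechanism(sets$Crenarchaeota)
  b <- inferMechanism(sets$Crenarchaeota)
  expect_identical(lapply(a, eventTable), lapply(b, eventTable))

  # disabling MIM2-MIT removes every disassemble event (cascade)
  rules <- defaultRuleSet()
  r <- ruleTable(rules)
  r$status[r$domain_a == "MIM2" & r$domain_b == "MIT"] <- "disabled"
  disabled <- methods::new("InteractionRuleSet", rules = r)
  for (grp in c("Crenarchaeota", "Thaumarchaeota")) {
    sc <- inferMechanism(sets[[grp]], rules = disabled)
    for (s in sc)
      expect_false("disassemble" %in% eventTable(s)$event)
  }
  # replay: no event ever uses a disabled rule
  for (s in inferMechanism(sets$Crenarchaeota, rules = disabled)) {
    ev <- eventTable(s)
    expect_false(any(grepl("MIM2-MIT", ev$rule)))
  }
})

test_that("auto start selection needs exactly one membrane binder", {
  sets <- ancestralProteinSets()
  p <- proteinTable(sets$Asgard)
  d <- domainTable(sets$Asgard)
  no_anchor <- architectureSet(p, d[d$domain_type != "ANCHR", ])
  expect_error(inferMechanism(no_anchor), "membrane-binding")
  expect_error(inferMechanism(sets$Asgard, start = "nope"), "unknown")
  # explicit start overrides auto detection
  sc <- inferMechanism(no_anchor, start = "CdvBa1")
  expect_identical(eventTable(sc[[1]])$actor[1], "CdvBa1")
})

test_that("rule sets round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  writeRuleSet(defaultRuleSet(), f)
  back <- readRuleSet(f)
  expect_identical(ruleTable(back), ruleTable(defaultRuleSet()))
})
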