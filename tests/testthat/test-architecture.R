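.protMeta <- function(ids, sp = "TACK_Crenarchaeota", family = "CdvB",
                      org = "org1") {
  data.frame(protein_id = ids, organism = org, super_phylum = sp,
             family = family, stringsAsFactors = FALSE)
}

test_that("overlapping same-type calls merge to their coordinate union", {
  ann <- data.frame(protein_id = "P1", domain_type = "Snf7",
                    start = c(10L, 40L), end = c(60L, 90L),
                    evidence = c("db_scan", "motif_regex"),
                    source = "x", stringsAsFactors = FALSE)
  arch <- assembleArchitectures(ann, proteins = .protMeta("P1"))
  d <- domainTable(arch)
  expect_identical(nrow(d), 1L)
  expect_identical(d$start, 10L)
  expect_identical(d$end, 90L)
  expect_identical(d$evidence, "db_scan")  # strongest evidence wins

  # merging is idempotent
  arch2 <- assembleArchitectures(d[, c("protein_id", "domain_type", "start",
                                       "end", "evidence")],
                                 proteins = .protMeta("P1"))
  expect_identical(domainTable(arch2)$start, d$start)
  expect_identical(domainTable(arch2)$end, d$end)

  # non-overlapping same-type calls stay separate
  ann$start <- c(10L, 70L); ann$end <- c(60L, 90L)
  arch3 <- assembleArchitectures(ann, proteins = .protMeta("P1"))
  expect_identical(nrow(domainTable(arch3)), 2L)
})

test_that("MIM2 matches deduplicate with class precedence total > Sulf > Core", {
  mm <- scanMim2(c(P1 = "LPKLPKKPLP"))
  arch <- assembleArchitectures(motifMatches = mm,
                                proteins = .protMeta("P1"))
  d <- domainTable(arch)
  expect_identical(nrow(d), 1L)
  expect_identical(d$domain_type, "MIM2")
  expect_identical(d$proline_count, 4L)  # the total-class match is kept
  expect_identical(d$start, 1L)
  expect_identical(d$end, 10L)

  # a protein with no calls keeps an empty architecture
  arch0 <- assembleArchitectures(proteins = .protMeta("P9"))
  expect_identical(nrow(domainTable(arch0)), 0L)
  expect_identical(proteinTable(arch0)$protein_id, "P9")
})

test_that("CdvC filter keeps Vps4_C/MIT carriers and allowlisted ids", {
  mk <- function(id, doms) {
    data.frame(protein_id = id, domain_type = doms,
               start = 10L * seq_along(doms),
               end = 10L * seq_along(doms) + 5L,
               evidence = "db_scan", proline_count = NA_integer_,
               stringsAsFactors = FALSE)
  }
  prot <- .protMeta(c("aaa_only", "mit_only", "exception"),
                    family = "CdvC")
  arch <- architectureSet(prot, rbind(mk("aaa_only", "AAA_ATPase"),
                                      mk("mit_only", "MIT"),
                                      mk("exception", "AAA_ATPase")))
  res <- filterCdvC(arch, allowlist = "exception")
  expect_setequal(proteinTable(res$kept)$protein_id,
                  c("mit_only", "exception"))
  expect_identical(res$rejected$protein_id, "aaa_only")
  expect_match(res$rejected$reason, "no Vps4_C or MIT")
  expect_identical(unname(attr(res$kept, "keep_reason")["exception"]),
                   "allowlist")
})

test_that("CdvB classification follows the domain-set rules", {
  mk_arch <- function(doms, sp) {
    d <- data.frame(protein_id = "P", domain_type = doms,
                    start = 10L * seq_along(doms),
                    end = 10L * seq_along(doms) + 5L,
                    evidence = "db_scan", proline_count = NA_integer_,
                    stringsAsFactors = FALSE)
    architectureSet(.protMeta("P", sp = sp), d)
  }
  cls <- function(doms, sp) classifyCdvB(mk_arch(doms, sp))$class
  expect_identical(cls(c("Snf7", "MIM2", "BWH"), "TACK_Crenarchaeota"),
                   "CdvB_class")
  expect_identical(cls(c("Snf7", "MIM2"), "TACK_Crenarchaeota"),
                   "CdvB12_class")
  expect_identical(cls("Snf7", "TACK_Crenarchaeota"), "CdvB3_class")
  expect_identical(cls(c("Snf7", "BWH"), "TACK_Crenarchaeota"),
                   "unclassified")
  expect_identical(cls(c("ANCHR", "Snf7", "MIM1"), "Asgard"), "CdvBa1")
  expect_identical(cls(c("Snf7", "MIM2"), "Asgard"), "CdvBa2")
  expect_identical(cls("MIT", "Asgard"), "unclassified")
  expect_identical(cls("Snf7", "Euryarchaeota"), "unclassified")
})

test_that("the bundled table yields 3 Cren classes and 2 Asgard clades", {
  arch <- loadFixture("archaea_architectures")
  pt <- proteinTable(arch)
  cls <- classifyCdvB(arch)
  cren_b <- pt$protein_id[pt$super_phylum == "TACK_Crenarchaeota" &
                            pt$family == "CdvB"]
  cren_cls <- cls$class[cls$protein_id %in% cren_b]
  expect_setequal(unique(cren_cls),
                  c("CdvB_class", "CdvB12_class", "CdvB3_class"))
  asg_b <- pt$protein_id[pt$super_phylum == "Asgard" & pt$family == "CdvB"]
  asg_cls <- cls$class[cls$protein_id %in% asg_b]
  expect_setequal(unique(asg_cls), c("CdvBa1", "CdvBa2"))
})

test_that("shared domains are the intersection of group unions", {
  arch <- loadFixture("archaea_architectures")
  pt <- proteinTable(arch)
  g <- ifelse(pt$super_phylum %in% c("TACK_Crenarchaeota",
                                     "TACK_Thaumarchaeota"),
              "TACK", pt$super_phylum)
  gm <- tapply(g, pt$organism, function(z) z[1])
  shared <- sharedDomains(arch, gm)
  expect_setequal(shared, c("Snf7", "AAA_ATPase", "MIT", "Vps4_C"))

  # single group: union of its domains
  one <- tapply(rep("all", nrow(pt)), pt$organism, function(z) z[1])
  expect_setequal(sharedDomains(arch, one),
                  unique(domainTable(arch)$domain_type))

  # brute-force containment property on random tables
  withr::local_seed(7)
  for (i in 1:15) {
    ra <- randomArchitectureSet(8)
    orgs <- unique(proteinTable(ra)$organism)
    gr <- stats::setNames(sample(c("g1", "g2"), length(orgs),
                                 replace = TRUE), orgs)
    if (length(unique(gr)) < 2) next
    shared_r <- sharedDomains(ra, gr)
    for (grp in unique(gr)) {
      ids <- proteinTable(ra)$protein_id[
        proteinTable(ra)$organism %in% names(gr)[gr == grp]]
      dom_union <- unique(domainTable(ra)$domain_type[
        domainTable(ra)$protein_id %in% ids])
      expect_true(all(shared_r %in% dom_union))
    }
  }
})

test_that("organism homolog counts treat 'none' families as absent", {
  prot <- data.frame(protein_id = c("a", "b"),
                     organism = c("o1", "o2"),
                     super_phylum = "Euryarchaeota",
                     family = c("CdvB", "none"), stringsAsFactors = FALSE)
  arch <- architectureSet(prot)
  expect_identical(unname(organismsWithHomologs(arch)), c(1L, 1L))
})

test_that("gene neighbourhood buckets minimal rank distances", {
  coords <- data.frame(
    organism = rep(c("o1", "o2", "o3"), times = c(7, 9, 3)),
    gene_id = c(paste0("o1g", 1:7), paste0("o2g", 1:9), paste0("o3g", 1:3)),
    start = c(1:7 * 100, 1:9 * 100, 1:3 * 100), stringsAsFactors = FALSE)
  fams <- c(o1g5 = "CdvA", o1g6 = "CdvB", o1g7 = "CdvC",  # ranks 5,6,7
            o2g5 = "CdvB", o2g9 = "CdvC",                 # ranks 5 and 9
            o3g2 = "CdvC")                                # single gene
  res <- geneNeighborhood(coords, fams)
  expect_identical(res$classification[res$organism == "o1"], "direct")
  expect_identical(res$classification[res$organism == "o2"], "close")
  expect_identical(res$classification[res$organism == "o3"], "absent")
  dup <- coords; dup$start[2] <- dup$start[1]
  expect_error(geneNeighborhood(dup, fams), "duplicate")
})
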