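# Bundled synthetic reference tables. These are constructed stand-ins (see
# the file headers under inst/extdata): they reproduce the published
# per-group distribution statements about archaeal Cdv machineries - counts,
# domain vocabularies, class structure - without transcribing any original
# per-protein data.

.FIXTURES <- c("archaea_architectures", "asgard_cdvb", "domain_presence",
               "superphylum_tree")

#' Load a bundled synthetic reference fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{archaea_architectures}{\code{\link{ArchitectureSet}} covering 51
#'     archaeal organisms (37 with at least one CdvABC homolog, 14 without).
#'     Protein rows with family "none" mark organisms surveyed without any
#'     Cdv homolog; homologs in which no conserved domain was identified have
#'     no domain rows.}
#'   \item{asgard_cdvb}{list with \code{sequences} (AAStringSet),
#'     \code{ss} (named H/E/C strings), \code{clades} (named truth labels)
#'     and \code{annotations} (data.frame of externally annotated domains)
#'     for the two Asgard CdvB clades.}
#'   \item{domain_presence}{\code{\link{PresenceMatrix}} of family-qualified
#'     domain characters across the four archaeal lineages.}
#'   \item{superphylum_tree}{rooted \code{ape::phylo} tree of the four
#'     lineages, with named internal nodes (TACK, AsgardTACK, LACA).}
#' }
#'
#' @param name one of the fixture names above.
#' @return the fixture object (type depends on the fixture).
#' @export
#' @examples
#' arch <- loadFixture("archaea_architectures")
#' organismsWithHomologs(arch)
loadFixture <- function(name) {
  .assertScalarString(name, "name")
  if (!name %in% .FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "), call. = FALSE)
  path <- function(f) system.file("extdata", f, package = "CdvArch",
                                  mustWork = TRUE)
  switch(name,
    archaea_architectures = {
      tab <- utils::read.table(
        path("synthetic_archaea_architectures.tsv"), header = TRUE,
        sep = "\t", quote = "", comment.char = "#",
        stringsAsFactors = FALSE, na.strings = "NA")
      tab$protein_id[is.na(tab$protein_id) | tab$protein_id == ""] <-
        paste0(tab$organism[is.na(tab$protein_id) | tab$protein_id == ""],
               " (no Cdv homolog)")
      prot <- unique(tab[, c("protein_id", "organism", "super_phylum",
                             "family")])
      dom <- tab[!is.na(tab$domain_type) & nzchar(tab$domain_type),
                 c("protein_id", "domain_type", "start", "end", "evidence",
                   "proline_count")]
      architectureSet(prot, dom)
    },
    asgard_cdvb = {
      tab <- utils::read.table(
        path("synthetic_asgard_cdvb.tsv"), header = TRUE, sep = "\t",
        quote = "", comment.char = "#", stringsAsFactors = FALSE)
      seqs <- Biostrings::AAStringSet(stats::setNames(tab$seq,
                                                      tab$protein_id))
      ann <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        trip <- strsplit(strsplit(tab$domains[i], ";")[[1]], ":")
        do.call(rbind, lapply(trip, function(t3)
          data.frame(protein_id = tab$protein_id[i], domain_type = t3[1],
                     start = as.integer(t3[2]), end = as.integer(t3[3]),
                     evidence = "db_scan", source = "synthetic",
                     stringsAsFactors = FALSE)))
      }))
      list(sequences = seqs,
           ss = stats::setNames(tab$ss, tab$protein_id),
           clades = stats::setNames(tab$clade, tab$protein_id),
           organisms = stats::setNames(tab$organism, tab$protein_id),
           annotations = ann)
    },
    domain_presence =
      readPresenceMatrix(path("synthetic_domain_presence.tsv")),
    superphylum_tree =
      readNewickTree(path("synthetic_superphylum_tree.nwk")))
}
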