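# S4 containers for the Cdv domain-architecture pipeline.

#' ArchitectureSet: proteins and their domain instances
#'
#' Container pairing a protein metadata table (one row per protein: id,
#' organism, super-phylum, family) with a domain-instance table (one row per
#' called domain: type, 1-based inclusive coordinates, evidence class and,
#' for MIM2 instances, the proline count of the matched span).
#'
#' @slot proteins data.frame with columns \code{protein_id}, \code{organism},
#'   \code{super_phylum}, \code{family}.
#' @slot domains data.frame with columns \code{protein_id},
#'   \code{domain_type}, \code{start}, \code{end}, \code{evidence},
#'   \code{proline_count}.
#' @export
setClass("ArchitectureSet",
         representation(proteins = "data.frame", domains = "data.frame"))

setValidity("ArchitectureSet", function(object) {
  p <- object@proteins
  d <- object@domains
  msgs <- character()
  need_p <- c("protein_id", "organism", "super_phylum", "family")
  if (!all(need_p %in% names(p)))
    msgs <- c(msgs, paste("proteins table needs columns:",
                          paste(need_p, collapse = ", ")))
  need_d <- c("protein_id", "domain_type", "start", "end", "evidence",
              "proline_count")
  if (!all(need_d %in% names(d)))
    msgs <- c(msgs, paste("domains table needs columns:",
                          paste(need_d, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(p$protein_id))
      msgs <- c(msgs, "duplicated protein_id in proteins table")
    if (nrow(d)) {
      if (!all(d$protein_id %in% p$protein_id))
        msgs <- c(msgs, "domain rows reference unknown protein_id")
      bad <- setdiff(unique(d$domain_type), domainVocabulary())
      if (length(bad))
        msgs <- c(msgs, paste("domain types outside the vocabulary:",
                              paste(bad, collapse = ", ")))
      if (any(!is.finite(d$start) | !is.finite(d$end) | d$start < 1 |
                d$end < d$start))
        msgs <- c(msgs, "domain coordinates must satisfy 1 <= start <= end")
      bad_ev <- setdiff(unique(d$evidence), .EVIDENCE_LEVELS)
      if (length(bad_ev))
        msgs <- c(msgs, paste("unknown evidence class:",
                              paste(bad_ev, collapse = ", ")))
    }
    bad_sp <- setdiff(unique(p$super_phylum), c(superPhyla(), NA))
    if (length(bad_sp))
      msgs <- c(msgs, paste("unknown super_phylum:",
                            paste(bad_sp, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' InteractionRuleSet: unordered domain-pair interaction rules
#'
#' @slot rules data.frame with columns \code{domain_a}, \code{domain_b},
#'   \code{status} (validated/putative/disabled) and \code{effect}
#'   (binding/polymerization).
#' @export
setClass("InteractionRuleSet", representation(rules = "data.frame"))

setValidity("InteractionRuleSet", function(object) {
  r <- object@rules
  need <- c("domain_a", "domain_b", "status", "effect")
  if (!all(need %in% names(r)))
    return(paste("rules table needs columns:", paste(need, collapse = ", ")))
  msgs <- character()
  .tryVocab <- tryCatch({
    .assertDomainTypes(c(r$domain_a, r$domain_b)); NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(.tryVocab)) msgs <- c(msgs, .tryVocab)
  if (!all(r$status %in% c("validated", "putative", "disabled")))
    msgs <- c(msgs, "status must be validated, putative or disabled")
  if (!all(r$effect %in% c("binding", "polymerization")))
    msgs <- c(msgs, "effect must be binding or polymerization")
  key <- apply(cbind(pmin(r$domain_a, r$domain_b),
                     pmax(r$domain_a, r$domain_b)), 1, paste, collapse = "|")
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicate domain pair in rule set")
  if (length(msgs)) msgs else TRUE
})

#' PPINetwork: domain-rule-justified protein-protein interaction network
#'
#' @slot nodes character vector of protein (or, in qualitative mode, family)
#'   labels.
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{domain_a}, \code{domain_b}, \code{status}, \code{effect}. Edges are
#'   unordered; self-loops encode polymerization.
#' @slot qualitative logical; TRUE when proteins were collapsed to family
#'   labels and duplicate family/domain-pair edges deduplicated.
#' @export
setClass("PPINetwork",
         representation(nodes = "character", edges = "data.frame",
                        qualitative = "logical"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  need <- c("node_a", "node_b", "domain_a", "domain_b", "status", "effect")
  if (!all(need %in% names(e)))
    return(paste("edges table needs columns:", paste(need, collapse = ", ")))
  if (nrow(e) && !all(c(e$node_a, e$node_b) %in% object@nodes))
    return("edge endpoint not in node set")
  TRUE
})

#' MechanismScenario: one ordered assembly/disassembly scenario
#'
#' @slot events data.frame with columns \code{step}, \code{event}
#'   (membrane_bind/recruit/polymerize/bind/disassemble), \code{actor},
#'   \code{target}, \code{rule}.
#' @slot unresolved character vector of proteins for which no disassembly
#'   route exists.
#' @slot branch_id integer scenario index (1-based, deterministic order).
#' @export
setClass("MechanismScenario",
         representation(events = "data.frame", unresolved = "character",
                        branch_id = "integer"))

setValidity("MechanismScenario", function(object) {
  ev <- object@events
  need <- c("step", "event", "actor", "target", "rule")
  if (!all(need %in% names(ev)))
    return(paste("events table needs columns:", paste(need, collapse = ", ")))
  kinds <- c("membrane_bind", "recruit", "polymerize", "bind", "disassemble")
  if (nrow(ev)) {
    if (!all(ev$event %in% kinds))
      return("unknown event kind")
    if (ev$event[1] != "membrane_bind")
      return("first event must be membrane_bind")
    if (!identical(ev$step, seq_len(nrow(ev))))
      return("step must be 1..n in order")
  }
  TRUE
})

#' PresenceMatrix: binary taxa-by-character domain presence matrix
#'
#' Characters are family-qualified domain labels (e.g. \code{"CdvB:MIM2"})
#' because the same domain type on different families evolves independently.
#'
#' @slot states integer matrix in \{0,1\} with taxa as rownames and
#'   characters as colnames.
#' @export
setClass("PresenceMatrix", representation(states = "matrix"))

setValidity("PresenceMatrix", function(object) {
  s <- object@states
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("states matrix needs taxa rownames and character colnames")
  if (anyDuplicated(rownames(s))) return("duplicated taxa")
  if (anyDuplicated(colnames(s))) return("duplicated characters")
  if (!all(s %in% c(0L, 1L))) return("states must be 0 or 1")
  TRUE
})

#' AncestralReconstruction: per-node states and parsimony scores
#'
#' @slot tree the rooted \code{ape::phylo} tree the reconstruction lives on;
#'   all nodes carry labels (tip labels plus internal node labels).
#' @slot states character matrix (nodes x characters) over
#'   \{"0", "1", "ambiguous"\}; rownames are node labels, tips first.
#' @slot scores named integer vector of per-character parsimony scores.
#' @slot events data.frame of mapped gain/loss events (filled by
#'   \code{mapEvents}); columns \code{branch}, \code{character}, \code{type}.
#' @slot policy character; root-resolution policy applied ("none",
#'   "dollo_single_gain" or "presence_bias").
#' @export
setClass("AncestralReconstruction",
         representation(tree = "ANY", states = "matrix", scores = "integer",
                        events = "data.frame", policy = "character"))

setValidity("AncestralReconstruction", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  s <- object@states
  if (!all(s %in% c("0", "1", "ambiguous")))
    return("states must be '0', '1' or 'ambiguous'")
  n_nodes <- length(object@tree$tip.label) + object@tree$Nnode
  if (nrow(s) != n_nodes) return("states must have one row per tree node")
  if (!identical(sort(names(object@scores)), sort(colnames(s))))
    return("scores must be named by character")
  TRUE
})
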