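# Domain-domain interaction rules and rule-justified PPI networks.

#' Default domain-interaction rule set
#'
#' Four experimentally validated pairings — MIM2-MIT binding, BWI-BWH
#' binding, Snf7-Snf7 polymerization and Vps4_C-Vps4_C polymerization — plus
#' two putative ones: CdvA_beta self-polymerization (experimental evidence is
#' inconclusive, so it is excluded from qualitative interaction counts but
#' available to mechanism inference) and MIM1-MIT binding.
#'
#' @return an \code{\link{InteractionRuleSet}}.
#' @export
defaultRuleSet <- function() {
  rules <- data.frame(
    domain_a = c("MIM2", "BWI", "Snf7", "Vps4_C", "CdvA_beta", "MIM1"),
    domain_b = c("MIT", "BWH", "Snf7", "Vps4_C", "CdvA_beta", "MIT"),
    status = c("validated", "validated", "validated", "validated",
               "putative", "putative"),
    effect = c("binding", "binding", "polymerization", "polymerization",
               "polymerization", "binding"),
    stringsAsFactors = FALSE)
  methods::new("InteractionRuleSet", rules = rules)
}

#' Read an interaction rule set from JSON
#'
#' Schema: a JSON array of objects \code{\{"domains": [a, b], "status": ...,
#' "effect": ...\}}.
#'
#' @param path path to the JSON file.
#' @return an \code{\link{InteractionRuleSet}}.
#' @export
readRuleSet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rules <- do.call(rbind, lapply(raw, function(r) {
    if (length(r$domains) != 2L)
      stop("each rule needs exactly two domains", call. = FALSE)
    data.frame(domain_a = r$domains[[1]], domain_b = r$domains[[2]],
               status = r$status, effect = r$effect,
               stringsAsFactors = FALSE)
  }))
  methods::new("InteractionRuleSet", rules = rules)
}

#' Write an interaction rule set to JSON
#' @param rules an \code{\link{InteractionRuleSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRuleSet <- function(rules, path) {
  r <- ruleTable(rules)
  lst <- lapply(seq_len(nrow(r)), function(i)
    list(domains = c(r$domain_a[i], r$domain_b[i]), status = r$status[i],
         effect = r$effect[i]))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Enabled rules as a data.frame, optionally without putative ones.
.enabledRules <- function(rules, includePutative = TRUE) {
  r <- ruleTable(rules)
  r <- r[r$status != "disabled", , drop = FALSE]
  if (!includePutative) r <- r[r$status != "putative", , drop = FALSE]
  r
}

#' Build a domain-rule-justified PPI network
#'
#' An edge is added for every (unordered) pair of nodes, self-pairs included,
#' such that one carries domain d1 and the other d2 for some enabled rule
#' \{d1, d2\}. In qualitative mode proteins are first collapsed to their
#' family labels (CdvA / CdvB / CdvC) and duplicate (family pair, domain
#' pair) edges are deduplicated, so a family counts one polymerization edge
#' regardless of paralog multiplicity; putative rules are excluded from
#' qualitative networks (they are drawn grey, not counted).
#'
#' @param arch an \code{\link{ArchitectureSet}}.
#' @param rules an \code{\link{InteractionRuleSet}} (default
#'   \code{defaultRuleSet()}).
#' @param qualitative logical; collapse proteins to family labels (default
#'   FALSE).
#' @param includePutative logical; include putative-status rules (default:
#'   TRUE at protein level, FALSE in qualitative mode).
#' @return a \code{\link{PPINetwork}}.
#' @export
buildPpiNetwork <- function(arch, rules = defaultRuleSet(),
                            qualitative = FALSE,
                            includePutative = !qualitative) {
  r <- .enabledRules(rules, includePutative)
  p <- proteinTable(arch)
  d <- domainTable(arch)
  if (qualitative) {
    node_of <- ifelse(p$family %in% c("CdvA", "CdvB", "CdvC"), p$family,
                      p$protein_id)
  } else {
    node_of <- p$protein_id
  }
  names(node_of) <- p$protein_id
  nodes <- unique(unname(node_of))
  dom_of_node <- lapply(nodes, function(nd) {
    ids <- p$protein_id[node_of == nd]
    unique(d$domain_type[d$protein_id %in% ids])
  })
  names(dom_of_node) <- nodes
  edges <- list()
  for (i in seq_along(nodes)) for (j in i:length(nodes)) {
    da <- dom_of_node[[i]]; db <- dom_of_node[[j]]
    for (k in seq_len(nrow(r))) {
      hit <- (r$domain_a[k] %in% da && r$domain_b[k] %in% db) ||
        (r$domain_b[k] %in% da && r$domain_a[k] %in% db)
      if (i == j && r$domain_a[k] == r$domain_b[k])
        hit <- r$domain_a[k] %in% da
      if (i == j && r$domain_a[k] != r$domain_b[k])
        hit <- r$domain_a[k] %in% da && r$domain_b[k] %in% da
      if (hit)
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = nodes[i], node_b = nodes[j],
          domain_a = min(r$domain_a[k], r$domain_b[k]),
          domain_b = max(r$domain_a[k], r$domain_b[k]),
          status = r$status[k], effect = r$effect[k],
          stringsAsFactors = FALSE)
    }
  }
  e <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(node_a = character(), node_b = character(),
               domain_a = character(), domain_b = character(),
               status = character(), effect = character(),
               stringsAsFactors = FALSE)
  rownames(e) <- NULL
  methods::new("PPINetwork", nodes = nodes, edges = e,
               qualitative = qualitative)
}

# Affinity tiers used for mechanism tie-breaking; lower = stronger.
# membrane binding (0) > BWI-BWH (1) > Snf7-Snf7 (2) > MIM2/MIM1-MIT (3)
# > Vps4_C-Vps4_C (4).
.affinityTier <- function(domain_a, domain_b) {
  key <- paste(pmin(domain_a, domain_b), pmax(domain_a, domain_b), sep = "-")
  tiers <- c("BWH-BWI" = 1, "Snf7-Snf7" = 2, "MIM2-MIT" = 3, "MIM1-MIT" = 3,
             "Vps4_C-Vps4_C" = 4)
  unname(tiers[key])
}

#' Rank candidate interactions by assumed affinity
#'
#' Total order used to decide which of several possible interactions occurs
#' next: membrane binding first, then BWI-BWH, then Snf7-Snf7 polymerization,
#' then MIM2/MIM1-MIT binding, then Vps4_C-Vps4_C. Within the MIT-binding
#' tier, candidates whose MIM2 carries more prolines rank higher (the
#' four-proline motif of CdvB-class homologs is assumed to out-compete the
#' two-proline motif of CdvB1/2-class homologs); MIM1 candidates, which carry
#' no proline count, rank after counted MIM2 candidates. Remaining ties break
#' lexicographically on the actor and target labels, so the order is
#' deterministic.
#'
#' @param candidates data.frame with columns \code{actor}, \code{target},
#'   \code{domain_a}, \code{domain_b} and optionally \code{proline_count}.
#' @return the same data.frame, reordered (strongest first), with a
#'   \code{tier} column appended.
#' @export
rankAffinity <- function(candidates) {
  if (!nrow(candidates)) return(cbind(candidates, tier = numeric(0)))
  tier <- .affinityTier(candidates$domain_a, candidates$domain_b)
  tier[is.na(tier)] <- 99
  pc <- if (is.null(candidates$proline_count)) rep(NA_real_,
                                                   nrow(candidates)) else
    as.numeric(candidates$proline_count)
  pc[is.na(pc)] <- -Inf
  o <- order(tier, -pc, candidates$actor, candidates$target)
  out <- candidates[o, , drop = FALSE]
  out$tier <- tier[o]
  rownames(out) <- NULL
  out
}
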