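# Generics and accessor/show methods.

#' @rdname ArchitectureSet-class
#' @param x an object with a protein table.
#' @export
setGeneric("proteinTable", function(x) standardGeneric("proteinTable"))

#' @rdname ArchitectureSet-class
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname InteractionRuleSet-class
#' @param x an object with an interaction-rule table.
#' @export
setGeneric("ruleTable", function(x) standardGeneric("ruleTable"))

#' @rdname PPINetwork-class
#' @param x a network or scenario object.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname MechanismScenario-class
#' @param x a scenario object.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname MechanismScenario-class
#' @export
setGeneric("unresolvedProteins",
           function(x) standardGeneric("unresolvedProteins"))

#' @rdname PresenceMatrix-class
#' @param x a presence matrix or reconstruction object.
#' @export
setGeneric("presenceStates", function(x) standardGeneric("presenceStates"))

#' @rdname AncestralReconstruction-class
#' @param x a reconstruction object.
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))

#' @rdname AncestralReconstruction-class
#' @export
setGeneric("parsimonyScores",
           function(x) standardGeneric("parsimonyScores"))

#' @rdname ArchitectureSet-class
#' @export
setMethod("proteinTable", "ArchitectureSet", function(x) x@proteins)

#' @rdname ArchitectureSet-class
#' @export
setMethod("domainTable", "ArchitectureSet", function(x) x@domains)

#' @rdname InteractionRuleSet-class
#' @export
setMethod("ruleTable", "InteractionRuleSet", function(x) x@rules)

#' @rdname PPINetwork-class
#' @export
setMethod("edgeTable", "PPINetwork", function(x) x@edges)

#' @rdname MechanismScenario-class
#' @export
setMethod("eventTable", "MechanismScenario", function(x) x@events)

#' @rdname MechanismScenario-class
#' @export
setMethod("unresolvedProteins", "MechanismScenario", function(x) x@unresolved)

#' @rdname PresenceMatrix-class
#' @export
setMethod("presenceStates", "PresenceMatrix", function(x) x@states)

#' @rdname AncestralReconstruction-class
#' @export
setMethod("nodeStates", "AncestralReconstruction", function(x) x@states)

#' @rdname AncestralReconstruction-class
#' @export
setMethod("parsimonyScores", "AncestralReconstruction", function(x) x@scores)

setMethod("show", "ArchitectureSet", function(object) {
  cat("ArchitectureSet with", nrow(object@proteins), "proteins,",
      nrow(object@domains), "domain instances\n")
  sp <- table(object@proteins$super_phylum)
  if (length(sp))
    cat("  super-phyla:", paste(names(sp), sp, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "InteractionRuleSet", function(object) {
  r <- object@rules
  cat("InteractionRuleSet with", nrow(r), "rules\n")
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s-%s  %s (%s)\n", r$domain_a[i], r$domain_b[i],
                r$effect[i], r$status[i]))
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork (", if (object@qualitative) "qualitative" else "protein",
      " level): ", length(object@nodes), " nodes, ", nrow(object@edges),
      " edges\n", sep = "")
})

setMethod("show", "MechanismScenario", function(object) {
  ev <- object@events
  cat("MechanismScenario (branch", object@branch_id, ") with", nrow(ev),
      "events\n")
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %d. %s(%s%s) [%s]\n", ev$step[i], ev$event[i],
                ev$actor[i],
                ifelse(is.na(ev$target[i]) | ev$target[i] == "", "",
                       paste0(" -> ", ev$target[i])), ev$rule[i]))
  if (length(object@unresolved))
    cat("  unresolved:", paste(object@unresolved, collapse = ", "), "\n")
})

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@states), "taxa x", ncol(object@states),
      "characters\n")
})

setMethod("show", "AncestralReconstruction", function(object) {
  cat("AncestralReconstruction over", ncol(object@states), "characters",
      "(policy:", object@policy, ")\n")
  cat("  total parsimony score:", sum(object@scores), "\n")
})
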