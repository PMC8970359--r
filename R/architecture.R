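# Per-protein domain architectures: assembly (merge of overlapping calls),
# the CdvC homolog filter, the CdvB class taxonomy and table-level summaries.

.evidenceRank <- function(ev) match(ev, .EVIDENCE_LEVELS)  # higher = stronger

# MIM2 class precedence when several regex matches sit on one protein.
.MIM2_PRECEDENCE <- c("MIM2_total", "MIM2_Sulf", "MIM2_Core", "putative_MIM2")

#' Assemble per-protein domain architectures
#'
#' Combines externally produced domain annotations with regex motif matches
#' into one \code{\link{ArchitectureSet}}. Overlapping calls of the same
#' domain type on one protein are merged to a single instance spanning their
#' coordinate union, keeping the strongest contributing evidence
#' (db_scan > motif_regex > ss_annotation > putative). MIM2 motif matches are
#' first deduplicated to one instance per protein using the class precedence
#' total > Sulf > Core > putative; the retained match's proline count is kept.
#' Assembly is idempotent: re-assembling merged output is a no-op.
#'
#' @param annotations data.frame of annotation rows (see
#'   \code{\link{readDomainAnnotations}}); may be NULL.
#' @param motifMatches data.frame from \code{\link{scanMim2}} and/or
#'   \code{\link{detectPutativeMim2}}; may be NULL.
#' @param proteins data.frame of protein metadata (\code{protein_id},
#'   \code{organism}, \code{super_phylum}, \code{family}). When NULL it is
#'   derived from the ids present, with metadata left NA and family
#'   "unassigned".
#' @param sequences optional \code{AAStringSet}; when given, annotations
#'   referencing unknown proteins are an error.
#' @return an \code{\link{ArchitectureSet}}.
#' @export
assembleArchitectures <- function(annotations = NULL, motifMatches = NULL,
                                  proteins = NULL, sequences = NULL) {
  rows <- list()
  if (!is.null(annotations) && nrow(annotations)) {
    .assertDomainTypes(annotations$domain_type)
    if (!is.null(sequences)) {
      miss <- setdiff(annotations$protein_id, names(sequences))
      if (length(miss))
        stop("annotation references unknown protein(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    }
    a <- annotations[, c("protein_id", "domain_type", "start", "end",
                         "evidence")]
    a$proline_count <- if (is.null(annotations$proline_count))
      NA_integer_ else as.integer(annotations$proline_count)
    rows[[length(rows) + 1L]] <- a
  }
  if (!is.null(motifMatches) && nrow(motifMatches)) {
    mm <- motifMatches
    # one MIM2 instance per protein, best class first
    mm <- mm[order(mm$protein_id,
                   match(mm$pattern, .MIM2_PRECEDENCE),
                   mm$start), , drop = FALSE]
    mm <- mm[!duplicated(mm$protein_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = mm$protein_id, domain_type = "MIM2",
      start = mm$start, end = mm$end, evidence = mm$evidence,
      proline_count = as.integer(mm$proline_count),
      stringsAsFactors = FALSE)
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), domain_type = character(),
               start = integer(), end = integer(), evidence = character(),
               proline_count = integer(), stringsAsFactors = FALSE)

  merged <- .mergeSameTypeOverlaps(all_rows)

  if (is.null(proteins)) {
    ids <- unique(c(merged$protein_id,
                    if (!is.null(sequences)) names(sequences)))
    proteins <- data.frame(protein_id = ids, organism = NA_character_,
                           super_phylum = NA_character_,
                           family = "unassigned", stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(merged$protein_id, proteins$protein_id)
    if (length(miss))
      stop("domain calls reference protein(s) missing from metadata: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  architectureSet(proteins, merged)
}

# Merge overlapping same-type instances per protein (coordinate union,
# strongest evidence, max proline count among contributors).
.mergeSameTypeOverlaps <- function(d) {
  if (!nrow(d)) return(d)
  d <- d[order(d$protein_id, d$domain_type, d$start, d$end), , drop = FALSE]
  out <- list()
  split_idx <- split(seq_len(nrow(d)), paste(d$protein_id, d$domain_type,
                                             sep = "\r"))
  for (idx in split_idx) {
    cur <- d[idx[1], ]
    for (i in idx[-1]) {
      row <- d[i, ]
      if (row$start <= cur$end) {  # overlap or containment -> union
        cur$end <- max(cur$end, row$end)
        if (.evidenceRank(row$evidence) > .evidenceRank(cur$evidence))
          cur$evidence <- row$evidence
        pc <- c(cur$proline_count, row$proline_count)
        cur$proline_count <- if (all(is.na(pc))) NA_integer_ else
          max(pc, na.rm = TRUE)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- row
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res$proline_count <- as.integer(res$proline_count)
  rownames(res) <- NULL
  res
}

#' Filter CdvC candidates
#'
#' AAA+ ATPase regions are widespread, so an AAA_ATPase hit alone does not
#' make a CdvC homolog: candidates are kept only when they carry a Vps4_C or
#' a MIT domain, or appear on an explicit allowlist of known exceptions.
#'
#' @param candidates an \code{\link{ArchitectureSet}} of candidate proteins.
#' @param allowlist character vector of protein ids exempt from the rule.
#' @return list with elements \code{kept} (ArchitectureSet) and
#'   \code{rejected} (data.frame with \code{protein_id} and \code{reason}).
#' @export
filterCdvC <- function(candidates, allowlist = character()) {
  p <- proteinTable(candidates)
  d <- domainTable(candidates)
  has <- function(id, type) any(d$domain_type[d$protein_id == id] == type)
  keep <- logical(nrow(p))
  reason <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    id <- p$protein_id[i]
    if (has(id, "Vps4_C") || has(id, "MIT")) {
      keep[i] <- TRUE; reason[i] <- "Vps4_C/MIT"
    } else if (id %in% allowlist) {
      keep[i] <- TRUE; reason[i] <- "allowlist"
    } else {
      reason[i] <- "no Vps4_C or MIT domain"
    }
  }
  kept_ids <- p$protein_id[keep]
  kept <- architectureSet(p[keep, , drop = FALSE],
                          d[d$protein_id %in% kept_ids, , drop = FALSE])
  rejected <- data.frame(protein_id = p$protein_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  attr(kept, "keep_reason") <- stats::setNames(reason[keep], kept_ids)
  list(kept = kept, rejected = rejected)
}

#' Classify CdvB homologs by domain architecture
#'
#' TACK proteins are assigned to the three-class taxonomy: CdvB class
#' (Snf7 + MIM2 + BWH), CdvB1/2 class (Snf7 + MIM2, no BWH, no ANCHR) and
#' CdvB3 class (Snf7 only). Asgard proteins are split by the ANCHR call into
#' CdvBa1 (Snf7 + ANCHR) and CdvBa2 (Snf7 without ANCHR). Proteins matching
#' no rule are "unclassified", never forced. Putative MIM2 instances count as
#' MIM2. Classification is total and deterministic.
#'
#' @param arch an \code{\link{ArchitectureSet}} whose proteins have family
#'   CdvB (others are classified "unclassified").
#' @return data.frame with columns \code{protein_id}, \code{class}.
#' @export
classifyCdvB <- function(arch) {
  p <- proteinTable(arch)
  d <- domainTable(arch)
  cls <- vapply(seq_len(nrow(p)), function(i) {
    id <- p$protein_id[i]
    sp <- p$super_phylum[i]
    dom <- unique(d$domain_type[d$protein_id == id])
    dom <- intersect(dom, domainVocabulary())
    if (!identical(p$family[i], "CdvB")) return("unclassified")
    if (identical(sp, "Asgard")) {
      if ("Snf7" %in% dom && "ANCHR" %in% dom) return("CdvBa1")
      if ("Snf7" %in% dom) return("CdvBa2")
      return("unclassified")
    }
    if (sp %in% c("TACK_Crenarchaeota", "TACK_Thaumarchaeota")) {
      if (all(c("Snf7", "MIM2", "BWH") %in% dom)) return("CdvB_class")
      if (all(c("Snf7", "MIM2") %in% dom) && !("BWH" %in% dom) &&
            !("ANCHR" %in% dom)) return("CdvB12_class")
      if (identical(sort(dom), "Snf7")) return("CdvB3_class")
      return("unclassified")
    }
    "unclassified"
  }, "")
  data.frame(protein_id = p$protein_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Domains shared by every organism group
#'
#' Returns the domain types present in at least one organism of every group
#' of a partition (e.g. the three super-phyla); across the bundled reference
#' table this intersection is \{Snf7, AAA_ATPase, MIT, Vps4_C\}.
#'
#' @param arch an \code{\link{ArchitectureSet}}.
#' @param groups named character vector or factor mapping every organism in
#'   the table to exactly one group.
#' @return character vector of shared domain types.
#' @export
sharedDomains <- function(arch, groups) {
  p <- proteinTable(arch)
  d <- domainTable(arch)
  orgs <- unique(p$organism)
  miss <- setdiff(orgs, names(groups))
  if (length(miss))
    stop("organism(s) missing from groups: ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- as.character(groups[orgs])
  names(groups) <- orgs
  per_group <- split(orgs, groups)
  if (any(!lengths(per_group)))
    stop("empty group in partition", call. = FALSE)
  dom_of_org <- function(os) {
    ids <- p$protein_id[p$organism %in% os]
    unique(d$domain_type[d$protein_id %in% ids])
  }
  sets <- lapply(per_group, dom_of_org)
  Reduce(intersect, sets)
}

#' Count organisms with and without Cdv homologs
#'
#' An organism counts as "with" when it has at least one protein of family
#' CdvA, CdvB or CdvC.
#'
#' @param arch an \code{\link{ArchitectureSet}}.
#' @return named integer vector \code{c(with = ..., without = ...)}.
#' @export
organismsWithHomologs <- function(arch) {
  p <- proteinTable(arch)
  if (!nrow(p)) stop("empty architecture table", call. = FALSE)
  has_cdv <- tapply(p$family %in% c("CdvA", "CdvB", "CdvC"), p$organism, any)
  c(with = sum(has_cdv), without = sum(!has_cdv))
}

#' Classify Cdv gene neighbourhoods
#'
#' For each organism, genes are ranked along the chromosome by start
#' coordinate and the minimal pairwise rank distance among Cdv genes is
#' bucketed: \code{<= directK} is "direct", \code{<= closeK} "close",
#' otherwise "distant"; organisms with fewer than two Cdv genes are
#' "absent". Thresholds are package defaults.
#'
#' @param coords data.frame with columns \code{organism}, \code{gene_id},
#'   \code{start} (any additional columns are ignored).
#' @param families named character vector mapping gene_id to family
#'   (CdvA/CdvB/CdvC); genes absent from the map are non-Cdv.
#' @param directK rank distance treated as direct neighbourhood (default 1).
#' @param closeK rank distance treated as close neighbourhood (default 5).
#' @return data.frame with columns \code{organism}, \code{min_distance},
#'   \code{classification}.
#' @export
geneNeighborhood <- function(coords, families, directK = 1L, closeK = 5L) {
  need <- c("organism", "gene_id", "start")
  if (!all(need %in% names(coords)))
    stop("coords needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(coords, coords$organism), function(g) {
    if (anyDuplicated(g$start))
      stop("duplicate gene coordinates in organism ", g$organism[1],
           call. = FALSE)
    g <- g[order(g$start), ]
    rank <- seq_len(nrow(g))
    cdv <- rank[g$gene_id %in% names(families)]
    if (length(cdv) < 2L)
      return(data.frame(organism = g$organism[1], min_distance = NA_integer_,
                        classification = "absent", stringsAsFactors = FALSE))
    dmin <- min(diff(sort(cdv)))
    cl <- if (dmin <= directK) "direct" else if (dmin <= closeK) "close"
      else "distant"
    data.frame(organism = g$organism[1], min_distance = dmin,
               classification = cl, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
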