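# Synthetic-data generators: sequences with planted MIM2/ANCHR features and
# binary domain evolution on a tree. Fully deterministic under a fixed seed;
# no hidden global RNG state is left behind.

#' Generate protein sequences with planted motifs
#'
#' Background residues are drawn i.i.d. uniformly from
#' \code{backgroundAlphabet} (uniform rather than an empirical archaeal
#' composition: a simpler null). Planted MIM2 motifs are instantiated by
#' sampling the phi/x template positions uniformly from their residue
#' classes; literal-P positions are always proline, so motif recall is 1 by
#' construction and, when the background excludes P, precision is 1 as well.
#' Optionally an ANCHR-like N-terminal helix is written into the
#' secondary-structure track (an H-run of \code{anchr$helixLen} within the
#' first 30 residues), with or without an interior helix-breaking proline.
#'
#' @param nProteins number of sequences.
#' @param lengthRange integer length 2; lengths are sampled uniformly in this
#'   range (default c(120, 200)).
#' @param backgroundAlphabet residue set for the background (default the 20
#'   amino acids; pass e.g. \code{setdiff(aminoAcids(), "P")} for a
#'   proline-free background).
#' @param planted list of plant specifications, each
#'   \code{list(pattern = <MIM2 pattern name or literal span>,
#'   position = "nterm"|"cterm"|"uniform")}; every spec is planted once per
#'   protein.
#' @param anchr NULL or \code{list(helixLen = 10, withProline = FALSE)}.
#' @param seed integer seed; fully determines the output.
#' @return list with elements \code{sequences} (\code{AAStringSet}),
#'   \code{truth} (data.frame of planted matches in \code{\link{scanMim2}}
#'   shape) and \code{ss} (named character vector of H/E/C tracks).
#' @export
simulateSequences <- function(nProteins, lengthRange = c(120L, 200L),
                              backgroundAlphabet = aminoAcids(),
                              planted = list(), anchr = NULL, seed = 1L) {
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2])
  plant_len <- function(p) {
    if (p$pattern %in% names(mim2Patterns()))
      nchar(mim2Patterns()[[p$pattern]]) else nchar(p$pattern)
  }
  max_plant <- if (length(planted)) max(vapply(planted, plant_len, 0L)) else 0L
  if (max_plant > lengthRange[1])
    stop("planted span longer than minimum sequence length", call. = FALSE)
  .withSeed(seed, {
    seqs <- character(nProteins)
    ss <- character(nProteins)
    truth <- list()
    ids <- sprintf("sim%03d", seq_len(nProteins))
    for (i in seq_len(nProteins)) {
      L <- if (lengthRange[1] == lengthRange[2]) lengthRange[1] else
        sample(lengthRange[1]:lengthRange[2], 1L)
      chars <- sample(backgroundAlphabet, L, replace = TRUE)
      track <- rep("C", L)
      reserved <- rep(FALSE, L)
      if (!is.null(anchr)) {
        hl <- anchr$helixLen %||% 10L
        if (hl < 8L) stop("anchr helixLen must be >= 8", call. = FALSE)
        h_start <- 3L
        h_end <- min(h_start + hl - 1L, min(30L, L))
        track[h_start:h_end] <- "H"
        no_p <- setdiff(backgroundAlphabet, "P")
        chars[1:min(30L, L)] <-
          sample(no_p, min(30L, L), replace = TRUE)
        if (isTRUE(anchr$withProline))
          chars[h_start + (h_end - h_start) %/% 2L] <- "P"
        reserved[1:min(30L, L)] <- TRUE
      }
      for (p in planted) {
        len <- plant_len(p)
        pos_policy <- p$position %||% "uniform"
        lo <- switch(pos_policy,
                     nterm = 1L,
                     cterm = max(1L, L - max(len, ceiling(L / 3L)) + 1L),
                     uniform = 1L)
        hi <- switch(pos_policy,
                     nterm = max(lo, min(L - len + 1L, ceiling(L / 3L))),
                     cterm = L - len + 1L,
                     uniform = L - len + 1L)
        # avoid reserved (ANCHR) prefix where possible
        cand <- lo:hi
        free <- cand[vapply(cand, function(st)
          !any(reserved[st:(st + len - 1L)]), TRUE)]
        st <- if (length(free)) free[sample.int(length(free), 1L)] else
          cand[sample.int(length(cand), 1L)]
        if (p$pattern %in% names(mim2Patterns())) {
          tpl <- strsplit(mim2Patterns()[[p$pattern]], "")[[1]]
          inst <- vapply(tpl, function(sym) switch(sym,
            f = sample(.PHI_SET, 1L), x = sample(.X_SET, 1L), P = "P"), "")
          chars[st:(st + len - 1L)] <- inst
          span <- paste(inst, collapse = "")
          truth[[length(truth) + 1L]] <- data.frame(
            protein_id = ids[i], pattern = p$pattern, start = st,
            end = st + len - 1L, span = span,
            proline_count = .countP(span), evidence = "motif_regex",
            stringsAsFactors = FALSE)
        } else {
          chars[st:(st + len - 1L)] <- strsplit(p$pattern, "")[[1]]
          truth[[length(truth) + 1L]] <- data.frame(
            protein_id = ids[i], pattern = "literal", start = st,
            end = st + len - 1L, span = p$pattern,
            proline_count = .countP(p$pattern), evidence = "motif_regex",
            stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      ss[i] <- paste(track, collapse = "")
    }
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- ids
    truth_df <- if (length(truth)) do.call(rbind, truth) else .emptyMatches()
    rownames(truth_df) <- NULL
    list(sequences = sequences, truth = truth_df,
         ss = stats::setNames(ss, ids))
  })
}

#' The 20-letter amino-acid alphabet
#' @return character vector of the 20 standard residues.
#' @export
aminoAcids <- function() .AA20

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate binary domain evolution along a rooted tree
#'
#' States evolve from the root towards the leaves: on each branch a present
#' character is lost with probability \code{lossProb} and an absent one
#' gained with probability \code{gainProb}, independently per character and
#' branch. Leaves are collected into one \code{\link{PresenceMatrix}} per
#' replicate.
#'
#' @param tree a rooted \code{ape::phylo} tree.
#' @param rootStates named 0/1 vector, one entry per character.
#' @param gainProb per-branch 0 -> 1 probability.
#' @param lossProb per-branch 1 -> 0 probability.
#' @param nReplicates number of independent replicates.
#' @param seed integer seed; fully determines the output.
#' @return list of \code{\link{PresenceMatrix}} objects, length
#'   \code{nReplicates}.
#' @export
simulateDomainEvolution <- function(tree, rootStates, gainProb = 0,
                                    lossProb = 0.1, nReplicates = 1L,
                                    seed = 1L) {
  stopifnot(gainProb >= 0, gainProb <= 1, lossProb >= 0, lossProb <= 1)
  tree <- .labelledTree(tree)
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  chars <- names(rootStates)
  if (is.null(chars)) stop("rootStates must be named by character",
                           call. = FALSE)
  tr2 <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- tr2$edge[rev(seq_len(nrow(tr2$edge))), , drop = FALSE]
  .withSeed(seed, {
    lapply(seq_len(nReplicates), function(rep_i) {
      node_states <- matrix(0L, n_nodes, length(chars))
      node_states[root, ] <- as.integer(rootStates)
      for (e in seq_len(nrow(pre_edges))) {
        u <- pre_edges[e, 1]; v <- pre_edges[e, 2]
        s <- node_states[u, ]
        flip_up <- stats::runif(length(chars)) < gainProb
        flip_down <- stats::runif(length(chars)) < lossProb
        node_states[v, ] <- ifelse(s == 1L,
                                   ifelse(flip_down, 0L, 1L),
                                   ifelse(flip_up, 1L, 0L))
      }
      m <- node_states[seq_len(n_tip), , drop = FALSE]
      dimnames(m) <- list(tree$tip.label, chars)
      methods::new("PresenceMatrix", states = m)
    })
  })
}

#' Ancestral Cdv protein sets of the three super-phylum groups
#'
#' The protein complements most likely present in the last common ancestor
#' of Crenarchaeota (CdvA with BWI; the three CdvB classes; CdvC), of
#' Thaumarchaeota (CdvA with MIM2; one CdvB; CdvC) and of Asgard archaea
#' (no CdvA; the CdvBa1/CdvBa2 pair; CdvC). MIM2 instances carry the class
#' proline counts (4 for CdvB-class motifs, 2 for CdvB1/2-class and the
#' other two-proline motifs) that drive affinity tie-breaking in mechanism
#' inference.
#'
#' @return named list of three \code{\link{ArchitectureSet}} objects:
#'   Crenarchaeota, Thaumarchaeota, Asgard.
#' @export
ancestralProteinSets <- function() {
  mk <- function(org, sp, fam_dom) {
    proteins <- data.frame(
      protein_id = names(fam_dom), organism = org, super_phylum = sp,
      family = vapply(fam_dom, `[[`, "", "family"),
      stringsAsFactors = FALSE)
    dom_rows <- do.call(rbind, lapply(names(fam_dom), function(id) {
      d <- fam_dom[[id]]$domains
      data.frame(protein_id = id, domain_type = names(d),
                 start = unname(vapply(d, `[`, 0L, 1L)),
                 end = unname(vapply(d, `[`, 0L, 2L)),
                 evidence = "db_scan",
                 proline_count = unname(vapply(d, `[`, 0L, 3L)),
                 stringsAsFactors = FALSE)
    }))
    dom_rows$proline_count[dom_rows$proline_count == 0L] <- NA_integer_
    architectureSet(proteins, dom_rows)
  }
  # domains: name -> c(start, end, proline_count-or-0)
  cren <- mk("ancestral Crenarchaeon", "TACK_Crenarchaeota", list(
    CdvA = list(family = "CdvA", domains = list(
      CdvA_alpha = c(10L, 150L, 0L), CdvA_beta = c(160L, 240L, 0L),
      BWI = c(245L, 255L, 0L))),
    CdvB = list(family = "CdvB", domains = list(
      Snf7 = c(5L, 170L, 0L), BWH = c(175L, 215L, 0L),
      MIM2 = c(220L, 229L, 4L))),
    `CdvB1/2` = list(family = "CdvB", domains = list(
      Snf7 = c(5L, 170L, 0L), MIM2 = c(200L, 209L, 2L))),
    CdvB3 = list(family = "CdvB", domains = list(Snf7 = c(5L, 170L, 0L))),
    CdvC = list(family = "CdvC", domains = list(
      MIT = c(5L, 80L, 0L), AAA_ATPase = c(100L, 300L, 0L),
      Vps4_C = c(320L, 365L, 0L)))))
  thaum <- mk("ancestral Thaumarchaeon", "TACK_Thaumarchaeota", list(
    CdvA = list(family = "CdvA", domains = list(
      CdvA_alpha = c(10L, 150L, 0L), CdvA_beta = c(160L, 240L, 0L),
      MIM2 = c(250L, 259L, 4L))),
    CdvB = list(family = "CdvB", domains = list(
      Snf7 = c(5L, 170L, 0L), MIM2 = c(200L, 209L, 2L))),
    CdvC = list(family = "CdvC", domains = list(
      MIT = c(5L, 80L, 0L), AAA_ATPase = c(100L, 300L, 0L),
      Vps4_C = c(320L, 365L, 0L)))))
  asgard <- mk("ancestral Asgard archaeon", "Asgard", list(
    CdvBa1 = list(family = "CdvB", domains = list(
      ANCHR = c(1L, 25L, 0L), Snf7 = c(30L, 190L, 0L),
      MIM1 = c(200L, 215L, 0L))),
    CdvBa2 = list(family = "CdvB", domains = list(
      Snf7 = c(25L, 185L, 0L), MIM2 = c(200L, 209L, 2L))),
    CdvC = list(family = "CdvC", domains = list(
      MIT = c(5L, 80L, 0L), AAA_ATPase = c(100L, 300L, 0L),
      Vps4_C = c(320L, 365L, 0L)))))
  list(Crenarchaeota = cren, Thaumarchaeota = thaum, Asgard = asgard)
}
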