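# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the motif oracle is a symbol-by-symbol sliding
# window (no regular expressions), the parsimony oracle enumerates all
# internal labelings.

PHI_ORACLE <- strsplit("AILMFVPGW", "")[[1]]
X_ORACLE <- strsplit("RKDE", "")[[1]]
TEMPLATES_ORACLE <- c(MIM2_Core = "fPxfP", MIM2_total = "fPxfPxxPfP",
                      MIM2_Sulf = "xfxxffPxfPxfP")

oracleScanMim2 <- function(seq, patterns = names(TEMPLATES_ORACLE)) {
  chars <- strsplit(seq, "")[[1]]
  out <- list()
  for (p in patterns) {
    tpl <- strsplit(TEMPLATES_ORACLE[[p]], "")[[1]]
    k <- length(tpl)
    if (length(chars) < k) next
    for (st in seq_len(length(chars) - k + 1L)) {
      w <- chars[st:(st + k - 1L)]
      ok <- TRUE
      for (j in seq_len(k)) {
        ok <- switch(tpl[j],
                     f = w[j] %in% PHI_ORACLE,
                     x = w[j] %in% X_ORACLE,
                     P = w[j] == "P")
        if (!ok) break
      }
      if (ok)
        out[[length(out) + 1L]] <- data.frame(
          pattern = p, start = st, end = st + k - 1L,
          span = paste(w, collapse = ""), proline_count = sum(w == "P"),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pattern = character(), start = integer(),
                      end = integer(), span = character(),
                      proline_count = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, match(res$pattern, names(TEMPLATES_ORACLE))), ,
      drop = FALSE]
}

# Exact minimum-change parsimony by enumeration of all internal labelings.
bruteParsimony <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  best <- Inf
  root_set <- integer(0)
  node_sets <- vector("list", n_tip + n_int)
  for (r in seq_len(nrow(combos))) {
    lab <- c(unname(leaf_states[tree$tip.label]), combos[r, ])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) {
      best <- changes
      node_sets <- lapply(lab, identity)
    } else if (changes == best) {
      node_sets <- mapply(function(s, l) union(s, l), node_sets, lab,
                          SIMPLIFY = FALSE)
    }
  }
  list(score = best,
       sets = lapply(node_sets, function(s) sort(unlist(s))))
}

# Random rooted tree with n tips; with prob. poly_frac each internal edge is
# collapsed, producing polytomies.
randomTree <- function(n, poly_frac = 0.3) {
  tr <- ape::rtree(n)
  if (n > 2 && poly_frac > 0) {
    internal <- which(tr$edge[, 2] > length(tr$tip.label))
    collapse <- internal[stats::runif(length(internal)) < poly_frac]
    tr$edge.length[collapse] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
  }
  tr
}

# Random ArchitectureSet: n proteins with random domain subsets.
randomArchitectureSet <- function(n_prot, organisms = c("orgA", "orgB")) {
  vocab <- domainVocabulary()
  rows <- list()
  prot <- data.frame(protein_id = sprintf("p%02d", seq_len(n_prot)),
                     organism = sample(organisms, n_prot, replace = TRUE),
                     super_phylum = sample(superPhyla(), n_prot,
                                           replace = TRUE),
                     family = sample(c("CdvA", "CdvB", "CdvC"), n_prot,
                                     replace = TRUE),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_prot)) {
    k <- sample(0:4, 1)
    if (!k) next
    doms <- sample(vocab, k)
    for (j in seq_along(doms)) {
      st <- 10L * j
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = prot$protein_id[i], domain_type = doms[j],
        start = st, end = st + 8L, evidence = "db_scan",
        proline_count = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  architectureSet(prot, if (length(rows)) do.call(rbind, rows) else NULL)
}

randomSequence <- function(len, alphabet = aminoAcids()) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

readNewickTreeText <- function(txt) ape::read.tree(text = txt)
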