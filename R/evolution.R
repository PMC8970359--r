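# Maximum-parsimony reconstruction of binary domain presence/absence on a
# rooted tree, and gain/loss event mapping.
#
# Scoring uses unit-cost Sankoff dynamic programming with an up/down pass,
# which is exact on polytomies and reduces to Fitch on binary trees. The
# per-node state set holds every state that appears in at least one
# most-parsimonious labeling; nodes whose set has both states are reported
# "ambiguous" until a resolution policy is applied.

# Ensure every node of a phylo tree carries a label; internal nodes without
# one get "node<K>" (K = node number).
.labelledTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object",
                                     call. = FALSE)
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label) || !length(tree$node.label))
    tree$node.label <- rep("", tree$Nnode)
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- paste0("node", which(blank) + n_tip)
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("node labels must be unique", call. = FALSE)
  tree
}

.nodeLabels <- function(tree) c(tree$tip.label, tree$node.label)

# Children list indexed by node number.
.childrenList <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# Unit-cost Sankoff up/down pass for one binary character.
# leaf_states: named 0/1 vector covering all tips.
# Returns list(score, sets) where sets[[v]] is the vector of states (0/1)
# attainable at node v in some most-parsimonious labeling.
.sankoff <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  ch <- .childrenList(tree)
  tr2 <- ape::reorder.phylo(tree, "postorder")
  up <- matrix(Inf, n_nodes, 2)  # columns: state 0, state 1
  for (i in seq_len(n_tip)) {
    s <- leaf_states[[tree$tip.label[i]]]
    up[i, s + 1L] <- 0
  }
  parents <- unique(tr2$edge[, 1])  # postorder guarantee: children first
  for (v in parents) {
    acc <- c(0, 0)
    for (c_ in ch[[v]]) {
      # min over child state of child cost + mismatch
      acc <- acc + c(min(up[c_, 1], up[c_, 2] + 1),
                     min(up[c_, 2], up[c_, 1] + 1))
    }
    up[v, ] <- acc
  }
  score <- min(up[root, ])
  # down pass: down[v, s] = best cost of the tree outside v's subtree with
  # v in state s (cost of edge above v included).
  down <- matrix(0, n_nodes, 2)
  pre <- rev(parents)  # root first
  for (v in pre) {
    kids <- ch[[v]]
    # per-parent-state contribution of each child
    contrib <- lapply(kids, function(c_)
      c(min(up[c_, 1], up[c_, 2] + 1), min(up[c_, 2], up[c_, 1] + 1)))
    total <- Reduce(`+`, contrib)
    for (i in seq_along(kids)) {
      c_ <- kids[i]
      sib <- total - contrib[[i]]
      for (s in 0:1) {
        # parent state t: down[v,t] + siblings given t + edge (t -> s)
        down[c_, s + 1L] <- min(
          down[v, 1] + sib[1] + (s != 0),
          down[v, 2] + sib[2] + (s != 1))
      }
    }
  }
  sets <- lapply(seq_len(n_nodes), function(v) {
    tot <- up[v, ] + down[v, ]
    which(tot == score) - 1L
  })
  list(score = as.integer(score), sets = sets, up = up)
}

#' Maximum-parsimony ancestral reconstruction of domain presence
#'
#' Reconstructs ancestral presence/absence of each binary character on a
#' rooted tree (polytomies allowed) by exact minimum-change parsimony.
#' Nodes whose most-parsimonious state is not unique are reported
#' "ambiguous"; no ACCTRAN/DELTRAN-style resolution is imposed. Branch
#' lengths are ignored.
#'
#' @param tree a rooted \code{ape::phylo} tree.
#' @param matrix a \code{\link{PresenceMatrix}} whose taxa match the tree
#'   leaves exactly.
#' @param characters subset of characters to reconstruct (default: all).
#' @return an \code{\link{AncestralReconstruction}} with policy "none".
#' @export
fitchReconstruction <- function(tree, matrix,
                                characters = colnames(presenceStates(matrix))) {
  tree <- .labelledTree(tree)
  states <- presenceStates(matrix)
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss))
    stop("leaf missing from presence matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(characters, colnames(states))
  if (length(bad))
    stop("unknown character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_nodes <- length(tree$tip.label) + tree$Nnode
  out <- matrix("ambiguous", n_nodes, length(characters),
                dimnames = list(.nodeLabels(tree), characters))
  scores <- stats::setNames(integer(length(characters)), characters)
  for (k in characters) {
    leaf <- stats::setNames(states[tree$tip.label, k], tree$tip.label)
    res <- .sankoff(tree, leaf)
    scores[k] <- res$score
    out[, k] <- vapply(res$sets, function(s)
      if (length(s) == 2L) "ambiguous" else as.character(s), "")
  }
  methods::new("AncestralReconstruction", tree = tree, states = out,
               scores = scores,
               events = data.frame(branch = character(),
                                   character = character(),
                                   type = character(),
                                   stringsAsFactors = FALSE),
               policy = "none")
}

# Resolve one character top-down into a concrete most-parsimonious labeling
# consistent with a fixed root state (conditional-optimal choice per child,
# ties resolved toward the parent state).
.resolveTopDown <- function(tree, leaf_states, root_state) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  res <- .sankoff(tree, leaf_states)
  up <- res$up
  ch <- .childrenList(tree)
  assign_ <- integer(n_nodes)
  assign_[root] <- root_state
  tr2 <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(unique(tr2$edge[, 1]))
  for (v in pre) {
    t <- assign_[v]
    for (c_ in ch[[v]]) {
      cost0 <- up[c_, 1] + (t != 0)
      cost1 <- up[c_, 2] + (t != 1)
      assign_[c_] <- if (cost0 < cost1) 0L else if (cost1 < cost0) 1L else t
    }
  }
  assign_
}

#' Resolve ambiguous ancestral states
#'
#' Three policies. \code{"none"} keeps ambiguity. \code{"dollo_single_gain"}
#' forces, per character, a unique gain on the branch into the most recent
#' common ancestor of the presence leaves, with losses placed as shallowly as
#' possible below it. \code{"presence_bias"} resolves an ambiguous root to
#' present for characters carrying auxiliary evidence (e.g. gene-cluster
#' co-location of the encoding genes) and to absent otherwise, then resolves
#' the remaining nodes to a most-parsimonious labeling consistent with that
#' root (ties toward the parent state).
#'
#' @param recon an \code{\link{AncestralReconstruction}} from
#'   \code{\link{fitchReconstruction}}.
#' @param policy one of "none", "dollo_single_gain", "presence_bias".
#' @param biasCharacters characters whose ambiguous root resolves to present
#'   under "presence_bias".
#' @param matrix the \code{\link{PresenceMatrix}} used for the
#'   reconstruction (needed to re-derive labelings; required for policies
#'   other than "none").
#' @return a resolved \code{\link{AncestralReconstruction}}.
#' @export
resolveRoot <- function(recon, policy = c("none", "dollo_single_gain",
                                          "presence_bias"),
                        biasCharacters = character(), matrix = NULL) {
  policy <- match.arg(policy)
  if (policy == "none") return(recon)
  if (is.null(matrix))
    stop("matrix is required for policy '", policy, "'", call. = FALSE)
  tree <- recon@tree
  states <- presenceStates(matrix)
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  out <- recon@states
  scores <- recon@scores
  ch <- .childrenList(tree)
  for (k in colnames(out)) {
    leaf <- stats::setNames(states[tree$tip.label, k], tree$tip.label)
    if (policy == "dollo_single_gain") {
      ones <- tree$tip.label[leaf == 1L]
      assign_ <- integer(n_nodes)
      if (length(ones)) {
        mrca <- if (length(ones) == 1L) match(ones, tree$tip.label) else
          ape::getMRCA(tree, ones)
        # presence on nodes inside the mrca subtree that still have a
        # presence leaf below (or are such a leaf)
        has_one_below <- logical(n_nodes)
        tr2 <- ape::reorder.phylo(tree, "postorder")
        has_one_below[seq_len(n_tip)] <- leaf[tree$tip.label] == 1L
        for (v in unique(tr2$edge[, 1]))
          has_one_below[v] <- any(has_one_below[ch[[v]]])
        in_subtree <- logical(n_nodes)
        in_subtree[mrca] <- TRUE
        pre <- rev(unique(tr2$edge[, 1]))
        for (v in pre) for (c_ in ch[[v]])
          if (in_subtree[v]) in_subtree[c_] <- TRUE
        assign_ <- as.integer(in_subtree & has_one_below)
        # event count under Dollo resolution
        n_loss <- sum(vapply(seq_len(nrow(tree$edge)), function(i) {
          u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
          assign_[u] == 1L && assign_[v] == 0L
        }, TRUE))
        scores[k] <- 1L + n_loss
      } else scores[k] <- 0L
      out[, k] <- as.character(assign_)
    } else {  # presence_bias
      root_cell <- out[root, k]
      root_state <- if (root_cell == "ambiguous") {
        if (k %in% biasCharacters) 1L else 0L
      } else as.integer(root_cell)
      out[, k] <- as.character(.resolveTopDown(tree, leaf, root_state))
    }
  }
  methods::new("AncestralReconstruction", tree = tree, states = out,
               scores = scores, events = recon@events, policy = policy)
}

#' Map gain/loss events onto branches
#'
#' For a fully resolved reconstruction, emits one event per branch whose two
#' endpoint states differ: a gain where absence turns to presence and a loss
#' where presence turns to absence. For a character whose state is 1 at the
#' root itself no gain branch exists.
#'
#' @param recon a resolved \code{\link{AncestralReconstruction}}.
#' @return data.frame with columns \code{branch} (label of the child node of
#'   the branch), \code{character}, \code{type} ("gain"/"loss").
#' @export
mapEvents <- function(recon) {
  states <- recon@states
  amb <- which(states == "ambiguous", arr.ind = TRUE)
  if (nrow(amb))
    stop("ambiguous states remain at node(s): ",
         paste(unique(rownames(states)[amb[, 1]]), collapse = ", "),
         "; apply a resolution policy first", call. = FALSE)
  tree <- recon@tree
  labels <- .nodeLabels(tree)
  out <- list()
  for (k in colnames(states)) {
    s <- as.integer(states[, k])
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      if (s[u] != s[v])
        out[[length(out) + 1L]] <- data.frame(
          branch = labels[v], character = k,
          type = if (s[v] == 1L) "gain" else "loss",
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(branch = character(), character = character(),
               type = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Ancestral domain architecture at a node
#'
#' Characters reconstructed as present at the node, grouped by their family
#' qualifier (the part before ":" in family-qualified character names).
#'
#' @param recon a resolved \code{\link{AncestralReconstruction}}.
#' @param node node label (tip or internal).
#' @return named list: family -> character vector of domain types.
#' @export
ancestralArchitecture <- function(recon, node) {
  states <- recon@states
  if (!node %in% rownames(states))
    stop("unknown node: ", node, call. = FALSE)
  present <- colnames(states)[states[node, ] == "1"]
  if (any(states[node, ] == "ambiguous"))
    stop("node ", node, " has ambiguous states; resolve first",
         call. = FALSE)
  fam <- sub(":.*$", "", present)
  dom <- sub("^[^:]*:", "", present)
  split(dom, fam)
}
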