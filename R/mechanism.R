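# Recursive mechanism inference: from a membrane-bound starting protein,
# expand the interaction network step by step, taking the highest-affinity
# enabled interaction at each state and forking a scenario only at documented
# ambiguity points (a putative-status move competing with a validated
# MIT-tier move). Deterministic throughout.

# Internal protein view: list(name, domains, family, mim2_prolines,
# disassembler, membrane).
.proteinViews <- function(arch) {
  p <- proteinTable(arch)
  d <- domainTable(arch)
  views <- lapply(seq_len(nrow(p)), function(i) {
    id <- p$protein_id[i]
    dd <- d[d$protein_id == id, , drop = FALSE]
    mim2_p <- dd$proline_count[dd$domain_type == "MIM2"]
    mim2_p <- if (length(mim2_p) && !all(is.na(mim2_p)))
      max(mim2_p, na.rm = TRUE) else NA_integer_
    doms <- unique(dd$domain_type)
    list(name = id, domains = doms, family = p$family[i],
         mim2_prolines = mim2_p,
         disassembler = all(c("MIT", "AAA_ATPase") %in% doms),
         membrane = any(c("ANCHR", "CdvA_beta") %in% doms))
  })
  names(views) <- p$protein_id
  views
}

# Binding-rule lookup between two domain vectors; returns best rule row or
# NULL. Validated preferred over putative.
.bindingRulesBetween <- function(rules, da, db) {
  r <- rules[rules$effect == "binding", , drop = FALSE]
  hits <- r[(r$domain_a %in% da & r$domain_b %in% db) |
              (r$domain_b %in% da & r$domain_a %in% db), , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits[order(hits$status != "validated",
             .affinityTier(hits$domain_a, hits$domain_b)), , drop = FALSE]
}

.ruleLabel <- function(a, b) paste(min(a, b), max(a, b), sep = "-")

# Static disassembly-route analysis: a protein is resolvable when it can be
# removed from the division site - it is itself a MIT+AAA disassembler, it
# carries a motif with an enabled binding rule to MIT while a disassembler
# exists, or it is tethered through an enabled BWI/BWH link to a resolvable
# protein (it leaves with its tether).
.unresolvedProteins <- function(views, rules) {
  has_disassembler <- any(vapply(views, `[[`, TRUE, "disassembler"))
  mit_partners <- rules$domain_a[rules$effect == "binding" &
                                   rules$domain_b == "MIT"]
  mit_partners <- c(mit_partners,
                    rules$domain_b[rules$effect == "binding" &
                                     rules$domain_a == "MIT"])
  resolvable <- vapply(views, function(v) {
    v$disassembler ||
      (has_disassembler && any(v$domains %in% mit_partners))
  }, TRUE)
  bwi_enabled <- any((rules$domain_a == "BWI" & rules$domain_b == "BWH") |
                       (rules$domain_a == "BWH" & rules$domain_b == "BWI"))
  if (bwi_enabled) {
    repeat {
      changed <- FALSE
      for (nm in names(views)) {
        if (resolvable[nm]) next
        v <- views[[nm]]
        mine <- intersect(v$domains, c("BWI", "BWH"))
        if (!length(mine)) next
        partner_dom <- setdiff(c("BWI", "BWH"), mine)
        partners <- names(views)[vapply(views, function(w)
          any(partner_dom %in% w$domains), TRUE)]
        if (any(resolvable[partners])) {
          resolvable[nm] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  names(resolvable)[!resolvable]
}

#' Infer assembly/disassembly mechanism scenarios
#'
#' Depth-first expansion from a designated membrane-binding starting protein.
#' At every state the enabled candidate moves (recruitment through a binding
#' rule, ring formation through a polymerization rule) are collected,
#' candidates recruiting the same protein are collapsed to one event, and the
#' strongest candidate under \code{\link{rankAffinity}} is executed. A
#' putative-status move (such as CdvA_beta self-polymerization) is dominated
#' by validated moves of the BWI-BWH or Snf7-Snf7 tiers but incomparable with
#' MIT-binding-tier moves: there the expansion forks into one scenario per
#' choice, up to \code{maxBranches}. When a MIT+AAA_ATPase protein binds a
#' partner on an assembled ring, disassembly fires immediately, removing
#' partners in affinity order (MIM2 partners by descending proline count,
#' then MIM1 partners); a disassembler that instead recruited a further
#' protein through its MIT acts as a linker and cannot also disassemble.
#' Proteins with no enabled disassembly route are reported in
#' \code{unresolved}.
#'
#' @param arch an \code{\link{ArchitectureSet}} of the proteins in play.
#' @param rules an \code{\link{InteractionRuleSet}} (default
#'   \code{defaultRuleSet()}; putative rules are enabled for mechanism
#'   inference).
#' @param start protein id of the initiating protein, or \code{"auto"} to
#'   pick the unique membrane-binding protein (one carrying ANCHR or
#'   CdvA_beta).
#' @param maxBranches cap on the number of scenarios (default 8).
#' @return list of \code{\link{MechanismScenario}} objects, deterministic in
#'   content and order.
#' @export
inferMechanism <- function(arch, rules = defaultRuleSet(), start = "auto",
                           maxBranches = 8L) {
  views <- .proteinViews(arch)
  r <- .enabledRules(rules, includePutative = TRUE)
  if (identical(start, "auto")) {
    mb <- names(views)[vapply(views, `[[`, TRUE, "membrane")]
    if (length(mb) != 1L)
      stop("start = 'auto' needs exactly one membrane-binding protein; ",
           "found: ", if (length(mb)) paste(mb, collapse = ", ") else "none",
           call. = FALSE)
    start <- mb
  }
  if (!start %in% names(views))
    stop("unknown starting protein: ", start, call. = FALSE)
  unresolved <- sort(.unresolvedProteins(views, r))

  scenarios <- list()

  emit <- function(events) {
    ev <- do.call(rbind, events)
    ev$step <- seq_len(nrow(ev))
    ev <- ev[, c("step", "event", "actor", "target", "rule")]
    rownames(ev) <- NULL
    scenarios[[length(scenarios) + 1L]] <<- ev
  }

  evrow <- function(event, actor, target, rule)
    data.frame(event = event, actor = actor, target = target, rule = rule,
               stringsAsFactors = FALSE)

  # Candidate moves for a state. State fields:
  #  recruited: character vector; ring: logical (a polymerize event fired);
  #  suppressed_selfpoly: protein names whose self-poly was forked away;
  #  linker: names of disassemblers locked into a linker role.
  candidateMoves <- function(st) {
    moves <- list()
    pr <- r[r$effect == "polymerization" & r$domain_a == r$domain_b, ,
            drop = FALSE]
    # ring formation: seed protein already recruited shares the
    # polymerization domain; joins every carrier of that domain at once.
    if (!st$ring) {
      for (k in seq_len(nrow(pr))) {
        dom <- pr$domain_a[k]
        if (dom == "Vps4_C") next  # disassembler oligomerisation, not a ring
        seeds <- intersect(st$recruited, names(views)[vapply(
          views, function(v) dom %in% v$domains, TRUE)])
        if (!length(seeds)) next
        seed <- sort(seeds)[1]
        if (pr$status[k] == "putative" && seed %in% st$suppressed_selfpoly)
          next
        joiners <- setdiff(names(views)[vapply(
          views, function(v) dom %in% v$domains, TRUE)], st$recruited)
        moves[[length(moves) + 1L]] <- list(
          type = "polymerize", actor = seed, joiners = sort(joiners),
          domain_a = dom, domain_b = dom, status = pr$status[k],
          proline_count = NA_integer_)
      }
    }
    # recruitment through binding rules
    br <- r[r$effect == "binding", , drop = FALSE]
    for (k in seq_len(nrow(br))) {
      for (inside in st$recruited) {
        vi <- views[[inside]]
        for (outside in setdiff(names(views), st$recruited)) {
          vo <- views[[outside]]
          ok <- (br$domain_a[k] %in% vi$domains &&
                   br$domain_b[k] %in% vo$domains) ||
            (br$domain_b[k] %in% vi$domains &&
               br$domain_a[k] %in% vo$domains)
          if (!ok) next
          # proline count of whichever partner carries the MIM2
          pc <- NA_integer_
          if ("MIM2" %in% c(br$domain_a[k], br$domain_b[k]))
            pc <- if ("MIM2" %in% vi$domains) vi$mim2_prolines else
              vo$mim2_prolines
          moves[[length(moves) + 1L]] <- list(
            type = if (vo$disassembler) "bind" else "recruit",
            actor = outside, partner = inside,
            domain_a = br$domain_a[k], domain_b = br$domain_b[k],
            status = br$status[k], proline_count = pc)
        }
      }
    }
    moves
  }

  # Collapse candidates with the same newcomer; order deterministically.
  collapseAndRank <- function(moves) {
    if (!length(moves)) return(moves)
    key <- vapply(moves, function(m)
      paste(m$type, m$actor, sep = "\r"), "")
    collapsed <- lapply(split(moves, key), function(grp) {
      df <- data.frame(
        actor = vapply(grp, `[[`, "", "actor"),
        target = vapply(grp, function(m)
          if (!is.null(m$partner)) m$partner else m$actor, ""),
        domain_a = vapply(grp, `[[`, "", "domain_a"),
        domain_b = vapply(grp, `[[`, "", "domain_b"),
        proline_count = vapply(grp, function(m)
          as.numeric(m$proline_count), 0),
        status = vapply(grp, `[[`, "", "status"),
        stringsAsFactors = FALSE)
      df$idx <- seq_along(grp)
      validated <- df[df$status == "validated", , drop = FALSE]
      pick_from <- if (nrow(validated)) validated else df
      best <- rankAffinity(pick_from)[1, ]
      grp[[best$idx]]
    })
    ord_df <- data.frame(
      actor = vapply(collapsed, `[[`, "", "actor"),
      target = vapply(collapsed, function(m)
        if (!is.null(m$partner)) m$partner else m$actor, ""),
      domain_a = vapply(collapsed, `[[`, "", "domain_a"),
      domain_b = vapply(collapsed, `[[`, "", "domain_b"),
      proline_count = vapply(collapsed, function(m)
        as.numeric(m$proline_count), 0),
      stringsAsFactors = FALSE)
    ranked <- rankAffinity(cbind(ord_df, idx = seq_along(collapsed)))
    collapsed[ranked$idx]
  }

  fireDisassembly <- function(st, disassembler, events) {
    # partners on the ring reachable through enabled MIT-binding rules
    cand <- list()
    for (p in setdiff(st$recruited, disassembler)) {
      v <- views[[p]]
      rule <- .bindingRulesBetween(r, v$domains, c("MIT"))
      if (is.null(rule)) next
      cand[[length(cand) + 1L]] <- data.frame(
        actor = p, target = disassembler,
        domain_a = rule$domain_a[1], domain_b = rule$domain_b[1],
        proline_count = if ("MIM2" %in% c(rule$domain_a[1],
                                          rule$domain_b[1]))
          as.numeric(v$mim2_prolines) else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (length(cand)) {
      ordd <- rankAffinity(do.call(rbind, cand))
      for (i in seq_len(nrow(ordd)))
        events[[length(events) + 1L]] <- evrow(
          "disassemble", disassembler, ordd$actor[i],
          .ruleLabel(ordd$domain_a[i], ordd$domain_b[i]))
    }
    events
  }

  expand <- function(st, events) {
    repeat {
      if (length(scenarios) >= maxBranches) return(invisible(NULL))
      moves <- collapseAndRank(candidateMoves(st))
      if (!length(moves)) { emit(events); return(invisible(NULL)) }
      statuses <- vapply(moves, `[[`, "", "status")
      tiers <- .affinityTier(vapply(moves, `[[`, "", "domain_a"),
                             vapply(moves, `[[`, "", "domain_b"))
      tiers[is.na(tiers)] <- 99
      validated_idx <- which(statuses == "validated")
      putative_idx <- which(statuses == "putative")
      if (length(putative_idx) && length(validated_idx)) {
        best_val <- validated_idx[which.min(tiers[validated_idx])]
        if (min(tiers[validated_idx]) >= 3) {
          # documented ambiguity: putative move vs MIT-tier validated move
          pm <- moves[[putative_idx[1]]]
          st_b <- st
          st_b$suppressed_selfpoly <- union(st_b$suppressed_selfpoly,
                                            pm$actor)
          # branch 1: take the putative move first
          st_a <- applyMove(st, pm)
          expand(st_a$state, c(events, st_a$events))
          # branch 2: suppress it and continue with the validated move
          res <- applyMove(st_b, moves[[best_val]])
          st <- res$state
          events <- c(events, res$events)
          if (res$terminate) { emit(events); return(invisible(NULL)) }
          next
        }
        chosen <- moves[[best_val]]
      } else if (length(validated_idx)) {
        chosen <- moves[[validated_idx[which.min(tiers[validated_idx])]]]
      } else {
        chosen <- moves[[putative_idx[1]]]
      }
      res <- applyMove(st, chosen)
      st <- res$state
      events <- c(events, res$events)
      if (res$terminate) { emit(events); return(invisible(NULL)) }
    }
  }

  applyMove <- function(st, m) {
    events <- list()
    terminate <- FALSE
    if (m$type == "polymerize") {
      actor_lab <- if (length(m$joiners))
        paste(m$joiners, collapse = ",") else m$actor
      events[[1]] <- evrow("polymerize", actor_lab, m$actor,
                           .ruleLabel(m$domain_a, m$domain_b))
      st$recruited <- union(st$recruited, m$joiners)
      st$ring <- TRUE
    } else if (m$type == "recruit") {
      events[[1]] <- evrow("recruit", m$actor, m$partner,
                           .ruleLabel(m$domain_a, m$domain_b))
      st$recruited <- union(st$recruited, m$actor)
      # a disassembler that recruited this protein through its MIT becomes a
      # linker: it cannot also disassemble
      pv <- views[[m$partner]]
      if (pv$disassembler && "MIT" %in% c(m$domain_a, m$domain_b))
        st$linker <- union(st$linker, m$partner)
    } else if (m$type == "bind") {
      events[[1]] <- evrow("bind", m$actor, m$partner,
                           .ruleLabel(m$domain_a, m$domain_b))
      st$recruited <- union(st$recruited, m$actor)
      if (st$ring && !(m$actor %in% st$linker)) {
        events <- fireDisassembly(st, m$actor, events)
        terminate <- TRUE  # site disassembled
      }
    }
    list(state = st, events = events, terminate = terminate)
  }

  st0 <- list(recruited = start, ring = FALSE,
              suppressed_selfpoly = character(), linker = character())
  ev0 <- list(evrow("membrane_bind", start, "membrane", "membrane"))
  expand(st0, ev0)

  lapply(seq_along(scenarios), function(i)
    methods::new("MechanismScenario", events = scenarios[[i]],
                 unresolved = unresolved, branch_id = i))
}
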