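# MIM2 motif scanning, putative proline-rich MIM2 calls and ANCHR helix
# calls. The MIM2 templates are written over three symbol classes:
#   phi = hydrophobic residues [AILMFVPGW] (P and G included deliberately)
#   x   = charged residues     [RKDE]
#   P   = literal proline
# X (unknown residue) never satisfies phi or x.

.MIM2_TEMPLATES <- c(
  MIM2_Core  = "fPxfP",          # phi P x phi P
  MIM2_total = "fPxfPxxPfP",     # Core immediately followed by x x P phi P
  MIM2_Sulf  = "xfxxffPxfPxfP"   # x phi x x phi phi P x prefix, then Core
)

#' MIM2 motif patterns
#'
#' Returns the template strings of the three MIM2 motif classes, written over
#' the symbols \code{f} (hydrophobic class phi = AILMFVPGW), \code{x} (charged
#' class = RKDE) and literal \code{P}. Composite templates are immediate
#' concatenations (no gap): MIM2_total is the 5-residue core plus
#' \code{xxPfP}; MIM2_Sulf is the 8-residue prefix \code{xfxxffPx} plus the
#' core.
#'
#' @return named character vector of templates.
#' @export
#' @examples
#' mim2Patterns()
mim2Patterns <- function() .MIM2_TEMPLATES

# Coerce an AAStringSet or character vector to a named uppercase character
# vector of sequences.
.namedSeqStrings <- function(sequences) {
  nms <- names(sequences)
  s <- toupper(as.character(sequences))
  if (is.null(names(s))) names(s) <- nms
  if (is.null(names(s))) stop("sequences must be named", call. = FALSE)
  s
}

# Template symbol -> regex character class.
.templateToRegex <- function(template) {
  map <- c(f = "[AILMFVPGW]", x = "[RKDE]", P = "P")
  paste0(map[strsplit(template, "")[[1]]], collapse = "")
}

#' Minimum guaranteed prolines of a MIM2 pattern
#'
#' The number of literal P symbols in the template: a lower bound on the
#' proline count of any match (phi also contains P, so matches can carry
#' more). The core guarantees 2 prolines and the full motif 4; the difference
#' underlies the affinity ranking used in mechanism inference.
#'
#' @param pattern one of \code{"MIM2_Core"}, \code{"MIM2_total"},
#'   \code{"MIM2_Sulf"}.
#' @return integer count of literal prolines.
#' @export
#' @examples
#' minGuaranteedProlines("MIM2_Core")   # 2
#' minGuaranteedProlines("MIM2_total")  # 4
minGuaranteedProlines <- function(pattern) {
  .assertScalarString(pattern, "pattern")
  if (!pattern %in% names(.MIM2_TEMPLATES))
    stop("unknown pattern '", pattern, "'; known: ",
         paste(names(.MIM2_TEMPLATES), collapse = ", "), call. = FALSE)
  sum(strsplit(.MIM2_TEMPLATES[[pattern]], "")[[1]] == "P")
}

.emptyMatches <- function() {
  data.frame(protein_id = character(), pattern = character(),
             start = integer(), end = integer(), span = character(),
             proline_count = integer(), evidence = character(),
             stringsAsFactors = FALSE)
}

.countP <- function(spans) {
  vapply(strsplit(spans, ""), function(ch) sum(ch == "P"), 0L)
}

# Scan one uppercase sequence string for one template; all offsets,
# overlaps allowed (regex lookahead).
.scanOne <- function(seq, pattern) {
  template <- .MIM2_TEMPLATES[[pattern]]
  len <- nchar(template)
  if (nchar(seq) < len) return(NULL)
  rex <- paste0("(?=(", .templateToRegex(template), "))")
  m <- gregexpr(rex, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m)
  data.frame(start = starts, end = starts + len - 1L,
             span = substring(seq, starts, starts + len - 1L),
             stringsAsFactors = FALSE)
}

#' Scan sequences for MIM2 motifs
#'
#' Reports every match of every requested pattern at every offset
#' (overlapping matches are all reported; downstream consumers deduplicate).
#' Each match carries the proline count of its matched span. Because
#' MIM2_total begins with the core template, any MIM2_total match implies a
#' MIM2_Core match at the same start; a MIM2_Sulf match contains a core match
#' at offset +8.
#'
#' @param sequences an \code{AAStringSet} or named character vector of
#'   uppercase amino-acid sequences.
#' @param patterns subset of \code{names(mim2Patterns())} (default: all
#'   three).
#' @return data.frame with columns \code{protein_id}, \code{pattern},
#'   \code{start}, \code{end}, \code{span}, \code{proline_count},
#'   \code{evidence} (always \code{"motif_regex"}); zero rows when nothing
#'   matches.
#' @export
#' @examples
#' scanMim2(c(p1 = "LPKLP"))
scanMim2 <- function(sequences, patterns = names(mim2Patterns())) {
  bad <- setdiff(patterns, names(.MIM2_TEMPLATES))
  if (length(bad))
    stop("unknown pattern(s): ", paste(bad, collapse = ", "), call. = FALSE)
  seqs <- .namedSeqStrings(sequences)
  ids <- names(seqs)
  out <- list()
  for (i in seq_along(seqs)) {
    for (p in patterns) {
      hits <- .scanOne(seqs[[i]], p)
      if (!is.null(hits)) {
        hits$protein_id <- ids[i]
        hits$pattern <- p
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) return(.emptyMatches())
  res <- do.call(rbind, out)
  res$proline_count <- .countP(res$span)
  res$evidence <- "motif_regex"
  res <- res[, c("protein_id", "pattern", "start", "end", "span",
                 "proline_count", "evidence")]
  res <- res[order(res$protein_id, res$start,
                   match(res$pattern, names(.MIM2_TEMPLATES))), ]
  rownames(res) <- NULL
  res
}

#' Call putative MIM2 regions from proline density
#'
#' Proline-rich C-terminal regions that do not fit any of the MIM2 regular
#' expressions are flagged as putative MIM2: every window of \code{window}
#' residues lying in the C-terminal \code{ctermFraction} of the sequence that
#' contains at least \code{minProlines} prolines and does not overlap a full
#' MIM2 match qualifies; overlapping qualifying windows are merged into
#' maximal spans. The thresholds are package defaults (the published analyses
#' give none) and are exposed as arguments.
#'
#' @param sequences an \code{AAStringSet} or named character vector.
#' @param window window length in residues (>= 5; default 15).
#' @param minProlines minimum prolines per window (default 3).
#' @param ctermFraction fraction of the sequence, measured from the C
#'   terminus, in which windows are considered (default 0.5).
#' @return data.frame in the same shape as \code{\link{scanMim2}} with
#'   \code{pattern = "putative_MIM2"} and \code{evidence = "putative"}.
#' @export
detectPutativeMim2 <- function(sequences, window = 15L, minProlines = 3L,
                               ctermFraction = 0.5) {
  if (window < 5L) stop("window must be >= 5", call. = FALSE)
  seqs <- .namedSeqStrings(sequences)
  ids <- names(seqs)
  full <- scanMim2(seqs)
  out <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < window) next
    first_start <- max(1L, floor(L * (1 - ctermFraction)) + 1L)
    starts <- first_start:(L - window + 1L)
    if (!length(starts) || starts[1] > L - window + 1L) next
    chars <- strsplit(s, "")[[1]]
    isP <- as.integer(chars == "P")
    cum <- c(0L, cumsum(isP))
    pcount <- cum[starts + window] - cum[starts]
    ok <- pcount >= minProlines
    if (!any(ok)) next
    fm <- full[full$protein_id == ids[i], , drop = FALSE]
    if (nrow(fm)) {
      overlaps <- vapply(starts, function(st)
        any(st <= fm$end & (st + window - 1L) >= fm$start), TRUE)
      ok <- ok & !overlaps
    }
    if (!any(ok)) next
    qs <- starts[ok]
    qe <- qs + window - 1L
    # merge overlapping/adjacent qualifying windows into maximal spans
    o <- order(qs)
    qs <- qs[o]; qe <- qe[o]
    ms <- qs[1]; me <- qe[1]
    spans <- list()
    for (k in seq_along(qs)[-1]) {
      if (qs[k] <= me + 1L) me <- max(me, qe[k])
      else { spans[[length(spans) + 1L]] <- c(ms, me); ms <- qs[k]; me <- qe[k] }
    }
    spans[[length(spans) + 1L]] <- c(ms, me)
    for (sp in spans) {
      span_str <- substring(s, sp[1], sp[2])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = ids[i], pattern = "putative_MIM2",
        start = sp[1], end = sp[2], span = span_str,
        proline_count = .countP(span_str), evidence = "putative",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyMatches())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call the N-terminal ANCHR membrane-binding helix
#'
#' Examines the first \code{ntermLen} residues: the region is called a helix
#' when the longest run of H in the secondary-structure track reaches
#' \code{minHelixRun}; a proline inside that helix run (or, when there is no
#' run, anywhere in the window) breaks the ANCHR call. ANCHR is called iff
#' a helix is predicted and it contains no proline. Thresholds (run >= 8
#' within the first 30 residues) are package defaults chosen to separate the
#' two Asgard CdvB clades on the bundled reference table; both are exposed.
#'
#' @param sequences an \code{AAStringSet} or named character vector.
#' @param ss named character vector of H/E/C strings, same names and lengths
#'   as \code{sequences}.
#' @param ntermLen window length from the N terminus (default 30).
#' @param minHelixRun minimum H-run length to call a helix (default 8).
#' @return data.frame with columns \code{protein_id}, \code{region_start},
#'   \code{region_end}, \code{is_helix}, \code{has_proline},
#'   \code{anchr_call}.
#' @export
callAnchr <- function(sequences, ss, ntermLen = 30L, minHelixRun = 8L) {
  seqs <- .namedSeqStrings(sequences)
  ids <- names(seqs)
  miss <- setdiff(ids, names(ss))
  if (length(miss))
    stop("missing secondary structure for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- lapply(ids, function(id) {
    s <- seqs[[id]]
    track <- ss[[id]]
    if (nchar(track) != nchar(s))
      stop("secondary-structure length mismatch for ", id, call. = FALSE)
    n <- min(ntermLen, nchar(s))
    win_ss <- strsplit(substr(track, 1L, n), "")[[1]]
    win_aa <- strsplit(substr(s, 1L, n), "")[[1]]
    r <- rle(win_ss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    h <- which(r$values == "H")
    is_helix <- length(h) > 0 && max(r$lengths[h]) >= minHelixRun
    if (is_helix) {
      best <- h[which.max(r$lengths[h])]
      has_p <- any(win_aa[starts[best]:ends[best]] == "P")
    } else {
      has_p <- any(win_aa == "P")
    }
    data.frame(protein_id = id, region_start = 1L, region_end = n,
               is_helix = is_helix, has_proline = has_p,
               anchr_call = is_helix && !has_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
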