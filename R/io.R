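# Readers and writers for the external formats the pipeline touches:
# FASTA (Biostrings), TSV annotation/architecture tables, Newick trees (ape).

#' Read protein sequences from FASTA
#'
#' Headers in the pipe-delimited dialect \code{id|organism|super_phylum} are
#' parsed into per-record metadata; plain headers degrade gracefully (id only,
#' organism/super-phylum left \code{NA}). Residues are uppercased and must be
#' drawn from the 20-letter amino-acid alphabet plus \code{X}.
#'
#' @param path path to a FASTA file.
#' @return An \code{\link[Biostrings]{AAStringSet}} whose \code{mcols()} carry
#'   \code{organism} and \code{super_phylum}.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(headers)))
    stop("malformed FASTA: empty record header", call. = FALSE)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  ids <- trimws(vapply(strsplit(ids, "[ \t]"), `[`, "", 1L))
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record id",
                              call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  org <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else
    NA_character_, "")
  sp <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[3]) else
    NA_character_, "")
  bad_sp <- setdiff(sp[!is.na(sp)], superPhyla())
  if (length(bad_sp))
    stop("unknown super_phylum in FASTA header: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(raw))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", seqs)
  if (any(!ok))
    stop("invalid residue symbol in record(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(organism = org,
                                                super_phylum = sp)
  out
}

#' Write protein sequences to FASTA
#'
#' Metadata columns present in \code{mcols()} are serialised back into the
#' pipe-delimited header dialect, so write-then-read round-trips exactly.
#'
#' @param sequences an \code{AAStringSet} (metadata optional).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(sequences, path) {
  out <- if (methods::is(sequences, "AAStringSet")) sequences else
    Biostrings::AAStringSet(sequences)
  mc <- if (methods::is(sequences, "XStringSet"))
    S4Vectors::mcols(sequences) else NULL
  ids <- names(sequences)
  if (!is.null(mc) && all(c("organism", "super_phylum") %in% colnames(mc))) {
    org <- mc[["organism"]]
    sp <- mc[["super_phylum"]]
    has_meta <- !is.na(org) & !is.na(sp)
    ids[has_meta] <- paste(ids[has_meta], org[has_meta], sp[has_meta],
                           sep = "|")
  }
  names(out) <- ids
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read a domain annotation table (TSV)
#'
#' Expects a header line \code{protein_id, domain_type, start, end, evidence,
#' source} (tab-separated). Emulates consumption of summarised external
#' domain-scan output. In strict mode rows whose \code{domain_type} is outside
#' the 11-entry vocabulary are an error; in lenient mode they are dropped with
#' a warning.
#'
#' @param path path to the TSV file.
#' @param sequences optional \code{AAStringSet}; when given, coordinates are
#'   validated against sequence lengths and unknown protein ids are an error.
#' @param strict logical; reject unknown domain types (default TRUE).
#' @return data.frame with the validated annotation rows.
#' @export
readDomainAnnotations <- function(path, sequences = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("protein_id", "domain_type", "start", "end", "evidence", "source")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end)))
    stop("non-numeric start/end in annotation table", call. = FALSE)
  if (any(df$start < 1L))
    stop("start coordinates must be >= 1 (coordinates are 1-based inclusive)",
         call. = FALSE)
  if (any(df$end < df$start))
    stop("end < start in annotation row(s): ",
         paste(which(df$end < df$start), collapse = ", "), call. = FALSE)
  unknown <- !(df$domain_type %in% domainVocabulary())
  if (any(unknown)) {
    if (strict)
      stop("unknown domain_type: ",
           paste(unique(df$domain_type[unknown]), collapse = ", "),
           "; allowed: ", paste(domainVocabulary(), collapse = ", "),
           call. = FALSE)
    warning("dropping ", sum(unknown), " row(s) with unknown domain_type")
    df <- df[!unknown, , drop = FALSE]
  }
  bad_ev <- !(df$evidence %in% .EVIDENCE_LEVELS)
  if (any(bad_ev))
    stop("unknown evidence class: ",
         paste(unique(df$evidence[bad_ev]), collapse = ", "), call. = FALSE)
  if (!is.null(sequences)) {
    miss <- setdiff(df$protein_id, names(sequences))
    if (length(miss))
      stop("annotation references unknown protein(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    lens <- Biostrings::width(sequences)[match(df$protein_id,
                                               names(sequences))]
    over <- df$end > lens
    if (any(over))
      stop("annotation exceeds sequence length for: ",
           paste(unique(df$protein_id[over]), collapse = ", "),
           call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a domain annotation table (TSV)
#' @param annotations data.frame as returned by
#'   \code{\link{readDomainAnnotations}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomainAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-residue secondary-structure tracks (TSV)
#'
#' Expects columns \code{protein_id} and \code{ss}; each \code{ss} string is
#' over the alphabet \{H, E, C\} (helix / strand / coil) and, when sequences
#' are supplied, must match the sequence length.
#'
#' @param path path to the TSV file.
#' @param sequences optional \code{AAStringSet} for length validation.
#' @return named character vector of secondary-structure strings.
#' @export
readSecondaryStructure <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("protein_id", "ss") %in% names(df)))
    stop("secondary-structure TSV needs columns: protein_id, ss",
         call. = FALSE)
  if (any(!grepl("^[HEC]*$", df$ss)))
    stop("secondary structure strings may only contain H, E or C",
         call. = FALSE)
  if (anyDuplicated(df$protein_id))
    stop("duplicated protein_id in secondary-structure table", call. = FALSE)
  ss <- stats::setNames(df$ss, df$protein_id)
  if (!is.null(sequences)) {
    common <- intersect(names(ss), names(sequences))
    lens <- Biostrings::width(sequences)[match(common, names(sequences))]
    bad <- nchar(ss[common]) != lens
    if (any(bad))
      stop("secondary-structure length mismatch for: ",
           paste(common[bad], collapse = ", "), call. = FALSE)
  }
  ss
}

#' Read a rooted tree from a Newick file
#'
#' Thin validated wrapper around \code{\link[ape]{read.tree}}: exactly one
#' tree, unique leaf names; polytomies are allowed and preserved.
#'
#' @param path path to a Newick file.
#' @return an \code{ape::phylo} object.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e)
                   stop("Newick parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (is.null(tr))
    stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected exactly one tree in ", path, call. = FALSE)
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names in tree", call. = FALSE)
  tr
}

#' Write a tree to a Newick file
#' @param tree an \code{ape::phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a presence/absence matrix (TSV)
#'
#' First column \code{taxon}, one 0/1 column per (family-qualified) domain
#' character. Column names may use \code{.} in place of \code{:} (R header
#' mangling); both are accepted, \code{:} is restored.
#'
#' @param path path to the TSV file.
#' @return a \code{\link{PresenceMatrix}}.
#' @export
readPresenceMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "taxon")
    stop("presence matrix TSV must start with a 'taxon' column",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$taxon
  colnames(m) <- sub(".", ":", colnames(m), fixed = TRUE)
  methods::new("PresenceMatrix", states = m)
}

#' Construct an ArchitectureSet from plain tables
#'
#' @param proteins data.frame with columns \code{protein_id}, \code{organism},
#'   \code{super_phylum}, \code{family}.
#' @param domains data.frame with columns \code{protein_id},
#'   \code{domain_type}, \code{start}, \code{end}, \code{evidence} and
#'   optionally \code{proline_count}.
#' @return an \code{\link{ArchitectureSet}} with domains sorted by protein and
#'   start coordinate.
#' @export
architectureSet <- function(proteins, domains = NULL) {
  if (is.null(domains))
    domains <- data.frame(protein_id = character(), domain_type = character(),
                          start = integer(), end = integer(),
                          evidence = character(), proline_count = integer(),
                          stringsAsFactors = FALSE)
  if (is.null(domains$proline_count))
    domains$proline_count <- NA_integer_
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  domains$proline_count <- as.integer(domains$proline_count)
  keep <- c("protein_id", "domain_type", "start", "end", "evidence",
            "proline_count")
  domains <- domains[order(domains$protein_id, domains$start,
                           domains$end), keep, drop = FALSE]
  rownames(domains) <- NULL
  proteins <- proteins[, c("protein_id", "organism", "super_phylum",
                           "family"), drop = FALSE]
  rownames(proteins) <- NULL
  methods::new("ArchitectureSet", proteins = proteins, domains = domains)
}
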