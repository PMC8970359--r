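# Closed vocabularies shared across the package.

#' The closed Cdv domain vocabulary
#'
#' The eleven domain and motif types found on archaeal CdvA, CdvB and CdvC
#' proteins: the two CdvA sub-domains (alpha-helix rich and beta-sheet rich),
#' the Broken Winged-Helix interaction site (BWI) and domain (BWH), the two
#' MIT-interacting motifs (MIM1, MIM2), the filament-forming Snf7 (ESCRT-III)
#' domain, the Vps4 C-terminal oligomerisation domain, the MIT domain, the
#' AAA+ ATPase region, and the N-terminal membrane-binding ANCHR motif.
#'
#' @return Character vector of the 11 domain type names.
#' @export
#' @examples
#' domainVocabulary()
domainVocabulary <- function() {
  c("CdvA_alpha", "CdvA_beta", "BWI", "BWH", "MIM1", "MIM2",
    "Snf7", "Vps4_C", "MIT", "AAA_ATPase", "ANCHR")
}

#' Super-phylum labels accepted in protein metadata
#' @return Character vector of valid super-phylum labels.
#' @export
superPhyla <- function() {
  c("Euryarchaeota", "Asgard", "TACK_Crenarchaeota", "TACK_Thaumarchaeota",
    "other")
}

# 20-letter amino-acid alphabet; X is tolerated on input but never matches a
# motif symbol class.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Motif symbol classes: phi = hydrophobic (includes P and G), x = charged.
.PHI_SET <- strsplit("AILMFVPGW", "")[[1]]
.X_SET <- strsplit("RKDE", "")[[1]]

# Evidence classes ordered weakest -> strongest.
.EVIDENCE_LEVELS <- c("putative", "ss_annotation", "motif_regex", "db_scan")

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
  invisible(x)
}

.assertDomainTypes <- function(types) {
  bad <- setdiff(unique(types), domainVocabulary())
  if (length(bad))
    stop("unknown domain type(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(domainVocabulary(), collapse = ", "),
         call. = FALSE)
  invisible(types)
}

# Deterministic local RNG: run code under a seed without touching the
# caller's .Random.seed.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
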