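# NCLDV contig curation from marker-gene hit tables: screening, the
# four-of-five MAG quality rule, and species-level taxonomy assignment.

# Canonical NCLDV marker vocabulary: A32-like ATPase, B-family DNA
# polymerase, late transcription factor VLTF3, major capsid protein,
# superfamily II helicase.
NCLDV_MARKERS <- c("A32", "PolB", "VLTF3", "MCP", "SFII")

#' Normalize marker-gene names to the canonical five-token vocabulary
#'
#' Matching is case-insensitive so that `polb`, `PolB` and `POLB` all map to
#' `PolB`. Unknown names raise an error naming the offending value.
#'
#' @param x Character vector of marker names.
#' @return Character vector of canonical tokens.
#' @export
normalize_marker <- function(x) {
  idx <- match(toupper(x), toupper(NCLDV_MARKERS))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown marker name '%s' (row %d); expected one of %s",
                 x[bad], bad, paste(NCLDV_MARKERS, collapse = ", ")),
         call. = FALSE)
  }
  NCLDV_MARKERS[idx]
}

#' Screen contigs by NCLDV marker-gene content
#'
#' Keeps contigs carrying at least `min_markers` *distinct* canonical
#' markers. This is the catalog-entry rule: presence of NCLDV-specific
#' marker genes is what qualifies an assembled contig as a giant virus
#' population in the first place.
#'
#' @param hits Data frame with at least columns `contig_id` and `marker`.
#' @param min_markers Minimum number of distinct markers (default 1).
#' @return Sorted character vector of qualifying contig ids.
#' @export
screen_contigs <- function(hits, min_markers = 1L) {
  stopifnot(is.data.frame(hits),
            all(c("contig_id", "marker") %in% names(hits)))
  if (!is.numeric(min_markers) || length(min_markers) != 1L || min_markers < 1) {
    stop("min_markers must be a single integer >= 1", call. = FALSE)
  }
  if (nrow(hits) == 0L) return(character())
  mk <- normalize_marker(hits$marker)
  n_distinct <- tapply(mk, hits$contig_id, function(m) length(unique(m)))
  sort(names(n_distinct)[n_distinct >= min_markers])
}

#' MAG quality rule: at least four of the five NCLDV key markers
#'
#' @param marker_set Character vector of marker names (any case).
#' @return `TRUE` iff the set contains >= 4 distinct canonical markers.
#' @export
gvmag_quality <- function(marker_set) {
  if (length(marker_set) == 0L) return(FALSE)
  length(unique(normalize_marker(marker_set))) >= 4L
}

#' Assign species-level taxonomy to contigs from marker hits
#'
#' Hits below `min_identity` percent identity are discarded; the remaining
#' hits vote by reference taxon, majority wins, and ties are broken by the
#' higher mean identity among the tied taxa. Contigs with no qualifying hit
#' are labelled `"NOVEL"`. The rule is deterministic and independent of row
#' order.
#'
#' @param hits Data frame with columns `contig_id`, `marker`, `ref_taxon`,
#'   `pct_identity`.
#' @param min_identity Identity threshold in percent (default 30, a
#'   conservative amino-acid-level cut-off).
#' @param contig_ids Optional character vector of contigs that must appear
#'   in the output (those with no hits are `"NOVEL"`).
#' @return Data frame `contig_id`, `taxon`.
#' @export
assign_taxonomy <- function(hits, min_identity = 30, contig_ids = NULL) {
  stopifnot(is.data.frame(hits),
            all(c("contig_id", "ref_taxon", "pct_identity") %in% names(hits)))
  pid <- hits$pct_identity
  if (!is.numeric(pid) || anyNA(pid) || any(pid < 0 | pid > 100)) {
    stop("pct_identity must be numeric in [0, 100]", call. = FALSE)
  }
  keep <- hits[pid >= min_identity, , drop = FALSE]
  ids <- if (is.null(contig_ids)) sort(unique(hits$contig_id)) else contig_ids
  vote <- function(cid) {
    h <- keep[keep$contig_id == cid, , drop = FALSE]
    if (nrow(h) == 0L) return("NOVEL")
    votes <- table(h$ref_taxon)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    mean_id <- vapply(top, function(tx) mean(h$pct_identity[h$ref_taxon == tx]),
                      numeric(1))
    # tie on votes -> higher mean identity; residual tie -> lexicographic
    top[order(-mean_id, top)][1L]
  }
  data.frame(contig_id = ids,
             taxon = vapply(ids, vote, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
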