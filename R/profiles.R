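# Spatiotemporal aggregation: depth-wise time means with standard errors,
# taxon-level relative-abundance profiles, and abundance-weighted AMG
# carrier proportions.

#' Depth profile of a per-sample quantity, averaged through time
#'
#' Groups per-sample values by nominal depth and reports mean and standard
#' error (sd/sqrt(n), sample sd with n-1 denominator; `NA` when n = 1) per
#' depth. By default only planktonic samples contribute — depth profiles
#' are a water-column summary.
#'
#' @param values Named numeric vector, one value per sample id.
#' @param metadata Data frame with columns `sample_id`, `depth_m`,
#'   `habitat`.
#' @param habitat Habitat to include (default `"planktonic"`; use `NULL`
#'   for all samples).
#' @return Data frame `depth_m`, `mean`, `se`, `n`, sorted by depth.
#' @export
depth_time_mean <- function(values, metadata, habitat = "planktonic") {
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(c("sample_id", "depth_m", "habitat") %in% names(metadata)))
  missing <- setdiff(names(values), metadata$sample_id)
  if (length(missing) > 0L) {
    stop(sprintf("sample '%s' not present in metadata", missing[1L]),
         call. = FALSE)
  }
  md <- metadata[match(names(values), metadata$sample_id), ]
  if (!is.null(habitat)) {
    keep <- md$habitat %in% habitat
    values <- values[keep]
    md <- md[keep, ]
  }
  if (length(values) == 0L) {
    return(data.frame(depth_m = numeric(), mean = numeric(),
                      se = numeric(), n = integer()))
  }
  depths <- sort(unique(md$depth_m))
  out <- lapply(depths, function(d) {
    v <- values[md$depth_m == d]
    data.frame(depth_m = d, mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  })
  do.call(rbind, out)
}

#' Taxon-level relative-abundance profiles
#'
#' Sums member-contig relative abundances per taxon within each sample.
#' With `identified_only = TRUE` the `NOVEL` bin is dropped and each
#' column is renormalized over identified taxa only (the convention used
#' when displaying abundance among identifiable species); columns with no
#' identified abundance stay zero.
#'
#' @param tab A `coverage_table` in mode `"sum_to_one"`.
#' @param taxonomy Data frame `contig_id`, `taxon` (from
#'   [assign_taxonomy()]). Contigs missing from it are treated as `NOVEL`
#'   with a warning.
#' @param identified_only Drop `NOVEL` and renormalize (default FALSE).
#' @return Taxon x sample numeric matrix (possibly zero rows if nothing is
#'   identified under `identified_only`).
#' @export
taxon_profile <- function(tab, taxonomy, identified_only = FALSE) {
  stopifnot(inherits(tab, "coverage_table"))
  if (tab$mode != "sum_to_one") {
    stop("taxon_profile() expects a sum_to_one coverage table", call. = FALSE)
  }
  v <- tab$values
  tx <- taxonomy$taxon[match(rownames(v), taxonomy$contig_id)]
  if (anyNA(tx)) {
    warning(sprintf("%d contig(s) missing from taxonomy; treated as NOVEL",
                    sum(is.na(tx))))
    tx[is.na(tx)] <- "NOVEL"
  }
  prof <- rowsum(v, group = tx)
  prof <- prof[order(rownames(prof)), , drop = FALSE]
  if (identified_only) {
    prof <- prof[rownames(prof) != "NOVEL", , drop = FALSE]
    if (nrow(prof) == 0L) {
      warning("no taxonomically identified contigs; empty taxon profile")
      return(prof)
    }
    cs <- colSums(prof)
    cs[cs == 0] <- 1
    prof <- sweep(prof, 2L, cs, "/")
  }
  prof
}

#' Abundance-weighted proportion of AMG carriers per sample
#'
#' For a given auxiliary-metabolic-gene category, sums the relative
#' abundances of the contigs annotated with that category in each sample.
#' This weights carriers by how abundant they are, making the proportion
#' comparable across depths of unequal richness; `count_based = TRUE`
#' instead reports the unweighted fraction of detected contigs that carry
#' the category.
#'
#' @param tab A `coverage_table` in mode `"sum_to_one"`.
#' @param amg Data frame `contig_id`, `category`.
#' @param category Category to profile; must occur in `amg`.
#' @param count_based Use carrier counts among detected contigs instead of
#'   abundance weighting.
#' @return Named numeric vector, one proportion in \[0, 1\] per sample.
#' @export
amg_proportion <- function(tab, amg, category, count_based = FALSE) {
  stopifnot(inherits(tab, "coverage_table"),
            all(c("contig_id", "category") %in% names(amg)))
  if (tab$mode != "sum_to_one") {
    stop("amg_proportion() expects a sum_to_one coverage table", call. = FALSE)
  }
  known <- sort(unique(amg$category))
  if (!category %in% known) {
    stop(sprintf("unknown AMG category '%s'; known categories: %s",
                 category, paste(known, collapse = ", ")), call. = FALSE)
  }
  carriers <- unique(amg$contig_id[amg$category == category])
  carriers <- intersect(carriers, rownames(tab$values))
  if (count_based) {
    det <- tab$values > 0
    n_det <- colSums(det)
    n_car <- colSums(det[carriers, , drop = FALSE])
    out <- ifelse(n_det > 0, n_car / n_det, 0)
    return(stats::setNames(out, colnames(tab$values)))
  }
  colSums(tab$values[carriers, , drop = FALSE])
}
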