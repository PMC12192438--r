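# Vertical-transport calls, depth-of-origin assignment, and summer
# export-pulse classification for sediment-trap samples.

#' Call vertically transported contigs from trap detections
#'
#' A contig is called transported iff it is detected (non-zero Q2Q3
#' coverage) in at least one sediment-trap sample.
#'
#' @param detections Logical contig x sample matrix from
#'   [detect_coverage()].
#' @param metadata Data frame with `sample_id` and `habitat`
#'   (`"planktonic"` / `"sediment_trap"`).
#' @return Data frame `contig_id`, `transported`, `n_trap_detections`.
#' @export
transported_set <- function(detections, metadata) {
  stopifnot(is.matrix(detections), is.logical(detections),
            all(c("sample_id", "habitat") %in% names(metadata)))
  trap_ids <- metadata$sample_id[metadata$habitat == "sediment_trap"]
  trap_ids <- intersect(colnames(detections), trap_ids)
  if (length(trap_ids) == 0L) {
    stop("configuration error: no sediment-trap samples present", call. = FALSE)
  }
  n_det <- rowSums(detections[, trap_ids, drop = FALSE])
  data.frame(contig_id = rownames(detections),
             transported = n_det >= 1L,
             n_trap_detections = as.integer(n_det),
             stringsAsFactors = FALSE)
}

#' Depth of origin of each contig in the water column
#'
#' Operationalizes "depth of origin" as the planktonic depth at which the
#' contig's time-averaged relative abundance peaks; ties go to the
#' shallower depth. The shallowest depth of any planktonic detection is
#' reported alongside, since a population's first appearance and its
#' abundance peak are both defensible readings of where it originates.
#' Contigs never detected in the water column get `NA` for both (they are
#' trap-only).
#'
#' @param tab A `coverage_table` in mode `"sum_to_one"` restricted to, or
#'   at least containing, planktonic samples; trap samples are ignored.
#' @param metadata Data frame with `sample_id`, `depth_m`, `habitat`.
#' @return Data frame `contig_id`, `depth_of_origin_m`,
#'   `shallowest_detection_m`, `trap_only` is implied by `NA` origin.
#' @export
depth_of_origin <- function(tab, metadata) {
  stopifnot(inherits(tab, "coverage_table"))
  if (tab$mode != "sum_to_one") {
    stop("depth_of_origin() expects a sum_to_one coverage table", call. = FALSE)
  }
  plk <- metadata$sample_id[metadata$habitat == "planktonic"]
  plk <- intersect(colnames(tab$values), plk)
  if (length(plk) == 0L) {
    stop("no planktonic samples in coverage table", call. = FALSE)
  }
  v <- tab$values[, plk, drop = FALSE]
  depth <- metadata$depth_m[match(plk, metadata$sample_id)]
  depths <- sort(unique(depth))
  # time-mean relative abundance per depth (columns grouped by depth)
  mean_by_depth <- vapply(depths, function(d) {
    rowMeans(v[, depth == d, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(mean_by_depth))) {
    mean_by_depth <- matrix(mean_by_depth, nrow = nrow(v),
                            dimnames = list(rownames(v), NULL))
  }
  origin <- rep(NA_real_, nrow(v))
  shallowest <- rep(NA_real_, nrow(v))
  detected_any <- rowSums(v > 0) > 0
  for (i in which(detected_any)) {
    m <- mean_by_depth[i, ]
    # which.max returns the first (shallowest) index on exact ties because
    # depths are in increasing order
    origin[i] <- depths[which.max(m)]
    shallowest[i] <- min(depth[v[i, ] > 0])
  }
  data.frame(contig_id = rownames(v),
             depth_of_origin_m = origin,
             shallowest_detection_m = shallowest,
             stringsAsFactors = FALSE)
}

#' Full per-contig transport report
#'
#' Combines trap detection calls with water-column origin assignment.
#' Contigs detected in traps but never in the water column are flagged
#' `trap_only` — a pattern real trap-dominant taxa show.
#'
#' @param raw_tab A raw `coverage_table` over all samples.
#' @param metadata Sample metadata (see [transported_set()]).
#' @return Data frame: `contig_id`, `transported`, `n_trap_detections`,
#'   `depth_of_origin_m`, `shallowest_detection_m`, `trap_only`.
#' @export
transport_report <- function(raw_tab, metadata) {
  stopifnot(inherits(raw_tab, "coverage_table"), raw_tab$mode == "raw")
  det <- detect_coverage(raw_tab)
  ts <- transported_set(det, metadata)
  rel <- normalize_coverage(raw_tab, "sum_to_one")
  org <- depth_of_origin(rel, metadata)
  out <- merge(ts, org, by = "contig_id", sort = TRUE)
  out$trap_only <- out$transported & is.na(out$depth_of_origin_m)
  out
}

#' Classify summer export pulses in a particulate-flux series
#'
#' A trap sample is an export pulse iff its particulate carbon flux is at
#' least 150% of the long-term baseline mean (inclusive boundary). The rule
#' is a ratio, so it is invariant under a common rescaling of flux and
#' baseline (a change of units).
#'
#' @param flux Data frame with columns `sample_id`, `flux`,
#'   `baseline_mean` (a single long-term mean, recycled or per-row).
#' @return The input with a logical `pulse` column added.
#' @export
classify_export_pulse <- function(flux) {
  stopifnot(is.data.frame(flux),
            all(c("sample_id", "flux", "baseline_mean") %in% names(flux)))
  if (any(!is.finite(flux$baseline_mean)) || any(flux$baseline_mean <= 0)) {
    stop("baseline_mean must be positive", call. = FALSE)
  }
  if (any(!is.finite(flux$flux)) || any(flux$flux < 0)) {
    stop("flux values must be non-negative", call. = FALSE)
  }
  flux$pulse <- flux$flux >= 1.5 * flux$baseline_mean
  flux
}
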