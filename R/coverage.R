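# Q2Q3 coverage: trimmed central-quartile per-contig coverage and the
# normalizations used for relative-abundance displays.

#' Central two-quartile (Q2Q3) coverage of a contig
#'
#' Robust per-contig coverage statistic: the mean per-base depth over the
#' central two quartiles of position ranks. Positions are sorted by depth,
#' the lowest `floor(L/4)` and highest `floor(L/4)` ranks are discarded, and
#' the mean of the remainder is returned. Trimming the extremes makes the
#' statistic insensitive both to uncovered contig ends and to localized
#' pile-ups on conserved or repetitive regions, so it tracks the abundance
#' of the population the contig represents rather than mapping artefacts.
#'
#' A direct consequence of rank-based trimming is a breadth rule: a contig
#' whose covered positions number no more than `floor(L/4)` has Q2Q3
#' coverage exactly 0, so detection ("non-zero Q2Q3") requires breadth
#' greater than ~25% of the contig length.
#'
#' @param depths Numeric vector of per-base depths over the *full* contig
#'   length (positions without coverage must be present as zeros).
#' @return A single non-negative number. For contigs shorter than 4 bp the
#'   plain mean is returned (trimming is undefined).
#' @examples
#' q2q3(c(0, 0, 1, 2, 3, 10, 50, 100))  # k = 2, mean(1, 2, 3, 10) = 4
#' @export
q2q3 <- function(depths) {
  if (length(depths) == 0L) {
    stop("empty depth vector: contig length must be >= 1", call. = FALSE)
  }
  if (anyNA(depths) || any(depths < 0)) {
    stop("per-base depths must be non-negative and non-missing", call. = FALSE)
  }
  L <- length(depths)
  if (L < 4L) {
    return(mean(depths))
  }
  k <- L %/% 4L
  s <- sort(depths)
  mean(s[(k + 1L):(L - k)])
}

#' Build a raw Q2Q3 coverage table from per-base depth files
#'
#' Reads one samtools-depth-dialect file per sample (three tab-separated
#' columns: contig id, 1-based position, depth; no header) and computes the
#' Q2Q3 coverage of every cataloged contig in every sample. Positions absent
#' from a depth file are zero-filled; contigs absent entirely get Q2Q3 = 0.
#'
#' @param depth_files Character vector of file paths, one per sample.
#'   Sample names are taken from `names(depth_files)` if set, otherwise
#'   from the file basenames without extension.
#' @param catalog Data frame with columns `contig_id` and `length_bp`.
#' @return A `coverage_table` object (see [coverage_table_new()]) in mode
#'   `"raw"`, contigs as rows in catalog order, samples as columns.
#' @export
coverage_table <- function(depth_files, catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("contig_id", "length_bp") %in% names(catalog)))
  if (anyDuplicated(catalog$contig_id)) {
    stop("duplicated contig ids in catalog", call. = FALSE)
  }
  lens <- stats::setNames(as.integer(catalog$length_bp), catalog$contig_id)
  if (any(lens < 1L)) stop("contig lengths must be >= 1", call. = FALSE)
  samples <- names(depth_files)
  if (is.null(samples)) {
    samples <- sub("\\.[^.]*$", "", basename(depth_files))
  }
  vals <- matrix(0, nrow = length(lens), ncol = length(depth_files),
                 dimnames = list(names(lens), samples))
  for (j in seq_along(depth_files)) {
    d <- read_depth_file(depth_files[[j]])
    if (nrow(d) == 0L) next
    bad <- !(d$contig %in% names(lens))
    if (any(bad)) {
      stop(sprintf("depth file '%s': contig '%s' (row %d) not in catalog",
                   depth_files[[j]], d$contig[which(bad)[1L]], which(bad)[1L]),
           call. = FALSE)
    }
    over <- d$pos > lens[d$contig] | d$pos < 1L
    if (any(over)) {
      stop(sprintf("depth file '%s': row %d has position %d outside contig '%s' (length %d)",
                   depth_files[[j]], which(over)[1L], d$pos[which(over)[1L]],
                   d$contig[which(over)[1L]], lens[d$contig[which(over)[1L]]]),
           call. = FALSE)
    }
    for (cid in unique(d$contig)) {
      v <- numeric(lens[[cid]])
      rows <- d$contig == cid
      v[d$pos[rows]] <- d$depth[rows]
      vals[cid, j] <- q2q3(v)
    }
  }
  coverage_table_new(vals, mode = "raw")
}

#' Construct a coverage table object
#'
#' Thin S3 container for a contig x sample matrix of Q2Q3 coverages that
#' records which normalization has been applied.
#'
#' @param values Non-negative numeric matrix, contigs as rows, samples as
#'   columns, both dimnames set.
#' @param mode One of `"raw"`, `"sum_to_one"`, `"max_of_sample"`.
#' @return An object of class `coverage_table`: a list with elements
#'   `values` and `mode`.
#' @export
coverage_table_new <- function(values, mode = c("raw", "sum_to_one", "max_of_sample")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values) || any(values < 0)) {
    stop("coverage values must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("coverage matrix needs contig rownames and sample colnames", call. = FALSE)
  }
  structure(list(values = values, mode = mode), class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("coverage_table: %d contigs x %d samples, mode = %s\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Column-wise normalization of a raw coverage table
#'
#' Two display conventions are supported: `sum_to_one` divides each sample
#' column by its sum, giving relative abundances that sum to 1 within a
#' sample; `max_of_sample` divides by the column maximum, so the most
#' abundant contig in each sample scores 1. All-zero columns pass through
#' unchanged (no NaN). Normalization preserves the zero pattern, so
#' detection calls are unchanged.
#'
#' @param tab A `coverage_table` in mode `"raw"`.
#' @param mode `"sum_to_one"` or `"max_of_sample"`.
#' @return A `coverage_table` in the requested mode.
#' @export
normalize_coverage <- function(tab, mode = c("sum_to_one", "max_of_sample")) {
  stopifnot(inherits(tab, "coverage_table"))
  if (tab$mode != "raw") {
    stop("normalize_coverage() expects a raw coverage table", call. = FALSE)
  }
  mode <- match.arg(mode)
  v <- tab$values
  denom <- if (mode == "sum_to_one") colSums(v) else apply(v, 2L, max)
  denom[denom == 0] <- 1  # all-zero columns stay all-zero
  v <- sweep(v, 2L, denom, "/")
  coverage_table_new(v, mode = mode)
}

#' Detection calls from raw Q2Q3 coverage
#'
#' A contig is called detected in a sample iff its raw Q2Q3 coverage is
#' strictly positive. Because of the rank trimming in [q2q3()], this is
#' equivalent to requiring breadth of coverage above ~25% of the contig
#' length (strictly more than `floor(L/4)` covered positions).
#'
#' @param tab A `coverage_table` in mode `"raw"`.
#' @return Logical contig x sample matrix.
#' @export
detect_coverage <- function(tab) {
  stopifnot(inherits(tab, "coverage_table"))
  if (tab$mode != "raw") {
    stop("detect_coverage() expects a raw coverage table", call. = FALSE)
  }
  tab$values > 0
}

#' Per-sample percentage of reads mapped to the contig catalog
#'
#' @param metadata Data frame with columns `sample_id`, `total_reads`,
#'   `mapped_reads`.
#' @return Data frame `sample_id`, `pct_mapped` (percent, 0-100).
#' @export
fraction_reads_mapped <- function(metadata) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "total_reads", "mapped_reads") %in% names(metadata)))
  if (any(metadata$total_reads <= 0)) {
    stop("total_reads must be positive", call. = FALSE)
  }
  if (any(metadata$mapped_reads > metadata$total_reads)) {
    bad <- which(metadata$mapped_reads > metadata$total_reads)[1L]
    stop(sprintf("sample '%s': mapped_reads exceeds total_reads",
                 metadata$sample_id[bad]), call. = FALSE)
  }
  if (any(metadata$mapped_reads < 0)) {
    stop("mapped_reads must be non-negative", call. = FALSE)
  }
  data.frame(sample_id = metadata$sample_id,
             pct_mapped = 100 * metadata$mapped_reads / metadata$total_reads,
             stringsAsFactors = FALSE)
}

# samtools-depth dialect: contig <TAB> 1-based position <TAB> depth, no header.
read_depth_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("depth file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), pos = integer(), depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "pos", "depth"),
                         colClasses = c("character", "integer", "numeric"),
                         quote = "", comment.char = "")
  if (any(d$depth < 0)) {
    stop(sprintf("depth file '%s': negative depth", path), call. = FALSE)
  }
  d
}
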