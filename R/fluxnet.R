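# Flux-correlated population detection: per-contig gene-significance
# statistics against particulate carbon export flux, and a co-abundance
# network module (eigengene) gate in the weighted-correlation-network
# tradition.

#' Per-contig gene significance against carbon export flux
#'
#' Pearson correlation of each contig's trap abundance profile with the
#' particulate carbon flux across trap samples, with a two-sided p-value
#' from `t = r * sqrt(n-2) / sqrt(1-r^2)` against a t distribution with
#' n-2 degrees of freedom. Contigs with constant (typically all-zero)
#' trap profiles carry no correlation information; they are flagged and
#' given `NA` statistics.
#'
#' @param tab A `coverage_table` over trap samples (any mode; correlation
#'   is invariant to positive column scaling only through the profile
#'   itself, so pass the normalization you intend to analyse — the
#'   conventional choice is per-sample sum-to-one relative abundance).
#' @param flux Data frame `sample_id`, `flux`; rows are matched to the
#'   table's columns by sample id.
#' @return Data frame `contig_id`, `r`, `p`, `n`, `flagged_constant`.
#' @export
gene_significance <- function(tab, flux) {
  stopifnot(inherits(tab, "coverage_table"),
            all(c("sample_id", "flux") %in% names(flux)))
  common <- intersect(colnames(tab$values), flux$sample_id)
  if (length(common) < 4L) {
    stop("need at least 4 trap samples with flux values", call. = FALSE)
  }
  v <- tab$values[, common, drop = FALSE]
  f <- flux$flux[match(common, flux$sample_id)]
  if (stats::sd(f) == 0) stop("flux series is constant", call. = FALSE)
  n <- length(common)
  sds <- apply(v, 1L, stats::sd)
  flagged <- sds == 0
  r <- rep(NA_real_, nrow(v))
  r[!flagged] <- as.numeric(stats::cor(t(v[!flagged, , drop = FALSE]), f))
  # guard rounding: |r| can exceed 1 by eps under exact collinearity
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(contig_id = rownames(v), r = r, p = p, n = n,
             flagged_constant = flagged, stringsAsFactors = FALSE)
}

#' Build co-abundance modules by weighted correlation network analysis
#'
#' Unsigned weighted-network workflow over trap abundance profiles:
#' adjacency `a_ij = |cor(i, j)|^beta`, topological-overlap similarity,
#' average-linkage hierarchical clustering on the 1-TOM dissimilarity, and
#' a static cut at `cut_height`. Clusters smaller than `min_module_size`
#' are left unassigned (`"grey"`). Each module's eigengene is the first
#' principal component of its standardized member profiles, sign-oriented
#' so that its mean correlation with the members is positive, and is
#' correlated against the flux trait.
#'
#' Module labels are deterministic: modules are numbered `M1, M2, ...` by
#' decreasing size, ties broken by the lexicographically smallest member
#' contig id, so the labelling does not depend on input row order.
#'
#' @param tab A `coverage_table` over trap samples.
#' @param flux Data frame `sample_id`, `flux` (for module-trait
#'   correlations); `NULL` skips them.
#' @param beta Soft-threshold power (default 6, the common unsigned
#'   default).
#' @param min_module_size Smallest cluster kept as a module (default 5).
#' @param cut_height Static cut height on the 1-TOM dendrogram
#'   (default 0.25).
#' @return List: `assignments` (contig_id, module), `eigengenes`
#'   (sample x module matrix), `module_trait` (module, r, p) or NULL.
#' @export
build_modules <- function(tab, flux = NULL, beta = 6, min_module_size = 5L,
                          cut_height = 0.25) {
  stopifnot(inherits(tab, "coverage_table"), beta >= 1)
  v <- tab$values
  if (nrow(v) < 2L) stop("need at least 2 contigs to build modules", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (all(sds == 0)) stop("degenerate input: all contig profiles constant", call. = FALSE)
  keep <- sds > 0
  x <- t(v[keep, , drop = FALSE])  # samples x contigs
  C <- stats::cor(x)
  A <- abs(C)^beta
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  # deterministic relabelling: size desc, then smallest member id
  ids <- colnames(x)
  tab_cl <- split(ids, cl)
  sizes <- lengths(tab_cl)
  keep_cl <- tab_cl[sizes >= min_module_size]
  if (length(keep_cl) > 0L) {
    firsts <- vapply(keep_cl, function(m) min(m), character(1))
    ord <- order(-lengths(keep_cl), firsts)
    keep_cl <- keep_cl[ord]
    names(keep_cl) <- paste0("M", seq_along(keep_cl))
  }
  module <- stats::setNames(rep("grey", length(ids)), ids)
  for (lab in names(keep_cl)) module[keep_cl[[lab]]] <- lab
  assignments <- data.frame(contig_id = rownames(v),
                            module = ifelse(rownames(v) %in% ids,
                                            module[rownames(v)], "grey"),
                            stringsAsFactors = FALSE)

  eig <- NULL
  mt <- NULL
  if (length(keep_cl) > 0L) {
    eig <- matrix(NA_real_, nrow = nrow(x), ncol = length(keep_cl),
                  dimnames = list(rownames(x), names(keep_cl)))
    for (lab in names(keep_cl)) {
      xm <- scale(x[, keep_cl[[lab]], drop = FALSE])
      sv <- svd(xm, nu = 1, nv = 0)
      e <- sv$u[, 1]
      if (mean(stats::cor(e, xm)) < 0) e <- -e
      eig[, lab] <- e
    }
    if (!is.null(flux)) {
      common <- intersect(rownames(eig), flux$sample_id)
      f <- flux$flux[match(common, flux$sample_id)]
      nmod <- ncol(eig)
      r <- vapply(seq_len(nmod), function(j)
        stats::cor(eig[common, j], f), numeric(1))
      nn <- length(common)
      tstat <- r * sqrt(nn - 2) / sqrt(pmax(1 - r^2, 0))
      p <- 2 * stats::pt(-abs(tstat), df = nn - 2)
      mt <- data.frame(module = colnames(eig), r = r, p = p,
                       stringsAsFactors = FALSE)
    }
  }
  list(assignments = assignments, eigengenes = eig, module_trait = mt)
}

#' Select contigs positively correlated with carbon export flux
#'
#' The selection rule is per-contig: Pearson r > 0 and p < alpha. An
#' optional module gate additionally requires membership in a co-abundance
#' module whose eigengene is itself positively and significantly
#' correlated with flux. No multiple-testing correction is applied by
#' default (the selection criterion is raw p < .05); Benjamini-Hochberg is
#' available via `bh_correction`.
#'
#' @param gs Output of [gene_significance()].
#' @param modules Output of [build_modules()] or `NULL`.
#' @param alpha Significance level (default .05).
#' @param require_module_gate Apply the module gate (default FALSE).
#' @param bh_correction Benjamini-Hochberg adjust p-values before
#'   thresholding (default FALSE).
#' @return Sorted character vector of selected contig ids.
#' @export
select_flux_correlated <- function(gs, modules = NULL, alpha = 0.05,
                                   require_module_gate = FALSE,
                                   bh_correction = FALSE) {
  stopifnot(all(c("contig_id", "r", "p", "flagged_constant") %in% names(gs)),
            alpha > 0, alpha < 1)
  p <- gs$p
  if (bh_correction) p <- stats::p.adjust(p, method = "BH")
  sel <- !gs$flagged_constant & !is.na(gs$r) & gs$r > 0 & p < alpha
  ids <- gs$contig_id[sel]
  if (require_module_gate) {
    if (is.null(modules) || is.null(modules$module_trait)) {
      stop("module gate requested but module-trait correlations unavailable",
           call. = FALSE)
    }
    good <- modules$module_trait$module[
      modules$module_trait$r > 0 & modules$module_trait$p < alpha]
    in_good <- modules$assignments$contig_id[
      modules$assignments$module %in% good]
    ids <- intersect(ids, in_good)
  }
  sort(ids)
}
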