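# End-to-end pipeline: read a bundle of plain TSV inputs, run screening ->
# coverage -> normalization -> profiles -> transport -> flux correlation,
# and write stage outputs plus a JSON run summary.

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("input not found: %s", path), call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "", check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  d
}

#' Assemble a run configuration
#'
#' Paths default to the layout written by [write_bundle()]: all tables and
#' a `depth/` directory of per-sample depth files under one input
#' directory.
#'
#' @param input_dir Directory holding `contigs.tsv`, `markers.tsv`,
#'   `amg.tsv`, `metadata.tsv`, optional `flux.tsv`, and `depth/`.
#' @param out_dir Output directory for stage TSVs and `summary.json`.
#' @param min_markers Marker-screening threshold (default 1).
#' @param min_identity Taxonomy identity threshold in percent (default 30).
#' @param alpha Significance level for flux correlation (default .05).
#' @param identified_only Renormalize taxon profiles over identified taxa.
#' @param require_module_gate Gate flux selection on module-trait
#'   significance (default FALSE).
#' @param bh_correction Benjamini-Hochberg correction in flux selection.
#' @param beta,min_module_size,cut_height Network-module parameters, used
#'   only when `require_module_gate` is TRUE.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir,
                       min_markers = 1L, min_identity = 30,
                       alpha = 0.05, identified_only = FALSE,
                       require_module_gate = FALSE, bh_correction = FALSE,
                       beta = 6, min_module_size = 5L, cut_height = 0.25) {
  if (alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must be in (0, 1)", call. = FALSE)
  }
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 min_markers = min_markers, min_identity = min_identity,
                 alpha = alpha, identified_only = identified_only,
                 require_module_gate = require_module_gate,
                 bh_correction = bh_correction, beta = beta,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "run_config")
}

bundle_paths <- function(input_dir) {
  list(contigs = file.path(input_dir, "contigs.tsv"),
       markers = file.path(input_dir, "markers.tsv"),
       amg = file.path(input_dir, "amg.tsv"),
       metadata = file.path(input_dir, "metadata.tsv"),
       flux = file.path(input_dir, "flux.tsv"),
       depth_dir = file.path(input_dir, "depth"))
}

list_depth_files <- function(depth_dir) {
  files <- sort(list.files(depth_dir, pattern = "\\.depth\\.tsv$",
                           full.names = TRUE))
  stats::setNames(files, sub("\\.depth\\.tsv$", "", basename(files)))
}

#' Validate a pipeline input bundle
#'
#' Cross-checks sample ids across metadata, depth files and the flux
#' table, and reports orphans, duplicates and trap samples lacking flux.
#' Nothing is mutated; by default issues are reported rather than raised.
#'
#' @param config A [run_config()].
#' @param strict Raise an error if any issue is found (default FALSE).
#' @return Data frame `level` (`"warning"`/`"error"`), `message`; zero
#'   rows for a consistent bundle.
#' @export
validate_inputs <- function(config, strict = FALSE) {
  stopifnot(inherits(config, "run_config"))
  p <- bundle_paths(config$input_dir)
  issues <- list()
  add <- function(level, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg,
                                                 stringsAsFactors = FALSE)
  }
  for (nm in c("contigs", "markers", "metadata")) {
    if (!file.exists(p[[nm]])) add("error", sprintf("missing input: %s", p[[nm]]))
  }
  if (file.exists(p$metadata)) {
    md <- read_tsv_strict(p$metadata, c("sample_id", "habitat"))
    dup <- unique(md$sample_id[duplicated(md$sample_id)])
    for (d in dup) add("error", sprintf("duplicated sample id in metadata: %s", d))
    if (dir.exists(p$depth_dir)) {
      df <- list_depth_files(p$depth_dir)
      for (o in setdiff(names(df), md$sample_id)) {
        add("warning", sprintf("depth file without metadata entry: %s", o))
      }
      for (o in setdiff(md$sample_id, names(df))) {
        add("warning", sprintf("metadata sample without depth file: %s", o))
      }
    }
    if (file.exists(p$flux)) {
      fl <- read_tsv_strict(p$flux, c("sample_id", "flux"))
      dupf <- unique(fl$sample_id[duplicated(fl$sample_id)])
      for (d in dupf) add("error", sprintf("duplicated sample id in flux table: %s", d))
      trap <- md$sample_id[md$habitat == "sediment_trap"]
      for (o in setdiff(trap, fl$sample_id)) {
        add("warning", sprintf("trap sample without flux value: %s", o))
      }
      for (o in setdiff(fl$sample_id, md$sample_id)) {
        add("warning", sprintf("flux entry without metadata sample: %s", o))
      }
    }
  }
  out <- if (length(issues) == 0L) {
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, issues)
  if (strict && nrow(out) > 0L) {
    stop(sprintf("input validation failed: %s", out$message[1L]), call. = FALSE)
  }
  out
}

#' Run the full analysis pipeline on an input bundle
#'
#' Stages: marker screening of the catalog; Q2Q3 coverage from per-base
#' depth files; sum-to-one and max-of-sample normalizations; taxonomy
#' assignment and taxon profiles; AMG proportion profiles; transport
#' report; export-pulse classification; gene-significance flux correlation
#' and selection. All stage tables are written as TSV under
#' `config$out_dir`, together with `summary.json` (catalog size,
#' trap-detected count, flux-correlated count, pulse-sample count) and a
#' plain-text log echoing the configuration. The run is a pure function of
#' the inputs: rerunning with the same bundle gives identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- bundle_paths(config$input_dir)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("gvshuttle %s",
                         as.character(utils::packageVersion("gvshuttle"))),
                 sprintf("R %s", as.character(getRversion())),
                 paste("config:", paste(names(unclass(config)),
                                        vapply(unclass(config), function(x)
                                          paste(format(x), collapse = ","),
                                          character(1)),
                                        sep = "=", collapse = " ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  catalog <- stage("read", read_tsv_strict(p$contigs, c("contig_id", "length_bp")))
  hits <- stage("read", read_tsv_strict(
    p$markers, c("contig_id", "marker", "ref_taxon", "pct_identity")))
  metadata <- stage("read", read_tsv_strict(
    p$metadata, c("sample_id", "depth_m", "habitat", "total_reads",
                  "mapped_reads")))
  amg <- stage("read", read_tsv_strict(p$amg, c("contig_id", "category")))

  # screen: catalog restricted to marker-qualified contigs
  keep_ids <- stage("screen", screen_contigs(hits, config$min_markers))
  catalog <- catalog[catalog$contig_id %in% keep_ids, , drop = FALSE]
  if (nrow(catalog) == 0L) stop("pipeline stage 'screen' left an empty catalog",
                                call. = FALSE)

  depth_files <- list_depth_files(p$depth_dir)
  if (length(depth_files) == 0L) {
    stop(sprintf("pipeline stage 'coverage' failed: no depth files under %s",
                 p$depth_dir), call. = FALSE)
  }
  raw <- stage("coverage", coverage_table(depth_files, catalog))
  rel <- stage("normalize", normalize_coverage(raw, "sum_to_one"))
  mx <- stage("normalize", normalize_coverage(raw, "max_of_sample"))

  taxonomy <- stage("taxonomy",
                    assign_taxonomy(hits, config$min_identity,
                                    contig_ids = catalog$contig_id))
  tprof <- stage("profiles", taxon_profile(rel, taxonomy,
                                           identified_only = config$identified_only))
  frm <- stage("profiles", fraction_reads_mapped(metadata))
  mapped_prof <- stage("profiles", depth_time_mean(
    stats::setNames(frm$pct_mapped, frm$sample_id), metadata))
  amg_prof <- stage("profiles", {
    cats <- sort(unique(amg$category))
    do.call(rbind, lapply(cats, function(ct) {
      pr <- amg_proportion(rel, amg, ct)
      data.frame(category = ct, sample_id = names(pr), proportion = pr,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  })

  report <- stage("transport", transport_report(raw, metadata))

  flux <- NULL; gs <- NULL; selected <- character(); modules <- NULL
  trap_ids <- metadata$sample_id[metadata$habitat == "sediment_trap"]
  if (file.exists(p$flux)) {
    flux <- stage("flux", classify_export_pulse(
      read_tsv_strict(p$flux, c("sample_id", "flux", "baseline_mean"))))
    trap_rel <- coverage_table_new(
      rel$values[, intersect(colnames(rel$values), trap_ids), drop = FALSE],
      "sum_to_one")
    gs <- stage("fluxcor", gene_significance(trap_rel, flux))
    if (config$require_module_gate) {
      modules <- stage("fluxcor", build_modules(
        trap_rel, flux, beta = config$beta,
        min_module_size = config$min_module_size,
        cut_height = config$cut_height))
    }
    selected <- stage("fluxcor", select_flux_correlated(
      gs, modules, alpha = config$alpha,
      require_module_gate = config$require_module_gate,
      bh_correction = config$bh_correction))
  } else if (length(trap_ids) > 0L) {
    log_lines <- c(log_lines, "note: no flux table; flux correlation skipped")
  }

  summary <- list(
    catalog_size = nrow(catalog),
    n_samples = ncol(raw$values),
    n_trap_samples = length(intersect(colnames(raw$values), trap_ids)),
    n_trap_detected = sum(report$transported),
    n_flux_correlated = length(selected),
    n_pulse_samples = if (is.null(flux)) 0L else sum(flux$pulse))

  # stage outputs
  wt(data.frame(contig_id = rownames(raw$values), raw$values,
                check.names = FALSE), "coverage_q2q3.tsv")
  wt(taxonomy, "taxonomy.tsv")
  if (nrow(tprof) > 0L) {
    wt(data.frame(taxon = rownames(tprof), tprof, check.names = FALSE),
       "taxon_profile.tsv")
  }
  wt(mapped_prof, "depth_profiles.tsv")
  wt(amg_prof, "amg_profiles.tsv")
  wt(report, "transport_report.tsv")
  if (!is.null(flux)) wt(flux, "flux_pulses.tsv")
  if (!is.null(gs)) wt(gs, "gene_significance.tsv")
  if (!is.null(modules)) wt(modules$assignments, "modules.tsv")
  utils::write.table(data.frame(contig_id = selected),
                     file.path(out_dir, "flux_correlated_contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(summary = summary, catalog = catalog, coverage = raw,
                 relative = rel, max_norm = mx, taxonomy = taxonomy,
                 taxon_profile = tprof, amg_profiles = amg_prof,
                 transport = report, flux = flux, gene_significance = gs,
                 modules = modules, flux_correlated = selected))
}
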