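# Synthetic metagenome time-series generator. Emulates the statistical
# structure the downstream analysis assumes: a contig x (depth x month)
# planktonic coverage matrix with log-depth Gaussian niches, a sediment-trap
# sample block at abyssal depth, a seasonal particulate-carbon flux series
# with designated summer export pulses, and planted transported and
# flux-coupled contig subsets recorded in a truth table.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a six-year, approximately monthly open-ocean station
#' time series: 15 nominal depths from 5 to 4000 m, 72 monthly cruises,
#' 63 sediment-trap samples at 4000 m over three years, and a catalog of
#' 1496 giant-virus contigs of which ~31.3% reach the trap and ~6.75% are
#' additionally coupled to carbon export flux.
#'
#' @param seed Integer master seed. One global seed drives per-sample
#'   derived streams, so extending the sample grid never perturbs
#'   previously generated samples.
#' @param depths_m Strictly increasing planktonic depth grid in metres.
#' @param n_months Number of monthly planktonic cruises.
#' @param n_trap_samples Number of sediment-trap samples.
#' @param n_contigs Catalog size.
#' @param contig_length_range Length-2 integer range of contig lengths (bp).
#' @param frac_transported Fraction of contigs planted as vertically
#'   transported (non-zero trap coverage).
#' @param frac_flux_coupled Fraction of contigs whose trap abundance is
#'   coupled to flux (a subset of the transported contigs).
#' @param coupling_effect Dimensionless slope of trap abundance on
#'   standardized flux for coupled contigs.
#' @param noise_sd Lognormal sigma of the multiplicative coverage noise.
#' @param pulse_months Calendar months (1-12) whose flux is amplified to at
#'   least 1.5x baseline (summer export pulses).
#' @param baseline_flux Long-term mean particulate carbon flux
#'   (mg C m^-2 d^-1); plays the role of the multi-decade baseline.
#' @param detection_limit Planktonic coverage below this value is truncated
#'   to zero, creating the sparse detection structure of real read mapping.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       depths_m = c(5, 25, 45, 75, 100, 125, 150, 175, 200,
                                    225, 250, 500, 770, 1000, 4000),
                       n_months = 72L,
                       n_trap_samples = 63L,
                       n_contigs = 1496L,
                       contig_length_range = c(5000L, 50000L),
                       frac_transported = 0.313,
                       frac_flux_coupled = 0.0675,
                       coupling_effect = 1.0,
                       noise_sd = 0.3,
                       pulse_months = c(7L, 8L),
                       baseline_flux = 1.0,
                       detection_limit = 0.05) {
  cfg <- list(seed = as.integer(seed), depths_m = as.numeric(depths_m),
              n_months = as.integer(n_months),
              n_trap_samples = as.integer(n_trap_samples),
              n_contigs = as.integer(n_contigs),
              contig_length_range = as.integer(contig_length_range),
              frac_transported = frac_transported,
              frac_flux_coupled = frac_flux_coupled,
              coupling_effect = coupling_effect,
              noise_sd = noise_sd,
              pulse_months = as.integer(pulse_months),
              baseline_flux = baseline_flux,
              detection_limit = detection_limit)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$depths_m) == 0L) {
    stop("configuration error: empty depth grid", call. = FALSE)
  }
  if (any(diff(cfg$depths_m) <= 0)) {
    stop("configuration error: depths must be strictly increasing", call. = FALSE)
  }
  for (f in c("frac_transported", "frac_flux_coupled")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("configuration error: %s must be in [0, 1]", f), call. = FALSE)
    }
  }
  if (cfg$n_contigs < 1L) {
    stop("configuration error: n_contigs must be >= 1", call. = FALSE)
  }
  if (cfg$n_months < 1L || cfg$n_trap_samples < 0L) {
    stop("configuration error: sample counts must be positive", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  }
  if (cfg$baseline_flux <= 0) {
    stop("configuration error: baseline_flux must be > 0", call. = FALSE)
  }
  if (diff(cfg$contig_length_range) < 0 || cfg$contig_length_range[1] < 1L) {
    stop("configuration error: invalid contig_length_range", call. = FALSE)
  }
  invisible(cfg)
}

# Per-sample derived stream: a deterministic 31-bit hash of (seed, index).
# Each sample draws its noise from its own stream so that appending samples
# leaves earlier samples byte-identical.
derived_seed <- function(seed, idx) {
  v <- ((abs(as.numeric(seed)) %% 65521) * 32749 +
          as.numeric(idx) * 7919 + 1) %% 2147483647
  as.integer(v)
}

with_seed <- function(s, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(s)
  expr
}

# Reference taxa used for the synthetic catalog: species observed among the
# taxonomically identifiable NCLDV populations of North Pacific station
# metagenomes.
SYNTH_TAXA <- c("Chrysochromulina ericina virus",
                "Organic lake phycodnavirus",
                "Phaeocystis globosa virus 14T",
                "Bathycoccus sp. RCC716 virus",
                "Mimiviridae sp. ChoanoV1",
                "Chlorella virus XW01",
                "Pyramimonas orientalis virus",
                "Aureococcus anophagefferens virus")

SYNTH_AMG_CATEGORIES <- c("photosynthesis", "carbon_metabolism", "rhodopsin",
                          "nitrogen_cycle", "ammonium_transporter",
                          "phosphate_transporter")

#' Generate a synthetic giant-virus metagenome dataset
#'
#' Produces an in-memory bundle: contig catalog, marker-gene hit table, AMG
#' annotation table, sample metadata, flux table, planted-truth table, and
#' a raw contig x sample Q2Q3 coverage matrix covering both the planktonic
#' depth/time grid and the sediment-trap block.
#'
#' The generative model, per contig i:
#' * a depth niche: mean coverage at depth d is
#'   `amp_i * exp(-(log10(d) - mu_i)^2 / (2 w_i^2))`, with `mu_i` uniform on
#'   the log10 depth span and width `w_i` uniform on 0.15-0.5 log10 units —
#'   reproducing surface, deep-chlorophyll-maximum and mesopelagic peak
#'   structure;
#' * multiplicative lognormal noise (`sdlog = noise_sd`) per sample;
#'   planktonic coverage below `detection_limit` is truncated to zero;
#' * transported contigs additionally receive positive trap coverage
#'   `base_i * noise`; flux-coupled contigs (a subset) instead receive
#'   `base_i * max(1 + coupling_effect * z(flux), 0.05) * noise`, where
#'   `z(flux)` is the standardized flux over trap samples.
#'
#' The flux series is a seasonal sinusoid around `baseline_flux` with
#' samples in `pulse_months` amplified to >= 1.5x baseline, guaranteeing
#' both pulse and non-pulse trap samples.
#'
#' @param config A [sim_config()].
#' @return A `gv_sim` list: `config`, `catalog`, `markers`, `amg`,
#'   `metadata`, `flux`, `coverage` (a raw [coverage_table_new()] object),
#'   `truth` (per contig: `transported`, `flux_coupled`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_contigs

  # --- contig-level parameters from the master stream ---
  ctg <- with_seed(cfg$seed, {
    ids <- sprintf("ctg_%05d", seq_len(n))
    lens <- sample(seq(cfg$contig_length_range[1], cfg$contig_length_range[2]),
                   n, replace = TRUE)
    lg <- log10(cfg$depths_m)
    mu <- stats::runif(n, min(lg), max(lg))
    w <- stats::runif(n, 0.15, 0.5)
    amp <- exp(stats::rnorm(n, log(15), 0.8))
    trap_base <- exp(stats::rnorm(n, log(3), 0.8))
    n_tr <- round(cfg$frac_transported * n)
    transported <- sort(sample.int(n, n_tr))
    n_fc <- round(cfg$frac_flux_coupled * n)
    if (n_fc > n_tr) {
      stop("configuration error: frac_flux_coupled cannot exceed frac_transported",
           call. = FALSE)
    }
    flux_coupled <- sort(transported[sample.int(length(transported), n_fc)])
    # markers: every cataloged contig has >= 1; a small tail reaches the
    # four-of-five MAG quality bar
    n_mark <- sample(1:5, n, replace = TRUE,
                     prob = c(0.62, 0.25, 0.105, 0.015, 0.01))
    identified <- stats::runif(n) < 0.209
    taxon <- ifelse(identified,
                    sample(SYNTH_TAXA, n, replace = TRUE), "NOVEL")
    has_amg <- stats::runif(n) < 0.25
    amg_cat <- ifelse(has_amg,
                      sample(SYNTH_AMG_CATEGORIES, n, replace = TRUE), NA)
    list(ids = ids, lens = lens, mu = mu, w = w, amp = amp,
         trap_base = trap_base, transported = transported,
         flux_coupled = flux_coupled, n_mark = n_mark, taxon = taxon,
         amg_cat = amg_cat)
  })

  # marker hit rows (own derived stream)
  markers <- with_seed(derived_seed(cfg$seed, 999983L), {
    rows <- lapply(seq_len(n), function(i) {
      mk <- sample(NCLDV_MARKERS, ctg$n_mark[i])
      if (ctg$taxon[i] != "NOVEL") {
        data.frame(contig_id = ctg$ids[i], marker = mk,
                   ref_taxon = ctg$taxon[i],
                   pct_identity = round(stats::runif(length(mk), 35, 95), 1),
                   stringsAsFactors = FALSE)
      } else {
        # weak spurious hits only: below any sensible identity cut-off
        data.frame(contig_id = ctg$ids[i], marker = mk,
                   ref_taxon = sample(SYNTH_TAXA, length(mk), replace = TRUE),
                   pct_identity = round(stats::runif(length(mk), 15, 28), 1),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })

  amg <- data.frame(contig_id = ctg$ids[!is.na(ctg$amg_cat)],
                    category = ctg$amg_cat[!is.na(ctg$amg_cat)],
                    stringsAsFactors = FALSE)

  # --- sample grid: month-major planktonic samples, then trap samples ---
  nd <- length(cfg$depths_m)
  plk_month <- rep(seq_len(cfg$n_months), each = nd)
  plk_depth <- rep(cfg$depths_m, times = cfg$n_months)
  plk_ids <- sprintf("PLK_m%03d_d%04d", plk_month, round(plk_depth))
  plk_dates <- seq(as.Date("2010-01-15"), by = "month",
                   length.out = cfg$n_months)[plk_month]

  n_trap <- cfg$n_trap_samples
  if (n_trap > 0L) {
    trap_ids <- sprintf("TRP_%03d", seq_len(n_trap))
    # ~3 years of trap deployments regardless of count: evenly spaced
    trap_dates <- as.Date("2014-01-10") +
      round(seq(0, 3 * 365 - 20, length.out = n_trap))
  } else {
    trap_ids <- character()
    trap_dates <- as.Date(character())
  }

  # --- flux series: seasonal sinusoid + designated pulse months ---
  flux <- NULL
  zflux <- numeric(0)
  if (n_trap > 0L) {
    doy <- as.integer(format(trap_dates, "%j"))
    cal_month <- as.integer(format(trap_dates, "%m"))
    flux_vals <- with_seed(derived_seed(cfg$seed, 999979L), {
      f <- cfg$baseline_flux *
        (1 + 0.3 * sin(2 * pi * (doy - 120) / 365)) *
        exp(stats::rnorm(n_trap, 0, 0.1))
      is_pulse_month <- cal_month %in% cfg$pulse_months
      f[is_pulse_month] <- pmax(f[is_pulse_month], 1.55 * cfg$baseline_flux)
      f
    })
    flux <- data.frame(sample_id = trap_ids, flux = flux_vals,
                       baseline_mean = cfg$baseline_flux,
                       stringsAsFactors = FALSE)
    zflux <- as.numeric(scale(flux_vals))
    if (any(!is.finite(zflux))) zflux <- rep(0, n_trap)  # degenerate n=1
  }

  # --- coverage matrix, one derived noise stream per sample ---
  lg <- log10(cfg$depths_m)
  vals <- matrix(0, nrow = n, ncol = length(plk_ids) + n_trap,
                 dimnames = list(ctg$ids, c(plk_ids, trap_ids)))
  for (j in seq_along(plk_ids)) {
    mu_term <- exp(-(log10(plk_depth[j]) - ctg$mu)^2 / (2 * ctg$w^2))
    noise <- with_seed(derived_seed(cfg$seed, j),
                       exp(stats::rnorm(n, 0, cfg$noise_sd)))
    v <- ctg$amp * mu_term * noise
    v[v < cfg$detection_limit] <- 0
    vals[, j] <- v
  }
  is_tr <- logical(n); is_tr[ctg$transported] <- TRUE
  is_fc <- logical(n); is_fc[ctg$flux_coupled] <- TRUE
  for (t in seq_len(n_trap)) {
    j <- length(plk_ids) + t
    noise <- with_seed(derived_seed(cfg$seed, 500000L + t),
                       exp(stats::rnorm(n, 0, cfg$noise_sd)))
    mult <- rep(1, n)
    # linear response floored at a small positive value so coupled contigs
    # stay detectable in every trap sample
    mult[is_fc] <- pmax(1 + cfg$coupling_effect * zflux[t], 0.05)
    v <- ctg$trap_base * mult * noise
    v[!is_tr] <- 0
    vals[, j] <- v
  }

  # --- metadata ---
  meta_noise <- with_seed(derived_seed(cfg$seed, 999961L), {
    list(tot = round(exp(stats::rnorm(length(plk_ids) + n_trap, log(4e6), 0.3))),
         eps = exp(stats::rnorm(length(plk_ids) + n_trap, 0, 0.15)))
  })
  all_depth <- c(plk_depth, rep(4000, n_trap))
  # read recruitment to the catalog ~0.5% with a peak near 150-225 m
  frac <- 0.005 * (0.8 + 0.7 * exp(-((log10(all_depth) - log10(180)) / 0.12)^2 / 2)) *
    meta_noise$eps
  metadata <- data.frame(
    sample_id = c(plk_ids, trap_ids),
    date = as.character(c(plk_dates, trap_dates)),
    depth_m = all_depth,
    habitat = c(rep("planktonic", length(plk_ids)),
                rep("sediment_trap", n_trap)),
    total_reads = meta_noise$tot,
    mapped_reads = round(meta_noise$tot * frac),
    stringsAsFactors = FALSE)

  catalog <- data.frame(contig_id = ctg$ids, length_bp = ctg$lens,
                        stringsAsFactors = FALSE)
  truth <- data.frame(contig_id = ctg$ids,
                      transported = is_tr, flux_coupled = is_fc,
                      taxon = ctg$taxon,
                      niche_logdepth = ctg$mu,
                      stringsAsFactors = FALSE)

  structure(list(config = cfg, catalog = catalog, markers = markers,
                 amg = amg, metadata = metadata, flux = flux,
                 coverage = coverage_table_new(vals, "raw"), truth = truth),
            class = "gv_sim")
}

#' @export
print.gv_sim <- function(x, ...) {
  cat(sprintf(paste0("gv_sim: %d contigs, %d planktonic + %d trap samples, ",
                     "%d transported (%d flux-coupled)\n"),
              nrow(x$catalog),
              sum(x$metadata$habitat == "planktonic"),
              sum(x$metadata$habitat == "sediment_trap"),
              sum(x$truth$transported), sum(x$truth$flux_coupled)))
  invisible(x)
}

#' Write per-base depth files for a simulated dataset
#'
#' Materializes each sample of a simulated bundle as a samtools-depth-style
#' TSV (contig, 1-based position, depth; zero-depth positions omitted).
#' Per-base depths are drawn as Poisson counts around each contig's
#' simulated coverage level, using one derived random stream per sample, and
#' the realized in-memory Q2Q3 values are returned so callers can verify
#' that parsing the files reproduces them exactly.
#'
#' Intended for modest problem sizes (the per-base representation is
#' length x contigs x samples); large-scale statistical experiments use the
#' in-memory coverage matrix directly.
#'
#' @param sim A `gv_sim` bundle.
#' @param dir Output directory (created if needed); one `<sample_id>.depth.tsv`
#'   per sample.
#' @param samples Optional subset of sample ids to write.
#' @return Invisibly, a list with `files` (named paths) and `q2q3` (the
#'   realized raw coverage matrix for the written samples).
#' @export
write_depth_files <- function(sim, dir, samples = NULL) {
  stopifnot(inherits(sim, "gv_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- colnames(sim$coverage$values)
  if (!is.null(samples)) {
    if (!all(samples %in% ids)) stop("unknown sample id requested", call. = FALSE)
    ids <- samples
  }
  lens <- stats::setNames(sim$catalog$length_bp, sim$catalog$contig_id)
  files <- character(0)
  realized <- matrix(0, nrow = nrow(sim$coverage$values), ncol = length(ids),
                     dimnames = list(rownames(sim$coverage$values), ids))
  for (sid in ids) {
    j <- match(sid, colnames(sim$coverage$values))
    path <- file.path(dir, paste0(sid, ".depth.tsv"))
    rows <- with_seed(derived_seed(sim$config$seed, 800000L + j), {
      out <- vector("list", nrow(sim$catalog))
      for (i in seq_len(nrow(sim$catalog))) {
        lam <- sim$coverage$values[i, j]
        if (lam <= 0) next
        L <- lens[[i]]
        d <- stats::rpois(L, lam)
        realized[rownames(realized)[i], sid] <- q2q3(d)
        nz <- which(d > 0L)
        if (length(nz) == 0L) next
        out[[i]] <- data.frame(contig = names(lens)[i], pos = nz,
                               depth = d[nz], stringsAsFactors = FALSE)
      }
      out
    })
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(tab)) {
      file.create(path)
    } else {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    files[sid] <- path
  }
  invisible(list(files = files, q2q3 = realized))
}

#' Write a simulated bundle to disk as plain TSV files
#'
#' Writes `contigs.tsv`, `markers.tsv`, `amg.tsv`, `metadata.tsv`,
#' `flux.tsv`, `truth.tsv`, per-sample depth files under `depth/`, and a
#' `manifest.yaml` echoing the configuration and all paths. The directory
#' is a complete, self-describing input set for [run_pipeline()].
#'
#' @param sim A `gv_sim` bundle.
#' @param dir Output directory.
#' @param depth_files Write per-base depth files (default TRUE; disable for
#'   large bundles where the in-memory coverage matrix is used directly).
#' @return Invisibly, the manifest list.
#' @export
write_bundle <- function(sim, dir, depth_files = TRUE) {
  stopifnot(inherits(sim, "gv_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  manifest <- list(
    config = unclass(sim$config),
    files = list(
      contigs = wt(sim$catalog, "contigs.tsv"),
      markers = wt(sim$markers, "markers.tsv"),
      amg = wt(sim$amg, "amg.tsv"),
      metadata = wt(sim$metadata, "metadata.tsv"),
      truth = wt(sim$truth, "truth.tsv")))
  if (!is.null(sim$flux)) manifest$files$flux <- wt(sim$flux, "flux.tsv")
  if (depth_files) {
    dd <- write_depth_files(sim, file.path(dir, "depth"))
    manifest$files$depth_dir <- file.path(dir, "depth")
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
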