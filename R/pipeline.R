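#' Read a (multi-page) TIFF image stack
#'
#' Greyscale 8/16-bit or float TIFFs are read into a numeric array
#' `(y, x, frame)` on the encoded 0..1 scale. Pixel size is taken from
#' the config override; TIFF resolution metadata, when present and no
#' override is given, is used as um/px.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size override (um/px); required when the
#'   file carries no resolution metadata.
#' @return Numeric array with attribute `pixel_size_um`.
#' @export
read_image_stack <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("no images in ", path, call. = FALSE)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # first channel of RGB pages
    p
  })
  if (is.null(pixel_size_um)) {
    info <- attributes(pages[[1]])
    if (!is.null(info$x.resolution) && info$x.resolution > 0)
      pixel_size_um <- 1e4 / info$x.resolution  # assume res in px/cm
    else stop("no pixel size metadata in ", path,
              "; pass pixel_size_um", call. = FALSE)
  }
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  attr(arr, "pixel_size_um") <- pixel_size_um
  arr
}

#' Write an image stack as a multi-page TIFF
#'
#' @param stack Numeric array `(y, x, frame)` or matrix, values in
#'   0..1 (values outside are clipped).
#' @param path Output path.
#' @param bits_per_sample 8, 16 or 32 (32 = float, lossless).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits_per_sample = 16) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  stack <- pmin(pmax(stack, 0), 1)
  dim(stack) <- dim(stack)  # keep dims after pmin/pmax
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Write / read a table as RFC-4180 CSV
#'
#' @param rows Data frame.
#' @param path File path.
#' @return `write_table` returns `path` invisibly; `read_table_csv`
#'   returns a data frame.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a run configuration
#'
#' A run configuration binds the physical constants, acquisition
#' parameters, synthesis settings and statistical options of an
#' end-to-end run; it can be read from YAML. Unspecified components
#' take the package defaults. The configuration hash recorded in every
#' output identifies the exact parameter set that produced it.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "flow", "tracking", "morpho", "pericyte", "qpcr")`.
#' @param q0_ul_min Initial flow rate for the flow stage (ul/min).
#' @param geometry,constants,volumes,acquisition Component objects (or
#'   lists of fields overriding the defaults).
#' @param q_min_ul_min Flow stop threshold (ul/min).
#' @param fold_changes Named fold changes for the synthetic Ct design.
#' @param reference_genes Reference genes for the qPCR stage.
#' @param fdr_q Target FDR for the statistics.
#' @param seed Integer seed for all synthetic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stages = c("synth", "flow", "tracking", "morpho",
                                  "pericyte", "qpcr"),
                       q0_ul_min = 3.1,
                       geometry = chip_geometry(),
                       constants = fluid_constants(),
                       volumes = volume_condition(),
                       acquisition = acquisition_params(),
                       q_min_ul_min = 0.02,
                       fold_changes = c(ACTA2 = 9.5, CSPG4 = 4.5,
                                        PECAM1 = 3.3, COL4A1 = 4),
                       reference_genes = c("RNA18S", "GAPDH"),
                       fdr_q = 0.05,
                       seed = 1) {
  as_component <- function(x, ctor) {
    if (inherits(x, "list") && is.null(attr(x, "class")))
      do.call(ctor, x) else x
  }
  structure(list(
    stages = stages, q0_ul_min = q0_ul_min,
    geometry = as_component(geometry, chip_geometry),
    constants = as_component(constants, fluid_constants),
    volumes = as_component(volumes, volume_condition),
    acquisition = as_component(acquisition, acquisition_params),
    q_min_ul_min = q_min_ul_min, fold_changes = fold_changes,
    reference_genes = reference_genes, fdr_q = fdr_q, seed = seed),
    class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file whose top-level keys
#'   are `run_config` arguments.
#' @export
read_run_config <- function(path) {
  fields <- yaml::read_yaml(path)
  if (!is.null(fields$fold_changes))
    fields$fold_changes <- unlist(fields$fold_changes)
  do.call(run_config, fields)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order -- synthetic-data
#' generation, drainage simulation, flow-front tracking of a synthetic
#' stack, vessel morphometry of a synthetic tube network, pericyte
#' coverage of a constructed overlap pair, and qPCR fold-change
#' statistics -- writing one CSV per stage plus a JSON run manifest
#' into `out_dir`. Every output table carries the configuration hash;
#' re-running the same configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: config hash, package version,
#'   per-stage output paths and warnings.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  outputs <- list()
  warnings <- character()
  stamp <- function(df) { df$config_hash <- hash; df }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  synth <- NULL
  if (any(c("synth", "tracking", "morpho", "pericyte", "qpcr") %in%
          config$stages)) {
    synth <- run_stage("synth", {
      segs <- data.frame(x0 = c(30, 150), y0 = c(100, 40),
                         x1 = c(270, 150), y1 = c(100, 260),
                         width = c(40, 24))
      tubes <- synth_tube_network(segs, canvas_px = 300,
                                  noise_sd = 3, seed = config$seed)
      stack <- synth_flow_stack(config$q0_ul_min, config$volumes,
                                config$geometry, config$acquisition,
                                seed = config$seed)
      pair <- synth_overlap_pair(100, overlap_fraction = 0.5,
                                 seed = config$seed)
      ct <- synth_ct_table(config$fold_changes,
                           reference_genes = config$reference_genes,
                           seed = config$seed)
      list(tubes = tubes, stack = stack, pair = pair, ct = ct)
    })
    if ("synth" %in% config$stages) {
      tif <- file.path(out_dir, "synthetic_tubes.tif")
      write_image_stack(synth$tubes$image / max(synth$tubes$image), tif)
      ctf <- file.path(out_dir, "synthetic_ct.csv")
      write_table(stamp(synth$ct), ctf)
      outputs$synth <- c(tubes_tiff = tif, ct_csv = ctf)
    }
  }

  if ("flow" %in% config$stages) {
    fs <- run_stage("flow", simulate_drainage(
      config$q0_ul_min, config$volumes, config$geometry, config$constants,
      q_min_ul_min = config$q_min_ul_min))
    path <- file.path(out_dir, "flow_series.csv")
    keep <- seq(1, nrow(fs), length.out = min(nrow(fs), 200))
    write_table(stamp(as.data.frame(fs)[round(keep),
                c("t_min", "q_ul_min", "dh_mm", "dp_pa")]), path)
    summ <- list(duration_min = flow_duration(fs),
                 duration_h_rounded = flow_duration(fs, "h", TRUE),
                 tau_min = attr(fs, "tau_min"),
                 r_hyd_si = attr(fs, "r_hyd_si"),
                 config_hash = hash)
    sp <- file.path(out_dir, "flow_summary.json")
    jsonlite::write_json(summ, sp, auto_unbox = TRUE, digits = NA)
    outputs$flow <- c(series_csv = path, summary_json = sp)
  }

  if ("tracking" %in% config$stages) {
    res <- run_stage("tracking", analyze_flow_stack(
      synth$stack$stack, config$acquisition, config$geometry))
    path <- file.path(out_dir, "front_tracking.csv")
    write_table(stamp(res), path)
    outputs$tracking <- c(csv = path)
  }

  if ("morpho" %in% config$stages) {
    # phantom images carry controlled noise: full display range, no blur
    res <- run_stage("morpho", quantify_vessel_stack(
      synth$tubes$image, pixel_size_um = 1, display_range = c(0, 140),
      sigma = 0))
    df <- data.frame(area_percent = res$metrics$area_percent,
                     total_length_um = res$metrics$total_length_um,
                     mean_diameter_um = res$metrics$mean_diameter_um,
                     truth_area_percent = synth$tubes$truth$area_percent,
                     truth_length_um = synth$tubes$truth$total_length_um,
                     truth_diameter_um = synth$tubes$truth$mean_diameter_um)
    path <- file.path(out_dir, "network_metrics.csv")
    write_table(stamp(df), path)
    outputs$morpho <- c(csv = path)
  }

  if ("pericyte" %in% config$stages) {
    res <- run_stage("pericyte", pericyte_metrics(
      synth$pair$a, synth$pair$b))
    df <- data.frame(pericyte_area_percent = res$pericyte_area_percent,
                     coverage_percent = res$coverage_percent)
    path <- file.path(out_dir, "pericyte_metrics.csv")
    write_table(stamp(df), path)
    outputs$pericyte <- c(csv = path)
  }

  if ("qpcr" %in% config$stages) {
    res <- run_stage("qpcr", {
      scheme <- normalization_scheme(config$reference_genes)
      fc <- fold_change_table(synth$ct, scheme)
      stats <- compare_groups(fc, q = config$fdr_q)
      list(fc = fc, stats = stats)
    })
    fcp <- file.path(out_dir, "fold_changes.csv")
    stp <- file.path(out_dir, "gene_stats.csv")
    write_table(stamp(res$fc), fcp)
    write_table(stamp(res$stats), stp)
    outputs$qpcr <- c(fold_changes_csv = fcp, stats_csv = stp)
  }

  manifest <- list(config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("chipvasc")),
                   stages = config$stages,
                   outputs = outputs,
                   warnings = warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
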