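# End-to-end pipeline: ancestral ranges -> rate shifts -> regional series,
# with a JSON manifest recording seeds, parameters, input checksums and
# every output file.

.pipeline_defaults <- function() {
  list(tree = NULL, trees = NULL, regions = NULL, richness = NULL,
       clade_ages = NULL, out_dir = "drydiv-out", seed = 1L,
       max_trees = NULL, max_areas = NULL, strict_vicariance = FALSE,
       grid_step = 0.1, start = NULL, end = NULL, rho = 1, kmax = 1L,
       alpha = 0.05, df_per_shift = 3L, turnover = "free",
       bin_width = 5, window = c(15, 10), method = "ancestral",
       quiet = FALSE)
}

#' Assemble and validate a pipeline configuration
#'
#' Precedence: explicit arguments in `...` > values in the JSON config
#' `file` > package defaults.
#'
#' @param file optional JSON config file.
#' @param ... named overrides of any configuration field (see
#'   [run_pipeline()]).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- .pipeline_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop_drydiv("drydiv_config", "config file not found: %s", file)
    }
    fromfile <- jsonlite::read_json(file, simplifyVector = TRUE)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown) > 0L) {
      stop_drydiv("drydiv_config", "unknown config field(s): %s",
                  paste(unknown, collapse = ", "))
    }
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop_drydiv("drydiv_config", "unknown config field(s): %s",
                paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  for (f in c("tree", "regions")) {
    if (is.null(cfg[[f]])) {
      stop_drydiv("drydiv_config", "config field '%s' is required", f)
    }
  }
  for (f in c("tree", "trees", "regions", "richness", "clade_ages")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop_drydiv("drydiv_config", "%s file not found: %s", f, cfg[[f]])
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the three analysis stages in order — ancestral-range
#' reconstruction (S-DIVA + dispersal events), diversification-shift
#' detection (grid-search LRT selection + missing-taxa profile), and
#' regional divergence statistics — writing TSV/JSON outputs and a
#' manifest to `out_dir`.  Identical configurations and seeds reproduce
#' every output byte-for-byte; on a stage error, that stage's partial
#' outputs are renamed with a `.partial` suffix and a classed error names
#' the stage.
#'
#' @param config a [pipeline_config()], a JSON config path, or a list of
#'   fields.  Required fields: `tree` (representative chronogram path) and
#'   `regions`; optional `trees` (posterior sample), `richness`,
#'   `clade_ages`; analysis parameters `max_areas`, `grid_step`, `start`,
#'   `end`, `rho`, `kmax`, `alpha`, `df_per_shift`, `turnover`,
#'   `bin_width`, `window`, `method`, `max_trees`, `seed`, `out_dir`.
#' @param stages which stages to execute (the CLI's per-stage subcommands
#'   restrict this); inputs are always loaded and validated first.
#' @return (invisibly) the manifest list, also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("ancestral", "shifts", "regional")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) config <- pipeline_config(file = config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  say <- function(stage, msg) {
    if (!isTRUE(cfg$quiet)) message(sprintf("[drydiv:%s] %s", stage, msg))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage_files <- character(0)
  emit <- function(path) {
    outputs <<- c(outputs, path)
    stage_files <<- c(stage_files, path)
    path
  }
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    stage_files <<- character(0)
    tryCatch(fun(), error = function(e) {
      for (f in stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop_drydiv("drydiv_stage_failure", "stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
  }

  say("load", sprintf("reading inputs (tree=%s)", cfg$tree))
  tree <- read_chronogram(cfg$tree)
  regions <- read_region_table(cfg$regions)
  sample_trees <- if (!is.null(cfg$trees)) {
    read_tree_sample(cfg$trees, max_trees = cfg$max_trees,
                     seed = derive_seed(cfg$seed, 1L))
  } else tree_sample(list(tree), provenance = "mcc")
  richness <- if (!is.null(cfg$richness)) read_clade_richness(cfg$richness)
  clade_ages <- if (!is.null(cfg$clade_ages)) read_clade_ages(cfg$clade_ages)
  cost_model <- diva_cost_model(max_areas = cfg$max_areas,
                                strict_vicariance =
                                  isTRUE(cfg$strict_vicariance))
  # the representative tree contributes to the sample as an extra member
  all_trees <- tree_sample(c(unclass(sample_trees), list(tree)),
                           representative = tree, provenance = "synthetic",
                           validate = FALSE)

  run_stage("ancestral", function() {
    say("ancestral", sprintf("S-DIVA over %d trees", length(all_trees)))
    nrf <- sdiva(all_trees, regions, tree, cost_model)
    ntip <- ape::Ntip(tree)
    long <- do.call(rbind, lapply(seq_len(nrow(nrf$prob)), function(i) {
      p <- nrf$prob[i, ]
      sel <- which(!is.na(p) & p > 1e-9)
      if (length(sel) == 0L) return(NULL)
      data.frame(node = ntip + i, clade = nrf$node_keys[i],
                 coverage = nrf$coverage[i], range = nrf$state_labels[sel],
                 probability = unname(p[sel]), stringsAsFactors = FALSE)
    }))
    emit(.write_tsv(long, file.path(cfg$out_dir, "node_ranges.tsv")))
    disp <- extract_dispersals(nrf, rule = "modal", regions = regions)
    emit(.write_tsv(disp, file.path(cfg$out_dir, "dispersals.tsv")))
  })

  run_stage("shifts", function() {
    say("shifts", "grid-search shift detection")
    mfp <- NULL
    start <- cfg$start
    if (!is.null(richness)) {
      mfp <- missing_fraction_profile(tree, richness,
                                      grid_step = cfg$grid_step)
      emit(.write_tsv(mfp, file.path(cfg$out_dir, "missing_fraction.tsv")))
      if (is.null(start) && !is.na(attr(mfp, "jump_time"))) {
        start <- attr(mfp, "jump_time")
      }
    }
    fit <- fit_shifts(tree, kmax = cfg$kmax, grid_step = cfg$grid_step,
                      start = start, end = cfg$end, rho = cfg$rho,
                      df_per_shift = cfg$df_per_shift, alpha = cfg$alpha,
                      turnover = cfg$turnover,
                      seed = derive_seed(cfg$seed, 2L))
    emit(.write_tsv(fit$table, file.path(cfg$out_dir, "shift_models.tsv")))
    sel <- fit$fits[[fit$selected + 1L]]
    emit(file.path(cfg$out_dir, "selected_model.json"))
    jsonlite::write_json(
      list(k = sel$k, shift_times = sel$shift_times,
           net_rate = sel$r, turnover = sel$eps,
           lambda = sel$lambda, mu = sel$mu, loglik = sel$loglik,
           rho = cfg$rho,
           missing_taxa_cutoff = if (!is.null(mfp))
             attr(mfp, "jump_time") else NULL),
      file.path(cfg$out_dir, "selected_model.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  })

  run_stage("regional", function() {
    say("regional", sprintf("regional series over %d trees (method=%s)",
                            length(all_trees), cfg$method))
    assign <- assign_node_regions(all_trees, regions, method = cfg$method,
                                  cost_model = cost_model)
    rep_index <- length(all_trees)   # representative appended last
    series <- divergence_series(assign, bin_width = cfg$bin_width)
    emit(.write_tsv(series, file.path(cfg$out_dir, "divergence_series.tsv")))
    cum <- cumulative_accumulation(assign, index = rep_index)
    emit(.write_tsv(cum, file.path(cfg$out_dir, "cumulative.tsv")))
    fits <- fit_exponential(cum)
    emit(.write_tsv(fits, file.path(cfg$out_dir, "exponential_fits.tsv")))
    dens <- lineage_density(assign, index = rep_index)
    emit(.write_tsv(dens, file.path(cfg$out_dir, "lineage_density.tsv")))
    if (!is.null(clade_ages)) {
      sy <- synchrony_table(clade_ages, window = cfg$window)
      emit(.write_tsv(sy, file.path(cfg$out_dir, "synchrony.tsv")))
    }
  })

  inputs <- Filter(Negate(is.null),
                   cfg[c("tree", "trees", "regions", "richness",
                         "clade_ages")])
  manifest <- list(
    package = "drydiv",
    version = as.character(utils::packageVersion("drydiv")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg),
                             c("tree", "trees", "regions", "richness",
                               "clade_ages", "out_dir", "quiet"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(sort(outputs), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("done", sprintf("%d output files in %s", length(outputs) + 1L,
                      cfg$out_dir))
  invisible(manifest)
}
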