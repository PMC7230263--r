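#' Default demonstration pipeline configuration
#'
#' A small end-to-end configuration (reduced tile grid, two doses, one
#' fluid-dynamics case) that runs in well under a minute; the full-channel
#' defaults of the individual stages are documented in [scene_spec()] and
#' [sweep_nodule_geometry()].
#'
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_demo_config <- function() {
  list(
    master_seed = 1L,
    synth = list(grid_rows = 2L, grid_cols = 2L, tile_px = 128L,
                 n_planes = 4L, nodule_count = 12L,
                 doses = c(0, 500), survival_fractions = c(1, 0.18),
                 replicates = 3L, cv = 0.05),
    quant = list(cutoff = 2000, streaming = FALSE),
    stats = list(control_dose = 0),
    fluids = list(a_um = 40, porous = FALSE, height_um = 250,
                  length_mm = 1.2, cell_size_um = 4))
}

#' Run the full synthesize / quantify / summarize / fluids pipeline
#'
#' Orchestrates the four stages end to end: generates a synthetic
#' dose-response imaging experiment, quantifies every channel, normalizes
#' to the dose-0 controls and summarizes (mean +/- SEM, ANOVA with
#' Dunnett-style contrasts), and runs the requested fluid-dynamics cases.
#' All outputs are written to `output_dir` as CSV (first line a `# config
#' <hash>` comment embedding the configuration hash) plus a JSON manifest
#' recording the seed, configuration and stage timings. A failure in any
#' stage aborts with a stage-tagged error.
#'
#' @param config Nested configuration list; see [default_demo_config()]
#'   for the schema (top-level keys `master_seed`, `synth`, `quant`,
#'   `stats`, `fluids`; unknown keys are an error).
#' @param output_dir Directory for outputs (created if needed).
#' @param dry_run Validate the configuration and return the manifest
#'   skeleton without computing or writing anything.
#' @return (Invisibly) the manifest list; files `quant.csv`,
#'   `stats_summary.csv`, `stats_tests.csv`, `fluids_sweep.csv`,
#'   `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config = default_demo_config(),
                         output_dir = tempfile("perfushear_run_"),
                         dry_run = FALSE) {
  .validate_config(config)
  seed <- as.integer(config$master_seed)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  hash <- .config_hash(cfg_json)
  manifest <- list(package = "perfushear",
                   version = as.character(utils::packageVersion("perfushear")),
                   master_seed = seed, config_hash = hash,
                   config = config, outputs = character(0),
                   timings_s = list())
  if (dry_run) return(invisible(manifest))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- proc.time()[[3]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
    manifest$timings_s[[name]] <<- round(proc.time()[[3]] - t0, 2)
    out
  }
  emit <- function(df, file) {
    path <- file.path(output_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# config %s seed %d", hash, seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    manifest$outputs <<- c(manifest$outputs, file)
    path
  }

  ## ---- synth + quant + stats -------------------------------------------
  sy <- config$synth
  spec <- scene_spec(grid_rows = sy$grid_rows, grid_cols = sy$grid_cols,
                     tile_px = sy$tile_px, n_planes = sy$n_planes,
                     nodule_count = sy$nodule_count, seed = seed)
  expt <- stage("synth", simulate_experiment(
    doses = sy$doses, survival_fractions = sy$survival_fractions,
    replicates = sy$replicates, spec = spec, cv = sy$cv))

  qu <- config$quant
  quant_tbl <- stage("quant", {
    params <- do.call(calibrate_threshold, calibration_images(spec))
    rows <- list()
    for (d in seq_along(expt$doses)) for (r in seq_len(sy$replicates)) {
      qr <- quantify_channel(expt$datasets[[d]][[r]], params,
                             min_size_um2 = qu$cutoff,
                             streaming = isTRUE(qu$streaming))
      rows[[length(rows) + 1L]] <- data.frame(
        dose = expt$doses[d], replicate = r,
        live_area_um2 = qr$live_area_um2, object_count = qr$object_count,
        cutoff_um2 = qu$cutoff)
    }
    do.call(rbind, rows)
  })

  st <- config$stats
  stats_out <- stage("stats", {
    ctrl <- quant_tbl$live_area_um2[quant_tbl$dose == st$control_dose]
    norm <- normalize_to_control(quant_tbl$live_area_um2, ctrl)
    quant_tbl$normalized_area <- norm$treated
    by_dose <- split(quant_tbl$normalized_area, quant_tbl$dose)
    summ <- do.call(rbind, lapply(names(by_dose), function(d) {
      gs <- group_summary(by_dose[[d]], d)
      data.frame(dose = as.numeric(d), n = gs$n, mean_normalized = gs$mean,
                 sem = gs$sem)
    }))
    tests <- if (length(by_dose) >= 2L && all(lengths(by_dose) >= 2L)) {
      ord <- order(as.numeric(names(by_dose)) != st$control_dose)
      ad <- anova_dunnett(by_dose[ord], control_index = 1L,
                          seed = seed + 7L)
      data.frame(test = c("one-way ANOVA F",
                          rep("Dunnett vs control", nrow(ad$comparisons))),
                 group = c(NA, ad$comparisons$group),
                 statistic = c(ad$anova$statistic, ad$comparisons$statistic),
                 p = c(ad$anova$p_value, ad$comparisons$p_adjusted))
    } else data.frame(test = character(0), group = character(0),
                      statistic = numeric(0), p = numeric(0))
    list(quant = quant_tbl, summary = summ, tests = tests)
  })
  emit(stats_out$quant, "quant.csv")
  emit(stats_out$summary, "stats_summary.csv")
  emit(stats_out$tests, "stats_tests.csv")

  ## ---- fluids -----------------------------------------------------------
  fl <- config$fluids
  sweep <- stage("fluids", sweep_nodule_geometry(
    a_values = fl$a_um * 1e-6,
    porous_states = if (isTRUE(fl$porous)) c(FALSE, TRUE) else FALSE,
    geom = channel_geometry(height = fl$height_um * 1e-6,
                            length = fl$length_mm * 1e-3),
    mesh = mesh_spec(fl$cell_size_um * 1e-6)))
  emit(sweep, "fluids_sweep.csv")

  manifest$outputs <- c(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  allowed <- c("master_seed", "synth", "quant", "stats", "fluids")
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(allowed, names(config))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  blocks <- list(
    synth = c("grid_rows", "grid_cols", "tile_px", "n_planes",
              "nodule_count", "doses", "survival_fractions", "replicates",
              "cv"),
    quant = c("cutoff", "streaming"),
    stats = c("control_dose"),
    fluids = c("a_um", "porous", "height_um", "length_mm", "cell_size_um"))
  for (nm in names(blocks)) {
    bad <- setdiff(names(config[[nm]]), blocks[[nm]])
    if (length(bad))
      stop(sprintf("unknown keys in config$%s: %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    miss <- setdiff(blocks[[nm]], names(config[[nm]]))
    if (length(miss))
      stop(sprintf("missing keys in config$%s: %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(config$master_seed))
    stop("master_seed must be an integer", call. = FALSE)
  invisible(TRUE)
}

## dependency-free stable hash (FNV-1a over the serialized config JSON)
.config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
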