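#' Default run configuration for the full pipeline
#'
#' A single structured configuration driving every stage: scenario
#' (grid/flow/river), exposure parameters, community synthesis, and the
#' analysis settings (rarefaction depth, permutation counts, model terms).
#' The bundled defaults describe the desk-scale study: a 90 x 60 cell, 2 km
#' coastal grid with a land strip on the left edge, an alongshore residual
#' current of 0.1 m/s, one river with a wet-season flood hydrograph, and the
#' seven-site transect of [default_sites()].
#'
#' @param seed Master seed.
#' @return A nested list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    scenario = list(
      grid = list(nx = 90, ny = 60, dx = 2000, dy = 2000, land_cols = 2),
      flow = list(u = 0.02, v = 0.1,
                  description = "residual alongshore coastal current (+y)"),
      river = list(name = "tully", mouth = c(4, 15),
                   base_discharge = 2000,      # ML/d dry baseflow
                   flood_discharge = 60000,    # ML/d wet-season floods
                   flood_start = "2010-12-01", flood_end = "2011-03-10"),
      transport = list(K = 50, dt = 1800, depth = 5, boundary_mode = "open"),
      window = list(start = "2010-11-01", end = "2011-03-31")),
    exposure = list(threshold_fraction = 0.01, season_start = "11-01",
                    season_end = "03-31", map_cap = 20, snapshot_interval = 7),
    synthesis = list(euk_rate = 0.02, wet_offset = 0.5, season_shift = 0.05),
    analysis = list(rarefaction_depth = 279, n_perm = 999,
                    permanova_terms = c("category", "season")),
    seed = as.integer(seed)), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config` list.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  need <- c("scenario", "exposure", "synthesis", "analysis", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("run config missing block(s): ", paste(missing, collapse = ", "))
  g <- cfg$scenario$grid
  if (is.null(g$nx) || is.null(g$ny) || g$nx < 3 || g$ny < 3)
    stop("run config: invalid grid block")
  if (is.null(cfg$scenario$river$mouth)) stop("run config: river mouth missing")
  invisible(TRUE)
}

# build grid/flow/sources/params from the scenario block
build_scenario <- function(cfg) {
  sc <- cfg$scenario
  g <- sc$grid
  mask <- matrix(TRUE, g$nx, g$ny)
  if (g$land_cols > 0) mask[seq_len(g$land_cols), ] <- FALSE
  grid <- make_grid(g$nx, g$ny, g$dx, g$dy, mask)
  flow <- make_flow(grid, u = sc$flow$u, v = sc$flow$v,
                    description = sc$flow$description)
  window <- seq(as.Date(sc$window$start), as.Date(sc$window$end), by = "day")
  rv <- sc$river
  hydro <- data.frame(
    date = window,
    discharge = ifelse(window >= as.Date(rv$flood_start) &
                       window <= as.Date(rv$flood_end),
                       rv$flood_discharge, rv$base_discharge))
  src <- river_source(grid, unlist(rv$mouth), hydro, name = rv$name)
  tp <- sc$transport
  params <- transport_params(K = tp$K, dt = tp$dt, depth = tp$depth,
                             boundary_mode = tp$boundary_mode)
  list(grid = grid, flow = flow, sources = list(src), params = params,
       window = window)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: tracer simulation, exposure
#' maps, site classification and per-site exposure, synthetic community and
#' environment generation, diversity statistics, and multivariate
#' statistics (PCoA, PERMANOVA, indicator species, EFA, Pearson screening,
#' RDA), writing every stage output as TSV/JSON under `outdir` and returning
#' a machine-readable run manifest. Supplying `otu_table` (an [otu_tab()] or
#' a path to a TSV/BIOM table) together with `sample_data` skips the
#' simulation and synthesis stages and runs the statistics on the external
#' data.
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @param otu_table Optional external OTU table (skips simulation stages).
#' @param sample_data Optional per-sample metadata for an external table
#'   (must contain the PERMANOVA model terms).
#' @param sites Site table for the scenario (default [default_sites()]).
#' @return The run manifest (list, also written as `manifest.json`):
#'   config hash and echo, seeds, per-stage output files and timings.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = tempfile("run"),
                         seed = NULL, otu_table = NULL, sample_data = NULL,
                         sites = default_sites()) {
  validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), outputs = list())
  cfg_path <- file.path(outdir, "config.yml")
  write_run_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  t_all <- proc.time()[3]

  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[3] - t0, 2))
    out
  }
  register <- function(...) {
    for (f in list(...)) manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }

  ep <- do.call(exposure_params, config$exposure)
  external <- !is.null(otu_table)

  if (!external) {
    sim <- stage("simulate_tracers", function() {
      sc <- build_scenario(config)
      run_simulation(sc$grid, sc$flow, sc$sources, sc$params, sc$window)
    })
    emap <- stage("exposure_map", function() exposure_map(sim, ep))
    f_exp <- file.path(outdir, "exposure_map.tsv")
    write_exposure_tsv(emap, f_exp)
    register(f_exp)

    sexp <- stage("site_exposure", function() {
      scn <- scenario_config(sites = sites, seed = config$seed,
                             euk_rate = config$synthesis$euk_rate,
                             wet_offset = config$synthesis$wet_offset,
                             season_shift = config$synthesis$season_shift)
      list(scenario = scn,
           exposure = site_exposure(sim, sites, scn$dates, ep))
    })
    f_sites <- file.path(outdir, "site_exposure.tsv")
    write_site_exposure_tsv(sexp$exposure, f_sites)
    register(f_sites)

    synth <- stage("synth_data", function() {
      tab <- generate_otu_table(sexp$scenario, sexp$exposure)
      env <- generate_environment(sexp$scenario)
      env$water_qual_idx <- water_quality_index(env)
      list(table = tab$table, truth = tab$truth, env = env)
    })
    tab <- synth$table
    meta <- synth$truth
    f_otu <- file.path(outdir, "otu_table.tsv")
    f_truth <- file.path(outdir, "truth.tsv")
    f_env <- file.path(outdir, "environment.tsv")
    write_otu_tsv(tab, f_otu)
    utils::write.table(synth$truth, f_truth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(synth$env, f_env, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    register(f_otu, f_truth, f_env)
    env <- synth$env
  } else {
    tab <- stage("load_external_table", function() {
      if (inherits(otu_table, "otu_tab")) return(otu_table)
      if (grepl("\\.biom$", otu_table)) read_otu_biom(otu_table)
      else read_otu_tsv(otu_table)
    })
    meta <- sample_data
    if (is.null(meta)) stop("sample_data is required with an external OTU table")
    env <- NULL
  }

  divers <- stage("diversity", function() {
    prok <- subset_domain(tab, "prokaryote")
    rar <- rarefy(prok, depth = config$analysis$rarefaction_depth,
                  mode = "draw", seed = config$seed + 11L)
    keep <- rownames(rar$counts)
    adiv <- alpha_diversity(rar)
    list(rarefied = rar, keep = keep, alpha = adiv)
  })
  f_div <- file.path(outdir, "diversity.tsv")
  utils::write.table(divers$alpha, f_div, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  register(f_div)

  multiv <- stage("multivariate", function() {
    rar <- divers$rarefied
    rel <- relative_abundance(rar$counts)
    corr <- copy_number_correct(rel, rar$copy_number)
    meta_k <- meta[match(rownames(corr), meta$sample), , drop = FALSE]
    H <- hellinger(corr)
    D <- stats::dist(H)
    ord <- pcoa(D)
    terms <- config$analysis$permanova_terms
    terms <- terms[vapply(terms, function(t)
      length(unique(meta_k[[t]])) > 1, logical(1))]
    perm <- permanova(D, meta_k, terms,
                      n_perm = config$analysis$n_perm,
                      seed = config$seed + 21L)
    ind <- if ("category" %in% names(meta_k) &&
               all(table(meta_k$category) >= 2))
      indval(corr, meta_k$category, n_perm = config$analysis$n_perm,
             seed = config$seed + 31L) else NULL
    out <- list(ordination = ord, permanova = perm, indval = ind)
    if (!is.null(env)) {
      envk <- env[match(rownames(corr), env$sample), , drop = FALSE]
      evars <- rownames(env_loading_matrix())
      out$efa <- efa(envk[, evars], n_factors = "auto",
                     seed = config$seed + 41L)
      out$pearson <- pearson_matrix(envk[, evars])
      rep_vars <- c("rain_7d", "water_qual_idx", "salinity", "water_temp")
      out$rda <- rda(hellinger(corr), envk[, rep_vars],
                     n_perm = config$analysis$n_perm,
                     seed = config$seed + 51L)
    }
    out
  })
  f_perm <- file.path(outdir, "permanova.tsv")
  utils::write.table(multiv$permanova, f_perm, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_scores <- file.path(outdir, "pcoa_scores.tsv")
  utils::write.table(
    data.frame(sample = rownames(multiv$ordination$scores),
               multiv$ordination$scores[, 1:min(4, ncol(multiv$ordination$scores))]),
    f_scores, sep = "\t", row.names = FALSE, quote = FALSE)
  register(f_perm, f_scores)
  if (!is.null(multiv$indval)) {
    f_ind <- file.path(outdir, "indval.tsv")
    utils::write.table(multiv$indval, f_ind, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    register(f_ind)
  }

  manifest$elapsed_seconds <- round(proc.time()[3] - t_all, 2)
  manifest$config <- unclass(config)
  f_man <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(manifest, list(outdir = outdir, results = multiv,
                             diversity = divers)))
}
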