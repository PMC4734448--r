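#' Exposure-index parameters
#'
#' Parameters of the cumulative river-exposure index. The threshold is a
#' fraction of the river source concentration (default 1%); the index is
#' accumulated over the wet-season window (default 01 November - 31 March,
#' both ends inclusive; 151 days across a non-leap February); maps are
#' capped for display at `map_cap` concentration-days; running cumulative
#' snapshots are recorded every `snapshot_interval` days.
#'
#' @param threshold_fraction Concentration threshold as a fraction of the
#'   source concentration, in (0, 1). Default 0.01.
#' @param season_start,season_end Wet-season window bounds as `"mm-dd"`
#'   strings. Defaults `"11-01"` and `"03-31"` (window wraps the new year).
#' @param map_cap Display cap for exposure maps (conc.d, > 0). Default 20.
#' @param snapshot_interval Days between cumulative snapshots. Default 7.
#' @return An object of class `"exposure_params"`.
#' @export
exposure_params <- function(threshold_fraction = 0.01,
                            season_start = "11-01", season_end = "03-31",
                            map_cap = 20, snapshot_interval = 7) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (map_cap <= 0) stop("map_cap must be positive")
  if (snapshot_interval < 1) stop("snapshot_interval must be at least 1 day")
  structure(list(threshold_fraction = threshold_fraction,
                 season_start = season_start, season_end = season_end,
                 map_cap = map_cap, snapshot_interval = snapshot_interval),
            class = "exposure_params")
}

#' Is a date inside the wet-season window?
#'
#' @param dates Date vector.
#' @param params An [exposure_params()] object.
#' @return Logical vector.
#' @export
in_season <- function(dates, params = exposure_params()) {
  md <- format(as.Date(dates), "%m-%d")
  if (params$season_start > params$season_end) {
    md >= params$season_start | md <= params$season_end    # wraps new year
  } else {
    md >= params$season_start & md <= params$season_end
  }
}

#' Concentration exceedance above the threshold
#'
#' The piecewise kernel of the exposure index: `conc - thresh` where the
#' concentration strictly exceeds the threshold, else 0. The boundary case
#' `conc == thresh` yields 0.
#'
#' @param conc Non-negative concentration(s), as fraction of source
#'   concentration. Vectorised.
#' @param params An [exposure_params()] object.
#' @return Exceedance value(s), same shape as `conc`.
#' @examples
#' exceedance(c(0.005, 0.02, 0.01))   # 0, 0.01, 0
#' @export
exceedance <- function(conc, params = exposure_params()) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  ifelse(conc > params$threshold_fraction,
         conc - params$threshold_fraction, 0)
}

#' Cumulative river-exposure index of a daily concentration series
#'
#' Integrates the exceedance of a daily tracer concentration series over
#' time, giving concentration-days (conc.d): 20 days at 1% above the
#' threshold and 10 days at 2% above both yield 0.2 conc.d. The default
#' accumulates `sum(exceedance * 1 day)`; `method = "literal_t"` instead
#' weights each day's exceedance by its elapsed time (in days) since the
#' start of the series, an alternative reading retained for comparison.
#'
#' @param conc Daily concentration values (fractions of source
#'   concentration).
#' @param dates Optional Date vector parallel to `conc`; when supplied, only
#'   days inside the wet-season window of `params` are accumulated.
#' @param params An [exposure_params()] object.
#' @param method `"delta"` (default; exceedance times the 1-day step) or
#'   `"literal_t"` (exceedance times elapsed days since series start).
#' @return The exposure index in conc.d (a single number).
#' @examples
#' cumulative_exposure(rep(0.02, 20))   # 0.2
#' @export
cumulative_exposure <- function(conc, dates = NULL,
                                params = exposure_params(),
                                method = c("delta", "literal_t")) {
  method <- match.arg(method)
  if (length(conc) == 0L) stop("empty concentration series")
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    stopifnot(length(dates) == length(conc))
    keep <- in_season(dates, params)
    conc <- conc[keep]
    if (length(conc) == 0L) stop("no days inside the season window")
  }
  ex <- exceedance(conc, params)
  if (method == "delta") sum(ex) else sum(ex * (seq_along(ex) - 1))
}

#' Exposure maps from a tracer simulation
#'
#' Computes the per-cell cumulative exposure index for each tracer over the
#' wet-season days of the series, the combined (summed over tracers) map,
#' the display-capped combined map, and running cumulative snapshots every
#' `snapshot_interval` days.
#'
#' @param series A [run_simulation()] result whose `times` cover (at least
#'   part of) the season window.
#' @param params An [exposure_params()] object.
#' @return An object of class `"exposure_result"`: list with `index`
#'   (list of per-tracer `nx` by `ny` matrices), `combined`, `capped`
#'   (`pmin(combined, map_cap)`), `snapshots` (list of date-stamped combined
#'   cumulative maps), `params`.
#' @export
exposure_map <- function(series, params = exposure_params()) {
  stopifnot(inherits(series, "tracer_series"))
  keep <- which(in_season(series$times, params))
  if (length(keep) == 0L) stop("tracer series has no days inside the season window")
  nt <- length(series$tracer_names)
  g <- series$grid

  index <- vector("list", nt)
  names(index) <- series$tracer_names
  combined_run <- matrix(0, g$nx, g$ny)   # running combined cumulative index
  snapshots <- list()
  per_tracer <- lapply(seq_len(nt), function(k) matrix(0, g$nx, g$ny))

  for (step in seq_along(keep)) {
    ti <- keep[step]
    for (k in seq_len(nt)) {
      ex <- exceedance(series$conc[ti, k, , ], params)
      per_tracer[[k]] <- per_tracer[[k]] + ex       # delta t = 1 day
    }
    if (step %% params$snapshot_interval == 0) {
      snap <- Reduce(`+`, per_tracer)
      snapshots[[as.character(series$times[ti])]] <- snap
    }
  }
  combined <- Reduce(`+`, per_tracer)
  for (k in seq_len(nt)) index[[k]] <- per_tracer[[k]]
  structure(list(index = index, combined = combined,
                 capped = pmin(combined, params$map_cap),
                 snapshots = snapshots, params = params,
                 season_days = series$times[keep]),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf(
    "Exposure maps: %d tracer(s), %d season days, combined max %.2f conc.d (cap %.0f)\n",
    length(x$index), length(x$season_days), max(x$combined), x$params$map_cap))
  invisible(x)
}

#' Classify monitoring sites by distance to the nearest river mouth
#'
#' Sites upstream of the mouth are riverine; downstream sites are plume
#' when closer than 20 km and marine otherwise. A site at exactly 20 km is
#' classified marine (the plume rule uses a strict `<`).
#'
#' @param distance_km Non-negative distance(s) to the nearest influencing
#'   river mouth, km.
#' @param relation `"upstream"` or `"downstream"` (vectorised with
#'   `distance_km`).
#' @param plume_limit_km Plume/marine cut-off (default 20 km).
#' @return Character vector: `"riverine"`, `"plume"` or `"marine"`.
#' @examples
#' classify_site(c(12, 5, 35), c("upstream", "downstream", "downstream"))
#' @export
classify_site <- function(distance_km, relation, plume_limit_km = 20) {
  if (any(is.na(relation)) || !all(relation %in% c("upstream", "downstream")))
    stop("relation must be 'upstream' or 'downstream' for every site")
  if (any(distance_km < 0)) stop("distances must be non-negative")
  out <- ifelse(relation == "upstream", "riverine",
                ifelse(distance_km < plume_limit_km, "plume", "marine"))
  as.character(out)
}

#' Build a site table
#'
#' @param id Site identifiers.
#' @param cell_x,cell_y Grid indices of each site's cell (may be `NA` for
#'   off-grid upstream sites).
#' @param distance_km Distance to the nearest influencing river mouth.
#' @param relation `"upstream"` or `"downstream"`.
#' @return Data frame with a `category` column from [classify_site()].
#' @export
site_table <- function(id, cell_x, cell_y, distance_km, relation) {
  data.frame(id = id, cell_x = cell_x, cell_y = cell_y,
             distance_km = distance_km, relation = relation,
             category = classify_site(distance_km, relation),
             stringsAsFactors = FALSE)
}

#' Per-site exposure series at sampling dates
#'
#' For each site and sampling date, the running cumulative exposure index at
#' the site's grid cell, accumulated over the days of the current wet season
#' up to (and including) the sampling date. A date outside the wet season
#' carries no current-season exposure and scores 0: the index describes
#' ongoing river influence, which the dry season resets. Upstream
#' (riverine) sites sit in undiluted river water off the marine grid and
#' are assigned the fixed `riverine_value` year-round.
#'
#' @param series A [run_simulation()] result.
#' @param sites A [site_table()].
#' @param dates Sampling dates.
#' @param params An [exposure_params()] object.
#' @param riverine_value Exposure assigned to upstream sites (conc.d).
#' @return Data frame (site, date, category, exposure).
#' @export
site_exposure <- function(series, sites, dates, params = exposure_params(),
                          riverine_value = 60) {
  dates <- as.Date(dates)
  season <- in_season(series$times, params)
  res <- expand.grid(id = sites$id, date = dates, stringsAsFactors = FALSE)
  res$category <- sites$category[match(res$id, sites$id)]
  res$exposure <- NA_real_
  for (r in seq_len(nrow(res))) {
    s <- match(res$id[r], sites$id)
    if (sites$relation[s] == "upstream") {
      res$exposure[r] <- riverine_value
      next
    }
    if (!in_season(res$date[r], params)) { res$exposure[r] <- 0; next }
    # days of the current wet season (contiguous in-season block) up to date
    upto <- series$times <= res$date[r] & season &
      series$times > res$date[r] - 200
    if (any(upto)) {
      gap <- which(diff(series$times[upto]) > 1)
      if (length(gap)) {
        first_ok <- series$times[upto][max(gap) + 1]
        upto <- upto & series$times >= first_ok
      }
    }
    if (!any(upto)) { res$exposure[r] <- 0; next }
    conc <- series$conc[upto, , sites$cell_x[s], sites$cell_y[s], drop = FALSE]
    tot <- 0
    for (k in seq_len(dim(conc)[2]))
      tot <- tot + sum(exceedance(conc[, k, 1, 1], params))
    res$exposure[r] <- tot
  }
  res
}

#' Write per-site exposure results as TSV
#'
#' @param x Data frame from [site_exposure()].
#' @param path Output path.
#' @export
write_site_exposure_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an exposure map as long-format TSV
#'
#' @param result An [exposure_map()] result.
#' @param path Output path.
#' @param which `"combined"` or `"capped"`.
#' @export
write_exposure_tsv <- function(result, path, which = c("combined", "capped")) {
  which <- match.arg(which)
  m <- result[[which]]
  idx <- which(!is.na(m), arr.ind = TRUE)
  out <- data.frame(x = idx[, 1], y = idx[, 2], index = m[idx])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
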