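## Synthetic study generator: endmember communities, environmental
## covariates with a 4-factor structure, and OTU tables mixed along the
## riverine-to-marine exposure gradient. Everything is deterministic given
## the scenario seed (base R Mersenne-Twister stream; each generator derives
## its own sub-seed so stages are independently reproducible).

# geometric ranked abundances for n OTUs summing to `total`
ranked_abund <- function(n, total, q = 0.8) {
  w <- q^(seq_len(n) - 1)
  total * w / sum(w)
}

make_taxon_block <- function(prefix, n, kingdom, phylum, class, order, family,
                             genus, copy, total) {
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  tax <- sprintf("k__%s; p__%s; c__%s; o__%s; f__%s; g__%s; s__%s",
                 kingdom, phylum, class, order, family, genus,
                 sprintf("sp%02d", seq_len(n)))
  data.frame(otu = ids, taxonomy = tax, copy_number = copy,
             abundance = ranked_abund(n, total), stringsAsFactors = FALSE)
}

#' Riverine and marine endmember communities
#'
#' Deterministic endmember community profiles for the synthetic generator.
#' The marine endmember (~95 OTUs) is dominated by Rickettsiales
#' (Pelagibacteraceae), Thermoplasmata E2 (Marine Group II), Synechococcales
#' (*Prochlorococcus*, *Synechococcus*) and Acidimicrobiales (OCS155); the
#' riverine endmember (~65 OTUs) by Burkholderiales (Comamonadaceae,
#' Oxalobacteraceae), Sphingobacteriales and Xanthomonadales, with
#' Flavobacteriales present in both. Order-level marine means are calibrated
#' so Rickettsiales sits near 29.6% and E2 near 17.7% of the community.
#' 16S copy numbers run 1-8 by lineage (oligotrophic marine clades low,
#' copiotrophic riverine Proteobacteria high), injecting the copy-number
#' bias that correction is meant to remove.
#'
#' @return List with elements `riverine` and `marine`, each a data frame
#'   (`otu`, `taxonomy`, `copy_number`, `abundance` summing to 1), plus
#'   `eukaryote` (a small fixed eukaryote contaminant profile).
#' @export
endmember_communities <- function() {
  marine <- rbind(
    make_taxon_block("mar_pel", 20, "Bacteria", "Proteobacteria",
                     "Alphaproteobacteria", "Rickettsiales",
                     "Pelagibacteraceae", "Pelagibacter", 1, 0.296),
    make_taxon_block("mar_mgii", 12, "Archaea", "Euryarchaeota",
                     "Thermoplasmata", "E2", "Marine group II", "MGII", 1, 0.177),
    make_taxon_block("mar_proc", 8, "Bacteria", "Cyanobacteria",
                     "Synechococcophycideae", "Synechococcales",
                     "Synechococcaceae", "Prochlorococcus", 1, 0.085),
    make_taxon_block("mar_syn", 7, "Bacteria", "Cyanobacteria",
                     "Synechococcophycideae", "Synechococcales",
                     "Synechococcaceae", "Synechococcus", 2, 0.065),
    make_taxon_block("mar_ocs", 10, "Bacteria", "Actinobacteria",
                     "Acidimicrobiia", "Acidimicrobiales", "OCS155",
                     "uncultured", 2, 0.08),
    make_taxon_block("mar_flav", 12, "Bacteria", "Bacteroidetes",
                     "Flavobacteriia", "Flavobacteriales",
                     "Flavobacteriaceae", "NS5", 3, 0.10),
    make_taxon_block("mar_rhodo", 10, "Bacteria", "Proteobacteria",
                     "Alphaproteobacteria", "Rhodobacterales",
                     "Rhodobacteraceae", "Roseobacter", 2, 0.08),
    make_taxon_block("mar_ocean", 8, "Bacteria", "Proteobacteria",
                     "Gammaproteobacteria", "Oceanospirillales",
                     "Halomonadaceae", "Candidatus Portiera", 4, 0.06),
    make_taxon_block("mar_pir", 8, "Bacteria", "Planctomycetes",
                     "Planctomycetia", "Pirellulales", "Pirellulaceae",
                     "Pirellula", 2, 0.057))
  riverine <- rbind(
    make_taxon_block("riv_coma", 15, "Bacteria", "Proteobacteria",
                     "Betaproteobacteria", "Burkholderiales",
                     "Comamonadaceae", "Limnohabitans", 6, 0.27),
    make_taxon_block("riv_oxal", 5, "Bacteria", "Proteobacteria",
                     "Betaproteobacteria", "Burkholderiales",
                     "Oxalobacteraceae", "Herbaspirillum", 5, 0.08),
    make_taxon_block("riv_flex", 8, "Bacteria", "Bacteroidetes",
                     "Sphingobacteriia", "Sphingobacteriales",
                     "Flexibacteraceae", "Arcicella", 3, 0.15),
    make_taxon_block("riv_chit", 7, "Bacteria", "Bacteroidetes",
                     "Sphingobacteriia", "Sphingobacteriales",
                     "Chitinophagaceae", "Sediminibacterium", 3, 0.10),
    make_taxon_block("riv_xan", 10, "Bacteria", "Proteobacteria",
                     "Gammaproteobacteria", "Xanthomonadales",
                     "Xanthomonadaceae", "Arenimonas", 7, 0.15),
    make_taxon_block("riv_flav", 10, "Bacteria", "Bacteroidetes",
                     "Flavobacteriia", "Flavobacteriales",
                     "Flavobacteriaceae", "Flavobacterium", 3, 0.15),
    make_taxon_block("riv_acI", 10, "Bacteria", "Actinobacteria",
                     "Actinobacteria", "Actinomycetales", "ACK-M1",
                     "acI", 2, 0.10))
  eukaryote <- rbind(
    make_taxon_block("euk_mer", 2, "Eukaryota", "Cnidaria", "Hydrozoa",
                     "Anthoathecata", "Meronidae", "Merona", 1, 0.5),
    make_taxon_block("euk_diat", 3, "Eukaryota", "Stramenopiles",
                     "Bacillariophyta", "Thalassiosirales",
                     "Thalassiosiraceae", "Thalassiosira", 1, 0.5))
  list(riverine = riverine, marine = marine, eukaryote = eukaryote)
}

#' Default monitoring sites of the bundled scenario
#'
#' Seven sites mirroring a river-to-offshore transect: one freshwater site
#' 12 km upstream of the mouth, three plume sites under 20 km downstream and
#' three marine sites beyond. Grid cells assume the bundled 90 x 60 cell,
#' 2 km scenario with the mouth at cell (4, 15) and the plume carried
#' alongshore in +y.
#'
#' @return A [site_table()] data frame with a `bottom_depth_m` column.
#' @export
default_sites <- function() {
  s <- site_table(
    id = c("TR", "TT1", "TT2", "TT3", "TT4", "RI", "FI"),
    cell_x = c(NA, 4, 5, 5, 8, 10, 12),
    cell_y = c(NA, 16, 19, 23, 33, 45, 55),
    distance_km = c(12, 2, 8, 16, 36, 60, 80),
    relation = c("upstream", rep("downstream", 6)))
  s$bottom_depth_m <- c(2, 8, 12, 18, 32, 40, 45)
  s
}

#' Scenario configuration for the synthetic study
#'
#' Bundles the study design the generators emulate: sites, sampling dates
#' spanning wet and dry seasons, the sequencing-depth distribution, the
#' logistic exposure-to-riverine-fraction mixing, seasonal effect sizes and
#' the eukaryote contamination rate. Deterministic given `seed`.
#'
#' @param sites A [site_table()]-style data frame (default [default_sites()]).
#' @param dates Sampling dates. Default: six dates in 2011 spanning the wet
#'   (Jan/Feb/Mar) and dry (Jun/Aug/Oct) seasons.
#' @param depth_meanlog,depth_sdlog,depth_min Lognormal sequencing-depth
#'   distribution (reads per sample), clipped below at `depth_min`.
#' @param beta Logistic slope linking exposure (conc.d) to the riverine
#'   mixing fraction w. The default, with `intercept`, puts w near 0.02 at
#'   zero exposure and near 0.8 at 20 conc.d.
#' @param intercept Logistic intercept (baseline logit of w at exposure 0).
#' @param wet_offset Additive logit shift for wet-season samples.
#' @param season_shift Fraction of marine-endmember abundance reallocated
#'   between Pelagibacteraceae (favoured in the dry season) and Marine Group
#'   II (favoured in the wet season).
#' @param euk_rate Expected eukaryote fraction of reads.
#' @param seed Integer seed governing all generator randomness.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(sites = default_sites(),
                            dates = as.Date(c("2011-01-20", "2011-02-15",
                                              "2011-03-20", "2011-06-15",
                                              "2011-08-15", "2011-10-15")),
                            depth_meanlog = log(2500), depth_sdlog = 0.3,
                            depth_min = 300,
                            beta = (log(4) + 4) / 20, intercept = -4,
                            wet_offset = 0.5, season_shift = 0.05,
                            euk_rate = 0.02, seed = 1L) {
  stopifnot(depth_min >= 1, season_shift >= 0, euk_rate >= 0, euk_rate < 1)
  structure(list(sites = sites, dates = as.Date(dates),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 depth_min = depth_min, beta = beta, intercept = intercept,
                 wet_offset = wet_offset, season_shift = season_shift,
                 euk_rate = euk_rate, seed = as.integer(seed)),
            class = "scenario_config")
}

#' True loading matrix of the synthetic environmental covariates
#'
#' Fourteen observed variables load on four latent factors: MR1
#' rainfall/discharge, MR2 particulates and water quality (chlorophyll a,
#' suspended solids, POC, PN, PP, diuron), MR3 freshwater mixing (DIN, Si,
#' salinity with a negative loading), MR4 temperature and solar exposure.
#' Bottom depth is site-fixed and loads on no factor. Primary loadings are
#' `loading`, cross-loadings 0.
#'
#' @param loading Primary loading value (default 0.8).
#' @return 14 x 4 numeric matrix with variable rownames and columns
#'   `MR1`-`MR4`.
#' @export
env_loading_matrix <- function(loading = 0.8) {
  vars <- c("tully_discharge", "rain_7d", "diuron", "POC", "SS", "PN",
            "CHLA", "PP", "bottom_depth", "Si", "DIN", "salinity",
            "water_temp", "solar_exp_7d")
  L <- matrix(0, length(vars), 4, dimnames = list(vars, paste0("MR", 1:4)))
  L[c("tully_discharge", "rain_7d"), "MR1"] <- loading
  L[c("diuron", "POC", "SS", "PN", "CHLA", "PP"), "MR2"] <- loading
  L[c("Si", "DIN"), "MR3"] <- loading
  L["salinity", "MR3"] <- -loading
  L[c("water_temp", "solar_exp_7d"), "MR4"] <- loading
  L
}

#' Generate the synthetic environmental covariate table
#'
#' Draws four independent standard-normal factor scores per sample and maps
#' them through the [env_loading_matrix()] plus unique Gaussian noise
#' (sd `noise_sd`), giving standardized covariates with the target
#' correlation structure (e.g. expected r(rain_7d, tully_discharge) =
#' 0.8^2 / (0.8^2 + 0.6^2) = 0.64). Bottom depth is the standardized
#' site-fixed depth, not factor-driven. The latent factor scores are kept as
#' truth columns for recovery tests.
#'
#' @param scenario A [scenario_config()], or an integer number of samples
#'   (sites/dates metadata omitted in that case).
#' @param loading,noise_sd Primary loading and unique noise sd.
#' @param seed Overrides the scenario seed if given.
#' @return Data frame with sample metadata, the 14 covariates, and truth
#'   columns `MR1`-`MR4`.
#' @export
generate_environment <- function(scenario = scenario_config(), loading = 0.8,
                                 noise_sd = 0.6, seed = NULL) {
  if (is.numeric(scenario)) {
    n <- as.integer(scenario)
    meta <- data.frame(sample = sprintf("s%03d", seq_len(n)))
    site_depth <- NULL
  } else {
    meta <- expand.grid(site = scenario$sites$id,
                        date = scenario$dates, stringsAsFactors = FALSE)
    meta <- data.frame(sample = sprintf("%s_%s", format(meta$date, "%Y%m%d"),
                                        meta$site),
                       site = meta$site, date = meta$date,
                       season = ifelse(in_season(meta$date), "wet", "dry"),
                       category = scenario$sites$category[
                         match(meta$site, scenario$sites$id)],
                       stringsAsFactors = FALSE)
    n <- nrow(meta)
    site_depth <- scenario$sites$bottom_depth_m[
      match(meta$site, scenario$sites$id)]
  }
  if (n < 2) stop("at least 2 samples are required")
  if (is.null(seed)) seed <- if (is.numeric(scenario)) 1L else scenario$seed
  set.seed(seed + 101L)

  L <- env_loading_matrix(loading)
  scores <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(NULL, colnames(L)))
  X <- scores %*% t(L) + matrix(stats::rnorm(n * nrow(L), sd = noise_sd),
                                n, nrow(L))
  colnames(X) <- rownames(L)
  if (!is.null(site_depth)) {
    X[, "bottom_depth"] <- as.numeric(scale(site_depth)) +
      stats::rnorm(n, sd = 0.05)
  }
  cbind(meta, as.data.frame(X), as.data.frame(scores))
}

# season-modulated marine endmember: reallocates `shift` of total abundance
# from Pelagibacteraceae to Marine Group II in the wet season (reverse when
# dry), mirroring the observed dry/wet partition of the offshore community.
seasonal_marine <- function(marine, season, shift) {
  if (shift == 0) return(marine)
  a <- marine$abundance
  pel <- grepl("Pelagibacteraceae", marine$taxonomy)
  mgii <- grepl("o__E2", marine$taxonomy)
  delta <- if (season == "wet") shift else -shift
  moved <- delta  # mass moved from pel to mgii (can be negative)
  moved <- max(min(moved, sum(a[pel]) * 0.9), -sum(a[mgii]) * 0.9)
  a[pel] <- a[pel] * (1 - moved / sum(a[pel]))
  a[mgii] <- a[mgii] * (1 + moved / sum(a[mgii]))
  marine$abundance <- a / sum(a)
  marine
}

# expected (pre-bias) relative composition of one sample over the merged
# prokaryote taxon universe
expected_composition <- function(w, season, end, shift) {
  mar <- seasonal_marine(end$marine, season, shift)
  otus <- c(end$riverine$otu, mar$otu)
  e <- c(w * end$riverine$abundance, (1 - w) * mar$abundance)
  stats::setNames(e, otus)
}

#' Generate a synthetic OTU table along the exposure gradient
#'
#' For each site/date sample, the expected community is a two-endmember
#' mixture `w * riverine + (1 - w) * marine` with
#' `w = plogis(intercept + beta * exposure + wet_offset * is_wet)`, the
#' marine endmember season-modulated. Copy-number bias is injected by
#' multiplying expected relative abundances by 16S copy numbers and
#' renormalising before a multinomial draw at the sample's sequencing
#' depth; eukaryote contaminant reads are appended at `euk_rate`. The true
#' mixing fraction `w` is returned for every sample.
#'
#' @param scenario A [scenario_config()].
#' @param exposure Data frame with columns `id` (site), `date`, `exposure`
#'   (conc.d), e.g. from [site_exposure()]. Must cover every site/date pair.
#' @param endmembers Endmember list (default [endmember_communities()]).
#' @param seed Overrides the scenario seed if given.
#' @return List with `table` (an [otu_tab()]) and `truth` (data frame:
#'   sample, site, date, season, category, exposure, w, depth).
#' @export
generate_otu_table <- function(scenario = scenario_config(), exposure,
                               endmembers = endmember_communities(),
                               seed = NULL) {
  if (is.null(seed)) seed <- scenario$seed
  set.seed(seed + 202L)
  sites <- scenario$sites
  grid <- expand.grid(site = sites$id, date = scenario$dates,
                      stringsAsFactors = FALSE)
  key <- paste(grid$site, grid$date)
  ek <- paste(exposure$id, as.Date(exposure$date))
  m <- match(key, ek)
  if (anyNA(m)) stop("exposure values missing for some site/date pairs")
  exp_val <- exposure$exposure[m]

  season <- ifelse(in_season(grid$date), "wet", "dry")
  w <- stats::plogis(scenario$intercept + scenario$beta * exp_val +
                     scenario$wet_offset * (season == "wet"))
  w <- pmin(pmax(w, 0), 1)

  prok <- rbind(endmembers$riverine, endmembers$marine)
  euk <- endmembers$eukaryote
  all_otus <- c(prok$otu, euk$otu)
  taxonomy <- stats::setNames(c(prok$taxonomy, euk$taxonomy), all_otus)
  copy_number <- stats::setNames(c(prok$copy_number, euk$copy_number), all_otus)
  domain <- stats::setNames(c(rep("prokaryote", nrow(prok)),
                              rep("eukaryote", nrow(euk))), all_otus)

  n <- nrow(grid)
  depth <- pmax(scenario$depth_min,
                round(stats::rlnorm(n, scenario$depth_meanlog,
                                    scenario$depth_sdlog)))
  counts <- matrix(0L, n, length(all_otus),
                   dimnames = list(sprintf("%s_%s", format(grid$date, "%Y%m%d"),
                                           grid$site),
                                   all_otus))
  for (i in seq_len(n)) {
    e <- expected_composition(w[i], season[i], endmembers,
                              scenario$season_shift)
    biased <- e * copy_number[names(e)]
    biased <- biased / sum(biased)
    counts[i, names(e)] <- as.integer(
      stats::rmultinom(1, depth[i], biased))
    if (scenario$euk_rate > 0) {
      n_euk <- stats::rbinom(1, depth[i], scenario$euk_rate)
      if (n_euk > 0)
        counts[i, euk$otu] <- counts[i, euk$otu] +
          as.integer(stats::rmultinom(1, n_euk, euk$abundance))
    }
  }
  truth <- data.frame(sample = rownames(counts), site = grid$site,
                      date = grid$date, season = season,
                      category = sites$category[match(grid$site, sites$id)],
                      exposure = exp_val, w = w, depth = depth,
                      stringsAsFactors = FALSE)
  list(table = otu_tab(counts, taxonomy, copy_number, domain), truth = truth)
}

#' Estimate the riverine mixing fraction of each sample
#'
#' Least-squares unmixing of copy-number-corrected prokaryote relative
#' abundances onto the two endmember profiles: the estimate is the
#' projection `((y - m) . (r - m)) / ||r - m||^2` clipped to [0, 1], where
#' `r` and `m` are the riverine and (season-neutral) marine endmembers.
#'
#' @param table An [otu_tab()].
#' @param endmembers Endmember list (default [endmember_communities()]).
#' @param correct Apply copy-number correction first (default TRUE).
#' @return Named numeric vector of estimated fractions per sample.
#' @export
estimate_riverine_fraction <- function(table,
                                       endmembers = endmember_communities(),
                                       correct = TRUE) {
  prok <- subset_domain(table, "prokaryote")
  y <- relative_abundance(prok$counts)
  if (correct) {
    y <- t(apply(y, 1, copy_number_correct,
                 copy_number = prok$copy_number[colnames(y)]))
  }
  otus <- c(endmembers$riverine$otu, endmembers$marine$otu)
  r <- stats::setNames(c(endmembers$riverine$abundance,
                         numeric(nrow(endmembers$marine))), otus)
  m <- stats::setNames(c(numeric(nrow(endmembers$riverine)),
                         endmembers$marine$abundance), otus)
  common <- intersect(colnames(y), otus)
  d <- r[common] - m[common]
  w <- as.numeric((y[, common, drop = FALSE] -
                   matrix(m[common], nrow(y), length(common), byrow = TRUE)) %*%
                  d) / sum(d^2)
  stats::setNames(pmin(pmax(w, 0), 1), rownames(y))
}

#' Simplified water-quality index
#'
#' Scores each of four indicator concentrations (suspended solids,
#' chlorophyll a, particulate nitrogen, particulate phosphorus) +1 when at
#' or below its guideline value and -1 when above, and averages them,
#' yielding a per-sample index from -1 (poor) to +1 (very good). This is a
#' deliberately simple guideline-ratio scoring, not the full monitoring-
#' program methodology.
#'
#' @param env Data frame containing the indicator columns.
#' @param guidelines Named guideline values for `SS`, `CHLA`, `PN`, `PP`.
#'   The synthetic covariates are standardized, so the default guideline is
#'   0 (the long-term mean) for each.
#' @return Numeric vector of per-sample scores in `[-1, 1]`.
#' @export
water_quality_index <- function(env,
                                guidelines = c(SS = 0, CHLA = 0, PN = 0, PP = 0)) {
  need <- c("SS", "CHLA", "PN", "PP")
  if (!all(need %in% names(guidelines)))
    stop("guidelines must name SS, CHLA, PN and PP")
  missing <- setdiff(need, names(env))
  if (length(missing))
    stop("missing indicator column(s): ", paste(missing, collapse = ", "))
  scores <- sapply(need, function(v)
    ifelse(env[[v]] <= guidelines[[v]], 1, -1))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  rowMeans(scores)
}

#' Trailing 7-day mean of a daily series
#'
#' Mean of the values observed on the seven calendar days strictly before
#' `at` (i.e. `at - 7` through `at - 1`). Missing days are simply absent
#' from the mean; the number of days used is attached as attribute
#' `"n_days"`.
#'
#' @param dates Date vector of observations.
#' @param values Numeric vector parallel to `dates`.
#' @param at The reference date.
#' @return The windowed mean, with attribute `n_days`.
#' @export
rolling_7day_mean <- function(dates, values, at) {
  dates <- as.Date(dates); at <- as.Date(at)
  stopifnot(length(dates) == length(values))
  keep <- dates >= (at - 7) & dates <= (at - 1)
  if (!any(keep)) stop("no observations in the 7 days preceding ", at)
  out <- mean(values[keep])
  attr(out, "n_days") <- sum(keep)
  out
}
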