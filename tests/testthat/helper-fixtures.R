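# Shared fixtures built in code: small grids, hand-made tracer series and
# tiny OTU tables.

small_grid <- function(nx = 20, ny = 16, dx = 2000, dy = 2000, mask = NULL) {
  make_grid(nx, ny, dx, dy, mask)
}

# tracer_series with a prescribed per-day concentration function
# conc_fun(day_index) -> nx x ny matrix (single tracer)
manual_series <- function(grid, dates, conc_fun) {
  conc <- array(0, dim = c(length(dates), 1, grid$nx, grid$ny))
  for (i in seq_along(dates)) conc[i, 1, , ] <- conc_fun(i)
  structure(list(times = as.Date(dates), conc = conc, tracer_names = "r1",
                 grid = grid, params = transport_params(),
                 mass_lost = 0),
            class = "tracer_series")
}

random_counts <- function(n_samples, n_otus, lambda = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("otu%03d", seq_len(n_otus))))
  # keep every sample non-empty
  m[rowSums(m) == 0, 1] <- 1L
  m
}

tiny_otu_tab <- function(seed = 1) {
  set.seed(seed)
  counts <- random_counts(4, 6)
  otus <- colnames(counts)
  otu_tab(counts,
          taxonomy = setNames(sprintf(
            "k__Bacteria; p__P; c__C; o__O%d; f__F; g__G; s__s%d",
            rep(1:2, 3), 1:6), otus),
          copy_number = setNames(c(1, 2, 4, 1, 3, 2), otus),
          domain = setNames(c(rep("prokaryote", 5), "eukaryote"), otus))
}

# reduced pipeline configuration + matching sites for fast end-to-end tests
small_run_config <- function(seed = 1L) {
  cfg <- default_run_config(seed)
  cfg$scenario$grid <- list(nx = 30, ny = 24, dx = 2000, dy = 2000,
                            land_cols = 2)
  cfg$scenario$river$mouth <- c(4, 6)
  cfg$scenario$transport$dt <- 3600
  cfg$scenario$window <- list(start = "2010-12-01", end = "2011-02-28")
  cfg$analysis$n_perm <- 199
  cfg
}

small_sites <- function() {
  s <- site_table(id = c("TR", "P1", "P2", "M1", "M2"),
                  cell_x = c(NA, 4, 5, 7, 9),
                  cell_y = c(NA, 7, 11, 20, 23),
                  distance_km = c(12, 2, 10, 28, 40),
                  relation = c("upstream", rep("downstream", 4)))
  s$bottom_depth_m <- c(2, 8, 15, 30, 40)
  s
}
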