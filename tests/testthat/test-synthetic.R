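test_that("endmember communities are valid profiles with the expected richness contrast", {
  end <- endmember_communities()
  expect_equal(sum(end$riverine$abundance), 1)
  expect_equal(sum(end$marine$abundance), 1)
  expect_true(all(end$riverine$copy_number > 0))
  expect_true(all(end$marine$copy_number >= 1 & end$marine$copy_number <= 8))
  # river community is poorer than the marine one
  expect_equal(nrow(end$riverine), 65)
  expect_equal(nrow(end$marine), 95)
  expect_false(any(end$riverine$otu %in% end$marine$otu))
})

test_that("environment generation is deterministic and reproduces the factor correlations", {
  e1 <- generate_environment(200, seed = 5)
  e2 <- generate_environment(200, seed = 5)
  expect_identical(e1, e2)
  # r(rain, discharge) should approach lambda^2 / (lambda^2 + sd^2) = 0.64
  expect_gt(cor(e1$rain_7d, e1$tully_discharge), 0.5)
  # cross-factor variables stay uncorrelated
  expect_lt(abs(cor(e1$rain_7d, e1$water_temp)), 0.25)
  # salinity loads negatively on the freshwater-mixing factor
  expect_lt(cor(e1$salinity, e1$MR3), -0.5)
  expect_gt(cor(e1$DIN, e1$MR3), 0.5)
})

test_that("with no unique noise the observed variables are exact factor images", {
  e <- generate_environment(50, noise_sd = 0, seed = 2)
  expect_equal(cor(e$rain_7d, e$MR1), 1, tolerance = 1e-12)
  expect_equal(e$CHLA, 0.8 * e$MR2, tolerance = 1e-12)
  expect_equal(e$salinity, -0.8 * e$MR3, tolerance = 1e-12)
})

test_that("community mixing follows the logistic exposure response", {
  scn <- scenario_config(seed = 3)
  expo <- expand.grid(id = scn$sites$id, date = scn$dates)
  expo$exposure <- ifelse(scn$sites$relation[match(expo$id, scn$sites$id)] ==
                            "upstream", 60, 0)
  res <- generate_otu_table(scn, expo)
  tr <- res$truth
  # marine sites at zero exposure in the dry season sit at the baseline w
  base <- plogis(scn$intercept)
  expect_equal(unique(tr$w[tr$category == "marine" & tr$season == "dry"]),
               base, tolerance = 1e-12)
  expect_true(all(tr$w[tr$category == "riverine"] > 0.999))
  # w is monotone in exposure at fixed season
  w_of <- function(x) plogis(scn$intercept + scn$beta * x)
  xs <- sort(runif(20, 0, 40))
  expect_true(all(diff(w_of(xs)) > 0))
  # calibration anchor: 20 conc.d maps to w ~= 0.8
  expect_equal(w_of(20), 0.8, tolerance = 0.01)
})

test_that("identical seeds give identical OTU tables", {
  scn <- scenario_config(seed = 11)
  expo <- expand.grid(id = scn$sites$id, date = scn$dates)
  expo$exposure <- runif(nrow(expo), 0, 30)
  r1 <- generate_otu_table(scn, expo)
  r2 <- generate_otu_table(scn, expo)
  expect_identical(r1$table$counts, r2$table$counts)
  expect_identical(r1$truth, r2$truth)
})

test_that("generated riverine samples are poorer than marine ones at equal depth", {
  scn <- scenario_config(seed = 7)
  expo <- expand.grid(id = scn$sites$id, date = scn$dates)
  expo$exposure <- ifelse(scn$sites$relation[match(expo$id, scn$sites$id)] ==
                            "upstream", 60, 0)
  tab <- generate_otu_table(scn, expo)$table
  prok <- subset_domain(tab, "prokaryote")
  rar <- suppressMessages(rarefy(prok, 279, mode = "draw", seed = 1))
  rich <- alpha_diversity(rar)
  tr <- generate_otu_table(scn, expo)$truth
  cat_of <- tr$category[match(rich$sample, tr$sample)]
  expect_lt(mean(rich$richness[cat_of == "riverine"]),
            mean(rich$richness[cat_of == "marine"]))
})

test_that("marine order-level means sit near their calibration targets", {
  scn <- scenario_config(seed = 13)
  expo <- expand.grid(id = scn$sites$id, date = scn$dates)
  expo$exposure <- 0
  res <- generate_otu_table(scn, expo)
  prok <- subset_domain(res$table, "prokaryote")
  rel <- relative_abundance(prok$counts)
  corr <- copy_number_correct(rel, prok$copy_number)
  ord <- taxonomy_rank(prok, "order")
  marine <- res$truth$category == "marine"
  rick <- rowSums(corr[marine, ord[colnames(corr)] == "Rickettsiales"])
  e2 <- rowSums(corr[marine, ord[colnames(corr)] == "E2"])
  expect_lt(abs(mean(rick) - 0.296), 0.03)
  expect_lt(abs(mean(e2) - 0.177), 0.03)
})

test_that("riverine fraction estimates track the generating truth", {
  scn <- scenario_config(seed = 17)
  expo <- expand.grid(id = scn$sites$id, date = scn$dates)
  expo$exposure <- runif(nrow(expo), 0, 30)
  res <- generate_otu_table(scn, expo)
  west <- estimate_riverine_fraction(res$table)
  expect_gt(cor(west[res$truth$sample], res$truth$w), 0.95)
})

test_that("water quality index scores the four indicators symmetrically", {
  env <- data.frame(SS = c(-1, 1, -1, 2), CHLA = c(-1, 1, -1, -2),
                    PN = c(-0.5, 0.3, 2, 1), PP = c(-2, 0.1, 1, -1))
  expect_equal(water_quality_index(env), c(1, -1, 0, 0))
  expect_error(water_quality_index(env[, -1]), "missing indicator")
})

test_that("trailing 7-day mean uses the strictly preceding calendar week", {
  d <- seq(as.Date("2011-02-01"), as.Date("2011-02-20"), by = "day")
  expect_equal(as.numeric(rolling_7day_mean(d, rep(5, 20), "2011-02-15")), 5)
  vals <- seq_along(d)
  m <- rolling_7day_mean(d, vals, as.Date("2011-02-15"))
  expect_equal(as.numeric(m), mean(8:14))
  # gaps: mean over available days, count reported
  keep <- c(8, 10, 12)
  m2 <- rolling_7day_mean(d[keep], vals[keep], as.Date("2011-02-15"))
  expect_equal(as.numeric(m2), 10)
  expect_equal(attr(m2, "n_days"), 3)
  expect_error(rolling_7day_mean(d[1:3], vals[1:3], as.Date("2011-03-15")),
               "no observations")
})
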