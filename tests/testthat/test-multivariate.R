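test_that("Hellinger transform and distance match hand evaluation", {
  x <- rbind(a = c(3, 3, 4), b = c(3, 3, 4))
  expect_equal(as.numeric(hellinger_distance(x)), 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(hellinger_distance(disjoint)), sqrt(2))
  two <- rbind(a = c(1, 0), b = c(0.25, 0.75))
  expect_equal(as.numeric(hellinger_distance(two)),
               sqrt((1 - 0.5)^2 + (0 - sqrt(0.75))^2))
  expect_equal(as.numeric(hellinger_distance(two)), 1, tolerance = 1e-6)
  expect_error(hellinger(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("PCoA recovers a Euclidean configuration exactly", {
  set.seed(4)
  X <- matrix(rnorm(15 * 3), 15, 3)
  D <- dist(X)
  ord <- pcoa(D)
  expect_true(length(ord$negative_eigenvalues) == 0)
  # distances among scores reproduce the input distances
  expect_equal(as.numeric(dist(ord$scores)), as.numeric(D), tolerance = 1e-8)
  expect_equal(sum(ord$prop_explained), 1, tolerance = 1e-12)
})

test_that("PCoA on Hellinger distances equals PCA of the transformed table", {
  set.seed(9)
  Y <- matrix(rpois(20 * 30, 4), 20, 30)
  Y[rowSums(Y) == 0, 1] <- 1
  H <- hellinger(Y)
  ord <- pcoa(dist(H))
  pc <- prcomp(H, center = TRUE)$x
  for (k in 1:4) {
    err <- min(max(abs(ord$scores[, k] - pc[, k])),
               max(abs(ord$scores[, k] + pc[, k])))
    expect_lt(err, 1e-8)
  }
})

test_that("equidistant points give a flat positive spectrum", {
  n <- 7
  D <- matrix(1, n, n); diag(D) <- 0
  ord <- pcoa(D)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_equal(length(pos), n - 1)
  expect_lt(diff(range(pos)), 1e-10)
})

test_that("PERMANOVA one-term pseudo-F equals the within/between oracle", {
  set.seed(3)
  Y <- matrix(rnorm(18 * 5), 18, 5)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  D <- dist(Y)
  res <- permanova(D, data.frame(g = g), "g", n_perm = 99, seed = 1)
  # classical oracle from squared distance sums
  Dm <- as.matrix(D)^2
  N <- 18
  SS_tot <- sum(Dm[upper.tri(Dm)]) / N
  SS_w <- sum(sapply(levels(g), function(l) {
    idx <- which(g == l)
    sum(Dm[idx, idx][upper.tri(Dm[idx, idx])]) / length(idx)
  }))
  SS_a <- SS_tot - SS_w
  F_oracle <- (SS_a / 2) / (SS_w / (N - 3))
  expect_equal(res$F[1], F_oracle, tolerance = 1e-10)
  expect_equal(res$SS[1], SS_a, tolerance = 1e-10)
  expect_equal(sum(res$R2), 1, tolerance = 1e-12)
})

test_that("PERMANOVA sequential partition matches the reference implementation", {
  set.seed(14)
  Y <- matrix(rpois(24 * 12, 5), 24, 12)
  Y[rowSums(Y) == 0, 1] <- 1
  md <- data.frame(g = factor(rep(c("a", "b"), each = 12)),
                   z = rnorm(24))
  D <- hellinger_distance(Y)
  mine <- permanova(D, md, c("g", "z"), n_perm = 199, seed = 5)
  ref <- vegan::adonis2(D ~ g + z, data = md, permutations = 199, by = "terms")
  expect_equal(mine$SS, unname(ref$SumOfSqs)[1:3], tolerance = 1e-10)
  expect_equal(mine$F[1:2], unname(ref$F[1:2]), tolerance = 1e-10)
  expect_equal(mine$R2, unname(ref$R2)[1:3], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are sane, seeded, and detect no ghost effects", {
  set.seed(6)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  md <- data.frame(g = factor(rep(c("a", "b"), each = 10)))
  D <- dist(Y)
  p1 <- permanova(D, md, "g", n_perm = 199, seed = 9)
  p2 <- permanova(D, md, "g", n_perm = 199, seed = 9)
  expect_identical(p1, p2)
  expect_gte(p1$p[1], 1 / 200)
  # identical composition in the two groups: tiny R2
  Yc <- rbind(Y[1:10, ], Y[1:10, ])
  D2 <- dist(Yc + matrix(rnorm(80, sd = 1e-6), 20, 4))
  r <- permanova(D2, md, "g", n_perm = 99, seed = 1)
  expect_lt(r$R2[1], 0.1)
  # aliased terms are named
  md$g2 <- md$g
  expect_error(permanova(D, md, c("g", "g2"), n_perm = 99), "g2")
})

test_that("IndVal closed forms and permutation significance", {
  g <- rep(c("g1", "g2", "g3"), each = 4)
  m <- matrix(0, 12, 3, dimnames = list(paste0("s", 1:12), c("perfect", "uniform", "absent")))
  m[1:4, "perfect"] <- 5
  m[, "uniform"] <- 2
  res <- indval(m, g, n_perm = 999, seed = 2)
  perfect <- res[res$otu == "perfect", ]
  expect_equal(perfect$A, 1)
  expect_equal(perfect$B, 1)
  expect_equal(perfect$indval, 1)
  expect_lte(perfect$p, 0.05)
  expect_equal(perfect$group, "g1")
  uniform <- res[res$otu == "uniform", ]
  expect_equal(uniform$indval, sqrt(1 / 3), tolerance = 1e-12)
  expect_true(is.na(res[res$otu == "absent", "indval"]))
})

test_that("RDA reduces to group-mean PCA with categorical constraints", {
  set.seed(10)
  Y <- matrix(rnorm(18 * 6), 18, 6)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  r <- rda(Y, data.frame(g = g))
  # oracle: expand group means, PCA, compare non-zero eigenvalues
  Yc <- scale(Y, scale = FALSE)
  gm <- apply(Yc, 2, function(col) tapply(col, g, mean))
  fitted_oracle <- gm[as.integer(g), ]
  ev_oracle <- svd(fitted_oracle)$d^2 / (18 - 1)
  ev_oracle <- ev_oracle[ev_oracle > 1e-12]
  expect_equal(r$eigenvalues, ev_oracle, tolerance = 1e-8)
  # eigenvalue budget closes
  expect_equal(sum(r$eigenvalues) + sum(r$unconstrained_eigenvalues),
               r$total_variance, tolerance = 1e-10)
})

test_that("RDA agrees with the reference implementation, plain and partial", {
  set.seed(11)
  Y <- hellinger(matrix(rpois(25 * 15, 6), 25, 15))
  X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
  mine <- rda(Y, X[c("a", "b")])
  ref <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(mine$eigenvalues, unname(ref$CCA$eig), tolerance = 1e-10)
  expect_equal(mine$total_variance, ref$tot.chi, tolerance = 1e-10)
  partial <- rda(Y, X[c("a")], condition = X["c"])
  pref <- vegan::rda(Y ~ a + Condition(c), data = X)
  expect_equal(partial$eigenvalues, unname(pref$CCA$eig), tolerance = 1e-10)
})

test_that("RDA degenerate cases: orthogonal constraints and self-conditioning", {
  set.seed(12)
  X <- data.frame(x = rnorm(20))
  Y0 <- matrix(rnorm(20 * 5), 20, 5)
  # orthogonalise the response against the constraint
  Yc <- scale(Y0, scale = FALSE)
  Yorth <- qr.resid(qr(cbind(1, X$x)), Yc)
  r <- rda(Yorth, X)
  expect_lt(r$prop_constrained, 1e-10)
  r2 <- rda(Y0, X, condition = X)
  expect_lt(sum(r2$eigenvalues), 1e-20)
  X2 <- data.frame(a = rnorm(20))
  X2$b <- 2 * X2$a
  expect_error(rda(Y0, X2), "collinear")
})

test_that("stepwise AIC keeps real drivers and rejects noise and duplicates", {
  set.seed(13)
  hits <- 0
  null_empty <- 0
  for (i in 1:40) {
    n <- 40
    x <- rnorm(n)
    Y <- outer(x, rnorm(8)) + matrix(rnorm(n * 8, sd = 0.6), n, 8)
    data <- data.frame(x = x, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    sel <- stepwise_aic_rda(Y, data, c("n1", "x", "n2", "n3"))
    if ("x" %in% sel$terms) hits <- hits + 1
    Ynull <- matrix(rnorm(n * 8), n, 8)
    seln <- stepwise_aic_rda(Ynull, data, c("n1", "x", "n2", "n3"))
    if (length(seln$terms) == 0) null_empty <- null_empty + 1
  }
  expect_gt(hits / 40, 0.9)
  expect_gt(null_empty / 40, 0.5)
  # a duplicated covariate is never co-selected
  set.seed(14)
  x <- rnorm(40)
  Y <- outer(x, rnorm(8)) + matrix(rnorm(320, sd = 0.6), 40, 8)
  d <- data.frame(x = x, dup = x)
  sel <- stepwise_aic_rda(Y, d, c("x", "dup"))
  expect_lt(length(intersect(c("x", "dup"), sel$terms)), 2)
})

test_that("EFA recovers the generating four-factor structure", {
  env <- generate_environment(200, seed = 1)
  L <- env_loading_matrix()
  fm <- efa(env[, rownames(L)], n_factors = "auto", seed = 1)
  expect_equal(fm$n_factors, 4L)
  phi <- abs(tucker_congruence(fm$loadings, L))
  expect_true(all(apply(phi, 2, max) > 0.9))
  # invariants of the factor model
  expect_true(all(fm$communalities <= 1 + 1e-8))
  expect_true(all(fm$uniquenesses >= -1e-8))
  # co-assignment of the variable groups matches the generating factors
  same_factor <- function(vars) length(unique(fm$assignment[vars])) == 1
  expect_true(same_factor(c("rain_7d", "tully_discharge")))
  expect_true(same_factor(c("CHLA", "SS", "POC", "PN", "PP", "diuron")))
  expect_true(same_factor(c("DIN", "salinity", "Si")))
  expect_true(same_factor(c("water_temp", "solar_exp_7d")))
})

test_that("parallel analysis retains nothing on pure noise", {
  set.seed(15)
  zero_hits <- sum(replicate(10, {
    X <- matrix(rnorm(100 * 8), 100, 8)
    parallel_analysis(X)$n_factors == 0
  }))
  expect_gte(zero_hits, 8)
  X <- matrix(rnorm(100 * 8), 100, 8)
  fm0 <- efa(X, n_factors = 0)
  expect_equal(fm0$n_factors, 0L)
  expect_equal(ncol(fm0$loadings), 0)
})

test_that("Pearson screening matches hand computation and flags constants", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 7), c = c(3, 2, 1))
  pm <- pearson_matrix(X)
  expect_equal(pm$r["a", "a"], 1)
  expect_equal(pm$r["a", "c"], -1)
  expect_equal(pm$r["a", "b"], 0.9934, tolerance = 1e-4)
  # fraction of |r| > 0.3 among the 3 pairs (all exceed here)
  expect_equal(pm$fraction_above, 1)
  X2 <- cbind(X, k = c(5, 5, 5))
  pm2 <- suppressWarnings(pearson_matrix(X2))
  expect_true(all(is.na(pm2$r["k", c("a", "b", "c")])))
  expect_equal(pm2$fraction_above, 1)   # constant-column pairs excluded
})
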