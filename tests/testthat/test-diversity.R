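test_that("a full-depth draw is a permuted copy of the original sample", {
  v <- c(a = 7L, b = 3L, c = 5L)
  out <- rarefy(v, depth = 15, mode = "draw", seed = 1)
  expect_equal(out, v, ignore_attr = TRUE)   # full-depth draw returns every read
})

test_that("expected rarefied richness matches the closed forms", {
  r <- rarefy(c(a = 10, b = 10), depth = 2, mode = "expected")
  expect_equal(unname(attr(r, "expected_richness")), 2 * (1 - 0.5^2))
  expect_equal(unname(r), c(1, 1), ignore_attr = TRUE)  # expected counts depth * p
  rh <- rarefy(c(a = 10, b = 10), depth = 2, mode = "expected",
               method = "hypergeometric")
  expect_equal(unname(attr(rh, "expected_richness")),
               2 * (1 - choose(10, 2) / choose(20, 2)))
})

test_that("expected richness agrees with Monte-Carlo draws and grows with depth", {
  set.seed(8)
  v <- rpois(30, 4); v[v == 0] <- 1
  names(v) <- paste0("o", seq_along(v))
  N <- sum(v)
  depth <- 40
  er_mult <- attr(rarefy(v, depth, mode = "expected"), "expected_richness")
  er_hyp <- attr(rarefy(v, depth, mode = "expected",
                        method = "hypergeometric"), "expected_richness")
  p <- v / N
  draws_mult <- replicate(3000, sum(rmultinom(1, depth, p) > 0))
  reads <- rep.int(seq_along(v), v)
  draws_hyp <- replicate(3000, length(unique(sample(reads, depth))))
  expect_lt(abs(er_mult - mean(draws_mult)), 3 * sd(draws_mult) / sqrt(3000))
  expect_lt(abs(er_hyp - mean(draws_hyp)), 3 * sd(draws_hyp) / sqrt(3000))
  # monotone in depth
  ers <- sapply(c(5, 10, 20, 40, N), function(d)
    attr(rarefy(v, d, mode = "expected"), "expected_richness"))
  expect_true(all(diff(ers) >= 0))
  # hypergeometric richness agrees with the classic rarefaction oracle
  expect_equal(unname(er_hyp), unname(vegan::rarefy(t(v), depth)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("samples below depth are dropped with a report", {
  m <- rbind(s1 = c(5, 5), s2 = c(100, 100))
  colnames(m) <- c("a", "b")
  expect_message(out <- rarefy(m, depth = 50, mode = "draw", seed = 1),
                 "dropping 1 sample")
  expect_equal(rownames(out), "s2")
  expect_equal(attr(out, "dropped"), "s1")
  expect_error(rarefy(m, depth = 0), "at least 1")
})

test_that("copy-number correction normalises ratios and removes injected bias", {
  expect_equal(copy_number_correct(c(0.8, 0.2), c(4, 1)), c(0.5, 0.5))
  expect_equal(copy_number_correct(c(0.3, 0.7), c(2, 2)), c(0.3, 0.7))
  # idempotent with unit copy numbers
  x <- c(0.5, 0.25, 0.25)
  expect_equal(copy_number_correct(x, c(1, 1, 1)), x)
  expect_error(copy_number_correct(c(0.5, 0.5), c(0, 1)), "positive")
  # round trip: bias then correct is the identity on compositions
  set.seed(21)
  for (i in 1:20) {
    e <- runif(10); e <- e / sum(e)
    cn <- sample(1:8, 10, replace = TRUE)
    biased <- e * cn / sum(e * cn)
    expect_equal(copy_number_correct(biased, cn), e, tolerance = 1e-12)
  }
})

test_that("corrected multinomial draws recover the pre-bias composition", {
  set.seed(31)
  e <- c(0.5, 0.3, 0.15, 0.05)
  cn <- c(6, 3, 1, 2)
  biased <- e * cn / sum(e * cn)
  draws <- rmultinom(400, 4000, biased)
  rel <- t(draws) / 4000
  corrected <- copy_number_correct(rel, cn)
  expect_equal(unname(colMeans(corrected)), e, tolerance = 0.01)
})

test_that("alpha diversity matches brute-force formula evaluation", {
  one <- alpha_diversity(c(x = 5))
  expect_equal(one$richness, 1)
  expect_equal(one$shannon, 0)
  expect_equal(one$evenness, 0)
  expect_equal(one$chao1, 1)

  eq <- alpha_diversity(rep(7, 12))
  expect_equal(eq$shannon, log(12), tolerance = 1e-12)
  expect_equal(eq$evenness, 1, tolerance = 1e-12)

  hand <- alpha_diversity(c(4, 3, 2, 1, 1))
  expect_equal(hand$chao1, 5 + 2^2 / (2 * 1))   # F1 = 2, F2 = 1
  p <- c(4, 3, 2, 1, 1) / 11
  expect_equal(hand$shannon, -sum(p * log(p)), tolerance = 1e-12)

  # invariance under relabelling; Chao1 >= richness
  set.seed(5)
  for (i in 1:25) {
    v <- rpois(40, 2); v[1] <- v[1] + 1
    a <- alpha_diversity(v)
    b <- alpha_diversity(sample(v))
    expect_equal(a[-1], b[-1], tolerance = 1e-12)
    expect_gte(a$chao1, a$richness)
  }
  # bias-corrected Chao1 branch when no doubletons exist
  nf2 <- alpha_diversity(c(5, 1, 1, 1))
  expect_equal(nf2$chao1, 4 + 3 * 2 / 2)
})

test_that("one-sided Mann-Whitney matches enumeration and wilcox.test", {
  r <- mann_whitney_one_sided(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 6)          # 1 of the C(4,2) = 6 rank assignments
  expect_equal(r$method, "exact")

  # exact symmetry identity: p_greater = 1 - p_less + P(U = u)
  x <- c(1.2, 3.4, 0.5); y <- c(2.2, 5.1, 4.4)
  lt <- mann_whitney_one_sided(x, y, "less")
  gt <- mann_whitney_one_sided(x, y, "greater")
  expect_equal(gt$p, 1 - lt$p + dwilcox(lt$U, 3, 3), tolerance = 1e-12)

  # agreement with the standard implementation, exact branch
  w <- wilcox.test(x, y, alternative = "less", exact = TRUE)
  expect_equal(lt$p, w$p.value, tolerance = 1e-12)

  # large-sample branch with ties against wilcox.test's corrected normal
  set.seed(2)
  a <- round(rnorm(25, 0, 2), 1); b <- round(rnorm(30, 0.8, 2), 1)
  mine <- mann_whitney_one_sided(a, b, "less")
  ref <- suppressWarnings(wilcox.test(a, b, alternative = "less",
                                      exact = FALSE, correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$method, "normal approximation")
})

test_that("Mann-Whitney holds its size under the permutation null", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    x <- rnorm(10); y <- rnorm(10)
    mann_whitney_one_sided(x, y, "greater")$p <= 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("eukaryote-to-prokaryote ratio behaves as a scale-free count ratio", {
  counts <- rbind(s1 = c(10, 10, 0), s2 = c(10, 10, 29), s3 = c(0, 0, 4))
  colnames(counts) <- c("p1", "p2", "e1")
  tab <- otu_tab(counts,
                 taxonomy = setNames(rep("k__x; p__; c__; o__; f__; g__; s__", 3),
                                     colnames(counts)),
                 domain = setNames(c("prokaryote", "prokaryote", "eukaryote"),
                                   colnames(counts)))
  expect_warning(epr <- eukaryote_prokaryote_ratio(tab), "undefined")
  expect_equal(unname(epr[1]), 0)
  expect_equal(unname(epr[2]), 29 / 20)
  expect_true(is.na(epr[3]))
  tab2 <- otu_tab(counts[1:2, ] * 2, tab$taxonomy, tab$copy_number, tab$domain)
  expect_equal(unname(eukaryote_prokaryote_ratio(tab2)),
               unname(epr[1:2]))
})

test_that("rarefaction curves rise with depth and stay near expected richness", {
  set.seed(12)
  v <- matrix(rpois(40, 6), 1, dimnames = list("s1", paste0("o", 1:40)))
  rc <- rarefaction_curve(v, depths = c(20, 60, 120), n_boot = 60, seed = 3)
  expect_true(all(diff(rc$mean) > 0))
  er <- attr(rarefy(v, 60, mode = "expected", method = "hypergeometric"),
             "expected_richness")
  expect_lt(abs(rc$mean[rc$depth == 60] - er), 3 * rc$sd[rc$depth == 60] / sqrt(60))
})
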