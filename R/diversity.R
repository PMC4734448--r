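#' Rarefy an OTU table to a common depth
#'
#' Subsamples every sample to `depth` reads so diversity metrics are
#' comparable. `mode = "draw"` takes one random subsample without
#' replacement. `mode = "expected"` returns the expected count per OTU
#' under repeated subsampling — the limit of infinitely many bootstrap
#' replicates — which is `depth * p_i` under both resampling models; the
#' models differ in the expected richness they imply, attached as attribute
#' `"expected_richness"`:
#' with replacement (multinomial bootstrap, the default)
#' `E[S] = sum_i (1 - (1 - p_i)^depth)`, or without replacement
#' (hypergeometric, classic rarefaction)
#' `E[S] = sum_i (1 - choose(N - n_i, depth) / choose(N, depth))`.
#'
#' Samples with fewer than `depth` reads are dropped; their ids are attached
#' as attribute `"dropped"` and reported via a message.
#'
#' @param x An [otu_tab()], counts matrix (samples x OTUs), or single count
#'   vector.
#' @param depth Target depth (reads, >= 1).
#' @param mode `"draw"` or `"expected"`.
#' @param method Resampling model for `mode = "expected"`:
#'   `"multinomial"` (with replacement) or `"hypergeometric"` (without).
#' @param seed Optional seed for `mode = "draw"`.
#' @return Object of the same kind as `x` with rarefied counts (real-valued
#'   for `mode = "expected"`), plus attributes `dropped` and (expected mode)
#'   `expected_richness`.
#' @examples
#' rarefy(c(a = 10, b = 10), depth = 2, mode = "expected")
#' @export
rarefy <- function(x, depth, mode = c("draw", "expected"),
                   method = c("multinomial", "hypergeometric"), seed = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (depth < 1) stop("depth must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  vec_in <- is.null(dim(x)) && !inherits(x, "otu_tab")
  counts <- if (inherits(x, "otu_tab")) x$counts
            else if (vec_in) matrix(x, 1, dimnames = list("sample", names(x)))
            else as.matrix(x)
  if (any(counts %% 1 != 0)) stop("rarefaction needs integer counts")

  tot <- rowSums(counts)
  drop <- rownames(counts)[tot < depth]
  if (length(drop)) {
    message(sprintf("dropping %d sample(s) below depth %d: %s",
                    length(drop), depth, paste(drop, collapse = ", ")))
    counts <- counts[tot >= depth, , drop = FALSE]
    tot <- tot[tot >= depth]
  }
  if (nrow(counts) == 0L) stop("no samples at or above the requested depth")

  if (mode == "draw") {
    out <- counts * 0
    for (i in seq_len(nrow(counts))) {
      reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
      pick <- sample(reads, depth)
      tb <- tabulate(pick, nbins = ncol(counts))
      out[i, ] <- tb
    }
    storage.mode(out) <- "integer"
    exp_rich <- NULL
  } else {
    p <- sweep(counts, 1, tot, "/")
    out <- depth * p
    if (method == "multinomial") {
      exp_rich <- rowSums(1 - (1 - p)^depth)
    } else {
      exp_rich <- vapply(seq_len(nrow(counts)), function(i) {
        n <- counts[i, ]; N <- tot[i]
        pr_absent <- ifelse(N - n < depth, 0,
                            exp(lchoose(N - n, depth) - lchoose(N, depth)))
        sum((1 - pr_absent)[n > 0])
      }, numeric(1))
    }
    names(exp_rich) <- rownames(counts)
  }

  res <- if (inherits(x, "otu_tab")) {
    otu_tab(out, x$taxonomy, x$copy_number, x$domain)
  } else if (vec_in) stats::setNames(drop(out), colnames(counts)) else out
  attr(res, "dropped") <- drop
  if (mode == "expected") attr(res, "expected_richness") <- exp_rich
  res
}

#' Correct relative abundances for 16S gene copy number
#'
#' Divides each OTU's relative abundance by its gene copy number and
#' renormalises, converting read fractions into cell-abundance estimates:
#' `(a_i / c_i) / sum_j (a_j / c_j)`.
#'
#' @param relabund Relative abundance vector (sums to 1) or samples x OTUs
#'   matrix (rows sum to 1).
#' @param copy_number Positive copy numbers, recycled/matched by name when
#'   named.
#' @return Corrected relative abundances of the same shape, rows summing
#'   to 1.
#' @examples
#' copy_number_correct(c(0.8, 0.2), c(4, 1))   # 0.5 0.5
#' @export
copy_number_correct <- function(relabund, copy_number) {
  if (any(copy_number <= 0)) stop("copy numbers must be positive")
  if (is.matrix(relabund)) {
    if (!is.null(colnames(relabund)) && !is.null(names(copy_number)))
      copy_number <- copy_number[colnames(relabund)]
    adj <- sweep(relabund, 2, copy_number, "/")
    return(sweep(adj, 1, rowSums(adj), "/"))
  }
  if (!is.null(names(relabund)) && !is.null(names(copy_number)))
    copy_number <- copy_number[names(relabund)]
  adj <- relabund / copy_number
  adj / sum(adj)
}

#' Alpha diversity of one or more samples
#'
#' Observed richness, Shannon-Wiener index (natural log by default),
#' Shannon evenness `H / log(S)` (0 when only one OTU is present), and the
#' Chao1 richness estimator `S + F1^2 / (2 F2)` (bias-corrected
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` when no doubletons are present). Chao1
#' requires integer counts and is `NA` otherwise.
#'
#' @param x Count vector for a single sample, a samples x OTUs matrix, or an
#'   [otu_tab()].
#' @param base Logarithm base for Shannon (default `exp(1)`, nats).
#' @return Data frame with columns `sample`, `richness`, `shannon`,
#'   `evenness`, `chao1` (one row per sample).
#' @examples
#' alpha_diversity(c(4, 3, 2, 1, 1))
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  counts <- if (inherits(x, "otu_tab")) x$counts
            else if (is.null(dim(x))) matrix(x, 1, dimnames = list("sample", names(x)))
            else as.matrix(x)
  one <- function(v) {
    v <- v[v > 0]
    if (length(v) == 0L) stop("empty sample (no reads)")
    S <- length(v)
    p <- v / sum(v)
    H <- -sum(p * log(p, base = base))
    J <- if (S > 1) H / log(S, base = base) else 0
    chao <- NA_real_
    if (all(v %% 1 == 0)) {
      F1 <- sum(v == 1); F2 <- sum(v == 2)
      chao <- if (F2 > 0) S + F1^2 / (2 * F2)
              else S + F1 * (F1 - 1) / (2 * (F2 + 1))
    }
    c(richness = S, shannon = H, evenness = J, chao1 = chao)
  }
  res <- t(apply(counts, 1, one))
  data.frame(sample = rownames(counts), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-sided Mann-Whitney U test
#'
#' Rank-sum U statistic with a one-sided p-value: exact via the null U
#' distribution when the pooled sample size is at most 12 and there are no
#' ties, otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"` (x tends larger than y) or `"less"`.
#' @return List with `U` (for the first sample), `p`, and `method`.
#' @examples
#' mann_whitney_one_sided(c(1, 2), c(3, 4), alternative = "less")
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))

  if (!ties && nx + ny <= 12) {
    # exact null distribution of U (no ties)
    p <- if (alternative == "less") stats::pwilcox(U, nx, ny)
         else 1 - stats::pwilcox(U - 1, nx, ny)
    method <- "exact"
  } else {
    N <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(all_v)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) stop("all observations identical; U test undefined")
    z <- if (alternative == "greater") (U - 0.5 - mu) / sqrt(sigma2)
         else (U + 0.5 - mu) / sqrt(sigma2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method, alternative = alternative)
}

#' Eukaryote-to-prokaryote read ratio (EPR)
#'
#' Ratio of eukaryote to prokaryote read counts per sample, computed on
#' unrarefied counts. Samples with zero prokaryote reads yield `NA` with a
#' warning.
#'
#' @param table An [otu_tab()] with domain labels.
#' @return Named numeric vector per sample.
#' @export
eukaryote_prokaryote_ratio <- function(table) {
  stopifnot(inherits(table, "otu_tab"))
  euk <- rowSums(table$counts[, table$domain == "eukaryote", drop = FALSE])
  prok <- rowSums(table$counts[, table$domain == "prokaryote", drop = FALSE])
  out <- euk / prok
  if (any(prok == 0)) {
    warning("zero prokaryote reads in some samples; EPR undefined (NA)")
    out[prok == 0] <- NA_real_
  }
  out
}

#' Rarefaction curves
#'
#' Mean and sd of a diversity metric over repeated random subsamples at a
#' ladder of depths, for plotting observed-richness / Chao1 / Shannon
#' accumulation.
#'
#' @param x An [otu_tab()] or counts matrix.
#' @param depths Integer vector of depths.
#' @param metric `"richness"`, `"chao1"` or `"shannon"`.
#' @param n_boot Subsamples per depth (default 100).
#' @param seed Seed.
#' @return Data frame: sample, depth, mean, sd.
#' @export
rarefaction_curve <- function(x, depths, metric = c("richness", "chao1", "shannon"),
                              n_boot = 100, seed = 1) {
  metric <- match.arg(metric)
  counts <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    v <- counts[i, ]
    reads <- rep.int(seq_along(v), v)
    for (d in depths[depths <= sum(v)]) {
      vals <- replicate(n_boot, {
        tb <- tabulate(sample(reads, d), nbins = length(v))
        alpha_diversity(stats::setNames(tb, names(v)))[[metric]]
      })
      rows[[length(rows) + 1L]] <- data.frame(
        sample = rownames(counts)[i], depth = d,
        mean = mean(vals), sd = stats::sd(vals))
    }
  }
  do.call(rbind, rows)
}
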