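#' Hellinger transform and distance
#'
#' `hellinger()` closes each row to relative abundance and takes square
#' roots: `y'_ij = sqrt(y_ij / y_i.)`. `hellinger_distance()` is the
#' Euclidean distance between transformed rows; it is bounded by `sqrt(2)`
#' (attained by completely disjoint compositions) and Euclidean-embeddable,
#' which makes it safe for metric ordination of sparse compositional data.
#'
#' @param x Count or relative-abundance matrix (samples x OTUs), or an
#'   [otu_tab()].
#' @return `hellinger()`: the transformed matrix. `hellinger_distance()`: a
#'   `dist` object.
#' @export
hellinger <- function(x) {
  m <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("all-zero sample row")
  sqrt(sweep(m, 1, tot, "/"))
}

#' @rdname hellinger
#' @export
hellinger_distance <- function(x) stats::dist(hellinger(x))

# Gower-centred matrix G = -1/2 J D^2 J from a distance matrix
gower_center <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rm_, "+") + gm
  (G + t(G)) / 2
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower double-centring of the squared distances followed by
#' eigendecomposition. Sample scores are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; proportions explained are computed
#' over the positive eigenvalues only, with any negative eigenvalues
#' reported unchanged.
#'
#' @param D A `dist` object or symmetric distance matrix.
#' @return An object of class `"ordination_result"`: `eigenvalues` (all,
#'   decreasing), `prop_explained` (over positive eigenvalues), `scores`
#'   (samples x positive axes), `negative_eigenvalues`.
#' @export
pcoa <- function(D) {
  Dm <- as.matrix(D)
  G <- gower_center(Dm)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                   length(pos))
  rownames(scores) <- rownames(Dm)
  colnames(scores) <- paste0("PCo", seq_along(pos))
  structure(list(eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 scores = scores,
                 negative_eigenvalues = e$values[e$values < -tol],
                 kind = "PCoA"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s: %d samples, %d axes; first axes explain %s\n",
              x$kind, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.ordination_result <- function(x, axes = c(1, 2), col = 1, pch = 19, ...) {
  s <- x$scores[, axes, drop = FALSE]
  lab <- sprintf("%s (%.1f%%)", colnames(s), 100 * x$prop_explained[axes])
  graphics::plot(s, col = col, pch = pch, xlab = lab[1], ylab = lab[2], ...)
  invisible(x)
}

# cumulative hat matrices for a sequential model; errors on aliased terms
sequential_hats <- function(data, terms) {
  n <- nrow(data)
  Xf <- stats::model.matrix(stats::reformulate(terms), data)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qf$pivot[(qf$rank + 1):ncol(Xf)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(k)]), data)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
    ranks[k] <- q$rank
  }
  H0 <- matrix(1 / n, n, n)       # intercept-only hat
  list(hats = hats, ranks = ranks, H0 = H0)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix among sequential
#' model terms via hat matrices on the Gower-centred inner-product matrix (a
#' distance-based linear model), and tests each term's pseudo-F statistic
#' against random row permutations of the distance matrix. Sequential
#' (order-dependent) sums of squares; permutation of raw rows.
#'
#' @param D Distance matrix (`dist` or symmetric matrix).
#' @param data Data frame of sample covariates, rows aligned with `D`.
#' @param terms Character vector of term labels (columns of `data`),
#'   fitted sequentially in the order given.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed for the permutation stream.
#' @return Data frame with one row per term plus a residual row: `df`, `SS`,
#'   `F`, `R2`, `p` (`p = (1 + #{F* >= F}) / (1 + n_perm)`).
#' @export
permanova <- function(D, data, terms, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  G <- gower_center(D)
  n <- nrow(G)
  if (nrow(data) != n) stop("data rows must match the distance matrix")
  if (anyNA(data[terms])) stop("metadata incomplete for model terms")

  sq <- sequential_hats(data, terms)
  SS_tot <- sum(diag(G)) - n * mean(G)   # G is centred: second term ~ 0
  term_ss <- function(Gm) {
    tr <- vapply(sq$hats, function(H) sum(H * Gm), numeric(1))
    tr0 <- sum(sq$H0 * Gm)
    diff(c(tr0, tr))
  }
  SS <- term_ss(G)
  df <- diff(c(1L, sq$ranks))
  df_res <- n - sq$ranks[length(terms)]
  SS_res <- sum(diag(G)) - sum(sq$hats[[length(terms)]] * G)
  Fobs <- (SS / df) / (SS_res / df_res)

  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    SSp <- term_ss(Gp)
    SSrp <- sum(diag(Gp)) - sum(sq$hats[[length(terms)]] * Gp)
    Fp <- (SSp / df) / (SSrp / df_res)
    exceed <- exceed + (Fp >= Fobs)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  total <- sum(SS) + SS_res
  out <- data.frame(
    term = c(terms, "Residual"),
    df = c(df, df_res),
    SS = c(SS, SS_res),
    F = c(Fobs, NA),
    R2 = c(SS, SS_res) / total,
    p = c(pval, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  out
}

#' Indicator species analysis (IndVal)
#'
#' For each OTU and group: specificity `A` = group mean abundance divided by
#' the sum of group mean abundances (group-size-corrected), fidelity `B` =
#' fraction of the group's samples where the OTU occurs, and
#' `IndVal = sqrt(A * B)`; the statistic is the maximum over groups and its
#' significance comes from permuting group labels.
#'
#' @param x Abundance matrix (samples x OTUs) or [otu_tab()].
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Data frame per OTU: `otu`, `group` (best), `A`, `B`, `indval`,
#'   `p`. OTUs absent from every sample get `NA` statistics.
#' @export
indval <- function(x, groups, n_perm = 999, seed = NULL) {
  m <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  if (!is.null(seed)) set.seed(seed)

  stat_all <- function(g) {
    gm <- apply(m, 2, function(col) tapply(col, g, mean))   # groups x OTUs
    A <- sweep(gm, 2, colSums(gm), "/")                     # NaN when absent
    occ <- apply(m > 0, 2, function(col) tapply(col, g, mean))
    iv <- sqrt(A * occ)
    best <- apply(iv, 2, function(col)
      if (all(is.na(col))) 1L else which.max(col))
    list(stat = apply(iv, 2, max), best = rownames(iv)[best],
         A = A, B = occ, iv = iv)
  }
  present <- colSums(m) > 0
  obs <- stat_all(groups)
  exceed <- numeric(ncol(m))
  for (b in seq_len(n_perm)) {
    stat_p <- stat_all(sample(groups))$stat
    exceed <- exceed + (stat_p >= obs$stat)
  }
  p <- (1 + exceed) / (1 + n_perm)

  best_idx <- cbind(match(obs$best, levels(groups)), seq_len(ncol(m)))
  out <- data.frame(
    otu = colnames(m),
    group = obs$best,
    A = obs$A[best_idx],
    B = obs$B[best_idx],
    indval = obs$stat,
    p = p,
    stringsAsFactors = FALSE)
  out[!present, c("group")] <- NA
  out[!present, c("A", "B", "indval", "p")] <- NA
  attr(out, "n_perm") <- n_perm
  out
}

# residualise columns of M on the column space of Z (with intercept)
residualise <- function(M, Z) {
  q <- qr(cbind(1, Z))
  qr.resid(q, M)
}

#' (Partial) redundancy analysis
#'
#' Regresses a multivariate response (typically the Hellinger-transformed
#' community table) on constraint variables and eigen-analyses the fitted
#' values. With a `condition` block, both response and constraints are first
#' residualised on the conditioning variables, removing their contribution
#' (partial RDA). Eigenvalues are on the variance scale
#' (`d^2 / (n - 1)`), so constrained plus unconstrained eigenvalues add to
#' the total variance of the (residualised) response.
#'
#' @param Y Numeric response matrix (samples x variables).
#' @param X Constraints: data frame or numeric matrix.
#' @param condition Optional conditioning covariates (same form as `X`).
#' @param n_perm Permutations for the overall model test (0 = no test);
#'   rows of the residualised response are permuted.
#' @param seed Optional seed.
#' @return An `"ordination_result"` with `eigenvalues` (constrained),
#'   `unconstrained_eigenvalues`, `prop_explained` (per constrained axis,
#'   of total variance), `prop_constrained`, `scores` (sample scores on
#'   constrained axes), `variable_scores` (correlation of constraints with
#'   axes), `F`, `p`.
#' @export
rda <- function(Y, X, condition = NULL, n_perm = 0, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  to_mm <- function(d) {
    if (is.null(d)) return(NULL)
    if (is.data.frame(d)) stats::model.matrix(~ ., d)[, -1, drop = FALSE]
    else as.matrix(d)
  }
  Xm <- to_mm(X)
  Zm <- to_mm(condition)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (!is.null(Zm)) {
    Zc <- scale(Zm, center = TRUE, scale = FALSE)
    Yc <- residualise(Yc, Zc)
    Xm0 <- scale(Xm, center = TRUE, scale = FALSE)
    Xm <- residualise(Xm0, Zc)
    # constraints absorbed by the condition block carry no information;
    # drop them rather than projecting onto numerical noise
    live <- sqrt(colSums(Xm^2)) > 1e-8 * pmax(sqrt(colSums(Xm0^2)), 1)
    Xm <- Xm[, live, drop = FALSE]
  } else {
    Xm <- scale(Xm, center = TRUE, scale = FALSE)
  }
  if (ncol(Xm) > 0) {
    qx <- qr(Xm)
    if (qx$rank < ncol(Xm)) {
      dep <- colnames(Xm)[qx$pivot[(qx$rank + 1):ncol(Xm)]]
      stop("collinear constraints: ", paste(dep, collapse = ", "))
    }
    fit <- qr.fitted(qx, Yc)
  } else {
    qx <- NULL
    fit <- Yc * 0
  }
  res <- Yc - fit
  sv <- svd(fit)
  tol <- 1e-9 * max(sv$d, 1)
  keep <- which(sv$d > tol)
  eig <- sv$d[keep]^2 / (n - 1)
  tot <- sum(Yc^2) / (n - 1)
  svr <- svd(res)
  eig_u <- (svr$d[svr$d > tol])^2 / (n - 1)

  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  rownames(scores) <- rownames(Y)
  if (length(keep)) colnames(scores) <- paste0("RDA", seq_along(keep))
  vsc <- if (length(keep) && ncol(Xm))
    suppressWarnings(stats::cor(Xm, scores)) else NULL

  q <- if (is.null(qx)) 0L else qx$rank
  pz <- if (is.null(Zm)) 0 else qr(Zm)$rank
  SSc <- sum(fit^2); SSr <- sum(res^2)
  df_res <- n - q - pz - 1
  Fobs <- if (q > 0) (SSc / q) / (SSr / df_res) else NA_real_
  pval <- NA_real_
  if (n_perm > 0 && q > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0
    for (b in seq_len(n_perm)) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      fp <- qr.fitted(qx, Yp)
      Fp <- (sum(fp^2) / q) / (sum((Yp - fp)^2) / df_res)
      if (Fp >= Fobs) exceed <- exceed + 1
    }
    pval <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(eigenvalues = eig, unconstrained_eigenvalues = eig_u,
                 prop_explained = eig / tot,
                 prop_constrained = sum(eig) / tot,
                 total_variance = tot,
                 scores = scores, variable_scores = vsc,
                 F = Fobs, p = pval, rank = q, kind = "RDA"),
            class = "ordination_result")
}

#' Stepwise model selection for RDA by AIC
#'
#' Adds (and, for `direction = "both"`, drops) candidate constraint terms to
#' minimise an AIC analogue for the constrained fit:
#' `n * log(RSS / n) + 2 k`, where RSS is the residual sum of squares of the
#' multivariate regression and `k` its number of fitted parameters
#' (including the intercept). Ties break deterministically towards the
#' first-listed candidate. Collinear additions cannot reduce RSS and pay
#' the `2 k` penalty, so a duplicated covariate is never co-selected.
#'
#' @param Y Response matrix (e.g. Hellinger-transformed counts).
#' @param data Data frame holding the candidate variables.
#' @param candidates Character vector of candidate term names.
#' @param direction `"forward"` or `"both"`.
#' @return List: `terms` (selected, in selection order), `aic`, `history`
#'   (data frame of steps).
#' @export
stepwise_aic_rda <- function(Y, data, candidates,
                             direction = c("forward", "both")) {
  direction <- match.arg(direction)
  if (length(candidates) < 1) stop("at least one candidate term is required")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  aic_of <- function(terms) {
    if (length(terms) == 0L) {
      rss <- sum(Yc^2); k <- 1
    } else {
      X <- stats::model.matrix(stats::reformulate(terms), data)
      q <- qr(X)
      rss <- sum(qr.resid(q, Yc)^2)
      k <- q$rank
    }
    n * log(rss / n) + 2 * k
  }
  sel <- character(0)
  cur <- aic_of(sel)
  history <- data.frame(step = "<start>", aic = cur, stringsAsFactors = FALSE)
  repeat {
    moves <- c(
      stats::setNames(lapply(setdiff(candidates, sel), function(t) c(sel, t)),
                      paste0("+", setdiff(candidates, sel))),
      if (direction == "both" && length(sel))
        stats::setNames(lapply(sel, function(t) setdiff(sel, t)),
                        paste0("-", sel)))
    if (length(moves) == 0L) break
    aics <- vapply(moves, aic_of, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur - 1e-10) break
    sel <- moves[[best]]
    cur <- aics[best]
    history <- rbind(history, data.frame(step = names(moves)[best], aic = cur))
  }
  list(terms = sel, aic = cur, history = history)
}

#' Pearson correlation screening
#'
#' Pairwise Pearson correlations with two-sided t-test p-values, and the
#' fraction of variable pairs whose `|r|` exceeds a threshold. Constant
#' columns give `NA` correlations and are excluded from the fraction.
#'
#' @param X Numeric data frame or matrix (>= 3 complete rows per pair).
#' @param r_threshold Threshold for the reported fraction (default 0.3).
#' @return List: `r`, `p` (matrices), `fraction_above`, `r_threshold`.
#' @export
pearson_matrix <- function(X, r_threshold = 0.3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations")
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  up <- upper.tri(r)
  vals <- abs(r[up])
  frac <- mean(vals > r_threshold, na.rm = TRUE)
  list(r = r, p = p, fraction_above = frac, r_threshold = r_threshold)
}

#' Tucker's congruence coefficient between loading matrices
#'
#' `phi_jk = sum_i a_ij b_ik / sqrt(sum_i a_ij^2 sum_i b_ik^2)` for every
#' pair of columns; used to compare recovered factor loadings with truth
#' (sign-invariant in absolute value).
#'
#' @param A,B Loading matrices with matching rows.
#' @return Matrix of congruence coefficients (columns of A x columns of B).
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  num <- crossprod(A, B)
  den <- sqrt(outer(colSums(A^2), colSums(B^2)))
  num / den
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the 95th
#' percentile of eigenvalues from data whose columns are independently
#' permuted (destroying correlation but preserving margins). The retained
#' count is the number of leading eigenvalues exceeding their permuted
#' quantile.
#'
#' @param X Numeric data matrix.
#' @param n_iter Permutation datasets (default 100).
#' @param quantile Quantile of the null eigenvalues (default 0.95).
#' @param seed Optional seed.
#' @return List: `n_factors`, `observed` eigenvalues, `threshold`.
#' @export
parallel_analysis <- function(X, n_iter = 100, quantile = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  nulls <- replicate(n_iter, {
    Xp <- apply(X, 2, sample)
    eigen(stats::cor(Xp), symmetric = TRUE, only.values = TRUE)$values
  })
  thr <- apply(nulls, 1, stats::quantile, probs = quantile)
  above <- obs > thr
  k <- if (all(above)) length(obs) else which.min(above) - 1L
  list(n_factors = as.integer(k), observed = obs, threshold = thr)
}

#' Exploratory factor analysis by iterated principal-axis factoring
#'
#' Factors the correlation matrix with communalities iterated to
#' convergence (initialised at squared multiple correlations), optionally
#' choosing the number of factors by [parallel_analysis()], and applies a
#' varimax rotation. Each variable is assigned to its maximum-|loading|
#' factor. Factor scores use the regression method.
#'
#' @param X Numeric data frame or matrix (samples x variables).
#' @param n_factors Integer, or `"auto"` for parallel analysis.
#' @param rotation `"varimax"` or `"none"`.
#' @param max_iter Communality iteration cap (default 1000); non-convergence
#'   is an error reporting the iteration count.
#' @param tol Convergence tolerance on communalities.
#' @param seed Optional seed (parallel analysis).
#' @return An object of class `"factor_model"`: `loadings` (variables x
#'   factors, columns `MR1..`), `uniquenesses`, `communalities`,
#'   `n_factors`, `rotation`, `scores`, `assignment` (named factor per
#'   variable), `parallel` (if auto).
#' @export
efa <- function(X, n_factors = "auto", rotation = c("varimax", "none"),
                max_iter = 1000, tol = 1e-6, seed = NULL) {
  rotation <- match.arg(rotation)
  X <- as.matrix(X)
  vars <- colnames(X)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")

  pa <- NULL
  if (identical(n_factors, "auto")) {
    pa <- parallel_analysis(X, seed = seed)
    n_factors <- pa$n_factors
  }
  m <- as.integer(n_factors)
  p <- ncol(X)
  if (m == 0L) {
    return(structure(list(
      loadings = matrix(0, p, 0, dimnames = list(vars, NULL)),
      uniquenesses = stats::setNames(rep(1, p), vars),
      communalities = stats::setNames(rep(0, p), vars),
      n_factors = 0L, rotation = rotation,
      scores = matrix(0, nrow(X), 0),
      assignment = stats::setNames(rep(NA_character_, p), vars),
      parallel = pa), class = "factor_model"))
  }

  # initial communalities: squared multiple correlations
  Rinv <- tryCatch(solve(R), error = function(e) MASS_ginv(R))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0.05), 0.995)
  L <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rs <- R
    diag(Rs) <- h2
    e <- eigen(Rs, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
    h2_new <- pmin(rowSums(L^2), 0.998)   # guard against Heywood cases
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; converged <- TRUE; break }
    h2 <- h2_new
  }
  if (!converged)
    stop(sprintf("communality iteration did not converge in %d iterations",
                 max_iter))
  rownames(L) <- vars
  # Heywood guard: keep communalities strictly below 1
  over <- rowSums(L^2) > 0.999
  if (any(over)) L[over, ] <- L[over, ] * sqrt(0.999 / rowSums(L[over, , drop = FALSE]^2))
  if (rotation == "varimax" && m > 1) {
    vr <- stats::varimax(L, normalize = TRUE)
    L <- L %*% vr$rotmat
  }
  # order factors by explained variance; flip signs so each column's largest
  # loading is positive (presentation convention)
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(m)) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  colnames(L) <- paste0("MR", seq_len(m))

  scores <- scale(X) %*% Rinv %*% L      # regression method
  colnames(scores) <- colnames(L)
  assignment <- stats::setNames(colnames(L)[apply(abs(L), 1, which.max)], vars)
  structure(list(loadings = L,
                 uniquenesses = stats::setNames(1 - rowSums(L^2), vars),
                 communalities = stats::setNames(rowSums(L^2), vars),
                 n_factors = m, rotation = rotation, scores = scores,
                 assignment = assignment, parallel = pa, n_iter = it),
            class = "factor_model")
}

# minimal Moore-Penrose fallback for a near-singular correlation matrix
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("EFA (%s rotation): %d factors\n", x$rotation, x$n_factors))
  if (x$n_factors > 0) {
    cat("Variable assignments:\n")
    for (f in colnames(x$loadings)) {
      cat(sprintf("  %s: %s\n", f,
                  paste(names(x$assignment)[x$assignment == f], collapse = ", ")))
    }
  }
  invisible(x)
}
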