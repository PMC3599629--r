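#' Loevinger scalability coefficients for polytomous items
#'
#' `pairwise_scalability()` computes, on the listwise-complete cases, the
#' inter-item covariances `Cov_ij`, their comonotonic maxima `Covmax_ij`
#' (covariance after sorting both observed score vectors and pairing them
#' rank-wise — the largest covariance attainable over all pairings of the
#' two marginals), and the pairwise scalability
#' `H_ij = Cov_ij / Covmax_ij`. `scalability()` aggregates these into the
#' per-item coefficients `H_i = sum_j Cov_ij / sum_j Covmax_ij`, the total
#' `H = sum_{i<j} Cov_ij / sum_{i<j} Covmax_ij`, and the conventional
#' classification (below 0.3 unscalable, 0.3-0.4 weak, 0.4-0.5 medium,
#' 0.5 and above strong). `H = 1` characterises perfect Guttman data;
#' values near 0 arise under independence.
#'
#' Covariances use the population (divide-by-n) convention; the denominator
#' cancels in every H ratio.
#'
#' @param R a [response_matrix()].
#' @return `pairwise_scalability()`: list with symmetric matrices `H_pair`,
#'   `cov`, `covmax` (diagonal `NA`) and `n_used`. `scalability()`: object of
#'   class `"scalability_result"` with `H_pair`, `H_item`, `H_total`,
#'   `classification`, `n_used`.
#' @examples
#' R <- response_matrix(cbind(a = c(0, 0, 1, 1), b = c(0, 1, 1, 1)))
#' pairwise_scalability(R)$H_pair
#' @export
pairwise_scalability <- function(R) {
  stopifnot(is_response_matrix(R))
  if (n_items(R) < 2L) stop("need at least 2 items", call. = FALSE)
  X <- complete_cases(R)$values
  n <- nrow(X)
  if (n < 3L) stop("fewer than 3 complete cases", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate item with zero variance: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / n
  # comonotonic coupling: pairing k-th smallest with k-th smallest is the
  # same coupling as k-th largest with k-th largest
  Xs <- apply(X, 2L, sort)
  Cmax <- crossprod(scale(Xs, center = TRUE, scale = FALSE)) / n
  off <- upper.tri(Cmax) | lower.tri(Cmax)
  if (any(Cmax[off] <= 0))
    stop("degenerate item pair with Covmax <= 0", call. = FALSE)
  H <- C / Cmax
  diag(H) <- NA_real_
  diag(C) <- NA_real_
  diag(Cmax) <- NA_real_
  dimnames(H) <- dimnames(C) <- dimnames(Cmax) <-
    list(R$item_ids, R$item_ids)
  list(H_pair = H, cov = C, covmax = Cmax, n_used = n)
}

#' @rdname pairwise_scalability
#' @param components output of `pairwise_scalability()`.
#' @export
item_scalability <- function(components) {
  with(components, {
    num <- rowSums(cov, na.rm = TRUE)
    den <- rowSums(covmax, na.rm = TRUE)
    stats::setNames(num / den, rownames(cov))
  })
}

#' @rdname pairwise_scalability
#' @export
total_scalability <- function(components) {
  up <- upper.tri(components$cov)
  H <- sum(components$cov[up]) / sum(components$covmax[up])
  list(H_total = H, classification = classify_scalability(H))
}

#' @rdname pairwise_scalability
#' @param H a scalar total-scale coefficient.
#' @export
classify_scalability <- function(H) {
  stopifnot(is.numeric(H), length(H) == 1L)
  if (H < 0.3) "unscalable"
  else if (H < 0.4) "weak"
  else if (H < 0.5) "medium"
  else "strong"
}

#' @rdname pairwise_scalability
#' @export
scalability <- function(R) {
  comp <- pairwise_scalability(R)
  tot <- total_scalability(comp)
  structure(list(H_pair = comp$H_pair,
                 cov = comp$cov,
                 covmax = comp$covmax,
                 H_item = item_scalability(comp),
                 H_total = tot$H_total,
                 classification = tot$classification,
                 n_used = comp$n_used),
            class = "scalability_result")
}

#' @export
print.scalability_result <- function(x, ...) {
  cat(sprintf("<scalability_result> n = %d, H = %.3f (%s)\n",
              x$n_used, x$H_total, x$classification))
  print(round(x$H_item, 3))
  invisible(x)
}

# One-sided Z statistic for H_ij > 0 (equivalently Cov_ij > 0): the Pearson
# correlation r has null SD ~ 1/sqrt(n-1) under independence.
pair_z <- function(r, n) r * sqrt(n - 1)

#' Automatic item selection into Mokken scales
#'
#' Greedy bottom-up partitioning of the item set into scales. Each scale is
#' seeded with the unassigned pair of highest `H_ij` among pairs whose
#' scalability is significantly positive (one-sided Z test on the pair
#' correlation at `alpha_sig`); items are then added one at a time, choosing
#' the unassigned item that maximises the provisional scale's total H,
#' subject to the candidate's scalability against the scale being at least
#' `lowerbound` and significantly positive. Ties are broken by lower item
#' index, so the output is deterministic. Items never absorbed into a scale
#' are reported as unscalable. Used to probe multidimensionality: items
#' loading on separate latent dimensions end up in separate scales.
#'
#' @param R a [response_matrix()].
#' @param lowerbound scalability threshold c for admitting an item (default
#'   0.3, the conventional lower bound for a useful item).
#' @param alpha_sig significance level of the positivity tests.
#' @return List with `scales` (list of character vectors of item ids, in
#'   formation order) and `unscalable` (character vector).
#' @export
aisp <- function(R, lowerbound = 0.3, alpha_sig = 0.05) {
  stopifnot(is_response_matrix(R))
  X <- complete_cases(R)$values
  n <- nrow(X)
  comp <- pairwise_scalability(R)
  H <- comp$H_pair
  Cv <- comp$cov
  Cm <- comp$covmax
  rmat <- stats::cor(X)
  zcrit <- stats::qnorm(1 - alpha_sig)
  I <- ncol(X)
  unassigned <- seq_len(I)
  scales <- list()
  repeat {
    if (length(unassigned) < 2L) break
    # seed: best significantly positive pair among unassigned items
    best <- NULL
    bestH <- -Inf
    for (a in unassigned) for (b in unassigned) {
      if (b <= a) next
      if (pair_z(rmat[a, b], n) > zcrit && H[a, b] > bestH) {
        bestH <- H[a, b]; best <- c(a, b)
      }
    }
    if (is.null(best)) break
    scale_items <- best
    unassigned <- setdiff(unassigned, best)
    repeat {
      cand <- NULL
      candH <- -Inf
      for (k in unassigned) {
        hk <- sum(Cv[k, scale_items]) / sum(Cm[k, scale_items])
        rk <- stats::cor(X[, k], rowSums(X[, scale_items, drop = FALSE]))
        if (hk < lowerbound || !(pair_z(rk, n) > zcrit)) next
        prov <- c(scale_items, k)
        up <- utils::combn(prov, 2L)
        newH <- sum(Cv[t(up)]) / sum(Cm[t(up)])
        if (newH > candH + 1e-12) { candH <- newH; cand <- k }
      }
      if (is.null(cand)) break
      scale_items <- c(scale_items, cand)
      unassigned <- setdiff(unassigned, cand)
    }
    scales[[length(scales) + 1L]] <- R$item_ids[sort(scale_items)]
  }
  list(scales = scales, unscalable = R$item_ids[sort(unassigned)])
}

# Merge adjacent raw rest scores left-to-right until each group holds at
# least minsize persons; the trailing remainder joins the last group.
restscore_groups <- function(rest, minsize) {
  tab <- table(rest)
  vals <- as.numeric(names(tab))
  grp <- integer(length(vals))
  g <- 1L; acc <- 0L
  for (k in seq_along(vals)) {
    grp[k] <- g
    acc <- acc + tab[k]
    if (acc >= minsize) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && g > 1L) grp[grp == g] <- g - 1L   # remainder joins last
  groups <- grp[match(rest, vals)]
  match(groups, sort(unique(groups)))
}

#' Manifest monotonicity check by the restscore method
#'
#' For each item, persons are grouped by their rest score (total on the
#' remaining items, complete cases), merging adjacent rest scores until
#' every group holds at least `minsize` persons. For each item step
#' `k >= 1` the estimated step probability `P(X_i >= k | group)` should be
#' non-decreasing across the ordered groups; a decrease larger than `minvi`
#' between any lower and higher group is a violation, tested one-sided with
#' a two-proportion z-test at the 0.05 level.
#'
#' @param R a [response_matrix()].
#' @param minsize minimum restscore group size (default 15, which at n near
#'   60 gives roughly a low, a middle and a high group).
#' @param minvi smallest decrease counted as a violation (default 0.03).
#' @return Object of class `"monotonicity_report"`: per-item data frame with
#'   group count, active comparisons, violations, max violation and
#'   significant violations, plus the per-item group sizes.
#' @export
check_monotonicity <- function(R, minsize = 15, minvi = 0.03) {
  stopifnot(is_response_matrix(R))
  X <- complete_cases(R)$values
  I <- ncol(X)
  rows <- vector("list", I)
  group_sizes <- vector("list", I)
  for (j in seq_len(I)) {
    rest <- rowSums(X[, -j, drop = FALSE])
    grp <- restscore_groups(rest, minsize)
    G <- max(grp)
    group_sizes[[j]] <- tabulate(grp, nbins = G)
    if (G < 2L) {
      rows[[j]] <- data.frame(item = R$item_ids[j], n_groups = G,
                              active = 0L, violations = 0L, max_vi = 0,
                              significant = 0L, note = "insufficient persons")
      next
    }
    m <- R$n_categories[j] - 1L
    nv <- 0L; ns <- 0L; maxvi <- 0; act <- 0L
    for (k in seq_len(m)) {
      p <- vapply(seq_len(G), function(g) mean(X[grp == g, j] >= k), 0)
      ng <- group_sizes[[j]]
      for (g in seq_len(G - 1L)) for (h in seq(g + 1L, G)) {
        act <- act + 1L
        vi <- p[g] - p[h]
        if (vi > minvi) {
          nv <- nv + 1L
          maxvi <- max(maxvi, vi)
          pbar <- (p[g] * ng[g] + p[h] * ng[h]) / (ng[g] + ng[h])
          se <- sqrt(pbar * (1 - pbar) * (1 / ng[g] + 1 / ng[h]))
          if (se > 0 && (vi / se) > stats::qnorm(0.95)) ns <- ns + 1L
        }
      }
    }
    rows[[j]] <- data.frame(item = R$item_ids[j], n_groups = G, active = act,
                            violations = nv, max_vi = maxvi,
                            significant = ns, note = "")
  }
  structure(list(items = do.call(rbind, rows), group_sizes = group_sizes,
                 minsize = minsize, minvi = minvi),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat("<monotonicity_report> restscore method, minsize =", x$minsize, "\n")
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Invariant item ordering (non-intersection) check
#'
#' Items are ordered by their overall sample means (higher mean = easier).
#' For every item pair, persons are grouped on the rest score excluding both
#' items; within each group the conditional item means should preserve the
#' overall order. A reversal larger than `tolerance` is a violation, tested
#' one-sided with a paired t-test on the within-group score differences at
#' the 0.05 level. Crossing item response functions (e.g. items differing
#' strongly in discrimination) produce such reversals.
#'
#' @param R a [response_matrix()].
#' @param minsize minimum restscore group size (default 15).
#' @param tolerance smallest reversal counted; default `0.03 * max category
#'   code`, scaling the conventional 0.03 step tolerance to the score range.
#' @return Object of class `"iio_report"`: `pairs` data frame (one row per
#'   unordered item pair: violations, max magnitude, significant count) and
#'   `items` data frame tallying significant violations per item.
#' @export
check_iio <- function(R, minsize = 15, tolerance = NULL) {
  stopifnot(is_response_matrix(R))
  X <- complete_cases(R)$values
  if (is.null(tolerance)) tolerance <- 0.03 * max(R$n_categories - 1L)
  I <- ncol(X)
  means <- colMeans(X)
  pair_rows <- list()
  per_item_sig <- stats::setNames(integer(I), R$item_ids)
  for (a in seq_len(I - 1L)) for (b in seq((a + 1L), I)) {
    # e = easier (higher mean), d = harder; ties keep column order
    if (means[a] >= means[b]) { e <- a; d <- b } else { e <- b; d <- a }
    rest <- rowSums(X[, -c(a, b), drop = FALSE])
    grp <- restscore_groups(rest, minsize)
    G <- max(grp)
    nv <- 0L; ns <- 0L; maxvi <- 0
    if (G >= 1L) {
      for (g in seq_len(G)) {
        sel <- grp == g
        diffs <- X[sel, d] - X[sel, e]   # positive = order reversed
        vi <- mean(diffs)
        if (vi > tolerance) {
          nv <- nv + 1L
          maxvi <- max(maxvi, vi)
          if (stats::sd(diffs) > 0 && sum(sel) >= 2L) {
            tt <- stats::t.test(diffs, alternative = "greater")
            if (!is.na(tt$p.value) && tt$p.value < 0.05) {
              ns <- ns + 1L
              per_item_sig[a] <- per_item_sig[a] + 1L
              per_item_sig[b] <- per_item_sig[b] + 1L
            }
          }
        }
      }
    }
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(item_easy = R$item_ids[e], item_hard = R$item_ids[d],
                 n_groups = G, violations = nv, max_vi = maxvi,
                 significant = ns)
  }
  structure(list(pairs = do.call(rbind, pair_rows),
                 items = data.frame(item = R$item_ids,
                                    significant = as.integer(per_item_sig)),
                 tolerance = tolerance, minsize = minsize),
            class = "iio_report")
}

#' @export
print.iio_report <- function(x, ...) {
  cat("<iio_report> tolerance =", signif(x$tolerance, 3), "\n")
  print(x$items, row.names = FALSE)
  invisible(x)
}
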