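#' Bootstrap percentile confidence interval for a scale statistic
#'
#' Distributional assumptions for scalability coefficients are unreliable at
#' clinical sample sizes, so inference resamples the empirical distribution:
#' persons (rows) are drawn with replacement, preserving within-person item
#' dependence, and the statistic is recomputed on each replicate. Replicates
#' where the statistic is degenerate (e.g. a resampled item with zero
#' variance) are dropped and counted. The interval is the percentile
#' interval of the replicate distribution.
#'
#' Replicate-level RNG seeds are derived from `seed` by counter, so results
#' are reproducible and independent of execution order.
#'
#' @param R a [response_matrix()].
#' @param statistic function mapping a response_matrix to a scalar, e.g.
#'   `function(R) scalability(R)$H_total` or [cronbach_alpha()].
#' @param B number of bootstrap replicates (default 1000).
#' @param level nominal coverage (default 0.90).
#' @param seed integer RNG seed.
#' @return Object of class `"resample_interval"`: `point`, `lower`, `upper`,
#'   `level`, `B`, `B_used`, `seed`, `kind = "bootstrap"`, `replicates`,
#'   `degenerate` count and a `warning` flag when more than 20% of
#'   replicates were degenerate.
#' @export
bootstrap_ci <- function(R, statistic, B = 1000, level = 0.90, seed = 1L) {
  stopifnot(is_response_matrix(R), is.function(statistic),
            B >= 1, level > 0, level < 1)
  point <- statistic(R)
  n <- n_persons(R)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    Rb <- response_matrix(R$values[idx, , drop = FALSE],
                          n_categories = R$n_categories,
                          item_ids = R$item_ids)
    reps[b] <- tryCatch(statistic(Rb), error = function(e) NA_real_)
  }
  ok <- reps[!is.na(reps)]
  if (!length(ok)) stop("all bootstrap replicates degenerate", call. = FALSE)
  qs <- stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 1)
  structure(list(point = point, lower = qs[1L], upper = qs[2L],
                 level = level, B = B, B_used = length(ok), seed = seed,
                 kind = "bootstrap", replicates = ok,
                 degenerate = B - length(ok),
                 warning = (B - length(ok)) > 0.2 * B),
            class = "resample_interval")
}

derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' Permutation null interval for a single item's scalability
#'
#' Tests the hypothesis that an item does not cooperate with the rest of the
#' scale (`H_i = 0`): the item's response vector is permuted across persons
#' `B` times with all other items fixed — which preserves the item's
#' marginal distribution while destroying its association with the scale —
#' and `H_i` is recomputed each time. The percentile interval of this null
#' distribution is returned, with a flag saying whether the observed `H_i`
#' lies inside it (inside = compatible with a non-contributing item).
#'
#' @param R a [response_matrix()].
#' @param item item id or index.
#' @param B number of permutations (default 500).
#' @param level nominal level of the null interval (default 0.90).
#' @param seed integer RNG seed.
#' @return A `"resample_interval"` with `kind = "permutation"`, the observed
#'   `point`, the null interval, and `covered` (TRUE if the observed value
#'   lies inside the null interval).
#' @export
permutation_null_ci <- function(R, item, B = 500, level = 0.90, seed = 1L) {
  stopifnot(is_response_matrix(R), B >= 1, level > 0, level < 1)
  j <- item_index(R, item)
  Rc <- complete_cases(R)
  X <- Rc$values
  if (stats::sd(X[, j]) == 0)
    stop("degenerate item with zero variance: ", R$item_ids[j], call. = FALSE)
  observed <- item_scalability(pairwise_scalability(Rc))[j]
  n <- nrow(X)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    Xp <- X
    Xp[, j] <- X[sample.int(n), j]
    reps[b] <- item_h_of(Xp, j)
  }
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 1)
  structure(list(point = unname(observed), lower = qs[1L], upper = qs[2L],
                 level = level, B = B, B_used = B, seed = seed,
                 kind = "permutation", replicates = reps, degenerate = 0L,
                 covered = observed >= qs[1L] && observed <= qs[2L]),
            class = "resample_interval")
}

# H_i for column j of a complete integer matrix, without re-validating.
item_h_of <- function(X, j) {
  n <- nrow(X)
  x <- X[, j] - mean(X[, j])
  xs <- sort(X[, j])
  xs <- xs - mean(xs)
  num <- 0; den <- 0
  for (k in seq_len(ncol(X))) {
    if (k == j) next
    y <- X[, k]
    num <- num + sum(x * (y - mean(y))) / n
    ys <- sort(y)
    den <- den + sum(xs * (ys - mean(ys))) / n
  }
  num / den
}

#' @export
print.resample_interval <- function(x, ...) {
  cat(sprintf("<resample_interval:%s> point %.3f, %d%% interval [%.3f, %.3f], B = %d\n",
              x$kind, x$point, round(100 * x$level), x$lower, x$upper, x$B_used))
  invisible(x)
}
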