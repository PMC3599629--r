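# Independent oracles kept free of the implementation paths they check.

# All distinct permutations of a (small) multiset, as a matrix of rows.
multiset_permutations <- function(x) {
  if (length(x) <= 1L) return(matrix(x, nrow = 1L))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    sub <- multiset_permutations(rest)
    out[[length(out) + 1L]] <- cbind(v, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Brute-force maximum covariance over all pairings of the two marginals:
# hold x fixed, try every distinct rearrangement of y.
bruteforce_covmax <- function(x, y) {
  n <- length(x)
  perms <- multiset_permutations(y)
  best <- -Inf
  for (r in seq_len(nrow(perms))) {
    v <- sum((x - mean(x)) * (perms[r, ] - mean(y))) / n
    best <- max(best, v)
  }
  best
}

# Perfect Guttman (cumulative) data: person p endorses the s_p easiest steps
# over items with cuts laid out on a common difficulty ordering.
guttman_matrix <- function(n_persons, n_items, n_categories = 3L) {
  steps <- n_items * (n_categories - 1L)
  score <- round(seq(0, steps, length.out = n_persons))
  X <- matrix(0L, n_persons, n_items)
  # step difficulty order: item 1 step 1, item 2 step 1, ..., item 1 step 2, ...
  for (p in seq_len(n_persons)) {
    s <- score[p]
    full <- s %/% n_items          # complete sweeps of all items
    extra <- s %% n_items          # first `extra` items get one more step
    X[p, ] <- full + (seq_len(n_items) <= extra)
  }
  storage.mode(X) <- "integer"
  X
}

# textbook alpha from a covariance matrix
alpha_from_cov <- function(S) {
  I <- nrow(S)
  I / (I - 1) * (1 - sum(diag(S)) / sum(S))
}
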