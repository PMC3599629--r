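test_that("pairwise scalability matches hand-computed covariances", {
  R <- response_matrix(cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 1, 1)))
  comp <- pairwise_scalability(R)
  expect_equal(comp$cov[1, 2], 0.125)
  expect_equal(comp$covmax[1, 2], 0.125)
  expect_equal(comp$H_pair[1, 2], 1)
  R2 <- response_matrix(cbind(x1 = c(1, 0, 1, 0), x2 = c(0, 1, 0, 1)))
  comp2 <- pairwise_scalability(R2)
  expect_equal(comp2$cov[1, 2], -0.25)
  expect_equal(comp2$covmax[1, 2], 0.25)
  expect_equal(comp2$H_pair[1, 2], -1)
})

test_that("independent items have scalability near zero", {
  set.seed(42)
  R <- response_matrix(cbind(a = sample(0:2, 10000, TRUE),
                             b = sample(0:2, 10000, TRUE)))
  expect_lt(abs(pairwise_scalability(R)$H_pair[1, 2]), 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  R <- response_matrix(cbind(a = c(0L, 0L, 0L, 0L), b = c(0L, 1L, 2L, 1L)),
                       n_categories = c(2, 3))
  expect_error(pairwise_scalability(R), "zero variance.*a")
  expect_error(pairwise_scalability(
    response_matrix(matrix(0:1, 2, 2), n_categories = 2)), "fewer than 3")
})

test_that("sorted-coupling Covmax equals brute-force maximum over pairings", {
  set.seed(7)
  for (case in seq_len(1000)) {
    n <- sample(4:8, 1)
    ncat <- sample(2:3, 1)
    x <- sample(0:(ncat - 1), n, replace = TRUE)
    y <- sample(0:(ncat - 1), n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    R <- response_matrix(cbind(x = x, y = y), n_categories = ncat)
    got <- pairwise_scalability(R)$covmax[1, 2]
    expect_equal(got, bruteforce_covmax(x, y), tolerance = 1e-12)
  }
})

test_that("item and total coefficients satisfy the covariance-ratio identities", {
  set.seed(21)
  g <- generate_grm(150, a = runif(5, 0.6, 2), b = runif(5, -1, 1),
                    t = c(-1, 0, 1), seed = 8)
  comp <- pairwise_scalability(g$responses)
  Hi <- item_scalability(comp)
  # H_i is the covariance-weighted combination of its H_ij
  for (i in seq_along(Hi)) {
    w <- comp$covmax[i, -i]
    expect_equal(unname(Hi[i]), sum(w * comp$H_pair[i, -i]) / sum(w),
                 tolerance = 1e-12)
  }
  # H equals the covariance-weighted mean of the H_i
  tot <- total_scalability(comp)$H_total
  wi <- rowSums(comp$covmax, na.rm = TRUE)
  expect_equal(tot, sum(wi * Hi) / sum(wi), tolerance = 1e-12)
  expect_true(all(comp$H_pair[upper.tri(comp$H_pair)] <= 1))
  expect_lte(tot, 1)
})

test_that("perfect Guttman data scales perfectly", {
  for (cfg in list(c(10, 3, 2), c(25, 4, 3), c(40, 5, 4))) {
    X <- guttman_matrix(cfg[1], cfg[2], cfg[3])
    sc <- scalability(response_matrix(X, n_categories = cfg[3]))
    expect_equal(unname(sc$H_item), rep(1, cfg[2]))
    expect_equal(sc$H_total, 1)
    expect_equal(sc$classification, "strong")
  }
})

test_that("two-item instruments have H_1 = H_2 = H_12", {
  set.seed(5)
  g <- generate_grm(80, a = c(1, 1.5), b = c(0, 0.5), t = c(-0.5, 0.5), seed = 2)
  comp <- pairwise_scalability(g$responses)
  Hi <- item_scalability(comp)
  expect_equal(unname(Hi[1]), comp$H_pair[1, 2])
  expect_equal(unname(Hi[2]), comp$H_pair[1, 2])
})

test_that("classification thresholds follow the conventional cut-offs", {
  expect_equal(classify_scalability(0.103), "unscalable")
  expect_equal(classify_scalability(0.339), "weak")
  expect_equal(classify_scalability(0.45), "medium")
  expect_equal(classify_scalability(0.510), "strong")
  expect_equal(classify_scalability(0.3), "weak")
  expect_equal(classify_scalability(0.5), "strong")
})

test_that("monotone recoding keeps H within [-1, 1] and never adds codes", {
  set.seed(13)
  for (rep in 1:20) {
    g <- generate_grm(60, a = runif(4, 0.4, 2.5), b = runif(4, -1, 1.5),
                      t = c(-1.2, -0.3, 0.6, 1.3), seed = 100 + rep)
    R <- g$responses
    mapping <- sort(sample(0:2, 5, replace = TRUE))
    mapping <- mapping - mapping[1]
    while (any(diff(mapping) > 1)) mapping[which(diff(mapping) > 1)[1] + 1] <-
      mapping[which(diff(mapping) > 1)[1]] + 1
    M <- merge_categories(R, 1, mapping)
    expect_lte(M$n_categories[1], R$n_categories[1])
    H <- tryCatch(scalability(M)$H_pair, error = function(e) NULL)
    if (!is.null(H))
      expect_true(all(H[upper.tri(H)] >= -1 - 1e-12 & H[upper.tri(H)] <= 1 + 1e-12))
  }
})

test_that("AISP keeps a unidimensional scale together and splits blocks", {
  set.seed(1)
  kept <- 0L
  for (s in 1:20) {
    g <- generate_grm(500, a = runif(9, 1, 2.5), b = runif(9, -1, 1.5),
                      t = c(-1, 0, 1), seed = 400 + s)
    part <- aisp(g$responses)
    if (length(part$scales) == 1L && length(part$scales[[1]]) == 9L) kept <- kept + 1L
  }
  expect_gte(kept, 18L)   # single scale containing all 9 items, almost always
  split <- 0L
  for (s in 1:10) {
    g <- generate_multidim(500, n_blocks = 2, items_per_block = 5, a = 1.6,
                           seed = 500 + s)
    part <- aisp(g$responses)
    ok <- length(part$scales) == 2L &&
      setequal(part$scales[[1]], names(g$block_of)[g$block_of == g$block_of[[part$scales[[1]][1]]]])
    if (ok) split <- split + 1L
  }
  expect_gte(split, 9L)
})

test_that("AISP output partitions the item set and respects harsh bounds", {
  set.seed(1)
  g <- generate_grm(100, a = runif(6, 0.5, 1.5), b = runif(6, -1, 1),
                    t = c(-1, 0, 1), seed = 31)
  part <- aisp(g$responses, lowerbound = 0.99)
  all_items <- c(unlist(part$scales), part$unscalable)
  expect_setequal(all_items, g$responses$item_ids)
  expect_equal(anyDuplicated(all_items), 0L)
  # at c = 0.99 nothing beyond a seed pair can accrete
  expect_true(all(lengths(part$scales) == 2L) || length(part$scales) == 0L)
})

test_that("monotonicity check is clean on Guttman data and flags a built-in dip", {
  X <- guttman_matrix(60, 4, 3)
  rep_g <- check_monotonicity(response_matrix(X, n_categories = 3))
  expect_true(all(rep_g$items$violations == 0))
  # construct an item whose step-1 probability dips in the middle rest group
  set.seed(77)
  n <- 300
  theta <- sort(rnorm(n))
  others <- sapply(1:4, function(i)
    as.integer(cut(theta + rnorm(n, 0, 0.4), breaks = quantile(c(theta, -10, 10), 0:4 / 4),
                   labels = FALSE)) - 1L)
  colnames(others) <- paste0("o", 1:4)
  grp3 <- cut(rank(rowSums(others), ties.method = "first"), 3, labels = FALSE)
  pstep <- c(0.3, 0.1, 0.8)[grp3]          # middle group dips by 0.2
  bad <- as.integer(runif(n) < pstep)
  R <- response_matrix(cbind(others, bad = bad),
                       n_categories = c(rep(4, 4), 2))
  rep_bad <- check_monotonicity(R, minsize = 60)
  row <- rep_bad$items[rep_bad$items$item == "bad", ]
  expect_gt(row$violations, 0)
  expect_gt(row$significant, 0)
  expect_gt(row$max_vi, 0.1)
})

test_that("restscore grouping respects minimum sizes and group counts", {
  # 30 persons with distinct rest scores: minsize 15 gives exactly 2 groups
  X <- cbind(a = 0:29, b = 0:29, c = 0:29, d = 0:29)
  rep30 <- check_monotonicity(response_matrix(X, n_categories = 30),
                              minsize = 15)
  expect_true(all(rep30$items$n_groups == 2))
  for (gs in rep30$group_sizes) expect_equal(gs, c(15L, 15L))
  # comparisons = steps x 1 group pair
  expect_equal(rep30$items$active, rep(29L, 4))
  expect_true(all(rep30$items$violations == 0))
})

test_that("IIO holds for parallel items and fails for crossing curves", {
  # equal slopes, locations shifted: non-intersecting by construction
  g <- generate_grm(1000, a = c(1.5, 1.5, 1.2, 1.2), b = c(-0.75, 0.75, -0.5, 0.5),
                    t = c(-1, 0, 1), seed = 60)
  rep_ok <- check_iio(g$responses)
  expect_equal(sum(rep_ok$items$significant), 0)
  # crossing expected-score curves: a = 0.5 vs 2.5, locations crossing at 0
  g2 <- generate_grm(1000, a = c(0.5, 2.5, 1, 1), b = c(0, 0, -1, 1),
                     t = c(-1, 0, 1), seed = 61)
  rep_x <- check_iio(g2$responses)
  pair <- rep_x$pairs[(rep_x$pairs$item_easy %in% c("item1", "item2")) &
                      (rep_x$pairs$item_hard %in% c("item1", "item2")), ]
  expect_gt(pair$significant, 0)
})

test_that("single-pair IIO report covers exactly one pair", {
  g <- generate_grm(120, a = c(1, 1.5), b = c(-0.3, 0.6), t = c(-1, 0, 1),
                    seed = 9)
  rep1 <- check_iio(g$responses)
  expect_equal(nrow(rep1$pairs), 1L)
})
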