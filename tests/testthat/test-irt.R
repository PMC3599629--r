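test_that("Gauss-Hermite rules integrate normal moments exactly", {
  gh <- gauss_hermite(21)
  expect_equal(sum(gh$weights), 1)
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 3, tolerance = 1e-8)
})

test_that("rating scale model recovers its generating locations", {
  set.seed(1)
  cors <- maes <- numeric(5)
  for (s in 1:5) {
    beta <- runif(9, -1, 1)
    g <- generate_rsm(1000, beta = beta, tau = c(-0.9, 0.1, 0.8),
                      seed = 200 + s)
    f <- fit_rsm(g$responses)
    cors[s] <- cor(beta, f$beta)
    maes[s] <- mean(abs(beta - f$beta))
    expect_true(all(diff(f$loglik_trace) > -1e-7))   # EM monotone
    expect_equal(sum(f$tau), 0, tolerance = 1e-10)
  }
  expect_true(all(cors >= 0.95))
  expect_lte(mean(maes), 0.15)
})

test_that("identical response patterns get identical person estimates", {
  set.seed(6)
  g <- generate_rsm(200, beta = seq(-1, 1, length.out = 5),
                    tau = c(-0.7, 0.7), seed = 17)
  X <- g$responses$values
  X[2, ] <- X[1, ]
  f <- fit_rsm(response_matrix(X, n_categories = g$responses$n_categories))
  sc <- score_persons(f)
  expect_identical(sc$theta[1], sc$theta[2])
  expect_identical(sc$se[1], sc$se[2])
})

test_that("item relabeling permutes locations and leaves loglik unchanged", {
  g <- generate_rsm(300, beta = c(-0.8, 0, 0.9), tau = c(-0.6, 0.6), seed = 23)
  R <- g$responses
  perm <- c(3L, 1L, 2L)
  Rp <- response_matrix(R$values[, perm], n_categories = R$n_categories[perm],
                        item_ids = R$item_ids[perm])
  f1 <- fit_rsm(R)
  f2 <- fit_rsm(Rp)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(unname(f2$beta), unname(f1$beta[perm]), tolerance = 1e-3)
})

test_that("graded response model recovers discriminations and locations", {
  set.seed(2)
  a <- runif(9, 0.5, 2.5); b <- runif(9, -1, 1.5)
  g <- generate_grm(1000, a = a, b = b, t = c(-1.2, -0.3, 0.5, 1.1), seed = 77)
  f <- fit_grm(g$responses, "common", "free", compute_se = FALSE)
  expect_true(f$converged)
  expect_gte(cor(a, f$a), 0.95)
  expect_gte(cor(b, f$b), 0.95)
  expect_true(all(diff(f$loglik_trace) > -1e-7))
})

test_that("free thresholds on common-threshold data agree with the common fit", {
  set.seed(3)
  g <- generate_grm(800, a = runif(6, 0.8, 2), b = runif(6, -1, 1),
                    t = c(-1, 0, 1), seed = 55)
  fc <- fit_grm(g$responses, "common", "free", compute_se = TRUE)
  ff <- fit_grm(g$responses, "free", "free", compute_se = FALSE, start = fc)
  expect_true(all(abs(fc$b - ff$b) < 2 * fc$se_b + 0.05))
})

test_that("model nesting orders the log-likelihoods", {
  set.seed(4)
  g <- generate_grm(300, a = runif(7, 0.5, 2.5), b = runif(7, -1, 1),
                    t = c(-1, 0, 1), seed = 91)
  f_eq <- fit_grm(g$responses, "common", "equal", compute_se = FALSE)
  f_fa <- fit_grm(g$responses, "common", "free", compute_se = FALSE, start = f_eq)
  f_ft <- fit_grm(g$responses, "free", "free", compute_se = FALSE, start = f_fa)
  expect_lte(f_eq$loglik, f_fa$loglik + 1e-3)
  expect_lte(f_fa$loglik, f_ft$loglik + 1e-3)
})

test_that("likelihood-ratio test degenerates and counts df correctly", {
  set.seed(5)
  g <- generate_grm(200, a = runif(9, 0.8, 1.6), b = runif(9, -0.5, 1),
                    t = c(-1, 0, 1), seed = 13)
  f <- fit_grm(g$responses, "common", "free", compute_se = FALSE)
  same <- lr_test_equal_discrimination(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 8L)
})

test_that("reversing item codings flips locations and preserves slopes", {
  set.seed(8)
  a <- runif(5, 0.8, 2); b <- runif(5, -1, 1)
  g <- generate_grm(1500, a = a, b = b, t = c(-0.8, 0, 0.8), seed = 66)
  R <- g$responses
  Xr <- (R$n_categories[1] - 1L) - R$values
  Rr <- response_matrix(Xr, n_categories = R$n_categories,
                        item_ids = R$item_ids)
  f <- fit_grm(R, "common", "free", compute_se = FALSE)
  fr <- fit_grm(Rr, "common", "free", compute_se = FALSE)
  expect_equal(unname(fr$b), -unname(f$b), tolerance = 0.1)
  expect_equal(unname(fr$a), unname(f$a), tolerance = 0.15)
})

test_that("slope recovery error shrinks with sample size", {
  set.seed(9)
  a <- runif(6, 0.6, 2.2); b <- runif(6, -0.8, 1.2)
  mae <- sapply(c(200, 2000), function(n) {
    errs <- sapply(1:10, function(s) {
      g <- generate_grm(n, a = a, b = b, t = c(-1, 0, 1), seed = 3000 + s)
      f <- fit_grm(g$responses, "common", "free", compute_se = FALSE)
      mean(abs(f$a - a))
    })
    mean(errs)
  })
  expect_lt(mae[2], mae[1])
})

test_that("EAP scores respect pattern ordering, recentring and missingness", {
  set.seed(10)
  g <- generate_grm(150, a = runif(5, 0.8, 2), b = runif(5, -0.5, 1),
                    t = c(-1, 0, 1), seed = 29)
  # append the all-lowest pattern and an all-missing person
  X <- rbind(g$responses$values, 0L, NA_integer_)
  R <- response_matrix(X, n_categories = g$responses$n_categories)
  f <- fit_grm(response_matrix(g$responses$values,
                               n_categories = g$responses$n_categories),
               "common", "free", compute_se = FALSE)
  expect_message(sc <- score_persons(f, R), "excluded")
  n <- nrow(X)
  expect_true(is.na(sc$theta[n]))
  expect_equal(sc$excluded, n)
  # the all-lowest pattern sits at the minimum, tied only with its twins
  low <- sc$theta[n - 1L]
  expect_equal(low, min(sc$theta, na.rm = TRUE))
  at_min <- which(!is.na(sc$theta) & sc$theta <= low + 1e-12)
  expect_true(all(rowSums(X[at_min, , drop = FALSE]) == 0))
  scr <- score_persons(f, R, recenter = TRUE)
  expect_lt(abs(mean(scr$theta, na.rm = TRUE)), 1e-10)
  expect_equal(unname(scr$corrected_locations), unname(f$b - scr$shift))
})

test_that("sum score orders person estimates under the rating scale model", {
  g <- generate_rsm(400, beta = seq(-1, 1, length.out = 6),
                    tau = c(-0.8, 0, 0.8), seed = 37)
  f <- fit_rsm(g$responses)
  sc <- score_persons(f)
  ss <- rowSums(g$responses$values)
  runs <- split(sc$theta, ss)
  # theta depends on the data only through the sum score (to rounding)
  expect_true(all(vapply(runs, function(v) diff(range(v)) < 1e-9, TRUE)))
  means <- vapply(runs, mean, 0)[order(as.numeric(names(runs)))]
  expect_true(all(diff(means) > 0))
})

test_that("duplicating the instrument shrinks every posterior SD", {
  set.seed(12)
  g <- generate_grm(100, a = runif(4, 0.8, 1.8), b = runif(4, -0.5, 1),
                    t = c(-1, 0, 1), seed = 41)
  f <- fit_grm(g$responses, "common", "free", compute_se = FALSE)
  sc1 <- score_persons(f)
  double <- structure(list(
    a = c(f$a, f$a), b = c(f$b, f$b), t = f$t, d = c(f$d, f$d),
    loglik = f$loglik, converged = TRUE,
    model_tag = f$model_tag, nodes = f$nodes, weights = f$weights,
    item_ids = c(f$item_ids, paste0(f$item_ids, "_dup")),
    n_categories = c(f$n_categories, f$n_categories),
    data = cbind(f$data, f$data)), class = "grm_fit")
  sc2 <- score_persons(double)
  expect_true(all(sc2$se < sc1$se))
})

test_that("item information matches the 2PL closed form and a finite-difference oracle", {
  f <- structure(list(a = c(it = 1.7), b = c(it = 0.4), t = 0,
                      d = list(0.4), item_ids = "it", n_categories = 2L),
                 class = "grm_fit")
  info <- item_information(f, grid = seq(-3, 3, by = 0.01))
  P <- plogis(1.7 * (info$grid - 0.4))
  expect_equal(unname(info$item_info[, 1]), 1.7^2 * P * (1 - P),
               tolerance = 1e-10)
  peak <- info$grid[which.max(info$item_info[, 1])]
  expect_equal(peak, 0.4, tolerance = 0.01)
  expect_equal(max(info$item_info[, 1]), 1.7^2 / 4, tolerance = 1e-4)

  # polytomous: information = expected negative curvature of the log-likelihood
  a <- 1.4; d <- c(-0.9, 0.1, 1.2)
  fp <- structure(list(a = c(x = a), b = c(x = mean(d)), t = NULL,
                       d = list(d), item_ids = "x", n_categories = 4L),
                  class = "grm_fit")
  pts <- c(-1.5, -0.5, 0, 0.8, 1.9)
  info_p <- item_information(fp, grid = pts)
  h <- 1e-3
  catlogp <- function(th) {
    Ps <- plogis(a * (th - d))
    log(pmax(c(1, Ps) - c(Ps, 0), 1e-300))
  }
  for (q in seq_along(pts)) {
    th <- pts[q]
    p0 <- exp(catlogp(th))
    curv <- (catlogp(th + h) - 2 * catlogp(th) + catlogp(th - h)) / h^2
    expect_equal(unname(info_p$item_info[q, 1]), -sum(p0 * curv),
                 tolerance = 1e-4)
  }
})

test_that("information is non-negative and totals pointwise", {
  set.seed(14)
  g <- generate_grm(300, a = runif(5, 0.5, 2.5), b = runif(5, -1, 1.5),
                    t = c(-1, 0, 1), seed = 52)
  f <- fit_grm(g$responses, "common", "free", compute_se = FALSE)
  info <- item_information(f)
  expect_true(all(info$item_info >= 0))
  expect_equal(info$total, rowSums(info$item_info))
})

test_that("relative information shares honour symmetry and the <5 floor", {
  f <- structure(list(a = rep(1.3, 4), b = rep(0.2, 4), t = c(-1, 0, 1),
                      d = replicate(4, 0.2 + c(-1, 0, 1), simplify = FALSE),
                      item_ids = paste0("i", 1:4), n_categories = rep(4L, 4)),
                 class = "grm_fit")
  ri <- relative_information(item_information(f))
  expect_equal(ri$share, rep(25, 4), tolerance = 1e-10)
  expect_true(all(ri$bucket == "25"))
  f2 <- f
  f2$a <- c(0.05, 1.5, 1.5, 1.5)
  ri2 <- relative_information(item_information(f2))
  expect_equal(ri2$bucket[1], "<5")
  expect_equal(sum(ri2$share), 100, tolerance = 1e-10)
})

test_that("items with empty categories are recoded before fitting", {
  set.seed(16)
  g <- generate_grm(120, a = rep(1.5, 4), b = rep(-0.5, 4), t = c(-1, 0, 1),
                    seed = 71)
  X <- g$responses$values
  X[X[, 2] == 3L, 2] <- 2L    # empty the top category of item 2
  R <- response_matrix(X, n_categories = c(4L, 4L, 4L, 4L))
  f <- fit_grm(R, "free", "free", compute_se = FALSE)
  expect_named(f$recode, "item2")
  expect_equal(length(f$d[[2]]), 2L)
})
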