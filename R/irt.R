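## Marginal maximum likelihood estimation for the rating scale model and the
## graded response model, one EM engine for both. The latent trait is
## integrated out over a fixed Gauss-Hermite grid; the M-step maximises the
## expected complete-data log-likelihood with nlminb using analytic
## gradients, so the marginal log-likelihood is non-decreasing across
## iterations (GEM).

#' Gauss-Hermite quadrature for a standard normal latent trait
#'
#' Nodes and weights computed by the Golub-Welsch eigendecomposition of the
#' Jacobi matrix of the (probabilists') Hermite polynomials; the weights sum
#' to one and integrate expectations under N(0,1) exactly for polynomials up
#' to degree 2n - 1.
#'
#' @param n number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L))
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ord])^2)
}

PROB_FLOOR <- 1e-12

# log category probabilities for one graded-response item:
# P*(X >= k | theta) = plogis(a (theta - d_k)), d increasing, k = 1..m.
grm_item_logprob <- function(a, d, theta) {
  Pstar <- stats::plogis(a * outer(theta, d, "-"))   # Q x m
  P <- cbind(1, Pstar) - cbind(Pstar, 0)             # Q x (m+1)
  log(t(pmax(P, PROB_FLOOR)))                        # (m+1) x Q
}

# log category probabilities for one rating-scale item (adjacent categories):
# P(X = k | theta) propto exp(k a theta - k beta - C_k), C_k = sum_{l<=k} tau_l.
rsm_item_logprob <- function(a, beta, ccum, theta) {
  k <- seq_along(ccum) - 1L                          # 0..m
  eta <- outer(k, a * theta) - k * beta - ccum       # (m+1) x Q
  mx <- apply(eta, 2L, max)
  eta <- sweep(eta, 2L, mx)
  sweep(eta, 2L, log(colSums(exp(eta))))
}

# ---- shared EM engine -------------------------------------------------------

# x: integer matrix with NA; logprob(par) -> list of (m_i+1) x Q matrices;
# mstep(par, r) -> list(value = expected complete-data negative
# log-likelihood, gradient).
em_engine <- function(x, logprob, mstep, par0, weights, tol, max_iter,
                      inner_iter = 200L) {
  n <- nrow(x); I <- ncol(x); Q <- length(weights)
  obs <- !is.na(x)
  logw <- log(weights)
  estep <- function(logP) {
    logL <- matrix(rep(logw, each = n), n, Q)
    for (i in seq_len(I)) {
      o <- obs[, i]
      logL[o, ] <- logL[o, ] + logP[[i]][x[o, i] + 1L, , drop = FALSE]
    }
    mx <- logL[cbind(seq_len(n), max.col(logL, ties.method = "first"))]
    lik <- exp(logL - mx)
    rs <- rowSums(lik)
    list(loglik = sum(mx + log(rs)), W = lik / rs)
  }
  expected_counts <- function(W) {
    lapply(seq_len(I), function(i) {
      o <- obs[, i]
      agg <- rowsum(W[o, , drop = FALSE], group = x[o, i])
      ri <- matrix(0, max(x[, i], na.rm = TRUE) + 1L, Q)
      ri[as.integer(rownames(agg)) + 1L, ] <- agg
      ri
    })
  }
  par <- par0
  logP <- logprob(par)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- estep(logP)
    trace <- c(trace, es$loglik)
    if (iter > 1L && abs(trace[iter] - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    r <- expected_counts(es$W)
    cache <- NULL
    objf <- function(p) {
      cache <<- list(p = p, res = mstep(p, r))
      cache$res$value
    }
    grdf <- function(p) {
      if (is.null(cache) || !identical(p, cache$p))
        cache <<- list(p = p, res = mstep(p, r))
      cache$res$gradient
    }
    opt <- stats::nlminb(par, objf, grdf,
                         control = list(iter.max = inner_iter,
                                        eval.max = 2L * inner_iter))
    par <- opt$par
    logP <- logprob(par)
  }
  final <- estep(logP)
  list(par = par, loglik = final$loglik, trace = c(trace, final$loglik),
       converged = converged, n_iter = length(trace), posterior = final$W)
}

# marginal loglik at arbitrary par (for SE Hessians and LR diagnostics)
marginal_loglik <- function(x, logprob, par, weights) {
  n <- nrow(x); Q <- length(weights)
  obs <- !is.na(x)
  logP <- logprob(par)
  logL <- matrix(rep(log(weights), each = n), n, Q)
  for (i in seq_len(ncol(x))) {
    o <- obs[, i]
    logL[o, ] <- logL[o, ] + logP[[i]][x[o, i] + 1L, , drop = FALSE]
  }
  mx <- logL[cbind(seq_len(n), max.col(logL, ties.method = "first"))]
  sum(mx + log(rowSums(exp(logL - mx))))
}

num_hessian <- function(f, p, h = 1e-4) {
  k <- length(p)
  H <- matrix(0, k, k)
  f0 <- f(p)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(p + ei) - 2 * f0 + f(p - ei)) / h^2
    if (i < k) for (j in seq((i + 1L), k)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(p + ei + ej) - f(p + ei - ej) - f(p - ei + ej) + f(p - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

num_jacobian <- function(f, p, h = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (i in seq_along(p)) {
    ei <- replace(numeric(length(p)), i, h)
    J[, i] <- (f(p + ei) - f(p - ei)) / (2 * h)
  }
  J
}

pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# ---- graded response model --------------------------------------------------

# parameter transforms: a on log scale; common thresholds as increasing
# sum-zero t via log increments; free thresholds as first cut + log increments.
grm_parameterization <- function(I, ncat, thresholds, discrimination) {
  m <- ncat - 1L
  ia <- if (discrimination == "free") I else 1L
  if (thresholds == "common") {
    m0 <- m[1L]
    npar <- ia + I + (m0 - 1L)
    unpack <- function(par) {
      a <- exp(if (ia == I) par[1:I] else rep(par[1L], I))
      b <- par[ia + (1:I)]
      t_raw <- cumsum(c(0, exp(par[ia + I + seq_len(m0 - 1L)])))
      t <- t_raw - mean(t_raw)
      list(a = a, b = b, t = t, d = lapply(seq_len(I), function(i) b[i] + t))
    }
  } else {
    idx <- ia + c(0L, cumsum(m))
    npar <- ia + sum(m)
    unpack <- function(par) {
      a <- exp(if (ia == I) par[1:I] else rep(par[1L], I))
      d <- lapply(seq_len(I), function(i) {
        p <- par[(idx[i] + 1L):idx[i + 1L]]
        if (m[i] == 1L) p else cumsum(c(p[1L], exp(p[-1L])))
      })
      list(a = a, b = vapply(d, mean, 0), t = NULL, d = d)
    }
  }
  list(npar = npar, unpack = unpack, ia = ia, m = m, I = I,
       thresholds = thresholds, discrimination = discrimination)
}

# expected complete-data negative log-likelihood and its analytic gradient
# in the unconstrained parameterization, given expected counts r.
grm_mstep <- function(pz, nodes) {
  I <- pz$I; Q <- length(nodes)
  function(par, r) {
    pp <- pz$unpack(par)
    val <- 0
    g_a <- numeric(I)            # d negQ / d a_i (natural scale)
    g_d <- vector("list", I)     # d negQ / d d_ik
    for (i in seq_len(I)) {
      a <- pp$a[i]; d <- pp$d[[i]]; m <- length(d)
      z <- a * (matrix(nodes, m, Q, byrow = TRUE) - d)   # m x Q
      Pstar <- stats::plogis(z)
      w <- Pstar * (1 - Pstar)
      P <- rbind(1, Pstar) - rbind(Pstar, 0)             # (m+1) x Q
      Pf <- pmax(P, PROB_FLOOR)
      ri <- r[[i]]
      val <- val - sum(ri * log(Pf))
      A <- ri / Pf
      gd <- -a * rowSums(w * (A[seq_len(m), , drop = FALSE] -
                              A[seq_len(m) + 1L, , drop = FALSE]))
      U <- w * (z / a)                                   # w_k (theta - d_k)
      D <- rbind(0, U) - rbind(U, 0)                     # dP_k / da
      g_a[i] <- -sum(A * D)
      g_d[[i]] <- gd
    }
    grad <- numeric(length(par))
    if (pz$discrimination == "free") grad[1:I] <- g_a * pp$a
    else grad[1L] <- sum(g_a * pp$a)
    ia <- pz$ia
    if (pz$thresholds == "common") {
      m0 <- pz$m[1L]
      gd_mat <- do.call(rbind, g_d)                      # I x m0, wrt d_ik
      grad[ia + (1:I)] <- rowSums(gd_mat)
      g_t <- colSums(gd_mat)                             # wrt t_k
      ws <- par[ia + I + seq_len(m0 - 1L)]
      st <- sum(g_t)
      for (l in 2:m0)
        grad[ia + I + l - 1L] <-
          exp(ws[l - 1L]) * (sum(g_t[l:m0]) - (m0 - l + 1) / m0 * st)
    } else {
      pos <- ia
      for (i in seq_len(I)) {
        m <- pz$m[i]; gd <- g_d[[i]]
        grad[pos + 1L] <- sum(gd)
        if (m >= 2L) for (l in 2:m)
          grad[pos + l] <- exp(par[pos + l]) * sum(gd[l:m])
        pos <- pos + m
      }
    }
    list(value = val, gradient = grad)
  }
}

grm_pack_start <- function(x, ncat, pz) {
  I <- ncol(x); m <- ncat - 1L
  d0 <- lapply(seq_len(I), function(i) {
    xi <- x[, i][!is.na(x[, i])]
    p <- vapply(seq_len(m[i]), function(k) mean(xi >= k), 0)
    p <- pmin(pmax(p, 0.02), 0.98)
    cummax(-stats::qlogis(p) + seq_len(m[i]) * 1e-6)   # enforce strict increase
  })
  a0 <- if (pz$ia == I) rep(0, I) else 0
  if (pz$thresholds == "common") {
    b0 <- vapply(d0, mean, 0)
    tmat <- do.call(rbind, lapply(seq_len(I), function(i) d0[[i]] - b0[i]))
    t0 <- cummax(colMeans(tmat) + seq_len(m[1L]) * 1e-6)
    t0 <- t0 - mean(t0)
    c(a0, b0, log(pmax(diff(t0), 1e-3)))
  } else {
    c(a0, unlist(lapply(d0, function(d)
      if (length(d) == 1L) d else c(d[1L], log(pmax(diff(d), 1e-3))))))
  }
}

grm_start_from_fit <- function(fit, pz) {
  # warm start a free fit from a nested (equal-a and/or common-t) fit
  I <- length(fit$a)
  a0 <- if (pz$ia == I) log(fit$a) else log(fit$a[1L])
  if (pz$thresholds == "common") {
    c(a0, fit$b, log(pmax(diff(fit$t), 1e-6)))
  } else {
    c(a0, unlist(lapply(fit$d, function(d)
      if (length(d) == 1L) d else c(d[1L], log(pmax(diff(d), 1e-6))))))
  }
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' Cumulative-logit IRT model for ordered categories:
#' `P(X_i >= k | theta) = plogis(a_i (theta - b_i - t_k))` with shared
#' thresholds `t_k` (sum-zero, `thresholds = "common"`), or
#' `plogis(a_i (theta - b_ik))` with item-specific cuts
#' (`thresholds = "free"`). With `discrimination = "equal"` a single slope is
#' shared by all items, giving the rating-scale-like constrained model that
#' the equal-discrimination likelihood-ratio test compares against. The
#' latent trait is standard normal; estimation is EM over a Gauss-Hermite
#' grid, persons with missing cells contribute their observed items only.
#' Items with unobserved categories are recoded first (empty categories
#' merged downward) and the recode is logged in the fit.
#'
#' @param R a [response_matrix()].
#' @param thresholds `"common"` (requires equal category counts) or `"free"`.
#' @param discrimination `"free"` (item-specific slopes) or `"equal"`.
#' @param n_quadrature number of Gauss-Hermite nodes (default 41).
#' @param tol EM convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations; a non-converged fit is returned
#'   flagged, not errored.
#' @param compute_se compute standard errors from the numerically
#'   differentiated observed information (central differences, step 1e-4)?
#'   Skipping them speeds up simulation loops.
#' @param start optional warm start: a previous `grm_fit` (typically the
#'   nested constrained fit).
#' @return Object of class `"grm_fit"`: discriminations `a`, locations `b`,
#'   shared thresholds `t` (common variant) or per-item cuts `d`, `se_a`,
#'   `se_b`, `loglik`, `loglik_trace`, `converged`, `heywood` flag
#'   (any `a_i` > 20), `model_tag`, quadrature `nodes`/`weights`, and the
#'   `recode` log of any category merges.
#' @export
fit_grm <- function(R, thresholds = c("common", "free"),
                    discrimination = c("free", "equal"),
                    n_quadrature = 41, tol = 1e-5, max_iter = 500,
                    compute_se = TRUE, start = NULL) {
  stopifnot(is_response_matrix(R))
  thresholds <- match.arg(thresholds)
  discrimination <- match.arg(discrimination)
  pre <- drop_empty_categories(R)
  R <- pre$R
  if (thresholds == "common" && length(unique(R$n_categories)) != 1L)
    stop("common thresholds require all items to share a category count ",
         "(merge categories first)", call. = FALSE)
  x <- R$values
  gh <- gauss_hermite(n_quadrature)
  pz <- grm_parameterization(ncol(x), R$n_categories, thresholds, discrimination)
  logprob <- function(par) {
    pp <- pz$unpack(par)
    lapply(seq_len(ncol(x)), function(i)
      grm_item_logprob(pp$a[i], pp$d[[i]], gh$nodes))
  }
  par0 <- if (is.null(start)) grm_pack_start(x, R$n_categories, pz)
          else grm_start_from_fit(start, pz)
  em <- em_engine(x, logprob, grm_mstep(pz, gh$nodes), par0, gh$weights,
                  tol, max_iter)
  pp <- pz$unpack(em$par)
  fit <- structure(list(
    a = stats::setNames(pp$a, R$item_ids),
    b = stats::setNames(pp$b, R$item_ids),
    t = pp$t, d = pp$d,
    se_a = NULL, se_b = NULL,
    loglik = em$loglik, loglik_trace = em$trace,
    converged = em$converged, n_iter = em$n_iter,
    heywood = any(pp$a > 20),
    model_tag = paste0(ifelse(discrimination == "equal", "equal_a", "free_a"),
                       "_", ifelse(thresholds == "common", "common_t", "free_t")),
    n_params = pz$npar, par = em$par,
    nodes = gh$nodes, weights = gh$weights,
    item_ids = R$item_ids, n_categories = R$n_categories,
    recode = pre$recode, data = x),
    class = "grm_fit")
  if (compute_se) {
    negll <- function(p) -marginal_loglik(x, logprob, p, gh$weights)
    H <- num_hessian(negll, em$par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    fit$se_singular <- is.null(V)
    if (is.null(V)) V <- pinv(H)
    natural <- function(p) { u <- pz$unpack(p); c(u$a, u$b) }
    J <- num_jacobian(natural, em$par)
    Vn <- J %*% V %*% t(J)
    sds <- sqrt(pmax(diag(Vn), 0))
    I <- ncol(x)
    fit$se_a <- stats::setNames(sds[seq_len(I)], R$item_ids)
    fit$se_b <- stats::setNames(sds[I + seq_len(I)], R$item_ids)
  }
  fit
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit:%s> loglik %.2f, %sconverged in %d EM iterations\n",
              x$model_tag, x$loglik, if (x$converged) "" else "NOT ", x$n_iter))
  print(round(data.frame(a = x$a, b = x$b), 3))
  invisible(x)
}

# merge unobserved categories into their lower neighbour; returns the recoded
# matrix and a log of the mappings applied.
drop_empty_categories <- function(R) {
  recode <- list()
  for (j in seq_len(n_items(R))) {
    x <- R$values[, j]
    m <- R$n_categories[j]
    seen <- sort(unique(x[!is.na(x)]))
    if (length(seen) < 2L)
      stop("item '", R$item_ids[j], "' has fewer than 2 observed categories",
           call. = FALSE)
    if (length(seen) < m) {
      mapping <- pmax(findInterval(0:(m - 1L), seen) - 1L, 0L)
      recode[[R$item_ids[j]]] <- mapping
      R <- merge_categories(R, j, mapping)
    }
  }
  list(R = R, recode = recode)
}

# ---- rating scale model -----------------------------------------------------

#' Fit the Rasch rating scale model by marginal maximum likelihood
#'
#' Adjacent-category Rasch model for items sharing one set of category
#' thresholds: `P(X_i = k | theta)` proportional to
#' `exp(k theta - k beta_i - sum_{l<=k} tau_l)` with sum-zero thresholds
#' `tau`. All items are equally discriminating by construction, so a
#' person's raw sum score is sufficient for the trait. Identification fixes
#' the item slope at one and leaves the latent standard deviation free;
#' internally this is estimated in the equivalent standard-normal-latent
#' coordinates (one common slope `a` over z ~ N(0,1), with `theta = a z`),
#' and `a` is reported as `latent_sd`.
#'
#' @inheritParams fit_grm
#' @return Object of class `"rsm_fit"`: locations `beta`, sum-zero
#'   thresholds `tau`, `latent_sd`, `loglik`, `loglik_trace`, `converged`,
#'   quadrature nodes/weights, and the recode log.
#' @export
fit_rsm <- function(R, n_quadrature = 41, tol = 1e-5, max_iter = 500) {
  stopifnot(is_response_matrix(R))
  if (length(unique(R$n_categories)) != 1L)
    stop("the rating scale model requires a common number of categories ",
         "(merge categories first)", call. = FALSE)
  pre <- drop_empty_categories(R)
  if (length(pre$recode) && length(unique(pre$R$n_categories)) != 1L)
    stop("sparse categories broke the common category count; merge ",
         "categories explicitly before fitting", call. = FALSE)
  R <- pre$R
  x <- R$values
  I <- ncol(x); m <- R$n_categories[1L] - 1L
  gh <- gauss_hermite(n_quadrature)
  kk <- 0:m
  unpack <- function(par) {
    a <- exp(par[1L])
    beta <- par[1L + (1:I)]
    tau_free <- par[1L + I + seq_len(m - 1L)]
    tau <- c(tau_free, -sum(tau_free))
    list(a = a, beta = beta, tau = tau, ccum = c(0, cumsum(tau)))
  }
  logprob <- function(par) {
    pp <- unpack(par)
    lapply(seq_len(I), function(i)
      rsm_item_logprob(pp$a, pp$beta[i], pp$ccum, gh$nodes))
  }
  mstep <- function(par, r) {
    pp <- unpack(par)
    val <- 0
    g_a <- 0                      # d negQ / d a (natural)
    g_beta <- numeric(I)
    g_C <- numeric(m)             # wrt cumulative thresholds C_1..C_m (C_m fixed 0)
    for (i in seq_len(I)) {
      eta <- outer(kk, pp$a * gh$nodes) - kk * pp$beta[i] - pp$ccum
      mx <- apply(eta, 2L, max)
      eta <- sweep(eta, 2L, mx)
      ex <- exp(eta)
      den <- colSums(ex)
      P <- sweep(ex, 2L, den, "/")
      logP <- sweep(eta, 2L, log(den))
      ri <- r[[i]]
      if (nrow(ri) < m + 1L)
        ri <- rbind(ri, matrix(0, m + 1L - nrow(ri), ncol(ri)))
      val <- val - sum(ri * logP)
      nq <- colSums(ri)
      sq <- colSums(ri * kk)
      Ebar <- colSums(P * kk)
      g_beta[i] <- -sum(nq * Ebar - sq)
      g_a <- g_a - sum(gh$nodes * (sq - nq * Ebar))
      g_C <- g_C - (colSums(t(P[-1L, , drop = FALSE]) * nq) -
                    rowSums(ri[-1L, , drop = FALSE]))
    }
    grad <- numeric(length(par))
    grad[1L] <- g_a * pp$a
    grad[1L + (1:I)] <- g_beta
    for (l in seq_len(m - 1L)) grad[1L + I + l] <- sum(g_C[l:(m - 1L)])
    list(value = val, gradient = grad)
  }
  par0 <- c(0, -stats::qlogis(pmin(pmax(colMeans(x, na.rm = TRUE) / m, 0.05),
                                   0.95)),
            rep(0, m - 1L))
  em <- em_engine(x, logprob, mstep, par0, gh$weights, tol, max_iter)
  pp <- unpack(em$par)
  structure(list(
    beta = stats::setNames(pp$beta, R$item_ids),
    tau = pp$tau, latent_sd = pp$a,
    loglik = em$loglik, loglik_trace = em$trace,
    converged = em$converged, n_iter = em$n_iter,
    n_params = 1L + I + (m - 1L), par = em$par,
    nodes = gh$nodes, weights = gh$weights,
    item_ids = R$item_ids, n_categories = R$n_categories,
    recode = pre$recode, data = x),
    class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> loglik %.2f, latent SD %.3f, %sconverged\n",
              x$loglik, x$latent_sd, if (x$converged) "" else "NOT "))
  print(round(x$beta, 3))
  invisible(x)
}

# ---- model comparison -------------------------------------------------------

#' Likelihood-ratio test of equal item discriminations
#'
#' Compares the constrained graded-response fit (one shared slope) with the
#' free fit (item-specific slopes) on the same data. A strongly significant
#' statistic says the items do not weight the latent trait equally, so
#' sum-score (Rasch-family) models are doubtful and item-specific weights
#' are needed.
#'
#' @param fit_constrained `grm_fit` with `discrimination = "equal"`.
#' @param fit_free nested `grm_fit` with `discrimination = "free"`.
#' @param tol tolerance for the free log-likelihood falling below the
#'   constrained one (an optimisation failure beyond this errors).
#' @return List with `statistic`, `df` (= items - 1), `p`.
#' @export
lr_test_equal_discrimination <- function(fit_constrained, fit_free, tol = 0.01) {
  stopifnot(inherits(fit_constrained, "grm_fit"), inherits(fit_free, "grm_fit"))
  if (!identical(fit_constrained$item_ids, fit_free$item_ids))
    stop("fits are not on the same items", call. = FALSE)
  stat <- 2 * (fit_free$loglik - fit_constrained$loglik)
  if (stat < -tol)
    stop("free fit has lower likelihood than the constrained fit; ",
         "optimization failure", call. = FALSE)
  stat <- max(stat, 0)
  df <- length(fit_free$item_ids) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- person scoring ---------------------------------------------------------

# per-item log-probability matrices of a fit at an arbitrary theta grid
# (theta in model coordinates; the RSM slope is 1 on that scale)
fit_item_logprobs <- function(fit, theta) {
  if (inherits(fit, "grm_fit")) {
    lapply(seq_along(fit$item_ids), function(i)
      grm_item_logprob(fit$a[i], fit$d[[i]], theta))
  } else {
    ccum <- c(0, cumsum(fit$tau))
    lapply(seq_along(fit$item_ids), function(i)
      rsm_item_logprob(1, fit$beta[i], ccum, theta))
  }
}

# the grid of latent values (model coordinates) with prior weights
fit_theta_grid <- function(fit) {
  if (inherits(fit, "grm_fit")) list(theta = fit$nodes, weights = fit$weights)
  else list(theta = fit$latent_sd * fit$nodes, weights = fit$weights)
}

#' Expected a posteriori person scores
#'
#' Posterior mean and standard deviation of the latent trait for every
#' person, over the fit's quadrature grid, using each person's observed
#' items only. With `recenter = TRUE` the mean person estimate is subtracted
#' jointly from all person estimates and from the item locations, giving
#' locations expressed relative to the person mean ("corrected" locations).
#'
#' @param fit a `grm_fit` or `rsm_fit`.
#' @param R a [response_matrix()]; defaults to the data the model was fitted
#'   to. Category codes must match the (possibly recoded) fit.
#' @param recenter centre the person estimates at zero?
#' @return Object of class `"person_scores"`: `theta`, `se` (posterior SD),
#'   `recentered`, `shift`, `corrected_locations`, `excluded` (indices of
#'   persons with no observed items, scored `NA`).
#' @export
score_persons <- function(fit, R = NULL, recenter = FALSE) {
  x <- if (is.null(R)) fit$data else {
    stopifnot(is_response_matrix(R)); R$values
  }
  stopifnot(ncol(x) == length(fit$item_ids))
  grid <- fit_theta_grid(fit)
  logP <- fit_item_logprobs(fit, grid$theta)
  n <- nrow(x); Q <- length(grid$theta)
  logL <- matrix(rep(log(grid$weights), each = n), n, Q)
  obs <- !is.na(x)
  for (i in seq_len(ncol(x))) {
    o <- obs[, i]
    logL[o, ] <- logL[o, ] + logP[[i]][x[o, i] + 1L, , drop = FALSE]
  }
  excluded <- which(rowSums(obs) == 0L)
  mx <- apply(logL, 1L, max)
  W <- exp(logL - mx)
  W <- W / rowSums(W)
  theta <- as.numeric(W %*% grid$theta)
  m2 <- as.numeric(W %*% grid$theta^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  theta[excluded] <- NA_real_
  se[excluded] <- NA_real_
  shift <- 0
  loc <- if (inherits(fit, "grm_fit")) fit$b else fit$beta
  if (recenter) {
    shift <- mean(theta, na.rm = TRUE)
    theta <- theta - shift
    loc <- loc - shift
  }
  if (length(excluded))
    message(length(excluded), " person(s) with no observed items excluded from scoring")
  structure(list(theta = theta, se = se, recentered = recenter, shift = shift,
                 corrected_locations = loc, excluded = excluded),
            class = "person_scores")
}

#' @export
print.person_scores <- function(x, ...) {
  cat(sprintf("<person_scores> %d persons%s, theta range [%.2f, %.2f]\n",
              length(x$theta), if (x$recentered) " (recentered)" else "",
              min(x$theta, na.rm = TRUE), max(x$theta, na.rm = TRUE)))
  invisible(x)
}

# ---- item information -------------------------------------------------------

#' Item and test information functions for a graded response fit
#'
#' Samejima's graded-model information: with cumulative probabilities
#' `P*_k(theta)` (`P*_0 = 1`, `P*_{m+1} = 0`) and `w_k = P*_k (1 - P*_k)`,
#' the item information is
#' `I(theta) = a^2 sum_k (w_k - w_{k+1})^2 / P_k(theta)`.
#' For a dichotomous item this reduces to the two-parameter logistic
#' `a^2 P (1 - P)` with peak `a^2 / 4` at `theta = b`. Total information is
#' the pointwise sum over items.
#'
#' @param fit a `grm_fit`.
#' @param grid theta grid (default `seq(-4, 4, by = 0.05)`).
#' @return Object of class `"information_grid"`: `grid`, matrix `item_info`
#'   (grid x items), `total`.
#' @export
item_information <- function(fit, grid = seq(-4, 4, by = 0.05)) {
  stopifnot(inherits(fit, "grm_fit"))
  I <- length(fit$item_ids)
  info <- matrix(0, length(grid), I, dimnames = list(NULL, fit$item_ids))
  for (i in seq_len(I)) {
    a <- fit$a[i]; d <- fit$d[[i]]
    Pstar <- cbind(1, stats::plogis(a * outer(grid, d, "-")), 0)
    w <- Pstar * (1 - Pstar)
    P <- Pstar[, -ncol(Pstar), drop = FALSE] - Pstar[, -1L, drop = FALSE]
    P <- pmax(P, PROB_FLOOR)
    dw <- w[, -ncol(w), drop = FALSE] - w[, -1L, drop = FALSE]
    info[, i] <- a^2 * rowSums(dw^2 / P)
  }
  structure(list(grid = grid, item_info = info, total = rowSums(info)),
            class = "information_grid")
}

#' Relative item information shares
#'
#' Each item's share of the instrument's total information, taken as the
#' trapezoidal integral of its information function over the grid divided by
#' the integral of the total information, expressed in percent. For display
#' the share is also bucketed to the nearest multiple of five with a "<5"
#' floor, mirroring how approximate shares are conventionally reported; the
#' raw share is always retained.
#'
#' @param info an [item_information()] grid.
#' @return Data frame with `item`, `share` (percent), `bucket`.
#' @export
relative_information <- function(info) {
  stopifnot(inherits(info, "information_grid"))
  trap <- function(y) sum(diff(info$grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  tot <- trap(info$total)
  if (tot <= 0) stop("total information is zero on the grid", call. = FALSE)
  share <- 100 * apply(info$item_info, 2L, trap) / tot
  bucket <- ifelse(share < 5, "<5", as.character(5 * round(share / 5)))
  data.frame(item = colnames(info$item_info), share = unname(share),
             bucket = unname(bucket), stringsAsFactors = FALSE)
}
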