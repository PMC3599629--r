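#' Cronbach's alpha internal consistency
#'
#' Classical-test-theory comparator to the scalability analysis:
#' `alpha = I/(I-1) * (1 - sum(var_i) / var(total))` on the listwise-complete
#' cases, with unbiased (n-1) variances. Reported alongside H because alpha
#' rises mechanically with the number of items and rewards items clustered
#' at the same severity, which is exactly what a coverage-oriented
#' evaluation needs to see past.
#'
#' @param R a [response_matrix()].
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(R) {
  stopifnot(is_response_matrix(R))
  if (n_items(R) < 2L) stop("need at least 2 items", call. = FALSE)
  X <- complete_cases(R)$values
  vt <- stats::var(rowSums(X))
  if (vt == 0) stop("zero total-score variance", call. = FALSE)
  I <- ncol(X)
  I / (I - 1) * (1 - sum(apply(X, 2L, stats::var)) / vt)
}

#' Confidence interval for a person's rank
#'
#' Translates the imprecision of one person's trait estimate into rank
#' units: the trait confidence interval `theta_hat +/- z * SE` is mapped to
#' ranks by counting, at each endpoint, how many scored persons lie strictly
#' below it (`rank(x) = 1 + count below x`; ties between estimates are
#' resolved by person index). Relative ranks are percentages of the scored
#' sample.
#'
#' @param scores a [score_persons()] result.
#' @param person person row index.
#' @param level confidence level (default 0.95).
#' @return List of class `"rank_interval"`: `person`, `rank`, `n_scored`,
#'   `rank_lo`, `rank_hi`, `relative_lo`, `relative_hi`, `relative`.
#' @export
rank_interval <- function(scores, person, level = 0.95) {
  stopifnot(inherits(scores, "person_scores"))
  th <- scores$theta
  scored <- which(!is.na(th))
  if (!(person %in% scored)) stop("person ", person, " is not scored", call. = FALSE)
  if (length(scored) < 2L) stop("need at least 2 scored persons", call. = FALSE)
  n <- length(scored)
  z <- stats::qnorm((1 + level) / 2)
  lo <- th[person] - z * scores$se[person]
  hi <- th[person] + z * scores$se[person]
  rk_of <- function(x) 1L + sum(th[scored] < x)
  own <- 1L + sum(th[scored] < th[person]) +
    sum(th[scored] == th[person] & scored < person)
  out <- list(person = person, rank = own, n_scored = n,
              rank_lo = rk_of(lo), rank_hi = rk_of(hi),
              level = level,
              relative = round(100 * own / n),
              relative_lo = round(100 * rk_of(lo) / n),
              relative_hi = round(100 * rk_of(hi) / n))
  class(out) <- "rank_interval"
  out
}

#' @export
print.rank_interval <- function(x, ...) {
  cat(sprintf("<rank_interval> person %d: rank %d (n = %d), %d%% interval [%d, %d], relative [%d%%, %d%%]\n",
              x$person, x$rank, x$n_scored, round(100 * x$level),
              x$rank_lo, x$rank_hi, x$relative_lo, x$relative_hi))
  invisible(x)
}

#' Agreement between two instruments' person rankings
#'
#' If two instruments measure the same dimension, a person highly ranked by
#' one should be highly ranked by the other. Reports the Spearman rank
#' correlation of the trait estimates and the fraction of persons whose
#' ranks differ by at least `threshold` rank units (ties broken by person
#' index so each person has a unique rank).
#'
#' @param scoresA,scoresB [score_persons()] results on the same persons.
#' @param threshold rank-difference defining a discordant person (default 15).
#' @return List with `spearman`, `fraction_discordant`, `n`.
#' @export
rank_concordance <- function(scoresA, scoresB, threshold = 15) {
  stopifnot(inherits(scoresA, "person_scores"), inherits(scoresB, "person_scores"))
  ok <- !is.na(scoresA$theta) & !is.na(scoresB$theta)
  if (sum(ok) < 3L) stop("fewer than 3 persons scored by both", call. = FALSE)
  a <- scoresA$theta[ok]; b <- scoresB$theta[ok]
  ra <- rank(a, ties.method = "first")
  rb <- rank(b, ties.method = "first")
  list(spearman = stats::cor(a, b, method = "spearman"),
       fraction_discordant = mean(abs(ra - rb) >= threshold),
       n = sum(ok))
}

#' Flag aberrant response profiles
#'
#' Advisory flags, never exclusions: persons answering the same category on
#' every item ("constant" — apathetic/indifferent profiles), and persons
#' whose response pattern is unlikely under the fitted model, measured by
#' the standardized person log-likelihood statistic (observed pattern
#' log-likelihood at the person's EAP estimate, standardized by its model
#' expectation and variance) falling below `cutoff`.
#'
#' @param R a [response_matrix()]; defaults to the fit's data.
#' @param fit a `grm_fit` (or `rsm_fit`).
#' @param cutoff standardized person-fit cutoff (default -2).
#' @return Data frame with one row per flagged person: `person`, `reason`
#'   (`"constant"` or `"misfit"`), `statistic`.
#' @export
flag_profiles <- function(R = NULL, fit, cutoff = -2) {
  x <- if (is.null(R)) fit$data else { stopifnot(is_response_matrix(R)); R$values }
  sc <- suppressMessages(score_persons(fit, R))
  logP <- fit_item_logprobs(fit, fit_theta_grid(fit)$theta)
  theta_grid <- fit_theta_grid(fit)$theta
  n <- nrow(x)
  rows <- list()
  for (p in seq_len(n)) {
    obs <- which(!is.na(x[p, ]))
    if (length(obs) == 0L) next
    if (length(obs) >= 2L && stats::sd(x[p, obs]) == 0) {
      rows[[length(rows) + 1L]] <-
        data.frame(person = p, reason = "constant", statistic = NA_real_)
    }
    # interpolate each item's log-probabilities to the person's EAP
    q <- which.min(abs(theta_grid - sc$theta[p]))
    l <- 0; el <- 0; vl <- 0
    for (i in obs) {
      lp <- logP[[i]][, q]
      pr <- exp(lp)
      l <- l + lp[x[p, i] + 1L]
      el <- el + sum(pr * lp)
      vl <- vl + sum(pr * lp^2) - sum(pr * lp)^2
    }
    z <- if (vl > 0) (l - el) / sqrt(vl) else 0
    if (z < cutoff)
      rows[[length(rows) + 1L]] <-
        data.frame(person = p, reason = "misfit", statistic = z)
  }
  if (!length(rows))
    return(data.frame(person = integer(), reason = character(),
                      statistic = numeric()))
  do.call(rbind, rows)
}

#' Default configuration for the three-step evaluation
#'
#' @param ... overrides of the defaults: `lowerbound` (0.3), `minsize` (15),
#'   `minvi` (0.03), `bootstrap_B` (1000), `permutation_B` (500), `ci_level`
#'   (0.90), `rank_level` (0.95), `quadrature` (41), `alpha_sig` (0.05),
#'   `max_slope_ratio` (3), `seed` (1).
#' @return Named list of settings.
#' @export
three_step_config <- function(...) {
  cfg <- list(lowerbound = 0.3, minsize = 15, minvi = 0.03,
              bootstrap_B = 1000, permutation_B = 500,
              ci_level = 0.90, rank_level = 0.95, quadrature = 41,
              alpha_sig = 0.05, max_slope_ratio = 3, seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Run the three-step evaluation of one instrument
#'
#' Step 1 (always): Mokken scalability with bootstrap interval on the total
#' H, permutation null tests for items below the lower bound, automatic item
#' selection, monotonicity and invariant-item-ordering checks, and
#' Cronbach's alpha. If the instrument shows at least a weak scale
#' (H > 0.3 and every item H_i > 0), step 2 fits the equal-discrimination
#' model and tests it against item-specific discriminations. If equal
#' discrimination is rejected (likelihood-ratio p below `alpha_sig`, or the
#' fitted slope ratio max(a)/min(a) exceeding `max_slope_ratio`), step 3
#' fits the free-discrimination graded response model and reports locations,
#' information shares, person measures, coverage, and aberrant-profile
#' flags. Every skipped step records the rule that stopped it.
#'
#' @param R a [response_matrix()].
#' @param config a [three_step_config()].
#' @return Object of class `"evaluation_report"` with elements `step1`,
#'   `step2`, `step3`, and `gates` (each gate `proceed`/`stop` plus rule).
#' @export
run_three_step <- function(R, config = three_step_config()) {
  stopifnot(is_response_matrix(R))
  report <- list(config = config)

  ## Step 1 — nonparametric
  sc <- scalability(R)
  boot <- bootstrap_ci(R, function(r) scalability(r)$H_total,
                       B = config$bootstrap_B, level = config$ci_level,
                       seed = config$seed)
  weak_items <- names(sc$H_item)[sc$H_item < config$lowerbound]
  perms <- lapply(weak_items, function(it)
    permutation_null_ci(R, it, B = config$permutation_B,
                        level = config$ci_level, seed = config$seed))
  names(perms) <- weak_items
  report$step1 <- list(
    scalability = sc,
    bootstrap = boot,
    permutation = perms,
    aisp = aisp(R, lowerbound = config$lowerbound,
                alpha_sig = config$alpha_sig),
    monotonicity = check_monotonicity(R, minsize = config$minsize,
                                      minvi = config$minvi),
    iio = check_iio(R, minsize = config$minsize),
    alpha = cronbach_alpha(R))

  gate1_ok <- sc$H_total > 0.3 && all(sc$H_item > 0)
  report$gates <- list(step2 = list(
    outcome = if (gate1_ok) "proceed" else "stop",
    rule = "H > 0.3 and all H_i > 0"))
  if (!gate1_ok) {
    report$step2 <- report$step3 <- NULL
    class(report) <- "evaluation_report"
    return(report)
  }

  ## Step 2 — equal-discrimination gate
  common_ok <- length(unique(drop_empty_categories(R)$R$n_categories)) == 1L
  thr <- if (common_ok) "common" else "free"
  fit_eq <- fit_grm(R, thresholds = thr, discrimination = "equal",
                    n_quadrature = config$quadrature, compute_se = FALSE)
  fit_fr <- fit_grm(R, thresholds = thr, discrimination = "free",
                    n_quadrature = config$quadrature, compute_se = TRUE,
                    start = fit_eq)
  lr <- lr_test_equal_discrimination(fit_eq, fit_fr)
  slope_ratio <- max(fit_fr$a) / min(fit_fr$a)
  rsm_rejected <- lr$p < config$alpha_sig || slope_ratio > config$max_slope_ratio
  report$step2 <- list(thresholds = thr, fit_equal = fit_eq, lr = lr,
                       slope_ratio = slope_ratio,
                       rsm_suitable = !rsm_rejected)
  report$gates$step3 <- list(
    outcome = if (rsm_rejected) "proceed" else "stop",
    rule = sprintf("LR p < %.2f or max(a)/min(a) > %g",
                   config$alpha_sig, config$max_slope_ratio))
  if (!rsm_rejected) {
    # sum score is adequate; person measures come from the constrained model
    report$step2$scores <- score_persons(fit_eq, recenter = TRUE)
    report$step3 <- NULL
    class(report) <- "evaluation_report"
    return(report)
  }

  ## Step 3 — graded response model
  scores <- score_persons(fit_fr, recenter = TRUE)
  info <- item_information(fit_fr)
  thresholds_all <- unlist(fit_fr$d)
  report$step3 <- list(
    fit = fit_fr,
    scores = scores,
    information = info,
    relative_information = relative_information(info),
    coverage = list(
      person_quantiles = stats::quantile(scores$theta - scores$shift,
                                         c(0.05, 0.25, 0.5, 0.75, 0.95),
                                         na.rm = TRUE),
      location_range = range(fit_fr$b),
      threshold_range = range(thresholds_all)),
    flags = flag_profiles(fit = fit_fr))
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  s1 <- x$step1$scalability
  cat(sprintf("<evaluation_report>\nStep 1: H = %.3f (%s), 90%% CI [%.2f, %.2f], alpha = %.2f, n = %d\n",
              s1$H_total, s1$classification, x$step1$bootstrap$lower,
              x$step1$bootstrap$upper, x$step1$alpha, s1$n_used))
  g2 <- x$gates$step2
  cat(sprintf("Gate to step 2: %s (%s)\n", g2$outcome, g2$rule))
  if (!is.null(x$step2)) {
    cat(sprintf("Step 2: LR = %.2f on %d df, p = %.3g; slope ratio %.2f; equal discrimination %s\n",
                x$step2$lr$statistic, x$step2$lr$df, x$step2$lr$p,
                x$step2$slope_ratio,
                if (x$step2$rsm_suitable) "retained" else "rejected"))
  }
  if (!is.null(x$step3)) {
    ri <- x$step3$relative_information
    top <- ri[order(-ri$share), ][1:min(3, nrow(ri)), ]
    cat("Step 3: GRM locations in [",
        paste(sprintf("%.2f", x$step3$coverage$location_range), collapse = ", "),
        "]; top information shares: ",
        paste(sprintf("%s %.0f%%", top$item, top$share), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
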