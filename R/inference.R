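#' Exposure-corrected chi-square goodness-of-fit test
#'
#' Tests whether observed counts (e.g. marking events per month, or per diel
#' period) depart from the proportions implied by an exposure vector (e.g.
#' camera-trap days per month, or summed period durations), so that unequal
#' bin sizes do not masquerade as activity pattern. Expected counts are
#' `sum(observed) * exposure / sum(exposure)`; the statistic is the classical
#' `sum((O - E)^2 / E)` on `bins - 1` degrees of freedom. Optionally attaches
#' exact binomial post hoc tests per bin with Bonferroni correction.
#'
#' @param observed Non-negative integer counts per bin (named or not).
#' @param exposure Positive exposure weights per bin, same length.
#' @param posthoc Attach [binomial_posthoc()] results? Default TRUE.
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of bins.
#' @return A `gof_result`: list with `chi2`, `df`, `p`, `observed`,
#'   `expected`, and (optionally) a `posthoc` tibble.
#' @export
#' @examples
#' chisq_gof_exposure(c(15, 5), c(1, 1))
chisq_gof_exposure <- function(observed, exposure, posthoc = TRUE, m = length(observed)) {
  stopifnot(length(observed) == length(exposure))
  if (any(exposure <= 0)) stop("all exposures must be positive", call. = FALSE)
  if (sum(observed) <= 0) stop("no observations to test", call. = FALSE)
  expected <- sum(observed) * exposure / sum(exposure)
  if (any(expected < 1)) {
    warning("expected count below 1 in ", sum(expected < 1),
      " bin(s); chi-square approximation may be poor",
      call. = FALSE
    )
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  res <- structure(
    list(
      chi2 = chi2, df = df,
      p = stats::pchisq(chi2, df, lower.tail = FALSE),
      observed = observed, expected = expected, posthoc = NULL
    ),
    class = "gof_result"
  )
  if (posthoc) res$posthoc <- binomial_posthoc(observed, exposure, m = m)
  res
}

#' Exact binomial post hoc tests with Bonferroni correction
#'
#' For each bin, an exact two-sided binomial test of the bin's count among
#' `N = sum(observed)` trials at the exposure-implied null proportion
#' `p0 = exposure / sum(exposure)`. Two-sidedness is obtained by doubling the
#' smaller tail, capped at 1 (monotone in the departure from `p0`); the
#' Bonferroni-adjusted value is `min(1, m * raw)`.
#'
#' @inheritParams chisq_gof_exposure
#' @param m Number of tests assumed for the correction (default: bins).
#' @return Tibble `bin`, `observed`, `expected`, `p0`, `direction`
#'   (`"above"`/`"below"`), `p_raw`, `p_adj`.
#' @export
binomial_posthoc <- function(observed, exposure, m = length(observed)) {
  stopifnot(length(observed) == length(exposure), m >= 1)
  if (any(exposure <= 0)) stop("all exposures must be positive", call. = FALSE)
  n <- sum(observed)
  p0 <- exposure / sum(exposure)
  raw <- vapply(seq_along(observed), function(i) {
    k <- observed[i]
    lower <- stats::pbinom(k, n, p0[i])
    upper <- stats::pbinom(k - 1, n, p0[i], lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }, numeric(1))
  bins <- names(observed)
  if (is.null(bins)) bins <- as.character(seq_along(observed))
  tibble::tibble(
    bin = bins,
    observed = unname(as.numeric(observed)),
    expected = unname(n * p0),
    p0 = unname(p0),
    direction = unname(ifelse(observed >= n * p0, "above", "below")),
    p_raw = raw,
    p_adj = pmin(1, m * raw)
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Exposure-corrected chi-square GOF: chi2 = %.3f, df = %d, P = %.4g\n",
    x$chi2, x$df, x$p
  ))
  if (!is.null(x$posthoc)) {
    cat("Binomial post hocs (Bonferroni-adjusted):\n")
    print(x$posthoc)
  }
  invisible(x)
}

aicc_from_loglik <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Binomial GLM of debarking probability
#'
#' Fits a logistic regression of a binary response (visual marking performed
#' yes/no) on temporal covariates, typically sun-relative time, day-of-year
#' and their interaction. Fitting uses iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 50 iterations); covariates enter in
#' raw units (days; sun-time on its natural [-1, 1] scale). Reports Wald
#' standard errors and 95% confidence intervals (estimate +/- 1.96 SE) and
#' the small-sample AICc.
#'
#' @param data Data frame with the response and covariates (e.g. the output
#'   of [annotate_events()]).
#' @param formula Model formula; default `debark ~ sun_time * julian_date`.
#' @return A `logistic_fit`: list with `terms` tibble (`term`, `estimate`,
#'   `se`, `z`, `p`, `ci_lower`, `ci_upper`), `loglik`, `aicc`, `k`, `n`,
#'   `formula`, `response`, and the underlying `glm` object as `fit`.
#' @export
fit_debarking_model <- function(data, formula = debark ~ sun_time * julian_date) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("response must contain both classes", call. = FALSE)
  }
  k <- ncol(stats::model.matrix(formula, data = data))
  n <- nrow(mf)
  if (n <= k + 2) stop("too few observations for ", k, " parameters", call. = FALSE)

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop("IRLS did not converge within ", fit$iter, " iterations", call. = FALSE)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  runaway <- se > 100 & abs(est) > 10
  if (any(runaway) || (separation && any(se > 50))) {
    bad <- if (any(runaway)) names(est)[runaway] else names(est)[se > 50]
    stop("complete separation detected for term(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  z <- est / se
  ll <- as.numeric(stats::logLik(fit))
  terms_tbl <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    ci_lower = unname(est - 1.96 * se),
    ci_upper = unname(est + 1.96 * se)
  )
  structure(
    list(
      terms = terms_tbl, loglik = ll,
      aicc = aicc_from_loglik(ll, k, n),
      k = k, n = n, formula = formula,
      response = as.integer(y), fit = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binomial GLM:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, logLik = %.3f, AICc = %.3f\n", x$n, x$loglik, x$aicc))
  print(x$terms)
  invisible(x)
}

#' Compare candidate logistic models by AICc
#'
#' @param fits Named list of `logistic_fit` objects sharing the same response
#'   vector.
#' @return Tibble `model`, `k`, `loglik`, `aicc`, `delta_aicc`, `competing`
#'   (TRUE when `delta_aicc < 2`), sorted by AICc.
#' @export
compare_models_aicc <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  resp <- lapply(fits, `[[`, "response")
  if (length(fits) > 1 && !all(vapply(resp[-1], identical, logical(1), resp[[1]]))) {
    stop("models do not share the same response vector", call. = FALSE)
  }
  tbl <- tibble::tibble(
    model = names(fits),
    k = unname(vapply(fits, `[[`, numeric(1), "k")),
    loglik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    aicc = unname(vapply(fits, `[[`, numeric(1), "aicc"))
  )
  tbl$delta_aicc <- tbl$aicc - min(tbl$aicc)
  tbl$competing <- tbl$delta_aicc < 2
  tbl[order(tbl$aicc), ]
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical fixed-effects one-way analysis of variance on duration data,
#' followed by Tukey honest-significant-difference pairwise comparisons using
#' the studentized-range distribution. The per-pair t statistic is the mean
#' difference over its pooled standard error.
#'
#' @param values Numeric observations (e.g. seconds spent per behavior).
#' @param groups Group label per observation; at least two groups with at
#'   least two observations each.
#' @return An `anova_tukey`: list with `F`, `df1`, `df2`, `p` and a
#'   `pairwise` tibble (`group1`, `group2`, `difference`, `t`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
      paste(names(sizes)[sizes < 2], collapse = ", "),
      call. = FALSE
    )
  }
  d <- data.frame(values = values, groups = groups)
  fit <- stats::aov(values ~ groups, data = d)
  sm <- summary(fit)[[1]]
  msw <- sm["Residuals", "Mean Sq"]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  g1 <- vapply(pairs, `[`, character(1), 1)
  g2 <- vapply(pairs, `[`, character(1), 2)
  se_pair <- sqrt(msw * (1 / as.numeric(sizes[g1]) + 1 / as.numeric(sizes[g2])))
  structure(
    list(
      F = sm["groups", "F value"],
      df1 = sm["groups", "Df"],
      df2 = sm["Residuals", "Df"],
      p = sm["groups", "Pr(>F)"],
      pairwise = tibble::tibble(
        group1 = g1, group2 = g2,
        difference = unname(tk[, "diff"]),
        t = unname(tk[, "diff"] / se_pair),
        p_adj = unname(tk[, "p adj"])
      )
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3f, P = %.4g\n",
    x$df1, x$df2, x$F, x$p
  ))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' Serialize an inferential result to JSON
#'
#' Stable key names so downstream reports can rely on the structure.
#'
#' @param x A `gof_result`, `logistic_fit` or `anova_tukey`.
#' @param path Optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
result_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "gof_result")) {
    list(
      chi2 = x$chi2, df = x$df, p = x$p,
      observed = as.numeric(x$observed), expected = as.numeric(x$expected),
      posthoc = x$posthoc
    )
  } else if (inherits(x, "logistic_fit")) {
    list(
      formula = deparse(x$formula), n = x$n, loglik = x$loglik,
      aicc = x$aicc, terms = x$terms
    )
  } else if (inherits(x, "anova_tukey")) {
    list(F = x$F, df1 = x$df1, df2 = x$df2, p = x$p, pairwise = x$pairwise)
  } else {
    stop("unsupported result class", call. = FALSE)
  }
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
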