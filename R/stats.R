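#' @include AllClasses.R
NULL

#' Coefficient of variation
#'
#' Repeatability measure `CV = SD * 100 / mean` with the sample (n-1)
#' standard deviation.
#'
#' @param values numeric vector, length >= 2, non-zero mean
#' @return CV in percent
#' @examples
#' coefficientOfVariation(c(5, 5, 5))  # 0
#' @export
coefficientOfVariation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Mann-Whitney U test
#'
#' Default group test of the cardio assay (heartbeat distributions are
#' skewed, so rank tests are preferred over t tests). Exact p values are
#' used for small samples (`min(n) <= 8`, no ties), the normal approximation
#' with tie correction otherwise.
#'
#' @param a,b numeric samples (each non-empty)
#' @param twoSided two-sided test (default) or greater-tail
#' @return a [GroupComparison-class]; the statistic is the U of sample `a`
#' @export
mannWhitney <- function(a, b, twoSided = TRUE) {
  if (!length(a) || !length(b)) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = if (twoSided) "two.sided" else "greater",
                       exact = exact, correct = TRUE))
  new("GroupComparison", statistic = unname(wt$statistic),
      pValue = wt$p.value,
      testName = if (exact) "Mann-Whitney (exact)"
                 else "Mann-Whitney (normal approx.)",
      estimate = mean(a) - mean(b))
}

#' Welch two-sample t test
#'
#' Two-tailed t test assuming unequal variances (Satterthwaite degrees of
#' freedom), the two-group test of the angiogenesis assay. The degenerate
#' case of two zero-variance groups is handled explicitly: equal means give
#' p = 1, different means p = 0.
#'
#' @param a,b numeric samples, n >= 2 each
#' @return a [GroupComparison-class] with attribute `df`
#' @export
welchT <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    out <- new("GroupComparison", statistic = if (same) 0 else Inf,
               pValue = if (same) 1 else 0, testName = "Welch t",
               estimate = mean(a) - mean(b))
    attr(out, "df") <- NA_real_
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out <- new("GroupComparison", statistic = unname(tt$statistic),
             pValue = tt$p.value, testName = "Welch t",
             estimate = mean(a) - mean(b))
  attr(out, "df") <- unname(tt$parameter)
  out
}

#' One-way ANOVA with Dunnett's post test against the control
#'
#' Omnibus one-way ANOVA followed by Dunnett-adjusted two-sided comparisons
#' of every treated group against the vehicle control. The adjusted p values
#' are computed by Monte-Carlo evaluation of the null distribution of the
#' maximum absolute Dunnett statistic (group means and the pooled variance
#' resampled under the null; fixed internal seed, `nMC` draws), which
#' handles arbitrary group sizes reproducibly.
#'
#' @param groups named list of numeric vectors (each n >= 2)
#' @param controlIndex index of the control group in `groups`
#' @param alpha significance level (stored for reference)
#' @param nMC Monte-Carlo draws (>= 1e5)
#' @return list with `omnibusF`, `omnibusP`, `df`, and `comparisons` - one
#'   [GroupComparison-class] per non-control group (named)
#' @export
anovaDunnett <- function(groups, controlIndex = 1, alpha = 0.05, nMC = 1e5) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (controlIndex < 1 || controlIndex > length(groups))
    stop("invalid control index")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  nMC <- max(nMC, 1e5)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::lm(y ~ g)
  ## a perfect fit (noiseless phantom groups) is legitimate here; the
  ## zero-residual case is handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  ns <- lengths(groups)
  k <- length(groups)
  df <- length(y) - k
  s2 <- sum(stats::resid(fit)^2) / df
  n0 <- ns[controlIndex]
  m0 <- mean(groups[[controlIndex]])
  idx <- setdiff(seq_len(k), controlIndex)
  if (s2 == 0) {
    ## all groups internally constant: differences are either exact or null
    comparisons <- lapply(idx, function(j) {
      diffj <- mean(groups[[j]]) - m0
      p <- if (diffj == 0) 1 else 0
      new("GroupComparison", statistic = if (diffj == 0) 0 else Inf,
          pValue = p, adjustedP = p, testName = "Dunnett (Monte-Carlo)",
          estimate = diffj)
    })
    names(comparisons) <- names(groups)[idx]
    return(list(omnibusF = an$`F value`[1], omnibusP = an$`Pr(>F)`[1],
                df = c(an$Df[1], an$Df[2]), alpha = alpha,
                comparisons = comparisons))
  }
  tObs <- vapply(idx, function(j)
    (mean(groups[[j]]) - m0) / sqrt(s2 * (1 / ns[j] + 1 / n0)), numeric(1))
  ## Null distribution of max |t| over the k-1 correlated Dunnett statistics
  maxT <- withSeed(487 + length(y), {
    zm <- matrix(stats::rnorm(nMC * k), nMC, k)
    zm <- sweep(zm, 2, sqrt(ns), "/")  # group-mean draws, variance 1/n_j
    sdraw <- sqrt(stats::rchisq(nMC, df) / df)
    mx <- rep(0, nMC)
    for (j in seq_along(idx)) {
      tj <- abs(zm[, idx[j]] - zm[, controlIndex]) /
        (sdraw * sqrt(1 / ns[idx[j]] + 1 / n0))
      mx <- pmax(mx, tj)
    }
    mx
  })
  comparisons <- lapply(seq_along(idx), function(j) {
    praw <- 2 * stats::pt(-abs(tObs[j]), df)
    padj <- max(mean(maxT >= abs(tObs[j])), praw)
    new("GroupComparison", statistic = tObs[j], pValue = praw,
        adjustedP = min(1, padj), testName = "Dunnett (Monte-Carlo)",
        estimate = mean(groups[[idx[j]]]) - m0)
  })
  names(comparisons) <- names(groups)[idx]
  list(omnibusF = an$`F value`[1], omnibusP = an$`Pr(>F)`[1],
       df = c(an$Df[1], an$Df[2]), alpha = alpha,
       comparisons = comparisons)
}

#' Four-parameter logistic (variable-slope sigmoidal) dose-response fit
#'
#' Nonlinear least squares on log-dose:
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)`.
#' Starting values come from the response range and the dose whose response
#' is nearest the midpoint. Non-convergence is flagged, not thrown.
#'
#' @param dose dose vector (> 0), at least 5 distinct levels
#' @param response response vector, same length
#' @return list with `ic50`, `hill`, `top`, `bottom`, standard errors `se`,
#'   `converged`, and the `nls` fit object (NULL when not converged)
#' @examples
#' d <- makeDoseResponse(ic50 = 2.6, hill = 1.5)
#' fit4PL(d$dose, d$response)$ic50
#' @export
fit4PL <- function(dose, response) {
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 5)
    stop("need at least 5 dose levels")
  ld <- log(dose)
  mid <- (max(response) + min(response)) / 2
  start <- list(top = max(response), bottom = min(response),
                lic50 = ld[which.min(abs(response - mid))], hill = 1)
  failed <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                 bottom = NA_real_,
                 se = c(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                        bottom = NA_real_),
                 converged = FALSE, fit = NULL)
  fit <- tryCatch(
    stats::nls(response ~ bottom + (top - bottom) /
                 (1 + exp(hill * (ld - lic50))),
               start = start, algorithm = "port",  # robust to zero residuals
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  vc <- tryCatch(diag(stats::vcov(fit)), error = function(e) rep(NA_real_, 4))
  seLic50 <- sqrt(vc[match("lic50", names(cf))])
  list(ic50 = exp(unname(cf["lic50"])), hill = unname(cf["hill"]),
       top = unname(cf["top"]), bottom = unname(cf["bottom"]),
       se = c(ic50 = exp(unname(cf["lic50"])) * seLic50,  # delta method
              hill = sqrt(vc[match("hill", names(cf))]),
              top = sqrt(vc[match("top", names(cf))]),
              bottom = sqrt(vc[match("bottom", names(cf))])),
       converged = TRUE, fit = fit)
}

#' Empirical ROC threshold (Youden)
#'
#' Sweeps every cut point of the pooled samples and returns the
#' Youden-optimal threshold for separating bradycardic (treated, low rates)
#' from control (high rates) distributions: a value below the threshold is
#' called positive. Used to derive the bradycardia cutoff in beats per 15 s.
#'
#' @param controlRates numeric, control (negative) sample
#' @param treatedRates numeric, treated (positive) sample
#' @return list with `threshold`, `sensitivity` and `specificity` (percent),
#'   and `youdenJ`
#' @export
rocThreshold <- function(controlRates, treatedRates) {
  if (!length(controlRates) || !length(treatedRates))
    stop("both samples must be non-empty")
  pool <- sort(unique(c(controlRates, treatedRates)))
  cand <- c(pool[1] - 1, (pool[-1] + pool[-length(pool)]) / 2,
            pool[length(pool)] + 1)
  sens <- vapply(cand, function(th) mean(treatedRates < th), numeric(1))
  spec <- vapply(cand, function(th) mean(controlRates >= th), numeric(1))
  j <- sens + spec - 1
  i <- which.max(j)
  list(threshold = cand[i], sensitivity = 100 * sens[i],
       specificity = 100 * spec[i], youdenJ = j[i])
}
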