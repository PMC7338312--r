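# Descriptive and comparative statistics: 2x2 tables, odds ratios,
# McNemar, confusion metrics, rank statistics and propensity balance.

.as_table <- function(t) {
    if (is.matrix(t)) {
        stopifnot(all(dim(t) == 2L))
        return(t)
    }
    stopifnot(length(t) == 4L)
    matrix(as.numeric(t), 2L, byrow = TRUE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by probability-mass summation
#' (tables whose probability does not exceed the observed table's), the
#' convention used by common clinical software. A zero margin gives p = 1.
#'
#' @param t 2x2 matrix or length-4 vector (a, b, c, d) filled by row.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(t) {
    t <- .as_table(t)
    stopifnot(all(t >= 0), sum(t) > 0)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) return(1)
    stats::fisher.test(t)$p.value
}

#' Odds ratio with the Woolf (logit) confidence interval
#'
#' OR = ad/bc with 95% CI exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))
#' and the Fisher-exact p-value. With a zero cell, the Haldane correction
#' (adding 0.5 to every cell) is applied when \code{haldane = TRUE},
#' otherwise an error is raised.
#'
#' @param t 2x2 table as in \code{\link{fisherExact2x2}}.
#' @param haldane apply the 0.5 correction for zero cells (default TRUE).
#' @return list: \code{or}, \code{ci_low}, \code{ci_high}, \code{p_value}.
#' @export
oddsRatioWoolf <- function(t, haldane = TRUE) {
    t <- .as_table(t)
    p <- fisherExact2x2(t)
    if (any(t == 0)) {
        if (!haldane) stop("zero cell; enable the Haldane correction")
        t <- t + 0.5
    }
    or <- t[1, 1] * t[2, 2] / (t[1, 2] * t[2, 1])
    se <- sqrt(sum(1 / t))
    list(or = or, ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se), p_value = p)
}

#' Sensitivity, specificity and accuracy of a binary prediction
#'
#' @param predicted logical/0-1 predicted-positive flags.
#' @param actual logical/0-1 event flags.
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (each NA when undefined, e.g. no positives).
#' @export
confusionMetrics <- function(predicted, actual) {
    predicted <- as.logical(predicted); actual <- as.logical(actual)
    stopifnot(length(predicted) == length(actual))
    tp <- sum(predicted & actual); fn <- sum(!predicted & actual)
    fp <- sum(predicted & !actual); tn <- sum(!predicted & !actual)
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         accuracy = (tp + tn) / length(actual))
}

#' Exact McNemar test for paired binary predictions
#'
#' Exact binomial test on the discordant pairs (two-sided, capped at 1);
#' zero discordant pairs give p = 1.
#'
#' @param pred_a,pred_b paired binary predictions, or counts when
#'   \code{counts = TRUE} (then \code{pred_a}, \code{pred_b} are the two
#'   discordant counts).
#' @param actual event flags (used to orient correctness; optional - when
#'   absent the two predictions are compared directly).
#' @param counts interpret the first two arguments as discordant counts.
#' @return two-sided exact p-value.
#' @export
mcnemarExact <- function(pred_a, pred_b, actual = NULL, counts = FALSE) {
    if (counts) {
        n01 <- pred_a; n10 <- pred_b
    } else {
        pred_a <- as.logical(pred_a); pred_b <- as.logical(pred_b)
        if (!is.null(actual)) {
            actual <- as.logical(actual)
            ok_a <- pred_a == actual; ok_b <- pred_b == actual
            n01 <- sum(ok_a & !ok_b); n10 <- sum(!ok_a & ok_b)
        } else {
            n01 <- sum(pred_a & !pred_b); n10 <- sum(!pred_a & pred_b)
        }
    }
    nd <- n01 + n10
    if (nd == 0) return(1)
    min(1, stats::binom.test(n01, nd, 0.5)$p.value)
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors (mid-ranks for ties).
#' @return list with \code{rho} and \code{p}; constant input gives
#'   \code{rho = NA} with a message.
#' @export
spearmanRho <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
        message("constant vector: Spearman's rho undefined")
        return(list(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with mid-rank ties; the returned U relates to the ROC
#' area by U = AUC * n1 * n0.
#'
#' @param x,y samples from the two groups.
#' @return list with \code{U} and \code{p}.
#' @export
mannWhitney <- function(x, y) {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(U = unname(wt$statistic), p = wt$p.value)
}

#' Chi-square test on a contingency table
#'
#' @param t matrix of counts (2x2 vectors accepted as in
#'   \code{\link{fisherExact2x2}}).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with \code{chisq} and \code{p}.
#' @export
chiSquare <- function(t, correct = FALSE) {
    if (!is.matrix(t)) t <- .as_table(t)
    ct <- suppressWarnings(stats::chisq.test(t, correct = correct))
    list(chisq = unname(ct$statistic), p = ct$p.value)
}

#' Propensity-score balance between training and validation groups
#'
#' Logistic regression of group membership on the confounders; the score
#' distributions of the two groups are compared with a Mann-Whitney test.
#' Complete separation is detected (fitted probabilities collapsing to
#' 0/1) and flagged.
#'
#' @param data data.frame containing group label and confounders.
#' @param group_col name of the binary group column.
#' @param confounders character vector of confounder column names; when
#'   empty, all scores equal the group prevalence.
#' @return list: \code{scores}, \code{p} (Mann-Whitney), \code{separation}
#'   flag, \code{model}.
#' @export
propensityBalance <- function(data, group_col, confounders) {
    g <- as.integer(as.logical(data[[group_col]]))
    if (length(confounders) == 0L) {
        sc <- rep(mean(g), length(g))
        return(list(scores = sc, p = 1, separation = FALSE, model = NULL))
    }
    fml <- stats::as.formula(paste("g ~",
        paste(confounders, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, data = cbind(data, g = g),
                                       family = stats::binomial()))
    sc <- stats::fitted(fit)
    sep <- any(sc > 1 - 1e-8) || any(sc < 1e-8) ||
        any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
    if (sep) message("separation detected in the propensity model")
    p <- if (length(unique(sc)) > 1L)
        suppressWarnings(stats::wilcox.test(sc[g == 1], sc[g == 0],
                                            exact = FALSE))$p.value
    else 1
    list(scores = sc, p = p, separation = sep, model = fit)
}
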