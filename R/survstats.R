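# ROC/Youden screening, Kaplan-Meier/log-rank, bootstrap Cox with
# Schoenfeld diagnostics, and C-index comparison. The "binary outcome" for
# ROC-based screening and C-index is the event status over observed
# follow-up (dead/alive, relapsed/not); a censoring-aware Harrell C on the
# time-to-event is available as an option but is not the default.

#' ROC screening of one feature against a binary outcome
#'
#' AUC (orientation chosen so AUC >= 0.5, recorded in \code{direction}),
#' a test of AUC = 0.5, and the Youden-optimal cutoff J = max(Se + Sp - 1).
#' Through the rank identity U = AUC n1 n0 the test of AUC = 0.5 uses the
#' exact (or continuity-corrected) Mann-Whitney null distribution, which
#' holds its size at screening-cohort sample sizes where the asymptotic
#' DeLong z-test is anti-conservative. Cutoff candidates are midpoints
#' between consecutive sorted unique values; Youden ties are broken toward
#' the candidate with maximal sensitivity, then the smaller threshold.
#'
#' @param values numeric feature values.
#' @param outcome binary outcome (0/1 or logical).
#' @param feature name recorded in the result.
#' @return one-row data.frame: \code{feature, c_index, p_value,
#'   youden_cutoff, sensitivity, specificity, direction}.
#' @export
rocScreen <- function(values, outcome, feature = "feature") {
    outcome <- as.integer(outcome)
    if (length(unique(outcome)) < 2L)
        stop("both outcome classes must be present")
    ok <- is.finite(values)
    values <- values[ok]; outcome <- outcome[ok]
    r <- pROC::roc(outcome, values, direction = "<", quiet = TRUE,
                   levels = c(0, 1))
    if (as.numeric(pROC::auc(r)) < 0.5)
        r <- pROC::roc(outcome, values, direction = ">", quiet = TRUE,
                       levels = c(0, 1))
    auc <- as.numeric(pROC::auc(r))
    p <- suppressWarnings(stats::wilcox.test(
        values[outcome == 1], values[outcome == 0]))$p.value
    # direction: ">" means larger values indicate the event
    higher_is_event <- r$direction == "<"
    su <- sort(unique(values))
    cands <- if (length(su) > 1L) (su[-1] + su[-length(su)]) / 2 else su
    n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
    se <- sp <- numeric(length(cands))
    for (i in seq_along(cands)) {
        pred <- if (higher_is_event) values > cands[i] else values < cands[i]
        se[i] <- sum(pred & outcome == 1) / n1
        sp[i] <- sum(!pred & outcome == 0) / n0
    }
    j <- se + sp - 1
    best <- which(j == max(j))
    best <- best[se[best] == max(se[best])]
    best <- best[which.min(cands[best])]
    data.frame(feature = feature, c_index = auc, p_value = p,
               youden_cutoff = cands[best], sensitivity = se[best],
               specificity = sp[best],
               direction = if (higher_is_event) ">" else "<",
               stringsAsFactors = FALSE)
}

#' Bonferroni gate for feature screening
#'
#' Keeps screening rows with p < alpha / m. With the default family-wise
#' alpha of 0.10 over the ten PET parameters, a nominal p below 0.01 is
#' required.
#'
#' @param selections data.frame with a \code{p_value} column (e.g. rows
#'   from \code{\link{rocScreen}}).
#' @param alpha family-wise level (default 0.10).
#' @param m number of comparisons (default 10).
#' @return the filtered data.frame (possibly zero rows).
#' @export
bonferroniGate <- function(selections, alpha = 0.10, m = 10L) {
    stopifnot(m >= 1L)
    selections[selections$p_value < alpha / m, , drop = FALSE]
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit estimates per group; with two or more groups, the
#' standard log-rank chi-square and p-value.
#'
#' @param times survival times (months).
#' @param events 0/1 event indicators.
#' @param group group labels.
#' @return list with \code{fit} (a \code{survfit}), and for >= 2 groups
#'   \code{chisq}, \code{p}.
#' @export
kmLogrank <- function(times, events, group) {
    group <- as.factor(group)
    df <- data.frame(times = times, events = events, group = group)
    fit <- survival::survfit(survival::Surv(times, events) ~ group,
                             data = df)
    if (nlevels(droplevels(group)) < 2L)
        return(list(fit = fit, chisq = NA_real_, p = NA_real_))
    sd <- survival::survdiff(survival::Surv(times, events) ~ group,
                             data = df)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
    list(fit = fit, chisq = unname(sd$chisq), p = p)
}

#' Multivariable Cox regression with bootstrap confidence intervals
#'
#' Partial-likelihood point estimates with percentile bootstrap 95%
#' intervals and p-values from the resampled coefficient distribution
#' (two-sided percentile inversion), plus a Schoenfeld-residual
#' proportional-hazards test per covariate. A warning (not an error) is
#' issued when events are fewer than covariates, and covariates whose
#' resampled fits fail to converge or show monotone likelihood are flagged.
#'
#' @param data data.frame containing the model variables.
#' @param time_col,event_col names of the survival time/event columns.
#' @param covariates character vector of covariate column names.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list of class \code{CoxFit}: \code{table} (HR, CI, p per
#'   covariate), \code{schoenfeld} (p per covariate), \code{n_boot},
#'   \code{n_events}, \code{flags}.
#' @export
coxBootstrap <- function(data, time_col, event_col, covariates,
                         n_boot = 1000L, seed = 1L) {
    stopifnot(all(c(time_col, event_col, covariates) %in% names(data)))
    n_events <- sum(data[[event_col]])
    if (n_events < length(covariates))
        warning(sprintf(
            "only %d events for %d covariates; estimates may be unstable",
            n_events, length(covariates)))
    fml <- stats::as.formula(paste0(
        "survival::Surv(", time_col, ", ", event_col, ") ~ ",
        paste(covariates, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = "breslow")
    beta <- stats::coef(fit)
    flags <- character(0)
    if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
        flags <- c(flags, paste("monotone likelihood suspected for:",
            paste(names(beta)[!is.finite(beta) | abs(beta) > 15],
                  collapse = ", ")))
    }
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    sch_p <- if (!is.null(zph)) {
        tb <- zph$table
        stats::setNames(tb[seq_along(beta), "p"], names(beta))
    } else stats::setNames(rep(NA_real_, length(beta)), names(beta))
    bmat <- with_seed(seed, {
        out <- matrix(NA_real_, n_boot, length(beta))
        for (b in seq_len(n_boot)) {
            idx <- sample.int(nrow(data), replace = TRUE)
            bf <- tryCatch(suppressWarnings(
                survival::coxph(fml, data = data[idx, , drop = FALSE],
                                ties = "breslow")),
                error = function(e) NULL)
            if (!is.null(bf)) {
                cb <- stats::coef(bf)
                cb[!is.finite(cb) | abs(cb) > 15] <- NA_real_
                out[b, ] <- cb
            }
        }
        out
    })
    ci <- apply(bmat, 2L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    # two-sided percentile inversion: smallest alpha whose CI excludes 0
    pboot <- vapply(seq_along(beta), function(j) {
        x <- bmat[, j]; x <- x[is.finite(x)]
        if (!length(x)) return(NA_real_)
        frac <- mean(x > 0)
        min(1, 2 * min(frac, 1 - frac))
    }, numeric(1))
    tab <- data.frame(
        covariate = names(beta),
        hr = exp(unname(beta)),
        ci_low = exp(ci[1, ]),
        ci_high = exp(ci[2, ]),
        p_value = pboot,
        schoenfeld_p = unname(sch_p),
        stringsAsFactors = FALSE)
    structure(list(table = tab, n_boot = n_boot, n_events = n_events,
                   flags = flags, seed = as.integer(seed), fit = fit),
              class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
    cat(sprintf("Bootstrap Cox model (%d resamples, %d events)\n",
                x$n_boot, x$n_events))
    tb <- x$table
    for (i in seq_len(nrow(tb)))
        cat(sprintf("  %-28s HR %6.2f (%.2f-%.2f)  P = %.3f  [PH p = %.2f]\n",
            tb$covariate[i], tb$hr[i], tb$ci_low[i], tb$ci_high[i],
            tb$p_value[i], tb$schoenfeld_p[i]))
    if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
    invisible(x)
}

#' Concordance index of a risk score
#'
#' For the default binary endpoint (event status over follow-up) the
#' C-index is the ROC AUC of the score; a constant score returns 0.5 by
#' the tie convention. With \code{method = "harrell"} the censoring-aware
#' Harrell concordance on the time-to-event is computed instead.
#'
#' @param outcome binary event status (default method) or survival time
#'   when \code{method = "harrell"}.
#' @param score numeric risk score (larger = higher risk).
#' @param method "binary" (default) or "harrell".
#' @param events event indicators, required for \code{method = "harrell"}.
#' @return concordance index in [0, 1].
#' @export
cIndex <- function(outcome, score, method = c("binary", "harrell"),
                   events = NULL) {
    method <- match.arg(method)
    if (method == "harrell") {
        if (is.null(events)) stop("'events' required for Harrell's C")
        cf <- survival::concordance(
            survival::Surv(outcome, events) ~ score, reverse = TRUE)
        return(unname(cf$concordance))
    }
    if (length(unique(score)) == 1L) return(0.5)
    r <- pROC::roc(as.integer(outcome), score, direction = "<",
                   quiet = TRUE, levels = c(0, 1))
    as.numeric(pROC::auc(r))
}

#' Compare two paired C-indices
#'
#' Paired nonparametric AUC-difference test (DeLong covariance) for two
#' risk scores evaluated on the same subjects against the same binary
#' endpoint.
#'
#' @param score_a,score_b risk scores on the same subjects.
#' @param outcome binary event status.
#' @return list with \code{c_a}, \code{c_b}, \code{delta}, \code{p}.
#' @export
compareCIndex <- function(score_a, score_b, outcome) {
    outcome <- as.integer(outcome)
    if (identical(as.numeric(score_a), as.numeric(score_b)))
        return(list(c_a = cIndex(outcome, score_a),
                    c_b = cIndex(outcome, score_b), delta = 0, p = 1))
    ra <- pROC::roc(outcome, as.numeric(score_a), direction = "<",
                    quiet = TRUE, levels = c(0, 1))
    rb <- pROC::roc(outcome, as.numeric(score_b), direction = "<",
                    quiet = TRUE, levels = c(0, 1))
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    list(c_a = as.numeric(pROC::auc(ra)), c_b = as.numeric(pROC::auc(rb)),
         delta = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
         p = tst$p.value)
}
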