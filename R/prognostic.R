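# Three-level PET risk pattern and the recursive-partitioning prognostic
# index built on top of it.

#' The shipped reference PET risk pattern
#'
#' The frozen two-cutoff rule (SUVmax > 6.67, discretized intensity
#' entropy > 2.50 nats) usable without refitting.
#'
#' @return a \linkS4class{PETRiskPattern}.
#' @export
referencePattern <- function() new("PETRiskPattern")

#' Assign the three-level PET subgroup
#'
#' Subgroup 1: primary feature (SUVmax) at or below its cutoff, regardless
#' of the secondary feature. Subgroup 2: primary above its cutoff but
#' secondary (entropy) at or below its cutoff. Subgroup 3: both above
#' their cutoffs (the high-risk PET pattern). Values exactly at a cutoff
#' fall on the lower-risk side.
#'
#' @param features named list / one-row data.frame with the pattern's
#'   feature names, or a numeric SUVmax when \code{entropy} is given.
#' @param pattern a \linkS4class{PETRiskPattern} (default the reference
#'   pattern).
#' @param entropy optional numeric; with a numeric first argument the two
#'   scalars are taken as SUVmax and entropy.
#' @return integer vector of subgroups in \{1, 2, 3\}.
#' @export
assignPETSubgroup <- function(features, pattern = referencePattern(),
                              entropy = NULL) {
    if (is.numeric(features) && !is.null(entropy)) {
        features <- data.frame(suv_max = features,
                               intensity_entropy = entropy)
        names(features) <- c(pattern@primaryFeature,
                             pattern@secondaryFeature)
    }
    prim <- features[[pattern@primaryFeature]]
    sec <- features[[pattern@secondaryFeature]]
    if (is.null(prim)) stop("missing primary feature '",
                            pattern@primaryFeature, "'")
    if (!all(is.finite(prim))) stop("primary feature must be finite")
    out <- rep(NA_integer_, length(prim))
    low <- prim <= pattern@primaryCutoff
    out[low] <- 1L
    need_sec <- !low
    if (any(need_sec)) {
        if (is.null(sec) || any(!is.finite(sec[need_sec])))
            stop("unclassifiable: secondary feature '",
                 pattern@secondaryFeature,
                 "' missing for patients above the primary cutoff")
        out[need_sec & sec <= pattern@secondaryCutoff] <- 2L
        out[need_sec & sec > pattern@secondaryCutoff] <- 3L
    }
    out
}

#' Derive the conditional two-stage PET cutoffs from a training cohort
#'
#' Stage 1 screens all ten PET parameters against the OS endpoint with
#' \code{\link{rocScreen}} and applies the Bonferroni gate (family-wise
#' 0.10 over 10 comparisons, i.e. nominal p < 0.01); the passing feature
#' with the largest C-index becomes the primary feature with its Youden
#' cutoff. Stage 2 re-screens the remaining parameters within the
#' subgroup above the primary cutoff at nominal alpha and takes the best
#' passing feature as the conditional secondary. If stage 1 passes
#' nothing the model degenerates to clinical factors only and \code{NULL}
#' is returned with a message.
#'
#' @param training data.frame with the ten PET feature columns and an
#'   OS event column.
#' @param event_col name of the binary OS event column.
#' @param features candidate feature names (default
#'   \code{\link{petFeatureNames}}).
#' @param alpha,m Bonferroni gate parameters for stage 1.
#' @param alpha_stage2 nominal level for the conditional stage (default
#'   0.05).
#' @return a \linkS4class{PETRiskPattern}, or \code{NULL} when no feature
#'   survives stage 1.
#' @export
deriveConditionalCutoff <- function(training, event_col = "os_event",
                                    features = petFeatureNames(),
                                    alpha = 0.10, m = length(features),
                                    alpha_stage2 = 0.05) {
    stopifnot(event_col %in% names(training))
    scr <- do.call(rbind, lapply(features, function(f)
        rocScreen(training[[f]], training[[event_col]], feature = f)))
    passed <- bonferroniGate(scr, alpha = alpha, m = m)
    if (nrow(passed) == 0L) {
        message("no PET parameter passed the Bonferroni gate; ",
                "model degenerates to clinical factors only")
        return(NULL)
    }
    passed <- passed[order(-passed$c_index, passed$p_value), , drop = FALSE]
    primary <- passed[1, ]
    sub <- training[training[[primary$feature]] > primary$youden_cutoff, ,
                    drop = FALSE]
    rest <- setdiff(features, primary$feature)
    secondary <- NULL
    if (nrow(sub) >= 4L && length(unique(sub[[event_col]])) == 2L) {
        scr2 <- do.call(rbind, lapply(rest, function(f)
            rocScreen(sub[[f]], sub[[event_col]], feature = f)))
        scr2 <- scr2[scr2$p_value < alpha_stage2, , drop = FALSE]
        if (nrow(scr2))
            secondary <- scr2[order(-scr2$c_index, scr2$p_value), ,
                              drop = FALSE][1, ]
    }
    if (is.null(secondary)) {
        message("no conditional secondary feature found; ",
                "pattern reduces to the primary cutoff alone")
        secondary <- data.frame(feature = primary$feature,
                                youden_cutoff = Inf)
    }
    new("PETRiskPattern",
        primaryFeature = primary$feature,
        primaryCutoff = primary$youden_cutoff,
        secondaryFeature = secondary$feature,
        secondaryCutoff = secondary$youden_cutoff,
        screening = scr)
}

# Log-rank chi-square for a binary split; returns NULL if a side is empty
# or too small.
.logrank_split <- function(times, events, flag, min_leaf) {
    if (sum(flag) < min_leaf || sum(!flag) < min_leaf) return(NULL)
    if (length(unique(flag)) < 2L) return(NULL)
    sd <- tryCatch(survival::survdiff(
        survival::Surv(times, events) ~ flag), error = function(e) NULL)
    if (is.null(sd)) return(NULL)
    list(chisq = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, 1L, lower.tail = FALSE))
}

.grow_node <- function(df, time_col, event_col, predictors, min_leaf,
                       alpha, overall_rate, depth, max_depth) {
    node <- list(n = nrow(df), events = sum(df[[event_col]]))
    if (depth >= max_depth || nrow(df) < 2L * min_leaf) {
        node$leaf <- TRUE
        node$class <- if (node$events / node$n > overall_rate) "poor"
                      else "good"
        return(node)
    }
    best <- NULL
    for (v in predictors) {
        flag <- as.logical(df[[v]])
        lr <- .logrank_split(df[[time_col]], df[[event_col]], flag, min_leaf)
        if (is.null(lr)) next
        if (is.null(best) || lr$chisq > best$chisq)
            best <- c(lr, list(variable = v))
    }
    if (is.null(best) || best$p >= alpha) {
        node$leaf <- TRUE
        node$class <- if (node$events / node$n > overall_rate) "poor"
                      else "good"
        return(node)
    }
    node$leaf <- FALSE
    node$variable <- best$variable
    node$chisq <- best$chisq
    node$p <- best$p
    flag <- as.logical(df[[best$variable]])
    node$left <- .grow_node(df[!flag, , drop = FALSE], time_col, event_col,
                            predictors, min_leaf, alpha, overall_rate,
                            depth + 1L, max_depth)
    node$right <- .grow_node(df[flag, , drop = FALSE], time_col, event_col,
                             predictors, min_leaf, alpha, overall_rate,
                             depth + 1L, max_depth)
    node
}

.tree_variables <- function(node) {
    if (node$leaf) return(character(0))
    c(node$variable, .tree_variables(node$left), .tree_variables(node$right))
}

#' Build the recursive-partitioning prognostic index
#'
#' Greedy binary partitioning of a survival endpoint over dichotomous
#' predictors using the log-rank statistic as the split criterion
#' (survival CART). Leaves are labelled \code{poor} when their event
#' proportion exceeds the cohort's overall event proportion, else
#' \code{good}. Fivefold cross-validation (stratified by event status)
#' reports, per predictor, the fraction of folds whose refitted tree uses
#' it - a stability summary guarding against overfitting.
#'
#' @param training data.frame with the predictor columns (logical/0-1),
#'   a time and an event column.
#' @param predictors character vector of dichotomous predictor names,
#'   e.g. \code{c("pet_high_risk", "clinical_flag")}.
#' @param time_col,event_col survival endpoint columns.
#' @param k cross-validation folds (default 5).
#' @param alpha split significance threshold (default 0.05).
#' @param min_leaf minimum patients per leaf (default 3).
#' @param max_depth maximum tree depth (default number of predictors).
#' @param seed integer seed for fold assignment.
#' @param pattern the \linkS4class{PETRiskPattern} recorded as provenance.
#' @return a \linkS4class{PrognosticModel}; single-leaf models (no split
#'   improves the criterion) are flagged with a message.
#' @export
buildRPATree <- function(training, predictors, time_col = "os_time",
                         event_col = "os_event", k = 5L, alpha = 0.05,
                         min_leaf = 3L, max_depth = length(predictors),
                         seed = 1L, pattern = referencePattern()) {
    stopifnot(all(predictors %in% names(training)))
    for (v in predictors)
        if (!all(training[[v]] %in% c(0, 1, TRUE, FALSE)))
            stop("predictor '", v, "' is not dichotomous")
    overall <- sum(training[[event_col]]) / nrow(training)
    tree <- .grow_node(training, time_col, event_col, predictors, min_leaf,
                       alpha, overall, 0L, max_depth)
    if (tree$leaf)
        message("no split improved the log-rank criterion: ",
                "single-leaf (null) model")
    cv <- with_seed(seed, {
        ev <- training[[event_col]] == 1
        folds <- integer(nrow(training))
        folds[ev] <- sample(rep_len(seq_len(k), sum(ev)))
        folds[!ev] <- sample(rep_len(seq_len(k), sum(!ev)))
        hits <- matrix(0, k, length(predictors),
                       dimnames = list(NULL, predictors))
        for (f in seq_len(k)) {
            sub <- training[folds != f, , drop = FALSE]
            tr <- .grow_node(sub, time_col, event_col, predictors, min_leaf,
                             alpha, sum(sub[[event_col]]) / nrow(sub),
                             0L, max_depth)
            hits[f, unique(.tree_variables(tr))] <- 1
        }
        data.frame(variable = predictors, stability = colMeans(hits),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    new("PrognosticModel", tree = tree, predictors = predictors, cv = cv,
        pattern = pattern, seed = as.integer(seed))
}

#' Classify patients with a fitted prognostic model
#'
#' Walks each patient down the partition tree and returns the leaf label.
#' Deterministic; missing predictor columns raise an error naming them.
#'
#' @param model a \linkS4class{PrognosticModel}.
#' @param patients data.frame with the model's predictor columns.
#' @return character vector of \code{"poor"} / \code{"good"}.
#' @export
classifyPatients <- function(model, patients) {
    used <- unique(.tree_variables(model@tree))
    missing <- setdiff(used, names(patients))
    if (length(missing))
        stop("missing predictor field(s): ", paste(missing, collapse = ", "))
    walk <- function(node, row) {
        if (node$leaf) return(node$class)
        if (is.na(row[[node$variable]]))
            stop("missing value for predictor '", node$variable, "'")
        if (as.logical(row[[node$variable]])) walk(node$right, row)
        else walk(node$left, row)
    }
    vapply(seq_len(nrow(patients)),
           function(i) walk(model@tree, patients[i, , drop = FALSE]),
           character(1))
}

#' The poor-prognosis rule implied by a fitted model
#'
#' Evaluates the tree on the four combinations of the two canonical
#' factors (high-risk PET pattern, clinical flag) and reports whether the
#' model classifies exactly \{subgroup 3 or clinical flag\} as poor.
#'
#' @param model a \linkS4class{PrognosticModel} fitted on predictors
#'   \code{pet_high_risk} and \code{clinical_flag}.
#' @return logical: TRUE when the model's poor set equals the two-factor
#'   OR rule.
#' @export
isTwoFactorRule <- function(model) {
    grid <- expand.grid(pet_high_risk = c(FALSE, TRUE),
                        clinical_flag = c(FALSE, TRUE))
    got <- tryCatch(classifyPatients(model, grid) == "poor",
                    error = function(e) rep(NA, 4L))
    want <- grid$pet_high_risk | grid$clinical_flag
    isTRUE(all(got == want))
}
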