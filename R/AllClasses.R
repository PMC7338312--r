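#' @import methods
NULL

#' SUVImage: a 3-D standardized-uptake-value volume
#'
#' Container for a body-weight-normalized SUV grid together with its voxel
#' spacing. SUV is dimensionless; spacing is in millimetres per axis.
#'
#' @slot values 3-D numeric array of SUV, all values >= 0.
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#'
#' @exportClass SUVImage
setClass("SUVImage",
    representation(values = "array", spacing = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@values)) != 3L)
            msg <- c(msg, "'values' must be a 3-D array")
        if (any(!is.finite(object@values)) || any(object@values < 0))
            msg <- c(msg, "SUV values must be finite and non-negative")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "'spacing' must be 3 positive values (mm)")
        if (length(msg)) msg else TRUE
    })

#' LesionMask: voxel membership flags for one lesion
#'
#' A logical array aligned with an \linkS4class{SUVImage}, a label and a
#' lesion kind (primary tumor or lymph node).
#'
#' @slot mask logical 3-D array, same shape as the image it belongs to.
#' @slot label character lesion identifier.
#' @slot kind either "tumor" or "node".
#'
#' @exportClass LesionMask
setClass("LesionMask",
    representation(mask = "array", label = "character", kind = "character"),
    prototype(label = "lesion", kind = "tumor"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
            msg <- c(msg, "'mask' must be a logical 3-D array")
        if (!any(object@mask))
            msg <- c(msg, "mask must contain at least one voxel")
        if (!object@kind %in% c("tumor", "node"))
            msg <- c(msg, "'kind' must be 'tumor' or 'node'")
        if (length(msg)) msg else TRUE
    })

#' DiscretizedVOI: fixed-bin-number gray levels within a lesion
#'
#' Integer gray levels 1..B for every voxel of a volume of interest, the
#' result of fixed-bin-number (FBN) discretization of the SUV range within
#' the mask.
#'
#' @slot levels integer 3-D array; NA outside the VOI, 1..B inside.
#' @slot nBins number of gray levels B.
#' @slot binEdges numeric(B + 1) bin edges in SUV units.
#' @slot spacing numeric(3) voxel spacing in mm (carried for texture code).
#'
#' @exportClass DiscretizedVOI
setClass("DiscretizedVOI",
    representation(levels = "array", nBins = "integer", binEdges = "numeric",
                   spacing = "numeric"),
    validity = function(object) {
        msg <- character()
        lv <- object@levels[!is.na(object@levels)]
        if (length(lv) == 0L)
            msg <- c(msg, "VOI must contain at least one voxel")
        if (length(lv) && (any(lv < 1L) || any(lv > object@nBins)))
            msg <- c(msg, "levels must lie in 1..nBins")
        if (object@nBins < 1L)
            msg <- c(msg, "nBins must be >= 1")
        if (length(msg)) msg else TRUE
    })

#' PETRiskPattern: the two-stage PET risk classification rule
#'
#' A primary feature with its cutoff (screening stage) and a secondary
#' feature with its cutoff applied conditionally above the primary cutoff.
#' Patients split into subgroup 1 (primary feature at or below its cutoff),
#' subgroup 2 (primary high, secondary at or below its cutoff) and
#' subgroup 3 (both high; the high-risk PET pattern). The shipped reference
#' pattern uses SUVmax > 6.67 and discretized intensity entropy > 2.50 nats.
#'
#' @slot primaryFeature name of the stage-1 feature (default "suv_max").
#' @slot primaryCutoff stage-1 cutoff in feature units.
#' @slot secondaryFeature name of the conditional stage-2 feature.
#' @slot secondaryCutoff stage-2 cutoff in feature units.
#' @slot screening data.frame of per-feature screening results (may be empty
#'   for a hand-specified pattern).
#'
#' @exportClass PETRiskPattern
setClass("PETRiskPattern",
    representation(primaryFeature = "character", primaryCutoff = "numeric",
                   secondaryFeature = "character", secondaryCutoff = "numeric",
                   screening = "data.frame"),
    prototype(primaryFeature = "suv_max", primaryCutoff = 6.67,
              secondaryFeature = "intensity_entropy", secondaryCutoff = 2.50,
              screening = data.frame()),
    validity = function(object) {
        msg <- character()
        if (length(object@primaryCutoff) != 1L || !is.finite(object@primaryCutoff))
            msg <- c(msg, "primaryCutoff must be a finite scalar")
        if (length(object@secondaryCutoff) != 1L || is.na(object@secondaryCutoff))
            msg <- c(msg, "secondaryCutoff must be a scalar (Inf allowed ",
                     "for a degenerate single-cutoff pattern)")
        if (length(msg)) msg else TRUE
    })

#' PrognosticModel: a fitted survival partition tree over dichotomous factors
#'
#' The prognostic index produced by recursive partitioning on binary risk
#' factors with a log-rank split criterion, together with its
#' cross-validation stability summary and provenance.
#'
#' @slot tree list; recursive node structure (split variable, children, leaf
#'   label).
#' @slot predictors character vector of candidate predictor names.
#' @slot cv data.frame; per-variable fraction of cross-validation folds in
#'   which the variable was selected for a split.
#' @slot pattern the \linkS4class{PETRiskPattern} used upstream (may be the
#'   reference pattern).
#' @slot seed integer seed recorded for reproducibility.
#'
#' @exportClass PrognosticModel
setClass("PrognosticModel",
    representation(tree = "list", predictors = "character", cv = "data.frame",
                   pattern = "PETRiskPattern", seed = "integer"))
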