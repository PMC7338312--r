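#' Accessors for petromics S4 objects
#'
#' @param object an S4 object from this package.
#' @return \code{suvValues} and \code{maskArray} return 3-D arrays;
#'   \code{voxelSpacing} returns numeric(3) in mm; \code{grayLevels}
#'   returns the integer level array of a \linkS4class{DiscretizedVOI};
#'   \code{nBins} its bin count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("suvValues", function(object) standardGeneric("suvValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("grayLevels", function(object) standardGeneric("grayLevels"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname accessors
setMethod("suvValues", "SUVImage", function(object) object@values)
#' @rdname accessors
setMethod("voxelSpacing", "SUVImage", function(object) object@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "DiscretizedVOI", function(object) object@spacing)
#' @rdname accessors
setMethod("maskArray", "LesionMask", function(object) object@mask)
#' @rdname accessors
setMethod("grayLevels", "DiscretizedVOI", function(object) object@levels)
#' @rdname accessors
setMethod("nBins", "DiscretizedVOI", function(object) object@nBins)

setMethod("show", "SUVImage", function(object) {
    d <- dim(object@values)
    cat(sprintf("SUVImage: %d x %d x %d voxels, spacing %s mm\n",
        d[1], d[2], d[3], paste(format(object@spacing), collapse = " x ")))
    cat(sprintf("  SUV range: %.3g .. %.3g\n",
        min(object@values), max(object@values)))
})

setMethod("show", "LesionMask", function(object) {
    cat(sprintf("LesionMask '%s' (%s): %d voxels\n",
        object@label, object@kind, sum(object@mask)))
})

setMethod("show", "DiscretizedVOI", function(object) {
    lv <- object@levels[!is.na(object@levels)]
    cat(sprintf("DiscretizedVOI: %d voxels, %d gray levels (%d occupied)\n",
        length(lv), object@nBins, length(unique(lv))))
})

setMethod("show", "PETRiskPattern", function(object) {
    cat("PETRiskPattern (three-level risk rule)\n")
    cat(sprintf("  subgroup 1: %s <= %.4g\n",
        object@primaryFeature, object@primaryCutoff))
    cat(sprintf("  subgroup 2: %s > %.4g and %s <= %.4g\n",
        object@primaryFeature, object@primaryCutoff,
        object@secondaryFeature, object@secondaryCutoff))
    cat(sprintf("  subgroup 3: %s > %.4g and %s > %.4g (high risk)\n",
        object@primaryFeature, object@primaryCutoff,
        object@secondaryFeature, object@secondaryCutoff))
})

setMethod("show", "PrognosticModel", function(object) {
    cat("PrognosticModel (log-rank recursive partitioning)\n")
    cat(sprintf("  predictors: %s\n", paste(object@predictors, collapse = ", ")))
    .show_node <- function(node, indent) {
        pad <- strrep(" ", indent)
        if (node$leaf) {
            cat(sprintf("%sleaf: %s (n = %d, events = %d)\n",
                pad, node$class, node$n, node$events))
        } else {
            cat(sprintf("%ssplit on %s\n", pad, node$variable))
            cat(sprintf("%s %s = FALSE:\n", pad, node$variable))
            .show_node(node$left, indent + 4L)
            cat(sprintf("%s %s = TRUE:\n", pad, node$variable))
            .show_node(node$right, indent + 4L)
        }
    }
    .show_node(object@tree, 2L)
    if (nrow(object@cv))
        cat(sprintf("  CV split stability: %s\n",
            paste(sprintf("%s %.0f%%", object@cv$variable,
                          100 * object@cv$stability), collapse = ", ")))
})
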