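# NIfTI / CSV / JSON interfaces.

#' Write an SUVImage (or mask) to NIfTI
#'
#' Writes a .nii or .nii.gz with the voxel spacing in the header (RAS
#' orientation).
#'
#' @param object an \linkS4class{SUVImage} or \linkS4class{LesionMask}.
#' @param path output file path.
#' @param spacing spacing in mm, required when writing a mask.
#' @return the path, invisibly.
#' @export
writeNIfTI <- function(object, path, spacing = NULL) {
    if (is(object, "SUVImage")) {
        arr <- suvValues(object); sp <- voxelSpacing(object)
    } else if (is(object, "LesionMask")) {
        if (is.null(spacing)) stop("spacing required to write a mask")
        arr <- array(as.integer(maskArray(object)), dim(maskArray(object)))
        sp <- spacing
    } else stop("unsupported object")
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read an SUV volume from NIfTI
#'
#' @param path NIfTI file.
#' @return an \linkS4class{SUVImage} with spacing taken from the header.
#' @export
readSUVImage <- function(path) {
    img <- RNifti::readNifti(path)
    SUVImage(array(as.numeric(img), dim(img)[1:3]),
             RNifti::pixdim(img)[1:3])
}

#' Write per-lesion features to CSV
#'
#' One row per lesion, columns exactly the feature-vector names.
#'
#' @param features data.frame from \code{\link{extractFeatures}} (rows may
#'   be stacked).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
    utils::write.csv(features, path, row.names = FALSE)
    invisible(path)
}

#' Serialize a fitted prognostic model to JSON
#'
#' Stores cutoffs, the partition tree, the cross-validation summary and
#' seeds so a fit can be archived and re-applied.
#'
#' @param model a \linkS4class{PrognosticModel}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeModelJSON <- function(model, path) {
    obj <- list(
        pattern = list(
            primary_feature = model@pattern@primaryFeature,
            primary_cutoff = model@pattern@primaryCutoff,
            secondary_feature = model@pattern@secondaryFeature,
            secondary_cutoff = model@pattern@secondaryCutoff),
        predictors = model@predictors,
        tree = model@tree,
        cv = model@cv,
        seed = model@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read a prognostic model from JSON
#'
#' @param path JSON written by \code{\link{writeModelJSON}}.
#' @return a \linkS4class{PrognosticModel}.
#' @export
readModelJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    fix_node <- function(n) {
        n$leaf <- isTRUE(n$leaf)
        if (!n$leaf) {
            n$left <- fix_node(n$left)
            n$right <- fix_node(n$right)
        }
        n
    }
    pat <- new("PETRiskPattern",
               primaryFeature = obj$pattern$primary_feature,
               primaryCutoff = obj$pattern$primary_cutoff,
               secondaryFeature = obj$pattern$secondary_feature,
               secondaryCutoff = obj$pattern$secondary_cutoff,
               screening = data.frame())
    new("PrognosticModel", tree = fix_node(obj$tree),
        predictors = as.character(obj$predictors),
        cv = as.data.frame(obj$cv), pattern = pat,
        seed = as.integer(obj$seed))
}
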