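#' Specify a PET tumor phantom
#'
#' Describes a synthetic SUV volume containing one tumor (a radially smooth
#' high-uptake focus) and optionally smaller nodal lesions. The tumor is a
#' Gaussian uptake profile whose 40%-of-peak isocontour sits at
#' \code{lesion_radius}, so fixed-threshold segmentation of the noiseless
#' image recovers a sphere of that radius. \code{heterogeneity} in [0, 1]
#' adds within-lesion multiplicative noise and high-uptake sub-foci, giving
#' monotone control of textural heterogeneity at fixed volume.
#'
#' @param grid_shape integer(3) voxels per axis.
#' @param voxel_spacing numeric(3) mm per axis (scalar recycled).
#' @param background_suv background SUV (> 0).
#' @param lesion_center voxel coordinates of the tumor center (defaults to
#'   the grid center).
#' @param lesion_radius tumor radius in mm at the 40% isocontour; must be at
#'   least twice the largest voxel spacing.
#' @param peak_suv lesion peak SUV (> background).
#' @param heterogeneity dimensionless in [0, 1].
#' @param node_specs optional list of sub-lists with fields \code{center},
#'   \code{radius}, \code{peak} describing nodal lesions.
#' @param seed integer; the same seed reproduces the phantom bit-identically.
#' @return a \code{PhantomSpec} (list with class attribute).
#' @export
phantomSpec <- function(grid_shape = c(48L, 48L, 48L),
                        voxel_spacing = c(2, 2, 2),
                        background_suv = 0.5,
                        lesion_center = NULL,
                        lesion_radius = 15,
                        peak_suv = 10,
                        heterogeneity = 0,
                        node_specs = list(),
                        seed = 1L) {
    if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
    if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
    spec <- list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_suv = background_suv,
                 lesion_center = lesion_center,
                 lesion_radius = lesion_radius,
                 peak_suv = peak_suv,
                 heterogeneity = heterogeneity,
                 node_specs = node_specs,
                 seed = as.integer(seed))
    class(spec) <- "PhantomSpec"
    validatePhantomSpec(spec)
    spec
}

validatePhantomSpec <- function(spec) {
    if (!(spec$peak_suv > spec$background_suv && spec$background_suv > 0))
        stop("need peak_suv > background_suv > 0")
    if (spec$lesion_radius < 2 * max(spec$voxel_spacing))
        stop("lesion_radius must be >= 2 x max(voxel_spacing)")
    if (spec$heterogeneity < 0 || spec$heterogeneity > 1)
        stop("heterogeneity must lie in [0, 1]")
    mm_extent <- spec$grid_shape * spec$voxel_spacing
    ctr <- spec$lesion_center * spec$voxel_spacing
    if (any(ctr - spec$lesion_radius < 0) ||
        any(ctr + spec$lesion_radius > mm_extent))
        stop("lesion extends outside the image grid: center ",
             paste(round(spec$lesion_center, 1), collapse = ","),
             " radius ", spec$lesion_radius, " mm vs grid ",
             paste(mm_extent, collapse = "x"), " mm")
    invisible(TRUE)
}

# Noiseless lesion profile: super-Gaussian (flat avid core with a fast
# shoulder), background + (peak - background) * exp(-c (d/R)^p), with c set
# so the 40%-of-peak contour sits at `radius` mm. The plateau makes the
# noiseless lesion nearly uniform inside the segmented volume, so the
# heterogeneity knob (noise + sub-foci) monotonically increases textural
# heterogeneity from that floor.
.lesion_profile <- function(dist_mm, radius, peak, background, p = 20) {
    frac <- (0.4 * peak - background) / (peak - background)
    if (frac <= 0 || frac >= 1)
        stop("0.4 * peak_suv must exceed background_suv")
    cc <- -log(frac)
    background + (peak - background) * exp(-cc * (dist_mm / radius)^p)
}

.dist_grid <- function(grid_shape, spacing, center) {
    x <- (seq_len(grid_shape[1]) - center[1]) * spacing[1]
    y <- (seq_len(grid_shape[2]) - center[2]) * spacing[2]
    z <- (seq_len(grid_shape[3]) - center[3]) * spacing[3]
    sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

#' Generate a PET phantom with its segmentation ground truth
#'
#' Builds the SUV volume described by a \code{\link{phantomSpec}}. The truth
#' mask marks voxels whose \emph{noiseless} SUV reaches 40% of the noiseless
#' lesion maximum, i.e. the target of fixed-threshold segmentation before
#' noise. With \code{heterogeneity = 0} the lesion is radially smooth;
#' larger values add seeded multiplicative lognormal noise and up to three
#' high-uptake sub-foci inside the lesion.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{image} (\linkS4class{SUVImage}),
#'   \code{truth} (\linkS4class{LesionMask} for the tumor) and
#'   \code{node_truth} (list of node truth masks).
#' @export
generatePhantom <- function(spec) {
    validatePhantomSpec(spec)
    gs <- spec$grid_shape; sp <- spec$voxel_spacing
    with_seed(spec$seed, {
        dist <- .dist_grid(gs, sp, spec$lesion_center)
        clean <- .lesion_profile(dist, spec$lesion_radius,
                                 spec$peak_suv, spec$background_suv)
        les_region <- dist <= 1.6 * spec$lesion_radius
        noisy <- clean
        if (spec$heterogeneity > 0) {
            h <- spec$heterogeneity
            n_foci <- round(3 * h)
            for (f in seq_len(n_foci)) {
                u <- stats::rnorm(3)
                u <- u / sqrt(sum(u^2)) * stats::runif(1, 0.2, 0.7) *
                    spec$lesion_radius
                fc <- spec$lesion_center + u / sp
                fd <- .dist_grid(gs, sp, fc)
                amp <- 0.4 * h * (spec$peak_suv - spec$background_suv)
                noisy <- noisy + amp *
                    exp(-fd^2 / (2 * (0.35 * spec$lesion_radius)^2))
            }
            # spatially correlated multiplicative noise, clamped so the
            # intensity range grows linearly with the heterogeneity knob
            # instead of sprouting heavy tails
            g <- gauss_smooth3(array(stats::rnorm(prod(gs)), gs), 1.5)
            g <- g / stats::sd(g[les_region])
            g <- pmin(pmax(g, -2), 2)
            mult <- 1 + 0.35 * h * g
            noisy[les_region] <- noisy[les_region] * mult[les_region]
        }
        node_truth <- list()
        if (length(spec$node_specs)) {
            for (nn in seq_along(spec$node_specs)) {
                ns <- spec$node_specs[[nn]]
                nd <- .dist_grid(gs, sp, ns$center)
                nprof <- .lesion_profile(nd, ns$radius, ns$peak,
                                         spec$background_suv)
                noisy <- pmax(noisy, nprof)
                node_truth[[nn]] <- LesionMask(
                    nprof >= 0.4 * max(nprof),
                    label = paste0("node", nn), kind = "node")
            }
        }
        truth <- LesionMask(clean >= 0.4 * max(clean), label = "tumor",
                            kind = "tumor")
        list(image = SUVImage(noisy, sp), truth = truth,
             node_truth = node_truth)
    })
}
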