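#' Fixed-threshold (T40) lesion segmentation
#'
#' Segments the lesion containing \code{seed_point} as the 26-connected
#' component of voxels with SUV at or above 40% of the lesion SUVmax. The
#' lesion SUVmax is itself defined on the grown region, so the operation is
#' iterated to a fixed point: threshold at 40% of the current regional
#' maximum, keep the component containing the seed, re-read the maximum,
#' repeat until the mask stabilises. The threshold comparison is inclusive
#' (\code{>=}), which keeps the maximum voxel by construction, and the
#' region is restricted to the seed's connected component so adjacent avid
#' structures are not merged.
#'
#' @param image an \linkS4class{SUVImage}.
#' @param seed_point integer(3) voxel coordinates inside the lesion.
#' @param threshold_fraction fraction of SUVmax (default 0.40).
#' @param label,kind passed to the returned \linkS4class{LesionMask}.
#' @return a \linkS4class{LesionMask}.
#' @export
segmentT40 <- function(image, seed_point, threshold_fraction = 0.40,
                       label = "lesion", kind = "tumor") {
    vals <- suvValues(image)
    dm <- dim(vals)
    seed_point <- as.integer(round(seed_point))
    if (any(seed_point < 1L) || any(seed_point > dm))
        stop("seed point outside the image grid")
    sidx <- seed_point[1] + (seed_point[2] - 1L) * dm[1] +
        (seed_point[3] - 1L) * dm[1] * dm[2]
    if (vals[sidx] <= 0)
        stop("seed point has non-positive SUV; it must lie inside a lesion")
    cur_max <- vals[sidx]
    ref_idx <- sidx  # current lesion reference voxel: argmax of the region
    mask <- NULL
    for (iter in seq_len(50L)) {
        thr <- threshold_fraction * cur_max
        above <- vals >= thr
        comp <- connected_components26(above)
        if (comp[ref_idx] == 0L)
            stop("seed voxel fell below threshold; not inside a lesion")
        new_mask <- comp == comp[ref_idx]
        new_max <- max(vals[new_mask])
        ref_idx <- which(new_mask & vals == new_max)[1L]
        if (!is.null(mask) && identical(new_mask, mask) && new_max == cur_max)
            break
        mask <- new_mask
        cur_max <- new_max
    }
    touches_border <- any(mask[1, , ]) || any(mask[dm[1], , ]) ||
        any(mask[, 1, ]) || any(mask[, dm[2], ]) ||
        any(mask[, , 1]) || any(mask[, , dm[3]])
    if (touches_border)
        stop("segmented region reaches the image border: seed appears to ",
             "lie in background uptake, not a lesion")
    if (sum(mask) < 64L)
        message(sprintf(
            "small lesion: %d voxels (< 64); texture indices may be unstable",
            sum(mask)))
    LesionMask(mask, label = label, kind = kind)
}

#' Metabolically active tumor volume
#'
#' MATV = voxel count times voxel volume, reported in mL (= cm^3).
#'
#' @param mask a \linkS4class{LesionMask} or logical array.
#' @param spacing voxel spacing in mm (required for a bare array).
#' @return volume in mL.
#' @export
computeMATV <- function(mask, spacing = NULL) {
    if (is(mask, "LesionMask")) mask <- maskArray(mask)
    if (is.null(spacing)) stop("voxel spacing (mm) is required")
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    n <- sum(mask)
    if (n == 0L) stop("mask is empty")
    n * prod(spacing) / 1000
}

#' Lesion asphericity from a surface mesh
#'
#' Asphericity ASP = (S^3 / (36 pi V^2))^(1/3) - 1 with V the mesh-enclosed
#' volume and S the mesh surface area; 0 for a perfect sphere, and larger
#' the more the shape deviates from sphericity (a cube gives
#' (6/pi)^(1/3) - 1, about 0.2407). The surface is a marching-tetrahedra
#' mesh of the 0.5 isocontour of the (lightly Gaussian-smoothed) binary
#' mask; meshing the smoothed indicator rather than measuring voxel faces
#' avoids the strong upward staircase bias of voxel-face surface area; the
#' cost is a mild corner-rounding bias for shapes with sharp edges (the
#' measured ASP of a voxelized cube falls below the closed form by a term
#' of order sigma/side). If smoothing would erase a very small lesion the
#' mask is meshed unsmoothed, and a single-voxel mask falls back to the
#' closed form for that voxel's box, which is exact for boxes.
#'
#' @param mask a \linkS4class{LesionMask} or logical array.
#' @param spacing voxel spacing in mm.
#' @param smooth_sigma Gaussian smoothing of the indicator, in voxels
#'   (default 0.75).
#' @return dimensionless asphericity (>= 0 up to mesh error).
#' @export
computeAsphericity <- function(mask, spacing = NULL, smooth_sigma = 0.75) {
    if (is(mask, "LesionMask")) mask <- maskArray(mask)
    if (is.null(spacing)) stop("voxel spacing (mm) is required")
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    n <- sum(mask)
    if (n == 0L) stop("mask is empty")
    if (n == 1L) {
        a <- spacing[1]; b <- spacing[2]; cc <- spacing[3]
        V <- a * b * cc
        S <- 2 * (a * b + b * cc + a * cc)
        return((S^3 / (36 * pi * V^2))^(1 / 3) - 1)
    }
    sv <- surface_mesh_measures(mask, spacing, smooth_sigma)
    unname((sv["area"]^3 / (36 * pi * sv["volume"]^2))^(1 / 3) - 1)
}

# Marching tetrahedra over the 0.5 level set of the (optionally smoothed)
# indicator field. Returns c(area, volume): triangle-area sum and the
# divergence-theorem volume of the closed mesh.
surface_mesh_measures <- function(mask, spacing, smooth_sigma = 0.75) {
    # pad by enough voxels that the smoothed field decays to ~0 outside
    pad <- max(2L, ceiling(3 * smooth_sigma) + 1L)
    dm <- dim(mask)
    big <- array(0, dm + 2L * pad)
    big[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <-
        as.numeric(mask)
    field <- gauss_smooth3(big, smooth_sigma)
    if (max(field) <= 0.5)  # smoothing erased the object: mesh it unsmoothed
        field <- big
    mesh_level_set(field, spacing, level = 0.5)
}

# Cube corners (binary coordinates) and the 6-tetra decomposition around the
# main diagonal; the induced face diagonals match between neighbouring
# cells, so the mesh is crack-free.
.tet_ids <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
.corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

mesh_level_set <- function(field, spacing, level = 0.5) {
    dm <- dim(field)
    inside <- field >= level
    # active cells: corners not all on one side
    cs <- function(arr, ox, oy, oz)
        arr[(1 + ox):(dm[1] - 1 + ox), (1 + oy):(dm[2] - 1 + oy),
            (1 + oz):(dm[3] - 1 + oz)]
    any_in <- cs(inside, 0, 0, 0); all_in <- any_in
    for (r in 2:8) {
        o <- .corner_off[r, ]
        ci <- cs(inside, o[1], o[2], o[3])
        any_in <- any_in | ci
        all_in <- all_in & ci
    }
    act <- which(any_in & !all_in)
    if (!length(act)) stop("level set is empty")
    cd <- dm - 1L
    ai <- arrayInd(act, cd)
    # corner values and mm coordinates for active cells
    vals <- matrix(0, length(act), 8L)
    px <- matrix(0, length(act), 8L); py <- px; pz <- px
    for (r in 1:8) {
        o <- .corner_off[r, ]
        lin <- (ai[, 1] + o[1]) + (ai[, 2] + o[2] - 1L) * dm[1] +
            (ai[, 3] + o[3] - 1L) * dm[1] * dm[2]
        vals[, r] <- field[lin]
        px[, r] <- (ai[, 1] + o[1]) * spacing[1]
        py[, r] <- (ai[, 2] + o[2]) * spacing[2]
        pz[, r] <- (ai[, 3] + o[3]) * spacing[3]
    }
    area <- 0; vol6 <- 0
    edge_pt <- function(a, b, w) {  # interpolated crossing on edge a->b
        t <- (level - vals[w, a]) / (vals[w, b] - vals[w, a])
        cbind(px[w, a] + t * (px[w, b] - px[w, a]),
              py[w, a] + t * (py[w, b] - py[w, a]),
              pz[w, a] + t * (pz[w, b] - pz[w, a]))
    }
    add_tris <- function(p1, p2, p3, ref_in) {
        # ref_in: coordinates of an interior point; orient normals outward
        e1 <- p2 - p1; e2 <- p3 - p1
        nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
        ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
        nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
        cx <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3
        cy <- (p1[, 2] + p2[, 2] + p3[, 2]) / 3
        cz <- (p1[, 3] + p2[, 3] + p3[, 3]) / 3
        s <- sign(nx * (cx - ref_in[, 1]) + ny * (cy - ref_in[, 2]) +
                  nz * (cz - ref_in[, 3]))
        s[s == 0] <- 1
        nx <- nx * s; ny <- ny * s; nz <- nz * s
        area <<- area + sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
        vol6 <<- vol6 + sum(cx * nx + cy * ny + cz * nz)
    }
    for (tt in seq_len(nrow(.tet_ids))) {
        id <- .tet_ids[tt, ]
        tin <- (vals[, id[1]] >= level) + 2L * (vals[, id[2]] >= level) +
            4L * (vals[, id[3]] >= level) + 8L * (vals[, id[4]] >= level)
        for (code in 1:14) {
            w <- which(tin == code)
            if (!length(w)) next
            bits <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)))
            ins <- id[bits]; outs <- id[!bits]
            if (length(ins) == 1L || length(ins) == 3L) {
                if (length(ins) == 3L) { odd <- outs; oth <- ins }
                else { odd <- ins; oth <- outs }
                # triangle: crossings on the three edges from the odd vertex
                p1 <- edge_pt(odd[1], oth[1], w)
                p2 <- edge_pt(odd[1], oth[2], w)
                p3 <- edge_pt(odd[1], oth[3], w)
                ref <- cbind(px[w, ins[1]], py[w, ins[1]], pz[w, ins[1]])
                add_tris(p1, p2, p3, ref)
            } else {
                # two in / two out: quad on the four crossing edges
                q1 <- edge_pt(ins[1], outs[1], w)
                q2 <- edge_pt(ins[1], outs[2], w)
                q3 <- edge_pt(ins[2], outs[2], w)
                q4 <- edge_pt(ins[2], outs[1], w)
                ref <- cbind(px[w, ins[1]], py[w, ins[1]], pz[w, ins[1]])
                add_tris(q1, q2, q3, ref)
                add_tris(q1, q3, q4, ref)
            }
        }
    }
    # interior cells (all 8 corners inside) contribute no surface but their
    # full volume; the divergence-theorem sum over the closed mesh already
    # accounts for everything because normals face outward globally.
    c(area = area, volume = abs(vol6) / 6)
}

#' Fixed-bin-number discretization of a VOI
#'
#' Maps each VOI voxel's SUV onto one of \code{B} gray levels using the
#' fixed-bin-number rule \code{level = min(B, 1 + floor(B * (x - min) /
#' (max - min)))}, with min and max taken over the VOI. Bins are half-open
#' on [min, max) with the maximum folded into bin B; a constant VOI maps
#' every voxel to level 1. The result is invariant to affine rescaling of
#' the VOI intensities.
#'
#' @param image an \linkS4class{SUVImage}.
#' @param mask a \linkS4class{LesionMask} (or logical array).
#' @param B number of bins (default 16).
#' @return a \linkS4class{DiscretizedVOI}.
#' @export
discretizeFBN <- function(image, mask, B = 16L) {
    vals <- suvValues(image)
    m <- if (is(mask, "LesionMask")) maskArray(mask) else mask
    if (!any(m)) stop("mask is empty")
    B <- as.integer(B)
    v <- vals[m]
    lo <- min(v); hi <- max(v)
    lev <- array(NA_integer_, dim(vals))
    if (hi == lo) {
        lev[m] <- 1L
        edges <- c(lo, rep(hi, B))
    } else {
        lev[m] <- pmin(B, 1L + as.integer(floor(B * (v - lo) / (hi - lo))))
        edges <- seq(lo, hi, length.out = B + 1L)
    }
    new("DiscretizedVOI", levels = lev, nBins = B, binEdges = edges,
        spacing = voxelSpacing(image))
}

#' Aggregate nodal lesion features
#'
#' Lymph-node summary across all involved nodes: MATV is the sum of the
#' nodal volumes while SUVmax and asphericity take the highest value among
#' lesions. Texture features are deliberately absent for nodes (nodal
#' lesions are generally too small for texture analysis).
#'
#' @param node_features list of per-node feature rows, each containing
#'   \code{suv_max}, \code{matv}, \code{asphericity}.
#' @return named list with \code{suv_max}, \code{matv}, \code{asphericity},
#'   or \code{NULL} when the list is empty (absent node features, not
#'   zeros).
#' @export
aggregateNodes <- function(node_features) {
    if (length(node_features) == 0L) return(NULL)
    g <- function(f) vapply(node_features, function(x) as.numeric(x[[f]]),
                            numeric(1))
    list(suv_max = max(g("suv_max")),
         matv = sum(g("matv")),
         asphericity = max(g("asphericity")))
}
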