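# Texture matrices (intensity histogram, GLCM, GLRLM, GLSZM) on a
# DiscretizedVOI and the heterogeneity features derived from them. All
# matrices are computed on the discretized VOI only: voxels outside the
# mask never enter a matrix, and runs/pairs are broken by masked-out
# voxels. Natural logarithms throughout.

#' Intensity histogram of a discretized VOI
#'
#' @param voi a \linkS4class{DiscretizedVOI}.
#' @return list with \code{counts} (length B) and \code{p} (probabilities).
#' @export
intensityHistogram <- function(voi) {
    lv <- grayLevels(voi)[!is.na(grayLevels(voi))]
    counts <- tabulate(lv, nbins = nBins(voi))
    list(counts = counts, p = counts / sum(counts))
}

#' Discretized intensity entropy
#'
#' Shannon entropy (natural log) of the fixed-bin-number histogram:
#' H = -sum p_i ln p_i over occupied bins, in nats. Bounded by ln B.
#'
#' @param h an intensity histogram from \code{\link{intensityHistogram}},
#'   or a \linkS4class{DiscretizedVOI}.
#' @return entropy in nats.
#' @export
intensityEntropy <- function(h) {
    if (is(h, "DiscretizedVOI")) h <- intensityHistogram(h)
    p <- h$p[h$p > 0]
    -sum(p * log(p))
}

# Crop the level array to the VOI bounding box (features are unchanged:
# everything outside the mask is NA and never enters a matrix).
crop_voi <- function(voi) {
    lv <- grayLevels(voi)
    idx <- which(!is.na(lv))
    ai <- arrayInd(idx, dim(lv))
    rng <- apply(ai, 2L, range)
    lv2 <- lv[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
              drop = FALSE]
    new("DiscretizedVOI", levels = lv2, nBins = nBins(voi),
        binEdges = voi@binEdges, spacing = voi@spacing)
}

# Per-direction symmetric gray-level co-occurrence counts at Chebyshev
# distance 1. Returns a list of B x B matrices (one per direction with at
# least one valid pair).
glcm_counts <- function(voi) {
    lv <- grayLevels(voi)
    dm <- dim(lv)
    B <- nBins(voi)
    dirs <- directions13()
    out <- vector("list", nrow(dirs))
    for (r in seq_len(nrow(dirs))) {
        pr <- shift_pairs(dm, dirs[r, ])
        if (!nrow(pr)) next
        a <- lv[pr[, 1]]; b <- lv[pr[, 2]]
        ok <- !is.na(a) & !is.na(b)
        if (!any(ok)) next
        a <- a[ok]; b <- b[ok]
        m <- matrix(0, B, B)
        tab <- table(factor(a, levels = 1:B), factor(b, levels = 1:B))
        m <- unclass(tab) + t(unclass(tab))  # symmetric: count both orders
        storage.mode(m) <- "double"
        out[[r]] <- m
    }
    out[!vapply(out, is.null, logical(1))]
}

#' Build the gray-level co-occurrence matrices
#'
#' Symmetric GLCMs over the 13 unique 3-D direction vectors at Chebyshev
#' distance 1, each normalized to a joint probability table. Directions
#' with no valid voxel pair (VOI too thin) are excluded from downstream
#' direction averages, with a message.
#'
#' @param voi a \linkS4class{DiscretizedVOI} with at least 2 voxels.
#' @return object of class \code{GLCMatrix}: list of per-direction
#'   probability matrices.
#' @export
buildGLCM <- function(voi) {
    if (sum(!is.na(grayLevels(voi))) < 2L)
        stop("GLCM needs at least two VOI voxels")
    cnt <- glcm_counts(crop_voi(voi))
    if (length(cnt) < 13L)
        message(sprintf("GLCM: %d of 13 directions had no valid pair%s",
                        13L - length(cnt),
                        "; they are excluded from the direction average"))
    if (!length(cnt))
        stop("no direction contains a valid voxel pair")
    probs <- lapply(cnt, function(m) m / sum(m))
    structure(list(p = probs), class = "GLCMatrix")
}

#' GLCM angular second moment (ASM)
#'
#' ASM = sum p(i,j)^2 per direction, averaged over directions; the
#' uniformity of the co-occurrence distribution (1 for a constant VOI).
#'
#' @param m a \code{GLCMatrix} from \code{\link{buildGLCM}}.
#' @return dimensionless ASM in (0, 1].
#' @export
glcmASM <- function(m) {
    mean(vapply(m$p, function(p) sum(p^2), numeric(1)))
}

#' GLCM sum entropy
#'
#' Entropy (natural log) of the diagonal-sum distribution
#' p_{x+y}(k) = sum_{i+j=k} p(i,j), per direction, averaged over
#' directions. Quantifies the randomness of the intensity distribution.
#'
#' @param m a \code{GLCMatrix}.
#' @return sum entropy in nats.
#' @export
glcmSumEntropy <- function(m) {
    mean(vapply(m$p, function(p) {
        B <- nrow(p)
        k <- outer(1:B, 1:B, `+`)
        pk <- vapply(2:(2 * B), function(kk) sum(p[k == kk]), numeric(1))
        pk <- pk[pk > 0]
        -sum(pk * log(pk))
    }, numeric(1)))
}

# Maximal same-level runs along each of the 13 directions. Returns, per
# direction, a B x Lmax count matrix r(i, l).
glrlm_counts <- function(voi) {
    lv <- grayLevels(voi)
    dm <- dim(lv)
    B <- nBins(voi)
    dirs <- directions13()
    res <- vector("list", nrow(dirs))
    lin_index <- function(i, j, k) i + (j - 1L) * dm[1] + (k - 1L) * dm[1] * dm[2]
    for (r in seq_len(nrow(dirs))) {
        off <- dirs[r, ]
        # starting voxels: those with no predecessor along -off inside grid
        i <- seq_len(dm[1]); j <- seq_len(dm[2]); k <- seq_len(dm[3])
        starts <- expand.grid(i = i, j = j, k = k)
        pred <- cbind(starts$i - off[1], starts$j - off[2], starts$k - off[3])
        is_start <- pred[, 1] < 1 | pred[, 1] > dm[1] |
            pred[, 2] < 1 | pred[, 2] > dm[2] |
            pred[, 3] < 1 | pred[, 3] > dm[3]
        starts <- starts[is_start, , drop = FALSE]
        runs_lv <- integer(0); runs_len <- integer(0)
        for (s in seq_len(nrow(starts))) {
            ci <- starts$i[s]; cj <- starts$j[s]; ck <- starts$k[s]
            line <- integer(0)
            while (ci >= 1 && ci <= dm[1] && cj >= 1 && cj <= dm[2] &&
                   ck >= 1 && ck <= dm[3]) {
                line <- c(line, lv[lin_index(ci, cj, ck)])
                ci <- ci + off[1]; cj <- cj + off[2]; ck <- ck + off[3]
            }
            rl <- rle(line)
            keep <- !is.na(rl$values)
            runs_lv <- c(runs_lv, rl$values[keep])
            runs_len <- c(runs_len, rl$lengths[keep])
        }
        if (!length(runs_lv)) next
        lmax <- max(runs_len)
        mat <- matrix(0, B, lmax)
        for (q in seq_along(runs_lv))
            mat[runs_lv[q], runs_len[q]] <- mat[runs_lv[q], runs_len[q]] + 1
        res[[r]] <- mat
    }
    res[!vapply(res, is.null, logical(1))]
}

#' Build the gray-level run-length matrices
#'
#' Runs are maximal same-level voxel segments along each of the 13 unique
#' 3-D directions; masked-out voxels break runs. Features from run-length
#' matrices are averaged over directions.
#'
#' @param voi a \linkS4class{DiscretizedVOI}.
#' @return object of class \code{RunLengthMatrix}: per-direction count
#'   matrices r(i, l).
#' @export
buildGLRLM <- function(voi) {
    if (!any(!is.na(grayLevels(voi)))) stop("empty VOI")
    structure(list(r = glrlm_counts(crop_voi(voi))), class = "RunLengthMatrix")
}

#' Run-length nonuniformity (RLNU)
#'
#' RLNU = (1/N_runs) sum_l (sum_i r(i,l))^2 per direction, averaged over
#' directions. Small when runs are equally distributed over run lengths.
#'
#' @param m a \code{RunLengthMatrix}.
#' @return dimensionless RLNU.
#' @export
rlnu <- function(m) {
    mean(vapply(m$r, function(r) {
        nr <- sum(r)
        sum(colSums(r)^2) / nr
    }, numeric(1)))
}

#' High gray-level run emphasis (HGLRE)
#'
#' HGLRE = (1/N_runs) sum_{i,l} i^2 r(i,l), averaged over directions. High
#' in images with many runs of high gray level.
#'
#' @param m a \code{RunLengthMatrix}.
#' @return dimensionless HGLRE.
#' @export
hglre <- function(m) {
    mean(vapply(m$r, function(r) {
        nr <- sum(r)
        sum((seq_len(nrow(r)))^2 * rowSums(r)) / nr
    }, numeric(1)))
}

#' Build the gray-level size-zone matrix
#'
#' Zones are 26-connected (Chebyshev distance 1) components of equal gray
#' level within the VOI; a single matrix s(i, z) of zone counts by zone
#' size, with no direction averaging.
#'
#' @param voi a \linkS4class{DiscretizedVOI}.
#' @return object of class \code{SizeZoneMatrix} with count matrix \code{s}.
#' @export
buildGLSZM <- function(voi) {
    voi <- crop_voi(voi)
    lv <- grayLevels(voi)
    B <- nBins(voi)
    sizes_lv <- integer(0); sizes_z <- integer(0)
    for (g in sort(unique(lv[!is.na(lv)]))) {
        comp <- connected_components26(!is.na(lv) & lv == g)
        if (!any(comp > 0)) next
        zs <- tabulate(comp[comp > 0])
        sizes_lv <- c(sizes_lv, rep(g, length(zs)))
        sizes_z <- c(sizes_z, zs)
    }
    zmax <- max(sizes_z)
    s <- matrix(0, B, zmax)
    for (q in seq_along(sizes_lv))
        s[sizes_lv[q], sizes_z[q]] <- s[sizes_lv[q], sizes_z[q]] + 1
    structure(list(s = s), class = "SizeZoneMatrix")
}

#' Zone-size nonuniformity (ZSNU)
#'
#' ZSNU = (1/N_zones) sum_z (sum_i s(i,z))^2; small when zones have similar
#' sizes throughout the image.
#'
#' @param m a \code{SizeZoneMatrix}.
#' @return dimensionless ZSNU.
#' @export
zsnu <- function(m) {
    nz <- sum(m$s)
    sum(colSums(m$s)^2) / nz
}

#' High gray-level zone emphasis (HGLZE)
#'
#' HGLZE = (1/N_zones) sum_{i,z} i^2 s(i,z); high in images with many zones
#' of high gray level.
#'
#' @param m a \code{SizeZoneMatrix}.
#' @return dimensionless HGLZE.
#' @export
hglze <- function(m) {
    nz <- sum(m$s)
    sum((seq_len(nrow(m$s)))^2 * rowSums(m$s)) / nz
}

#' Extract the full lesion feature vector
#'
#' Composes segmentation-derived quantities (SUVmax, MATV, asphericity)
#' with the six texture features computed on the fixed-bin-number
#' discretized VOI: discretized intensity entropy, GLCM ASM and sum
#' entropy, GLRLM RLNU and HGLRE, GLSZM ZSNU and HGLZE. Deterministic.
#'
#' @param image an \linkS4class{SUVImage}.
#' @param mask a \linkS4class{LesionMask}.
#' @param B bin count for FBN discretization (default 16).
#' @param smooth_sigma passed to \code{\link{computeAsphericity}}.
#' @return one-row data.frame with columns \code{suv_max, matv,
#'   asphericity, intensity_entropy, glcm_asm, glcm_sum_entropy, rlnu,
#'   hglre, zsnu, hglze} plus \code{n_voxels} and \code{small_lesion}
#'   (fewer than 64 voxels).
#' @export
extractFeatures <- function(image, mask, B = 16L, smooth_sigma = 1.0) {
    m <- maskArray(mask)
    sp <- voxelSpacing(image)
    voi <- discretizeFBN(image, mask, B)
    gl <- buildGLCM(voi)
    rl <- buildGLRLM(voi)
    sz <- buildGLSZM(voi)
    nvox <- sum(m)
    data.frame(
        suv_max = max(suvValues(image)[m]),
        matv = computeMATV(m, sp),
        asphericity = computeAsphericity(m, sp, smooth_sigma),
        intensity_entropy = intensityEntropy(voi),
        glcm_asm = glcmASM(gl),
        glcm_sum_entropy = glcmSumEntropy(gl),
        rlnu = rlnu(rl),
        hglre = hglre(rl),
        zsnu = zsnu(sz),
        hglze = hglze(sz),
        n_voxels = nvox,
        small_lesion = nvox < 64L)
}

#' The ten PET parameters used for feature screening
#' @return character vector of feature-column names.
#' @export
petFeatureNames <- function() {
    c("suv_max", "matv", "asphericity", "intensity_entropy", "glcm_asm",
      "glcm_sum_entropy", "rlnu", "hglre", "zsnu", "hglze")
}
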