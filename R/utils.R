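# Internal helpers shared across modules.

#' Construct an SUVImage
#'
#' @param values 3-D numeric array of SUV values.
#' @param spacing voxel spacing in mm, length 3 (recycled if scalar).
#' @return an \linkS4class{SUVImage}.
#' @export
SUVImage <- function(values, spacing = c(1, 1, 1)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("SUVImage", values = values, spacing = as.numeric(spacing))
}

#' Construct a LesionMask
#'
#' @param mask logical 3-D array.
#' @param label lesion identifier.
#' @param kind "tumor" or "node".
#' @return a \linkS4class{LesionMask}.
#' @export
LesionMask <- function(mask, label = "lesion", kind = "tumor") {
    storage.mode(mask) <- "logical"
    new("LesionMask", mask = mask, label = label, kind = kind)
}

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# generator calls never disturb the caller's stream.
with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# The 13 unique 3-D direction vectors at Chebyshev distance 1 (26-neighbour
# offsets modulo sign).
directions13 <- function() {
    d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
    keep <- apply(d, 1L, function(v) {
        v[3] > 0 || (v[3] == 0 && v[2] > 0) ||
            (v[3] == 0 && v[2] == 0 && v[1] > 0)
    })
    unname(d[keep, , drop = FALSE])
}

# Linear indices of voxels reachable from `idx` by offset (dx,dy,dz) without
# leaving the grid; returns a two-column matrix (from, to) of linear indices.
shift_pairs <- function(dm, off) {
    i <- seq_len(dm[1]); j <- seq_len(dm[2]); k <- seq_len(dm[3])
    ii <- i[i + off[1] >= 1 & i + off[1] <= dm[1]]
    jj <- j[j + off[2] >= 1 & j + off[2] <= dm[2]]
    kk <- k[k + off[3] >= 1 & k + off[3] <= dm[3]]
    if (!length(ii) || !length(jj) || !length(kk))
        return(matrix(integer(), ncol = 2L))
    g <- expand.grid(i = ii, j = jj, k = kk)
    from <- g$i + (g$j - 1L) * dm[1] + (g$k - 1L) * dm[1] * dm[2]
    to <- (g$i + off[1]) + (g$j + off[2] - 1L) * dm[1] +
        (g$k + off[3] - 1L) * dm[1] * dm[2]
    cbind(from, to)
}

# 26-connected components of a logical 3-D array. Returns an integer array
# with 0 outside and component ids inside.
connected_components26 <- function(flag) {
    dm <- dim(flag)
    idx <- which(flag)
    out <- array(0L, dm)
    if (!length(idx)) return(out)
    pos <- integer(prod(dm)); pos[idx] <- seq_along(idx)
    edges <- list()
    dirs <- directions13()
    for (r in seq_len(nrow(dirs))) {
        pr <- shift_pairs(dm, dirs[r, ])
        if (!nrow(pr)) next
        ok <- flag[pr[, 1]] & flag[pr[, 2]]
        if (any(ok)) edges[[length(edges) + 1L]] <-
            cbind(pos[pr[ok, 1]], pos[pr[ok, 2]])
    }
    if (length(edges)) {
        em <- do.call(rbind, edges)
        g <- igraph::graph_from_edgelist(em, directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
        comp <- igraph::components(g)$membership[seq_along(idx)]
    } else {
        comp <- seq_along(idx)
    }
    out[idx] <- as.integer(comp)
    out
}

# Separable Gaussian smoothing of a 3-D array (zero padding), sigma in voxels.
gauss_smooth3 <- function(x, sigma) {
    if (sigma <= 0) return(x)
    half <- max(1L, ceiling(3 * sigma))
    w <- exp(-((-half:half)^2) / (2 * sigma^2))
    w <- w / sum(w)
    dm <- dim(x)
    for (axis in 1:3) {
        acc <- array(0, dm)
        for (s in -half:half) {
            wt <- w[s + half + 1L]
            src <- x
            n <- dm[axis]
            keep_to <- max(1L, 1L - s):min(n, n - s)
            keep_from <- keep_to + s
            sl_to <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
            sl_from <- sl_to
            sl_to[[axis]] <- keep_to
            sl_from[[axis]] <- keep_from
            acc[sl_to[[1]], sl_to[[2]], sl_to[[3]]] <-
                acc[sl_to[[1]], sl_to[[2]], sl_to[[3]]] +
                wt * src[sl_from[[1]], sl_from[[2]], sl_from[[3]]]
        }
        x <- acc
    }
    x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
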