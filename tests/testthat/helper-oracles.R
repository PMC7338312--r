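# Naive brute-force texture enumerator, written independently of the
# package internals: triple loops over voxels, explicit line walking for
# runs, breadth-first flood fill for zones. Used as the oracle for
# equivalence tests. `lv` is an integer 3-D array with NA outside the VOI.

oracle_dirs <- local({
    d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    d <- d[rowSums(abs(d)) > 0, ]
    keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
        (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
    d[keep, , drop = FALSE]
})

oracle_entropy <- function(lv) {
    v <- lv[!is.na(lv)]
    p <- as.vector(table(v)) / length(v)
    -sum(p * log(p))
}

oracle_glcm <- function(lv, B) {
    dm <- dim(lv)
    out <- list()
    for (r in seq_len(nrow(oracle_dirs))) {
        dd <- oracle_dirs[r, ]
        m <- matrix(0, B, B)
        for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
            for (k in seq_len(dm[3])) {
                if (is.na(lv[i, j, k])) next
                i2 <- i + dd[1]; j2 <- j + dd[2]; k2 <- k + dd[3]
                if (i2 < 1 || i2 > dm[1] || j2 < 1 || j2 > dm[2] ||
                    k2 < 1 || k2 > dm[3]) next
                if (is.na(lv[i2, j2, k2])) next
                a <- lv[i, j, k]; b <- lv[i2, j2, k2]
                m[a, b] <- m[a, b] + 1
                m[b, a] <- m[b, a] + 1
            }
        if (sum(m) > 0) out[[length(out) + 1L]] <- m / sum(m)
    }
    out
}

oracle_glcm_features <- function(lv, B) {
    ps <- oracle_glcm(lv, B)
    asm <- sapply(ps, function(p) sum(p^2))
    se <- sapply(ps, function(p) {
        tot <- 0
        for (kk in 2:(2 * B)) {
            pk <- 0
            for (i in 1:B) for (j in 1:B) if (i + j == kk) pk <- pk + p[i, j]
            if (pk > 0) tot <- tot - pk * log(pk)
        }
        tot
    })
    list(asm = mean(asm), sum_entropy = mean(se))
}

oracle_runs <- function(lv) {
    dm <- dim(lv)
    per_dir <- list()
    for (r in seq_len(nrow(oracle_dirs))) {
        dd <- oracle_dirs[r, ]
        runs <- list()
        for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
            for (k in seq_len(dm[3])) {
                ip <- i - dd[1]; jp <- j - dd[2]; kp <- k - dd[3]
                if (ip >= 1 && ip <= dm[1] && jp >= 1 && jp <= dm[2] &&
                    kp >= 1 && kp <= dm[3]) next  # not a line start
                ci <- i; cj <- j; ck <- k
                line <- c()
                while (ci >= 1 && ci <= dm[1] && cj >= 1 && cj <= dm[2] &&
                       ck >= 1 && ck <= dm[3]) {
                    line <- c(line, lv[ci, cj, ck])
                    ci <- ci + dd[1]; cj <- cj + dd[2]; ck <- ck + dd[3]
                }
                q <- 1
                while (q <= length(line)) {
                    if (is.na(line[q])) { q <- q + 1; next }
                    e <- q
                    while (e + 1 <= length(line) && !is.na(line[e + 1]) &&
                           line[e + 1] == line[q]) e <- e + 1
                    runs[[length(runs) + 1L]] <- c(line[q], e - q + 1)
                    q <- e + 1
                }
            }
        per_dir[[r]] <- do.call(rbind, runs)
    }
    per_dir
}

oracle_glrlm_features <- function(lv) {
    rl <- oracle_runs(lv)
    rlnu_d <- sapply(rl, function(m) {
        nr <- nrow(m)
        sum(table(m[, 2])^2) / nr
    })
    hglre_d <- sapply(rl, function(m) sum(m[, 1]^2) / nrow(m))
    list(rlnu = mean(rlnu_d), hglre = mean(hglre_d))
}

# flood-fill zones (26-connectivity)
oracle_zones <- function(lv) {
    dm <- dim(lv)
    seen <- array(FALSE, dm)
    zones <- list()
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
        for (k in seq_len(dm[3])) {
            if (is.na(lv[i, j, k]) || seen[i, j, k]) next
            g <- lv[i, j, k]
            stack <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
            while (length(stack)) {
                c0 <- stack[[length(stack)]]
                stack[[length(stack)]] <- NULL
                size <- size + 1
                for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
                    if (dx == 0 && dy == 0 && dz == 0) next
                    ni <- c0[1] + dx; nj <- c0[2] + dy; nk <- c0[3] + dz
                    if (ni < 1 || ni > dm[1] || nj < 1 || nj > dm[2] ||
                        nk < 1 || nk > dm[3]) next
                    if (seen[ni, nj, nk] || is.na(lv[ni, nj, nk])) next
                    if (lv[ni, nj, nk] != g) next
                    seen[ni, nj, nk] <- TRUE
                    stack[[length(stack) + 1L]] <- c(ni, nj, nk)
                }
            }
            zones[[length(zones) + 1L]] <- c(g, size)
        }
    do.call(rbind, zones)
}

oracle_glszm_features <- function(lv) {
    z <- oracle_zones(lv)
    nz <- nrow(z)
    list(zsnu = sum(table(z[, 2])^2) / nz,
         hglze = sum(z[, 1]^2) / nz,
         n_zones = nz)
}

# wrap an integer level array as a DiscretizedVOI for the package side
as_voi <- function(lv, B, spacing = c(1, 1, 1)) {
    storage.mode(lv) <- "integer"
    new("DiscretizedVOI", levels = lv, nBins = as.integer(B),
        binEdges = seq(0, 1, length.out = B + 1L),
        spacing = spacing)
}

# random discretized grid with optional masked-out voxels
random_voi_array <- function(dm, B, p_na = 0) {
    lv <- array(sample.int(B, prod(dm), replace = TRUE), dm)
    if (p_na > 0) {
        drop <- stats::runif(prod(dm)) < p_na
        if (all(drop)) drop[1] <- FALSE
        lv[drop] <- NA_integer_
    }
    lv
}
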