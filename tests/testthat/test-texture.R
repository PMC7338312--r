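test_that("intensity entropy matches hand computations", {
    expect_equal(intensityEntropy(list(p = c(1, 0, 0))), 0)
    expect_equal(intensityEntropy(list(p = rep(1 / 16, 16))), log(16))
    expect_equal(intensityEntropy(list(p = c(2, 1, 1) / 4)),
                 -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("GLCM of the row 1,1,2 matches pair enumeration", {
    lv <- array(c(1L, 1L, 2L), c(3, 1, 1))
    voi <- as_voi(lv, 2)
    g <- buildGLCM(voi)   # only the x direction has pairs
    expect_length(g$p, 1L)
    expect_equal(g$p[[1]],
                 matrix(c(0.5, 0.25, 0.25, 0), 2, 2), ignore_attr = TRUE)
    expect_equal(glcmASM(g), 0.375)
    expect_equal(glcmSumEntropy(g), log(2))
})

test_that("a constant VOI gives the degenerate texture limits", {
    lv <- array(1L, c(3, 3, 3))
    voi <- as_voi(lv, 16)
    g <- buildGLCM(voi)
    expect_true(all(vapply(g$p, function(p) p[1, 1], numeric(1)) == 1))
    expect_equal(glcmASM(g), 1)
    expect_equal(glcmSumEntropy(g), 0)
    sz <- buildGLSZM(voi)
    expect_equal(zsnu(sz), 1)
    expect_equal(hglze(sz), 1)
    lv4 <- array(4L, c(2, 2, 2))
    expect_equal(hglze(buildGLSZM(as_voi(lv4, 4))), 16)  # level squared
})

test_that("GLRLM of the row 1,1,2 matches run enumeration per direction", {
    lv <- array(c(1L, 1L, 2L), c(3, 1, 1))
    rl <- buildGLRLM(as_voi(lv, 2))
    # the direction along x has runs (level 1, length 2), (level 2, length 1)
    xdir <- Filter(function(m) ncol(m) == 2, rl$r)
    expect_length(xdir, 1L)
    expect_equal(xdir[[1]],
                 matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
    nr <- sum(xdir[[1]])
    expect_equal(sum(colSums(xdir[[1]])^2) / nr, 1)         # RLNU
    expect_equal(sum(c(1, 4) * rowSums(xdir[[1]])) / nr, 2.5)  # HGLRE
})

test_that("GLSZM of the row 1,1,2 matches zone enumeration", {
    lv <- array(c(1L, 1L, 2L), c(3, 1, 1))
    sz <- buildGLSZM(as_voi(lv, 2))
    expect_equal(zsnu(sz), 1)
    expect_equal(hglze(sz), 2.5)
})

test_that("voxel conservation holds for run and zone matrices", {
    set.seed(21)
    for (rep in 1:5) {
        lv <- random_voi_array(c(4, 4, 4), B = 4, p_na = 0.15)
        nvox <- sum(!is.na(lv))
        rl <- buildGLRLM(as_voi(lv, 4))
        for (m in rl$r)
            expect_equal(sum(seq_len(ncol(m)) * colSums(m)), nvox)
        sz <- buildGLSZM(as_voi(lv, 4))
        expect_equal(sum(seq_len(ncol(sz$s)) * colSums(sz$s)), nvox)
    }
})

test_that("GLCM probabilities normalize and entropy respects its bounds", {
    set.seed(22)
    for (rep in 1:5) {
        lv <- random_voi_array(c(5, 4, 3), B = 6, p_na = 0.1)
        g <- buildGLCM(as_voi(lv, 6))
        for (p in g$p) {
            expect_equal(sum(p), 1)
            expect_equal(p, t(p))
        }
        H <- intensityEntropy(as_voi(lv, 6))
        expect_gte(H, 0)
        expect_lte(H, log(6))
    }
})

test_that("mirroring the VOI leaves texture features unchanged", {
    set.seed(23)
    lv <- random_voi_array(c(4, 4, 4), B = 4)
    mir <- lv[4:1, , ]
    f1 <- c(glcmASM(buildGLCM(as_voi(lv, 4))),
            glcmSumEntropy(buildGLCM(as_voi(lv, 4))),
            rlnu(buildGLRLM(as_voi(lv, 4))),
            hglre(buildGLRLM(as_voi(lv, 4))),
            zsnu(buildGLSZM(as_voi(lv, 4))),
            hglze(buildGLSZM(as_voi(lv, 4))))
    f2 <- c(glcmASM(buildGLCM(as_voi(mir, 4))),
            glcmSumEntropy(buildGLCM(as_voi(mir, 4))),
            rlnu(buildGLRLM(as_voi(mir, 4))),
            hglre(buildGLRLM(as_voi(mir, 4))),
            zsnu(buildGLSZM(as_voi(mir, 4))),
            hglze(buildGLSZM(as_voi(mir, 4))))
    expect_equal(f1, f2)
})

test_that("gray-level reversal preserves the symmetric features only", {
    set.seed(24)
    B <- 5L
    lv <- random_voi_array(c(4, 4, 4), B)
    rev_lv <- array(B + 1L - lv, dim(lv))
    expect_equal(glcmASM(buildGLCM(as_voi(lv, B))),
                 glcmASM(buildGLCM(as_voi(rev_lv, B))))
    expect_equal(rlnu(buildGLRLM(as_voi(lv, B))),
                 rlnu(buildGLRLM(as_voi(rev_lv, B))))
    expect_equal(zsnu(buildGLSZM(as_voi(lv, B))),
                 zsnu(buildGLSZM(as_voi(rev_lv, B))))
    expect_equal(intensityEntropy(as_voi(lv, B)),
                 intensityEntropy(as_voi(rev_lv, B)))
    # i^2-weighted features change under reversal (unless symmetric by luck)
    expect_false(isTRUE(all.equal(
        hglre(buildGLRLM(as_voi(lv, B))),
        hglre(buildGLRLM(as_voi(rev_lv, B))))))
})

test_that("zone labelling agrees with a flood-fill oracle on random grids", {
    set.seed(25)
    for (rep in 1:8) {
        lv <- random_voi_array(c(5, 5, 5), B = 3, p_na = 0.1)
        got <- buildGLSZM(as_voi(lv, 3))
        want <- oracle_glszm_features(lv)
        expect_equal(sum(got$s), want$n_zones)
        expect_equal(zsnu(got), want$zsnu)
        expect_equal(hglze(got), want$hglze)
    }
})

test_that("all texture features equal the naive enumerator on random grids", {
    set.seed(26)
    for (rep in 1:12) {
        lv <- random_voi_array(c(4, 4, 4), B = 4,
                               p_na = ifelse(rep %% 3 == 0, 0.2, 0))
        voi <- as_voi(lv, 4)
        oc <- oracle_glcm_features(lv, 4)
        expect_equal(glcmASM(buildGLCM(voi)), oc$asm)
        expect_equal(glcmSumEntropy(buildGLCM(voi)), oc$sum_entropy)
        orl <- oracle_glrlm_features(lv)
        rl <- buildGLRLM(voi)
        expect_equal(rlnu(rl), orl$rlnu)
        expect_equal(hglre(rl), orl$hglre)
        expect_equal(intensityEntropy(voi), oracle_entropy(lv))
    }
})

test_that("extractFeatures composes all ten parameters deterministically", {
    ph <- generatePhantom(phantomSpec(heterogeneity = 0.4, seed = 9))
    f1 <- extractFeatures(ph$image, ph$truth)
    f2 <- extractFeatures(ph$image, ph$truth)
    expect_identical(f1, f2)
    expect_named(f1, c(petFeatureNames(), "n_voxels", "small_lesion"))
    expect_gt(f1$matv, 0)
    expect_gte(f1$asphericity, 0)
    expect_true(f1$glcm_asm > 0 && f1$glcm_asm <= 1)
    expect_true(f1$intensity_entropy >= 0 &&
                f1$intensity_entropy <= log(16))
})

test_that("thin VOIs drop pairless directions from the GLCM average", {
    lv <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
    expect_message(g <- buildGLCM(as_voi(lv, 2)), "12 of 13")
    expect_length(g$p, 1L)
})
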