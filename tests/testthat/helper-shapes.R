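# Voxelized geometric shapes used across tests.

voxel_sphere <- function(radius_mm, spacing_mm, margin = 4L) {
    n <- ceiling(2 * radius_mm / spacing_mm) + 2L * margin
    ctr <- (n + 1) / 2
    x <- (seq_len(n) - ctr) * spacing_mm
    d <- sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
    d <= radius_mm
}

voxel_box <- function(a, b = a, c = a, margin = 4L) {
    m <- array(FALSE, c(a, b, c) + 2L * margin)
    m[margin + seq_len(a), margin + seq_len(b), margin + seq_len(c)] <- TRUE
    m
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# training-style cohort with both risk factors active, for prognostic tests
risk_cohort <- function(n = 300, seed = 1, ...) {
    cc <- generateCohort(cohortConfig(n_total = n, seed = seed, ...))
    df <- cc$cohort
    df$pet_high_risk <- assignPETSubgroup(df) == 3L
    df$clinical_flag <- df$ecog2 | df$n2c3
    df
}
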