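test_that("rocScreen handles perfect separation", {
    s <- rocScreen(c(1, 2, 3, 4), c(0, 0, 1, 1))
    expect_equal(s$c_index, 1)
    expect_gt(s$youden_cutoff, 2)
    expect_lte(s$youden_cutoff, 3)
    expect_equal(s$sensitivity, 1)
    expect_equal(s$specificity, 1)
    expect_error(rocScreen(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("rocScreen AUC equals the Mann-Whitney identity", {
    set.seed(31)
    for (rep in 1:5) {
        x <- rnorm(60)
        y <- rbinom(60, 1, 0.4)
        if (length(unique(y)) < 2) next
        auc <- rocScreen(x, y)$c_index
        n1 <- sum(y == 1); n0 <- sum(y == 0)
        u <- mannWhitney(x[y == 1], x[y == 0])$U
        expect_equal(max(u, n1 * n0 - u) / (n1 * n0), auc, tolerance = 1e-10)
    }
})

test_that("rocScreen is unbiased under the null", {
    set.seed(32)
    aucs <- replicate(60, rocScreen(rnorm(500),
                                    rbinom(500, 1, 0.5))$c_index)
    expect_gte(mean(aucs >= 0.5), 1)  # orientation keeps AUC >= 0.5
    expect_lte(stats::quantile(aucs, 0.95), 0.57)
})

test_that("the Bonferroni gate keeps p below alpha over m", {
    sel <- data.frame(feature = c("a", "b", "c"),
                      p_value = c(0.007, 0.011, 0.0099))
    kept <- bonferroniGate(sel, alpha = 0.10, m = 10)
    expect_setequal(kept$feature, c("a", "c"))
    expect_equal(nrow(bonferroniGate(sel, alpha = 0.05, m = 1)), 3L)
})

test_that("log-rank statistics behave on degenerate and separated data", {
    tm <- c(3, 5, 8, 12, 20, 24); ev <- c(1, 1, 0, 1, 1, 0)
    r <- kmLogrank(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
    expect_equal(r$chisq, 0, tolerance = 1e-12)
    expect_equal(r$p, 1)
    r2 <- kmLogrank(c(1:10, 101:110), rep(1, 20), rep(c("a", "b"), each = 10))
    expect_lt(r2$p, 0.001)
    # KM at t beyond the last event with no censoring = empirical fraction
    fit <- kmLogrank(c(2, 4, 6, 8), c(1, 1, 1, 0), rep("a", 4))$fit
    s <- summary(fit, times = 7)$surv
    expect_equal(s, 0.25)
})

test_that("bootstrap Cox recovers a configured hazard ratio", {
    cc <- generateCohort(cohortConfig(n_total = 2000, seed = 5))
    df <- cc$cohort
    df$pet <- cc$truth$pet_high_risk
    df$clin <- cc$truth$clinical_flag
    fit <- coxBootstrap(df, "os_time", "os_event", c("pet", "clin"),
                        n_boot = 80, seed = 2)
    expect_lt(abs(log(fit$table$hr[1]) - log(6.30)) / log(6.30), 0.10)
    expect_true(all(fit$table$ci_low <= fit$table$hr &
                    fit$table$hr <= fit$table$ci_high))
    expect_lt(fit$table$p_value[1], 0.05)
    expect_true(all(is.finite(fit$table$schoenfeld_p)))
})

test_that("duplicating every record leaves the point estimate unchanged", {
    cc <- generateCohort(cohortConfig(n_total = 150, seed = 8))
    df <- cc$cohort
    df$pet <- cc$truth$pet_high_risk
    f1 <- coxBootstrap(df, "os_time", "os_event", "pet", n_boot = 10,
                       seed = 1)
    f2 <- coxBootstrap(rbind(df, df), "os_time", "os_event", "pet",
                       n_boot = 10, seed = 1)
    expect_equal(f1$table$hr, f2$table$hr, tolerance = 1e-6)
})

test_that("bootstrap CIs cover a null effect at the nominal rate", {
    set.seed(33)
    cover <- vapply(1:30, function(sd) {
        cc <- generateCohort(cohortConfig(n_total = 200, seed = 5000 + sd,
                                          loghr_pet_os = 0))
        df <- cc$cohort
        df$pet <- cc$truth$pet_high_risk
        fit <- coxBootstrap(df, "os_time", "os_event", "pet", n_boot = 99,
                            seed = sd)
        fit$table$ci_low[1] <= 1 && 1 <= fit$table$ci_high[1]
    }, logical(1))
    expect_gte(mean(cover), 0.9)
})

test_that("a seeded bootstrap is reproducible and warns on few events", {
    cc <- generateCohort(cohortConfig(n_total = 60, seed = 12))
    df <- cc$cohort
    df$pet <- cc$truth$pet_high_risk
    a <- coxBootstrap(df, "os_time", "os_event", "pet", n_boot = 25, seed = 9)
    b <- coxBootstrap(df, "os_time", "os_event", "pet", n_boot = 25, seed = 9)
    expect_identical(a$table, b$table)
    few <- df[1:8, ]
    w <- capture_warnings(
        coxBootstrap(few, "os_time", "os_event",
                     c("pet", "age", "smoking", "surgery"),
                     n_boot = 5, seed = 1))
    expect_true(any(grepl("events", w)))
})

test_that("Schoenfeld p-values are near-uniform when hazards are proportional", {
    ps <- vapply(1:100, function(sd) {
        cc <- generateCohort(cohortConfig(n_total = 120, seed = 6000 + sd))
        df <- cc$cohort
        df$pet <- cc$truth$pet_high_risk
        fit <- survival::coxph(
            survival::Surv(os_time, os_event) ~ pet, data = df)
        survival::cox.zph(fit)$table["pet", "p"]
    }, numeric(1))
    ks <- stats::ks.test(ps, "punif")
    expect_gt(ks$p.value, 0.01)
})

test_that("C-index conventions: perfect score, ties and self-comparison", {
    y <- c(0, 0, 1, 1, 0, 1)
    expect_equal(cIndex(y, y), 1)
    expect_equal(cIndex(y, rep(2, 6)), 0.5)
    cmp <- compareCIndex(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6), y)
    expect_equal(cmp$delta, 0)
    expect_equal(cmp$p, 1)
    # Harrell's option on time-to-event data
    cc <- generateCohort(cohortConfig(n_total = 200, seed = 14))
    df <- cc$cohort
    ch <- cIndex(df$os_time, as.numeric(cc$truth$pet_high_risk),
                 method = "harrell", events = df$os_event)
    expect_gt(ch, 0.6)
})

test_that("the paired C-index comparison holds its type-I error", {
    set.seed(34)
    ps <- replicate(200, {
        y <- rbinom(80, 1, 0.4)
        if (length(unique(y)) < 2) return(NA_real_)
        a <- rnorm(80); b <- rnorm(80)
        compareCIndex(a, b, y)$p
    })
    ps <- ps[!is.na(ps)]
    expect_lt(mean(ps < 0.05), 0.10)
})
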