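test_that("PET subgroups follow the two-cutoff rule with lower-risk boundaries", {
    expect_equal(assignPETSubgroup(5.0, entropy = 2.9), 1L)
    expect_equal(assignPETSubgroup(7.0, entropy = 2.4), 2L)
    expect_equal(assignPETSubgroup(7.0, entropy = 2.6), 3L)
    # boundary values fall on the lower-risk side
    expect_equal(assignPETSubgroup(6.67, entropy = 3.0), 1L)
    expect_equal(assignPETSubgroup(7.0, entropy = 2.50), 2L)
    # entropy is irrelevant below the SUVmax cutoff
    expect_equal(assignPETSubgroup(data.frame(suv_max = 5,
                                              intensity_entropy = NA)), 1L)
    expect_error(assignPETSubgroup(data.frame(suv_max = 7,
                                              intensity_entropy = NA)),
                 "unclassifiable")
})

test_that("conditional cutoffs are recovered from a strong-effect cohort", {
    cc <- generateCohort(cohortConfig(n_total = 300, seed = 211,
                                      prev_ecog2 = 0, prev_n2c3 = 0,
                                      base_hazard_os = 2e-4,
                                      loghr_pet_os = 6.8))
    pat <- deriveConditionalCutoff(cc$cohort)
    expect_s4_class(pat, "PETRiskPattern")
    expect_setequal(c(pat@primaryFeature, pat@secondaryFeature),
                    c("suv_max", "intensity_entropy"))
    suvc <- if (pat@primaryFeature == "suv_max") pat@primaryCutoff
            else pat@secondaryCutoff
    entc <- if (pat@primaryFeature == "intensity_entropy") pat@primaryCutoff
            else pat@secondaryCutoff
    expect_lt(abs(suvc - 6.67), 0.4)
    expect_lt(abs(entc - 2.50), 0.06)
})

test_that("shifting the primary feature shifts its recovered cutoff equally", {
    cc <- generateCohort(cohortConfig(n_total = 200, seed = 212,
                                      prev_ecog2 = 0, prev_n2c3 = 0,
                                      base_hazard_os = 2e-4,
                                      loghr_pet_os = 6.8))
    df <- cc$cohort
    s1 <- rocScreen(df$suv_max, df$os_event, "suv_max")
    s2 <- rocScreen(df$suv_max + 3.5, df$os_event, "suv_max")
    expect_equal(s2$youden_cutoff, s1$youden_cutoff + 3.5)
})

test_that("pure-noise features yield no PET rule", {
    nulls <- vapply(1:25, function(sd) {
        cc <- generateCohort(cohortConfig(n_total = 45, seed = 7000 + sd,
                                          loghr_pet_os = 0,
                                          loghr_clin_os = 0,
                                          base_hazard_os = 0.006))
        is.null(suppressMessages(deriveConditionalCutoff(cc$cohort)))
    }, logical(1))
    expect_gte(mean(nulls), 0.8)
})

test_that("the partition tree finds a single active factor", {
    set.seed(41)
    n <- 120
    pet <- rep(c(TRUE, FALSE), each = n / 2)
    tm <- ifelse(pet, rexp(n, 0.15), rexp(n, 0.01))
    cens <- runif(n, 30, 120)
    df <- data.frame(pet_high_risk = pet,
                     clinical_flag = rbinom(n, 1, 0.2) == 1,
                     os_time = pmin(tm, cens),
                     os_event = as.integer(tm <= cens))
    m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"), seed = 3)
    expect_false(m@tree$leaf)
    expect_equal(m@tree$variable, "pet_high_risk")
    cls <- classifyPatients(m, data.frame(pet_high_risk = c(TRUE, FALSE),
                                          clinical_flag = FALSE))
    expect_equal(cls, c("poor", "good"))
})

test_that("the fitted index reproduces the two-factor poor-prognosis rule", {
    df <- risk_cohort(n = 300, seed = 42)
    m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"), seed = 5)
    expect_true(isTwoFactorRule(m))
    # monotonicity: moving a patient to higher risk never improves the class
    grid <- expand.grid(pet_high_risk = c(FALSE, TRUE),
                        clinical_flag = c(FALSE, TRUE))
    cls <- classifyPatients(m, grid)
    expect_equal(cls[1], "good")
    expect_true(all(cls[2:4] == "poor"))
    # permuting patient order with the same seed gives the same tree
    m2 <- buildRPATree(df[sample.int(nrow(df)), ],
                       c("pet_high_risk", "clinical_flag"), seed = 5)
    expect_equal(classifyPatients(m2, grid), cls)
    expect_true(all(m@cv$stability[m@cv$variable == "pet_high_risk"] >= 0.8))
})

test_that("a training cohort built to the published margins yields 15 poor", {
    # 45 patients: 13 in subgroup 3; 2 clinical-flag carriers outside it
    set.seed(43)
    s3 <- c(rep(TRUE, 13), rep(FALSE, 32))
    clin <- c(rep(FALSE, 13), rep(TRUE, 2), rep(FALSE, 30))
    risk <- s3 | clin
    tm <- ifelse(risk, rexp(45, 0.12), rexp(45, 0.004))
    cens <- runif(45, 40, 120)
    df <- data.frame(pet_high_risk = s3, clinical_flag = clin,
                     os_time = pmin(tm, cens),
                     os_event = as.integer(tm <= cens))
    m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"),
                      min_leaf = 2L, seed = 7)
    expect_true(isTwoFactorRule(m))
    expect_equal(sum(classifyPatients(m, df) == "poor"), 15L)
})

test_that("degenerate cohorts give a flagged single-leaf model", {
    set.seed(44)
    df <- data.frame(pet_high_risk = rbinom(60, 1, 0.4) == 1,
                     clinical_flag = rbinom(60, 1, 0.2) == 1,
                     os_time = rexp(60, 0.02) + 1,
                     os_event = rbinom(60, 1, 0.4))
    expect_message(m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"),
                                     seed = 2),
                   "single-leaf")
    expect_true(m@tree$leaf)
})

test_that("classification errors name missing predictors", {
    df <- risk_cohort(n = 200, seed = 45)
    m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"), seed = 1)
    expect_error(classifyPatients(m, data.frame(pet_high_risk = TRUE)),
                 "clinical_flag")
})

test_that("models survive a JSON round trip", {
    df <- risk_cohort(n = 250, seed = 46)
    m <- buildRPATree(df, c("pet_high_risk", "clinical_flag"), seed = 11)
    path <- tempfile(fileext = ".json")
    writeModelJSON(m, path)
    m2 <- readModelJSON(path)
    grid <- expand.grid(pet_high_risk = c(FALSE, TRUE),
                        clinical_flag = c(FALSE, TRUE))
    expect_equal(classifyPatients(m2, grid), classifyPatients(m, grid))
    expect_equal(m2@pattern@primaryCutoff, m@pattern@primaryCutoff)
    unlink(path)
})
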