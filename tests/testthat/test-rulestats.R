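test_that("hypergeometric tails match exact enumeration and edge cases", {
    expect_equal(rulePValue(10, 5, 5, 0), 1.0)
    expect_equal(rulePValue(10, 5, 5, 5), 1 / choose(10, 5))
    expect_equal(rulePValue(8, 8, 3, 3), 1.0)   # one-class population
    expect_equal(rulePValue(10, 5, 5, 5), hyperTailEnum(10, 5, 5, 5))
    expect_equal(rulePValue(9, 4, 6, 3), hyperTailEnum(9, 4, 6, 3))
    expect_error(rulePValue(10, 5, 11, 3), "inconsistent")
    expect_error(rulePValue(10, 5, 5, 6), "inconsistent")
    expect_error(rulePValue(10, 11, 5, 3), "inconsistent")
})

test_that("the tail probability is non-increasing in k", {
    for (N in c(8, 12)) {
        for (K in c(3, 6)) {
            for (n in c(2, 5)) {
                p <- vapply(0:min(n, K), function(k)
                    rulePValue(N, K, n, k), numeric(1))
                expect_true(all(diff(p) <= 1e-12))
            }
        }
    }
})

mkModel <- function(rules, sizes) {
    new("RuleModel", rules = rules, classLabels = names(sizes),
        classSizes = sizes, nTotal = sum(sizes))
}

test_that("rule filtering applies all three thresholds as stated", {
    sizes <- c(fetus = 30L, older = 70L)
    rules <- data.frame(
        conditions = I(list(c(cgA = "unmethylated"),
                            c(cgB = "methylated"),
                            c(cgC = "intermediate"),
                            c(cgD = "methylated"))),
        decision = c("fetus", "fetus", "fetus", "older"),
        accuracy = c(0.75, 0.9, 0.9, 0.95),
        support = c(20L, 15L, 14L, 40L),
        n_runs = 1L)
    model <- scoreRules(mkModel(rules, sizes))
    filt <- modelRules(filterRules(model))
    keys <- vapply(filt$conditions, function(cc) names(cc)[1], character(1))
    expect_false("cgA" %in% keys)   # accuracy 0.75 exactly: strict >
    expect_true("cgB" %in% keys)    # support 15 = half of class 30: kept
    expect_false("cgC" %in% keys)   # support 14 < 15
    expect_true("cgD" %in% keys)
})

test_that("Bonferroni scales raw p-values by the model size", {
    sizes <- c(a = 20L, b = 20L)
    one <- data.frame(conditions = I(list(c(cgA = "methylated"))),
                      decision = "a", accuracy = 1.0, support = 15L,
                      n_runs = 1L)
    rules <- do.call(rbind, rep(list(one), 100))
    rules$conditions <- I(lapply(1:100, function(i)
        setNames("methylated", paste0("cg", i))))
    model <- scoreRules(mkModel(rules, sizes))
    sc <- modelRules(model)
    expect_equal(sc$p_bonferroni, pmin(1, sc$p_raw * 100))
    expect_true(all(sc$p_bonferroni >= sc$p_raw))
    # raw p of ~4e-4 scaled by 100 rules stays under alpha = 0.05
    expect_lt(sc$p_raw[1], 5e-4)
    expect_lt(sc$p_bonferroni[1], 0.05)
    expect_identical(nrow(modelRules(filterRules(model))), 100L)
})

test_that("filtering is monotone under threshold relaxation", {
    set.seed(20)
    sizes <- c(a = 12L, b = 18L)
    rules <- data.frame(
        conditions = I(lapply(1:40, function(i)
            setNames(sample(STATES, 1), paste0("cg", i)))),
        decision = sample(names(sizes), 40, replace = TRUE),
        accuracy = runif(40, 0.5, 1),
        support = sample.int(18, 40, replace = TRUE),
        n_runs = 1L)
    rules$support <- pmin(rules$support,
                          as.integer(sizes[rules$decision]))
    model <- scoreRules(mkModel(rules, sizes))
    strict <- nrow(modelRules(filterRules(model, alpha = 0.01,
                                          min_accuracy = 0.9,
                                          support_frac = 0.8)))
    loose <- nrow(modelRules(filterRules(model, alpha = 0.2,
                                         min_accuracy = 0.6,
                                         support_frac = 0.3)))
    expect_lte(strict, loose)
    k_strict <- ruleKeyFrame(modelRules(filterRules(model, alpha = 0.01,
                                                    min_accuracy = 0.9,
                                                    support_frac = 0.8)))
    k_loose <- ruleKeyFrame(modelRules(filterRules(model, alpha = 0.2,
                                                   min_accuracy = 0.6,
                                                   support_frac = 0.3)))
    expect_true(all(k_strict$key %in% k_loose$key))
})

test_that("linear sites pass the regression check", {
    set.seed(4)
    ages <- seq(0, 80, length.out = 40)
    betas <- rbind(lin = 0.2 + 0.006 * ages + rnorm(40, 0, 0.02),
                   flat = runif(40, 0.4, 0.6))
    rownames(betas) <- c("lin", "flat")
    res <- regressionCheck(c(lin = "intermediate"), betas, ages)
    expect_true(res$significant)
    expect_lt(res$p_value, 1e-6)
})

test_that("jointly-informative site pairs escape the linear model", {
    # XOR-style construction: age class flips with the state combination,
    # while each site alone is uncorrelated with age
    set.seed(5)
    n <- 60
    a <- rep(c(0, 1), each = n / 2)
    b <- rep(c(0, 1, 1, 0), each = n / 4)
    young <- xor(a == 1, b == 1)
    ages <- ifelse(young, runif(n, 0, 20), runif(n, 40, 80))
    betas <- rbind(sx = ifelse(a == 1, 0.9, 0.1) + rnorm(n, 0, 0.02),
                   sy = ifelse(b == 1, 0.9, 0.1) + rnorm(n, 0, 0.02))
    betas <- pmin(pmax(betas, 0), 1)
    rownames(betas) <- c("sx", "sy")
    st <- discretizeBeta(betas)
    tab <- decisionTable(st, ifelse(young, "young", "old"))
    model <- scoreRules(combineModels(list(induceRules(tab)), tab))
    filt <- filterRules(model)
    expect_gt(nrow(modelRules(filt)), 0)
    expect_true(all(lengths(modelRules(filt)$conditions) == 2L))
    res <- regressionCheck(c(sx = "methylated", sy = "methylated"),
                           betas, ages)
    expect_false(res$significant)
})

test_that("degenerate regressions warn and report non-significance", {
    betas <- rbind(zv = rep(0.5, 20))
    rownames(betas) <- "zv"
    expect_warning(res <- regressionCheck("zv", betas, 1:20),
                   "zero-variance")
    expect_false(res$significant)
    expect_true(is.na(res$p_value))
    wide <- matrix(runif(50), 10, 5,
                   dimnames = list(paste0("cg", 1:10), NULL))
    expect_error(regressionCheck(paste0("cg", 1:5), wide, 1:5),
                 "more sites")
    expect_error(regressionCheck("cgMISSING", wide, 1:5), "absent")
})

test_that("the model-level regression check annotates every rule", {
    cohort <- simulateCohort(cohortSpec(
        30, c(-0.5, 60), n_noise_sites = 5,
        planted = list(plantedSite("cgS", 0, "up", 0.05, 0.7, 0.02)),
        seed = 6))
    st <- discretizeCohort(cohort)
    tab <- makeBinaryTables(st, sampleAges(cohort), cut_ages = 0L)[[1]]
    model <- scoreRules(combineModels(list(induceRules(tab)), tab))
    checked <- regressionCheckModel(model, cohort)
    rules <- modelRules(checked)
    expect_true(all(c("regression_p", "regression_significant")
                    %in% names(rules)))
    i <- vapply(rules$conditions, function(cc)
        identical(names(cc), "cgS"), logical(1))
    expect_true(any(rules$regression_significant[i]))
})
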