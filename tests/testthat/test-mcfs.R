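smallParams <- function(...) {
    mcfsParams(n_subsets = 60, subset_fraction = 0.5, n_splits = 2,
               n_permutations = 20, seed = 1, ...)
}

test_that("weighted accuracy averages per-class sensitivities", {
    expect_equal(weightedAccuracy(cbind(correct = c(5, 7),
                                        total = c(5, 7))), 1.0)
    expect_equal(weightedAccuracy(cbind(correct = c(10, 0),
                                        total = c(10, 10))), 0.5)
    # imbalance compensation: dumping all into the majority scores 0.5
    expect_equal(weightedAccuracy(cbind(correct = c(90, 0),
                                        total = c(90, 10))), 0.5)
    conf <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("a", "b")))
    expect_equal(weightedAccuracy(conf), mean(c(8 / 10, 9 / 10)))
    expect_error(weightedAccuracy(cbind(correct = integer(),
                                        total = integer())), "empty")
})

test_that("a constant feature earns zero importance and no significance", {
    set.seed(2)
    st <- rbind(const = rep("intermediate", 24),
                sig = rep(c("unmethylated", "methylated"), each = 12),
                noise = sample(STATES, 24, replace = TRUE))
    tab <- decisionTable(st, rep(c("young", "old"), each = 12))
    res <- runMCFS(tab, smallParams())
    expect_identical(unname(res@ri["const"]), 0)
    expect_gte(res@pValue[["const"]], res@params$alpha)
    expect_false("const" %in% significantFeatures(res))
    expect_true("sig" %in% significantFeatures(res))
    expect_equal(max(res@riNorm), 1)
    expect_true(all(res@ri >= 0) && all(res@riNorm >= 0) &&
                all(res@riNorm <= 1))
})

test_that("MCFS is deterministic under a fixed seed", {
    tab <- randomTable(c(10, 10), 6, seed = 5)
    r1 <- runMCFS(tab, smallParams())
    r2 <- runMCFS(tab, smallParams())
    expect_identical(r1@ri, r2@ri)
    expect_identical(significantFeatures(r1), significantFeatures(r2))
})

test_that("relabeling feature ids permutes importances identically", {
    tab <- randomTable(c(8, 8), 5, seed = 11)
    r1 <- runMCFS(tab, smallParams())
    renamed <- decisionTable(t(featureStates(tab)), tab@decision)
    colnames(renamed@states) <- paste0("pr_", colnames(tab@states))
    r2 <- runMCFS(renamed, smallParams())
    expect_identical(unname(r1@ri), unname(r2@ri))
    expect_identical(paste0("pr_", names(r1@ri)), names(r2@ri))
})

test_that("streaming RI equals RI recomputed from recorded tree splits", {
    tab <- randomTable(c(6, 6), 4, seed = 3)
    codes <- MethylAgeRules:::.codeStates(featureStates(tab))
    cls <- as.integer(droplevels(tab@decision)) - 1L
    for (uv in list(c(1, 1), c(2, 1.5))) {
        set.seed(8)
        out <- MethylAgeRules:::mcfs_engine_cpp(
            codes, cls, 2L, 40L, 3L, 2L, 0.66, uv[1], uv[2], 2L, TRUE)
        expect_equal(out$ri, riFromRecord(out$trees, 4, uv[1], uv[2]),
                     tolerance = 1e-12)
    }
})

test_that("degenerate tables are rejected", {
    st <- rbind(a = sample(STATES, 8, replace = TRUE))
    expect_error(decisionTable(st, rep("one", 8)), "2 distinct")
    tab <- randomTable(c(4, 4), 3, seed = 1)
    one_feat <- subsetFeatures(tab, "cg01")
    expect_error(runMCFS(one_feat, smallParams()), "2 features")
})

test_that("planted signal outranks noise and weaker effects rank lower", {
    ranksum <- function(high) {
        ranks <- numeric(3)
        for (s in 1:3) {
            planted <- list(plantedSite("cgSIG", 20, "up", 0.1, high, 0.05))
            cohort <- simulateCohort(cohortSpec(
                60, c(-0.5, 60), n_noise_sites = 40, planted = planted,
                seed = 100 + s))
            st <- discretizeCohort(cohort)
            tab <- makeBinaryTables(st, sampleAges(cohort), cut_ages = 20L)[[1]]
            res <- runMCFS(tab, mcfsParams(n_subsets = 100,
                                           subset_fraction = 0.1,
                                           n_splits = 2, n_permutations = 0,
                                           seed = 1))
            ranks[s] <- rank(-res@ri)[["cgSIG"]]
        }
        mean(ranks)
    }
    strong <- ranksum(0.6)
    weak <- ranksum(0.28)
    expect_lte(strong, 2)       # strong effect is essentially top-ranked
    expect_lte(strong, weak)    # increasing effect never worsens mean rank
})

test_that("per-cut selection returns aligned SFA sets and counts", {
    cohort <- simulateCohort(cohortSpec(
        40, c(-0.5, 60), n_noise_sites = 20,
        planted = list(plantedSite("cgSIG", 25, "up", 0.05, 0.9, 0.02)),
        seed = 12))
    st <- discretizeCohort(cohort)
    tabs <- makeBinaryTables(st, sampleAges(cohort),
                             cut_ages = c(0, 25, 50))
    sel <- selectSignificantPerCut(tabs, smallParams())
    expect_named(sel$sfa, c("cut0", "cut25", "cut50"))
    expect_identical(sel$counts$cut_age, c(0, 25, 50))
    expect_identical(sel$counts$n_significant, lengths(sel$sfa),
                     ignore_attr = TRUE)
    expect_true("cgSIG" %in% sel$sfa$cut25)
    # identical tables give identical SFA sets under the same seed
    sel2 <- selectSignificantPerCut(tabs[c(2, 2)], smallParams())
    expect_identical(sel2$sfa[[1]], sel2$sfa[[2]])
})

test_that("importance tables serialize with the 0/1 significance coding", {
    tab <- randomTable(c(8, 8), 4, seed = 6)
    res <- runMCFS(tab, smallParams())
    path <- tempfile(fileext = ".tsv")
    writeImportanceTable(res, path)
    df <- read.delim(path)
    expect_identical(names(df),
                     c("feature_id", "ri", "ri_norm", "p_value",
                       "significant"))
    expect_true(all(df$significant %in% 0:1))
})
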