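test_that("under-sampling balances every replicate to the smallest class", {
    tab <- randomTable(c(30, 12, 21, 45), 5, seed = 2)
    reps <- underSample(tab, n_reps = 10, seed = 1)
    expect_length(reps, 10L)
    for (r in reps) {
        cls <- table(r@decision)
        expect_true(all(cls == 12L))
        expect_identical(nrow(featureStates(r)), 48L)
    }
    # reproducible but not all identical
    reps2 <- underSample(tab, n_reps = 10, seed = 1)
    expect_identical(lapply(reps, featureStates),
                     lapply(reps2, featureStates))
    expect_gt(length(unique(lapply(reps, featureStates))), 1L)
})

test_that("balanced tables under-sample to themselves", {
    tab <- randomTable(c(8, 8), 4, seed = 3)
    reps <- underSample(tab, n_reps = 3, seed = 5)
    for (r in reps)
        expect_identical(featureStates(r), featureStates(tab))
    tiny <- randomTable(c(1, 5), 3, seed = 1)
    expect_error(underSample(tiny, 2, seed = 1), "fewer than 2")
})

test_that("a separating feature yields perfect singleton rules", {
    st <- rbind(sep = rep(c("unmethylated", "methylated"), c(4, 6)),
                junk = rep("intermediate", 10))
    tab <- decisionTable(st, rep(c("young", "old"), c(4, 6)))
    rules <- induceRules(tab)
    txt <- ruleText(rules)
    expect_true("IF sep=unmethylated THEN 'young' [accuracy=1, support=4]"
                %in% txt)
    expect_true("IF sep=methylated THEN 'old' [accuracy=1, support=6]"
                %in% txt)
    expect_true(all(rules$accuracy == 1))
    expect_true(all(lengths(rules$conditions) == 1L))
})

test_that("contradictory objects yield fractional accuracy, not errors", {
    st <- rbind(f1 = c("unmethylated", "unmethylated", "methylated",
                       "methylated", "unmethylated"),
                f2 = c("intermediate", "intermediate", "methylated",
                       "methylated", "intermediate"))
    # samples 1,2,5 identical; 5 carries the other class
    tab <- decisionTable(st, c("A", "A", "B", "B", "B"))
    rules <- induceRules(tab)
    expect_true(any(abs(rules$accuracy - 2 / 3) < 1e-12))
    expect_true(all(rules$accuracy > 0 & rules$accuracy <= 1))
})

test_that("induced rules equal the brute-force minimal-rule enumeration", {
    # quick random sweep; the deep 100-table sweep runs with the
    # acceptance checks
    for (s in 1:10) {
        set.seed(200 + s)
        sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
        tab <- randomTable(sizes, sample(2:4, 1), seed = 200 + s)
        a <- ruleKeyFrame(induceRules(tab))
        b <- enumerateRulesBrute(tab)
        b <- b[order(b$key), ]
        expect_equal(a$key, b$key)
        expect_equal(a$accuracy, b$accuracy)
        expect_equal(a$support, b$support)
    }
})

test_that("every induced rule is minimal on its induction table", {
    # strict accuracy decrease on condition deletion holds for consistent
    # tables (no identical patterns across classes)
    for (s in 1:5) {
        tab <- randomTable(c(4, 4), 3, seed = 300 + s)
        pat <- apply(featureStates(tab), 1, paste, collapse = "|")
        cls <- decisionClasses(tab)
        n_cls <- tapply(cls, pat, function(x) length(unique(x)))
        keep <- !(pat %in% names(n_cls)[n_cls > 1])
        if (length(unique(cls[keep])) < 2) next
        tab <- decisionTable(t(featureStates(tab)[keep, , drop = FALSE]),
                             cls[keep])
        st <- featureStates(tab)
        dec <- as.character(tab@decision)
        rules <- induceRules(tab)
        for (i in seq_len(nrow(rules))) {
            cc <- rules$conditions[[i]]
            if (length(cc) < 2) next
            for (drop in seq_along(cc)) {
                sub <- cc[-drop]
                m <- vapply(seq_len(nrow(st)), function(r)
                    all(st[r, names(sub)] == sub), logical(1))
                sub_acc <- sum(dec[m] == rules$decision[i]) / sum(m)
                expect_lt(sub_acc, rules$accuracy[i])
            }
        }
    }
})

test_that("johnson reducts are single minimal discerning rules", {
    for (s in 1:5) {
        tab <- randomTable(c(4, 4), 4, seed = 400 + s)
        jr <- induceRules(tab, method = "johnson")
        ex <- ruleKeyFrame(induceRules(tab))
        jk <- ruleKeyFrame(jr)
        expect_true(all(jk$key %in% ex$key))   # subset of the minimal rules
        expect_lte(nrow(jr), nrow(ex))
    }
})

test_that("combination unions rules, counts runs and re-evaluates support", {
    st <- rbind(sep = rep(c("unmethylated", "methylated"), c(30, 78)),
                jnk = sample(STATES, 108, replace = TRUE))
    full <- decisionTable(st, rep(c("fetus", "older"), c(30, 78)))
    reps <- underSample(full, n_reps = 10, seed = 2)
    model <- combineModels(lapply(reps, induceRules), full)
    rules <- modelRules(model)
    key <- vapply(seq_len(nrow(rules)), function(i)
        paste(names(rules$conditions[[i]]), rules$conditions[[i]],
              collapse = "&"), character(1))
    i <- which(key == "sep unmethylated" & rules$decision == "fetus")
    expect_length(i, 1L)
    # support re-evaluated on the full table reaches the whole class
    expect_identical(rules$support[i], 30L)
    expect_identical(rules$accuracy[i], 1)
    expect_identical(rules$n_runs[i], 10L)
    expect_true(all(rules$support >= 1))
    expect_true(all(rules$accuracy > 0 & rules$accuracy <= 1))
})

test_that("voting weighs support times accuracy with documented ties", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "unmethylated"),
                            c(cgB = "methylated"))),
        decision = c("olderThan50", "youngerThan50"),
        accuracy = c(0.95, 1.0), support = c(21L, 30L),
        n_runs = c(1L, 1L))
    model <- new("RuleModel", rules = rules,
                 classLabels = c("olderThan50", "youngerThan50"),
                 classSizes = c(olderThan50 = 40L, youngerThan50 = 60L),
                 nTotal = 100L)
    st <- matrix(c("unmethylated", "methylated"), 2, 1,
                 dimnames = list(c("cgA", "cgB"), "s1"))
    # both rules fire: 21*0.95 = 19.95 < 30*1.0 = 30
    expect_identical(classifySamples(st, model), "youngerThan50")
    only_a <- matrix(c("unmethylated", "intermediate"), 2, 1,
                     dimnames = list(c("cgA", "cgB"), "s1"))
    expect_identical(classifySamples(only_a, model), "olderThan50")
    neither <- matrix("intermediate", 2, 1,
                      dimnames = list(c("cgA", "cgB"), "s1"))
    expect_identical(classifySamples(neither, model), NA_character_)
})

test_that("cross-validation is perfect on a separable cohort", {
    st <- rbind(s1 = rep(c("unmethylated", "intermediate",
                           "methylated", "unmethylated"), each = 10),
                s2 = rep(c("methylated", "methylated",
                           "unmethylated", "intermediate"), each = 10),
                jnk = sample(STATES, 40, replace = TRUE))
    tab <- decisionTable(st, rep(c("fetus", "Age0-4", "Age5-27",
                                   "Age28plus"), each = 10))
    cv <- crossValidate(tab, folds = 5, undersample_reps = 5, seed = 1)
    expect_equal(cv@overallAccuracy, 1.0)
    expect_true(all(cv@counts[, "unclassified"] == 0L))
    expect_identical(unname(rowSums(cv@counts)), rep(10, 4))
})

test_that("fold validation rejects degenerate requests", {
    tab <- randomTable(c(10, 10), 4, seed = 5)
    expect_error(crossValidate(tab, folds = 1), "folds")
    expect_warning(crossValidate(randomTable(c(3, 12), 3, seed = 6),
                                 folds = 10, undersample_reps = 3,
                                 seed = 1),
                   "reducing folds")
})

test_that("rule text and TSV serialization carry the rule statistics", {
    st <- rbind(sep = rep(c("unmethylated", "methylated"), c(4, 6)),
                jnk = rep("intermediate", 10))
    tab <- decisionTable(st, rep(c("young", "old"), c(4, 6)))
    model <- combineModels(list(induceRules(tab)), tab)
    path <- tempfile(fileext = ".tsv")
    ann <- data.frame(probe_id = "sep", chrom = "1", gene = "HAAO",
                      region = "upstream")
    writeRules(model, path, annotations = ann)
    df <- read.delim(path)
    expect_true(all(c("conditions", "decision", "accuracy", "support",
                      "n_runs", "rendered") %in% names(df)))
    expect_match(df$rendered[grep("sep", df$conditions)][1],
                 "sep\\(HAAO_upstream\\)")
})
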