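mkModel2 <- function(rules, sizes) {
    new("RuleModel", rules = rules, classLabels = names(sizes),
        classSizes = sizes, nTotal = sum(sizes))
}

test_that("a single conjunctive rule yields one edge of strength acc*sup", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "intermediate", cgB = "intermediate"))),
        decision = "Age51plus", accuracy = 0.92, support = 25L, n_runs = 1L)
    model <- mkModel2(rules, c(Age51plus = 30L, rest = 70L))
    nw <- buildInteractionNetwork(model, "Age51plus")
    expect_identical(nrow(nw@edges), 1L)
    expect_equal(nw@edges$strength, 23.0)
    expect_identical(nw@edges$n_rules, 1L)
    expect_setequal(nw@nodes, c("cgA=intermediate", "cgB=intermediate"))
})

test_that("edge strengths accumulate over co-occurring rules", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "methylated", cgB = "unmethylated"),
                            c(cgA = "methylated", cgB = "unmethylated",
                              cgC = "intermediate"))),
        decision = c("old", "old"), accuracy = c(0.9, 0.8),
        support = c(10L, 5L), n_runs = 1L)
    model <- mkModel2(rules, c(old = 20L, young = 20L))
    nw <- buildInteractionNetwork(model, "old")
    ab <- nw@edges[nw@edges$cond_a == "cgA=methylated" &
                   nw@edges$cond_b == "cgB=unmethylated", ]
    expect_equal(ab$strength, 0.9 * 10 + 0.8 * 5)
    expect_identical(ab$n_rules, 2L)
    # the 3-condition rule feeds all three of its pairs
    expect_identical(nrow(nw@edges), 3L)
})

test_that("singleton-only models give empty networks, unknown classes err", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "methylated"), c(cgB = "unmethylated"))),
        decision = c("old", "old"), accuracy = c(1, 1),
        support = c(5L, 6L), n_runs = 1L)
    model <- mkModel2(rules, c(old = 10L, young = 10L))
    nw <- buildInteractionNetwork(model, "old")
    expect_identical(nrow(nw@edges), 0L)
    expect_length(nw@nodes, 2L)
    expect_error(buildInteractionNetwork(model, "ancient"), "unknown class")
})

test_that("total strength satisfies the conservation identity", {
    set.seed(9)
    n_rules <- 25
    conds <- lapply(seq_len(n_rules), function(i) {
        len <- sample(1:4, 1)
        setNames(sample(STATES, len, replace = TRUE),
                 sample(paste0("cg", 1:8), len))
    })
    rules <- data.frame(conditions = I(conds),
                        decision = "old",
                        accuracy = runif(n_rules, 0.5, 1),
                        support = sample.int(30, n_rules, replace = TRUE),
                        n_runs = 1L)
    model <- mkModel2(rules, c(old = 40L, young = 40L))
    nw <- buildInteractionNetwork(model, "old")
    expected <- sum(rules$accuracy * rules$support *
                    choose(lengths(rules$conditions), 2))
    expect_equal(sum(nw@edges$strength), expected)
})

test_that("adding a rule never decreases an existing edge's strength", {
    base <- data.frame(
        conditions = I(list(c(cgA = "methylated", cgB = "methylated"))),
        decision = "old", accuracy = 0.8, support = 10L, n_runs = 1L)
    more <- rbind(base, data.frame(
        conditions = I(list(c(cgA = "methylated", cgC = "unmethylated"))),
        decision = "old", accuracy = 0.9, support = 12L, n_runs = 1L))
    sizes <- c(old = 20L, young = 20L)
    e1 <- buildInteractionNetwork(mkModel2(base, sizes), "old")@edges
    e2 <- buildInteractionNetwork(mkModel2(more, sizes), "old")@edges
    for (i in seq_len(nrow(e1))) {
        j <- which(e2$cond_a == e1$cond_a[i] & e2$cond_b == e1$cond_b[i])
        expect_gte(e2$strength[j], e1$strength[i])
    }
})

test_that("top interactions rank by strength with documented tie-breaks", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "methylated", cgB = "methylated"),
                            c(cgC = "methylated", cgD = "methylated"),
                            c(cgE = "methylated", cgF = "methylated"))),
        decision = "old", accuracy = c(0.92, 0.65, 0.5),
        support = c(25L, 20L, 10L), n_runs = 1L)
    model <- mkModel2(rules, c(old = 30L, young = 30L))
    nw <- buildInteractionNetwork(model, "old")
    top <- topInteractions(nw, top_k = 2)
    expect_identical(nrow(top), 2L)
    expect_equal(top$strength, c(23.0, 13.0))
    one <- topInteractions(nw, top_k = 1)
    expect_identical(nrow(one), 1L)
    solo <- buildInteractionNetwork(mkModel2(rules[1, , drop = FALSE],
                                             model@classSizes), "old")
    expect_identical(nrow(topInteractions(solo, 5)), 1L)
})

test_that("interaction tables and DOT files serialize", {
    rules <- data.frame(
        conditions = I(list(c(cgA = "methylated", cgB = "intermediate"))),
        decision = "old", accuracy = 1, support = 10L, n_runs = 1L)
    model <- mkModel2(rules, c(old = 20L, young = 20L))
    nw <- buildInteractionNetwork(model, "old")
    tsv <- tempfile(fileext = ".tsv"); dot <- tempfile(fileext = ".dot")
    writeInteractions(nw, tsv, dot_path = dot)
    df <- read.delim(tsv)
    expect_identical(df$class, "old")
    expect_match(readLines(dot)[2], "--")
})
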