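# Independent oracles and fixture builders shared across tests.

STATES <- c("unmethylated", "intermediate", "methylated")

# random decision table with given class sizes and feature count
randomTable <- function(class_sizes, n_features, seed) {
    set.seed(seed)
    n <- sum(class_sizes)
    st <- matrix(sample(STATES, n * n_features, replace = TRUE),
                 nrow = n_features,
                 dimnames = list(sprintf("cg%02d", seq_len(n_features)),
                                 NULL))
    decisionTable(st, rep(paste0("c", seq_along(class_sizes)), class_sizes))
}

# Brute-force minimal-rule enumerator, independent of the discernibility
# route: a nonempty attribute subset A is sufficient for object o when no
# other-class sample matches o on A unless it matches o on every attribute;
# minimal sufficient subsets instantiated with o's states become rules.
enumerateRulesBrute <- function(table) {
    st <- featureStates(table)
    dec <- as.character(table@decision)
    n <- nrow(st); d <- ncol(st)
    subsets <- unlist(lapply(seq_len(d), function(k)
        combn(d, k, simplify = FALSE)), recursive = FALSE)
    sufficient <- function(o, A) {
        for (i in seq_len(n)) {
            if (dec[i] == dec[o]) next
            if (all(st[i, A] == st[o, A]) && !all(st[i, ] == st[o, ]))
                return(FALSE)
        }
        TRUE
    }
    keys <- character(0); conds <- list(); decs <- character(0)
    for (o in seq_len(n)) {
        if (!any(dec != dec[o])) next
        suff <- Filter(function(A) sufficient(o, A), subsets)
        minimal <- Filter(function(A)
            !any(vapply(suff, function(B)
                length(B) < length(A) && all(B %in% A), logical(1))), suff)
        for (A in minimal) {
            cc <- setNames(st[o, A], colnames(st)[A])
            key <- paste(paste(names(cc)[order(names(cc))],
                               cc[order(names(cc))], sep = "=",
                               collapse = "&"), dec[o], sep = "=>")
            if (!key %in% keys) {
                keys <- c(keys, key)
                conds[[length(conds) + 1L]] <- cc
                decs <- c(decs, dec[o])
            }
        }
    }
    support <- integer(length(conds)); accuracy <- numeric(length(conds))
    for (i in seq_along(conds)) {
        cc <- conds[[i]]
        m <- vapply(seq_len(n), function(s)
            all(st[s, names(cc)] == cc), logical(1))
        support[i] <- sum(m)
        accuracy[i] <- sum(dec[m] == decs[i]) / sum(m)
    }
    data.frame(key = keys, decision = decs, accuracy = accuracy,
               support = support, stringsAsFactors = FALSE)
}

# canonical keyed view of an induceRules() result for set comparison
ruleKeyFrame <- function(rules) {
    keys <- vapply(seq_len(nrow(rules)), function(i) {
        cc <- rules$conditions[[i]]
        o <- order(names(cc))
        paste(paste(names(cc)[o], cc[o], sep = "=", collapse = "&"),
              rules$decision[i], sep = "=>")
    }, character(1))
    out <- data.frame(key = keys, decision = rules$decision,
                      accuracy = rules$accuracy, support = rules$support,
                      stringsAsFactors = FALSE)
    out[order(out$key), ]
}

# Exhaustive hypergeometric right tail: enumerate every size-n draw from a
# population of N samples of which K are class members.
hyperTailEnum <- function(N, K, n, k) {
    if (n == 0) return(as.numeric(k <= 0))
    draws <- combn(N, n)
    hits <- colSums(draws <= K)   # members 1..K are the class
    mean(hits >= k)
}

# Recompute MCFS RI from a recorded list of per-tree splits and accuracies.
riFromRecord <- function(trees, d, u = 1, v = 1) {
    ri <- numeric(d)
    for (tr in trees) {
        if (!length(tr$feature)) next
        contrib <- tapply((tr$ig * tr$frac)^v, tr$feature, sum)
        idx <- as.integer(names(contrib))
        ri[idx] <- ri[idx] + tr$wacc^u * as.numeric(contrib)
    }
    ri
}

# small beta matrix helper
betaMatrix <- function(values, nrow, dimnames = NULL) {
    matrix(values, nrow = nrow, dimnames = dimnames)
}
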