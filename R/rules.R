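#' Under-sampling replicates of a decision table
#'
#' Balances class sizes by keeping every sample of the smallest class
#' and drawing, without replacement, an equally sized random subset from
#' each other class. Repeating the draw gives an ensemble of balanced
#' tables whose rule models are later combined, which avoids biasing the
#' classifier towards the larger classes.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed; replicates differ but the whole ensemble is
#'   reproducible.
#' @return List of \code{n_reps} balanced \linkS4class{DecisionTable}s.
#' @examples
#' st <- matrix(sample(methStates(), 60, TRUE), 20, 3,
#'              dimnames = list(NULL, c("cg1", "cg2", "cg3")))
#' tab <- decisionTable(t(st), rep(c("A", "B"), c(14, 6)))
#' reps <- underSample(tab, n_reps = 5, seed = 1)
#' table(reps[[1]]@decision)
#' @export
underSample <- function(table, n_reps = 100L, seed = 1L) {
    stopifnot(is(table, "DecisionTable"))
    dec <- droplevels(table@decision)
    sizes <- table(dec)
    m <- min(sizes)
    if (m < 2)
        stop("smallest class has fewer than 2 samples; cannot under-sample")
    by_class <- split(seq_along(dec), dec)
    set.seed(seed)
    lapply(seq_len(n_reps), function(r) {
        idx <- sort(unlist(lapply(by_class, function(members) {
            if (length(members) == m) members
            else sample(members, m)
        }), use.names = FALSE))
        .newDecisionTable(table@states[idx, , drop = FALSE], dec[idx],
                          table@cutAge)
    })
}

# canonical key of a rule: sorted conditions plus decision
.ruleKey <- function(conditions, decision) {
    o <- order(names(conditions))
    paste0(paste(names(conditions)[o], conditions[o], sep = "=",
                 collapse = "&"), "=>", decision)
}

# minimize a family of sets: drop duplicates and supersets
.minimizeFamily <- function(family) {
    family <- family[order(lengths(family))]
    keep <- logical(length(family))
    kept <- list()
    for (i in seq_along(family)) {
        s <- family[[i]]
        if (!any(vapply(kept, function(k) all(k %in% s), logical(1)))) {
            keep[i] <- TRUE
            kept[[length(kept) + 1L]] <- s
        }
    }
    family[keep]
}

# all minimal hitting sets of a family of integer sets (attribute indices).
# Branch on the elements of the first (shortest) set, excluding elements
# already tried in sibling branches; a final witness check keeps exactly
# the minimal transversals.
.minimalHittingSets <- function(family) {
    res <- list()
    rec <- function(fam, partial, excluded) {
        if (!length(fam)) {
            res[[length(res) + 1L]] <<- sort(partial)
            return(invisible())
        }
        S <- setdiff(fam[[1L]], excluded)
        for (i in seq_along(S)) {
            e <- S[i]
            fam2 <- fam[!vapply(fam, function(s) e %in% s, logical(1))]
            rec(fam2, c(partial, e), c(excluded, S[seq_len(i - 1L)]))
        }
    }
    rec(family, integer(), integer())
    if (!length(res)) return(res)
    res <- unique(res)
    # minimality: every element needs a witness set hit by it alone
    minimal <- vapply(res, function(h) {
        all(vapply(h, function(e) {
            any(vapply(family, function(s)
                e %in% s && length(intersect(s, h)) == 1L, logical(1)))
        }, logical(1)))
    }, logical(1))
    res[minimal]
}

# one reduct per object via the Johnson greedy set-cover heuristic,
# ties to the lowest attribute index, followed by redundancy pruning
.johnsonReduct <- function(family, attr_names) {
    fam <- family
    chosen <- integer()
    while (length(fam)) {
        cnt <- table(unlist(fam))
        ids <- as.integer(names(cnt))
        best <- ids[cnt == max(cnt)]
        e <- min(best)
        chosen <- c(chosen, e)
        fam <- fam[!vapply(fam, function(s) e %in% s, logical(1))]
    }
    # prune attributes made redundant by later picks
    for (e in rev(chosen)) {
        cand <- setdiff(chosen, e)
        if (length(cand) &&
            all(vapply(family, function(s) any(cand %in% s), logical(1))))
            chosen <- cand
    }
    sort(chosen)
}

#' Induce minimal IF-THEN rules from a decision table
#'
#' For every sample (object), the discernibility family collects, for
#' each sample of a different class, the set of attributes on which the
#' two differ. An attribute set that hits every such set discerns the
#' object from all (discernible) other-class samples; the minimal ones
#' are the object-related reducts. Substituting the object's states
#' into a reduct yields one IF-THEN rule whose decision is the object's
#' class. \code{method = "exhaustive"} (default) enumerates all minimal
#' reducts per object; \code{method = "johnson"} keeps one greedy
#' set-cover reduct per object (faster on large tables, same flavour of
#' rules). Identical rules from different objects are merged, and
#' accuracy (fraction of matching samples in the decision class) and
#' support (number of matching samples) are evaluated on the input
#' table.
#'
#' Contradictory objects (identical states, different classes) are
#' tolerated: pairs that no attribute discerns are skipped, so such
#' objects produce rules with accuracy below 1 rather than an error. An
#' object indistinguishable from every discernible other-class sample
#' (empty family) contributes one singleton rule per attribute.
#'
#' @param table a discretized \linkS4class{DecisionTable} with >= 2
#'   classes.
#' @param method \code{"exhaustive"} or \code{"johnson"}.
#' @param max_reducts per-object cap on enumerated reducts; exceeding it
#'   errors with a pointer to the Johnson method.
#' @return A data.frame of rules: list-column \code{conditions} (named
#'   character vector per rule: probe -> state), \code{decision},
#'   \code{accuracy}, \code{support}.
#' @examples
#' st <- matrix(rep(c("unmethylated", "methylated"), c(6, 6)), 6, 2,
#'              dimnames = list(NULL, c("cgA", "cgB")))
#' tab <- decisionTable(t(st), rep(c("young", "old"), each = 3))
#' induceRules(tab)
#' @export
induceRules <- function(table, method = c("exhaustive", "johnson"),
                        max_reducts = 20000L) {
    method <- match.arg(method)
    stopifnot(is(table, "DecisionTable"))
    st <- featureStates(table)
    dec <- as.character(table@decision)
    if (length(unique(dec)) < 2)
        stop("rule induction needs at least 2 decision classes")
    d <- ncol(st)
    attr_names <- colnames(st)

    if (d <= 64) {
        codes <- .codeStates(st)
        cls <- as.integer(factor(dec)) - 1L
        res <- induce_reducts_cpp(codes, cls, method == "exhaustive",
                                  as.integer(max_reducts))
        obj_red <- Map(function(o, rl) list(o = o, rl = rl),
                       res$objects, res$reducts)
    } else {
        obj_red <- .induceReductsR(st, dec, method, attr_names)
    }

    seen <- new.env(parent = emptyenv(), hash = TRUE)
    conds <- vector("list", 256L); decs <- character(256L); nr <- 0L
    for (entry in obj_red) {
        o <- entry$o
        for (h in entry$rl) {
            cc <- setNames(st[o, h], attr_names[h])
            key <- .ruleKey(cc, dec[o])
            if (is.null(seen[[key]])) {
                seen[[key]] <- TRUE
                nr <- nr + 1L
                if (nr > length(conds)) {
                    length(conds) <- 2L * length(conds)
                    length(decs) <- 2L * length(decs)
                }
                conds[[nr]] <- cc
                decs[nr] <- dec[o]
            }
        }
    }
    conds <- conds[seq_len(nr)]; decs <- decs[seq_len(nr)]
    ev <- .evaluateRules(conds, decs, st, dec)
    data.frame(conditions = I(conds), decision = decs,
               accuracy = ev$accuracy, support = ev$support,
               stringsAsFactors = FALSE)
}

# pure-R reduct computation, used beyond the 64-attribute bitmask limit
.induceReductsR <- function(st, dec, method, attr_names) {
    n <- nrow(st); d <- ncol(st)
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    out <- list()
    for (o in seq_len(n)) {
        okey <- paste(c(st[o, ], dec[o]), collapse = "\r")
        if (!is.null(seen[[okey]])) next
        seen[[okey]] <- TRUE
        other <- which(dec != dec[o])
        diff <- st[other, , drop = FALSE] !=
            matrix(st[o, ], length(other), d, byrow = TRUE)
        family <- lapply(seq_along(other), function(i) which(diff[i, ]))
        family <- family[lengths(family) > 0]
        if (!length(family)) {
            reducts <- as.list(seq_len(d))   # indiscernible object
        } else {
            family <- .minimizeFamily(family)
            reducts <- if (method == "exhaustive")
                .minimalHittingSets(family)
            else list(.johnsonReduct(family, attr_names))
        }
        out[[length(out) + 1L]] <- list(o = o, rl = reducts)
    }
    out
}

# conditions (named state vectors) -> attribute/state index lists
.ruleIndex <- function(conds, feature_names) {
    attrs <- lapply(conds, function(cc) {
        idx <- match(names(cc), feature_names)
        if (anyNA(idx)) stop("rule references unknown feature: ",
                             paste(names(cc)[is.na(idx)], collapse = ", "))
        idx
    })
    states <- lapply(conds, function(cc) match(unname(cc), methStates()) - 1L)
    list(attrs = attrs, states = states)
}

# accuracy/support of rules against a state matrix + labels
.evaluateRules <- function(conds, decs, st, dec) {
    if (!length(conds))
        return(list(support = integer(0), accuracy = numeric(0)))
    codes <- .codeStates(st)
    labels <- sort(unique(dec))
    cls <- match(dec, labels) - 1L
    ri <- .ruleIndex(conds, colnames(st))
    ev <- evaluate_rules_cpp(codes, cls, ri$attrs, ri$states,
                             match(decs, labels) - 1L)
    list(support = ev$support,
         accuracy = ifelse(ev$support > 0, ev$inclass / ev$support, 0))
}

#' Combine per-replicate rule sets into one model
#'
#' Takes the rules induced on each under-sampled replicate, keeps each
#' distinct rule (same conditions and decision) once while counting in
#' how many replicates it appeared (\code{n_runs}), and re-evaluates
#' accuracy and support on the full table — so a perfect fetal
#' singleton rule can reach the full fetal class as its support even
#' though every replicate only saw a subset.
#'
#' @param per_replicate_rules list of rule data.frames from
#'   [induceRules()].
#' @param full_table the \linkS4class{DecisionTable} the replicates were
#'   drawn from.
#' @return A \linkS4class{RuleModel}.
#' @export
combineModels <- function(per_replicate_rules, full_table) {
    stopifnot(is(full_table, "DecisionTable"), length(per_replicate_rules) >= 1)
    st <- featureStates(full_table)
    dec <- as.character(full_table@decision)
    idx_of <- new.env(parent = emptyenv(), hash = TRUE)
    conds <- list(); decs <- character(0); runs <- integer(0)
    for (rep_rules in per_replicate_rules) {
        if (!nrow(rep_rules)) next
        rep_keys <- vapply(seq_len(nrow(rep_rules)), function(i)
            .ruleKey(rep_rules$conditions[[i]], rep_rules$decision[i]),
            character(1))
        for (i in seq_along(rep_keys)) {
            k <- rep_keys[i]
            if (is.null(idx_of[[k]])) {
                idx_of[[k]] <- length(conds) + 1L
                conds[[length(conds) + 1L]] <- rep_rules$conditions[[i]]
                decs <- c(decs, rep_rules$decision[i])
                runs <- c(runs, 0L)
            }
        }
        for (k in unique(rep_keys)) {
            j <- idx_of[[k]]
            runs[j] <- runs[j] + 1L
        }
    }
    n_runs <- runs
    ev <- .evaluateRules(conds, decs, st, dec)
    keep <- ev$support > 0 & ev$accuracy > 0
    rules <- data.frame(conditions = I(conds[keep]), decision = decs[keep],
                        accuracy = ev$accuracy[keep],
                        support = ev$support[keep],
                        n_runs = unname(n_runs[keep]),
                        stringsAsFactors = FALSE)
    sizes <- table(factor(dec, levels = sort(unique(dec))))
    new("RuleModel", rules = rules,
        classLabels = names(sizes),
        classSizes = setNames(as.integer(sizes), names(sizes)),
        nTotal = length(dec))
}

#' Classify samples with a rule model
#'
#' Every rule whose conditions a sample satisfies votes
#' \code{support * accuracy} for its decision class; the class with the
#' largest vote wins. Ties go to the class with more training samples,
#' then to the lexicographically first label. A sample no rule fires on
#' is unclassified (\code{NA}).
#'
#' @param states character state matrix (probes x samples) or a
#'   \linkS4class{DecisionTable}.
#' @param model a \linkS4class{RuleModel}.
#' @return Character vector of predicted class labels (\code{NA} =
#'   unclassified), one per sample.
#' @export
classifySamples <- function(states, model) {
    stopifnot(is(model, "RuleModel"))
    st <- if (is(states, "DecisionTable")) featureStates(states)
          else t(states)
    rules <- model@rules
    labels <- model@classLabels
    # rules referencing probes absent from the sample table cannot fire
    usable <- vapply(rules$conditions, function(cc)
        all(names(cc) %in% colnames(st)), logical(1))
    rules <- rules[usable, , drop = FALSE]
    if (nrow(rules)) {
        ri <- .ruleIndex(rules$conditions, colnames(st))
        votes <- vote_rules_cpp(.codeStates(st), length(labels), ri$attrs,
                                ri$states, match(rules$decision, labels) - 1L,
                                rules$support * rules$accuracy)
        colnames(votes) <- labels
    } else {
        votes <- matrix(0, nrow(st), length(labels),
                        dimnames = list(NULL, labels))
    }
    pref <- order(-as.numeric(model@classSizes[labels]), labels)
    apply(votes, 1L, function(vv) {
        if (all(vv == 0)) return(NA_character_)
        top <- which(vv == max(vv))
        labels[top[order(match(top, pref))][1L]]
    })
}

#' Cross-validate the under-sampled rule classifier
#'
#' Stratified k-fold cross-validation of the full pipeline stage:
#' within each fold the training part is under-sampled, rules are
#' induced per replicate and combined on the training table, and the
#' held-out samples are classified. Unclassified samples count as
#' errors.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param folds number of folds (default 10); reduced with a warning if
#'   the smallest class has fewer members.
#' @param undersample_reps under-sampling replicates per fold.
#' @param seed integer seed.
#' @param method rule-induction method, see [induceRules()].
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
crossValidate <- function(table, folds = 10L, undersample_reps = 100L,
                          seed = 1L, method = "exhaustive") {
    stopifnot(is(table, "DecisionTable"))
    if (folds < 2) stop("folds must be >= 2")
    dec <- droplevels(table@decision)
    labels <- levels(dec)
    m <- min(table(dec))
    if (m < folds) {
        warning("smallest class has ", m, " samples; reducing folds to ", m)
        folds <- m
    }
    if (folds < 2) stop("degenerate folds: smallest class too small")
    set.seed(seed)
    fold_id <- integer(length(dec))
    for (lv in labels) {
        members <- sample(which(dec == lv))
        fold_id[members] <- rep_len(seq_len(folds), length(members))
    }
    fold_seeds <- sample.int(2^30, folds)

    counts <- matrix(0L, length(labels), length(labels) + 1L,
                     dimnames = list(labels, c(labels, "unclassified")))
    for (f in seq_len(folds)) {
        tr <- fold_id != f
        train <- .newDecisionTable(table@states[tr, , drop = FALSE],
                                   dec[tr], table@cutAge)
        reps <- underSample(train, n_reps = undersample_reps,
                            seed = fold_seeds[f])
        model <- combineModels(lapply(reps, induceRules, method = method),
                               train)
        pred <- classifySamples(
            .newDecisionTable(table@states[!tr, , drop = FALSE],
                              dec[!tr], table@cutAge), model)
        obs <- as.character(dec[!tr])
        pred[is.na(pred)] <- "unclassified"
        for (i in seq_along(obs))
            counts[obs[i], pred[i]] <- counts[obs[i], pred[i]] + 1L
    }
    per_class <- diag(counts[, labels, drop = FALSE]) / rowSums(counts)
    new("ConfusionMatrix", counts = counts,
        perClassAccuracy = setNames(per_class, labels),
        overallAccuracy = sum(diag(counts[, labels, drop = FALSE])) /
            sum(counts))
}

#' Render rules as human-readable IF-THEN text
#'
#' @param model a \linkS4class{RuleModel} or a rule data.frame.
#' @param annotations optional probe annotation data.frame (see
#'   [annotateProbes()]); conditions are then rendered as
#'   \code{cgID(GENE_region)=state}.
#' @return Character vector, one rule per element, e.g.
#'   \code{"IF cgA=methylated AND cgB=intermediate THEN 'olderThan50'
#'   [accuracy=0.95, support=21]"}.
#' @export
ruleText <- function(model, annotations = NULL) {
    rules <- if (is(model, "RuleModel")) model@rules else model
    if (!nrow(rules)) return(character())
    vapply(seq_len(nrow(rules)), function(i) {
        cc <- rules$conditions[[i]]
        ids <- names(cc)
        if (!is.null(annotations))
            ids <- .renderProbeIds(ids, annotations)
        sprintf("IF %s THEN '%s' [accuracy=%.3g, support=%d]",
                paste(ids, cc, sep = "=", collapse = " AND "),
                rules$decision[i], rules$accuracy[i],
                as.integer(rules$support[i]))
    }, character(1))
}

#' Write a rule model as TSV
#'
#' Conditions are serialized as \code{probe=state} pairs joined by
#' \code{" AND "}; statistical columns are included when present.
#'
#' @param model a \linkS4class{RuleModel}.
#' @param path output file.
#' @param annotations optional annotation table for rendered probe ids.
#' @export
writeRules <- function(model, path, annotations = NULL) {
    stopifnot(is(model, "RuleModel"))
    rules <- model@rules
    cond_str <- vapply(rules$conditions, function(cc)
        paste(names(cc), cc, sep = "=", collapse = " AND "), character(1))
    df <- data.frame(conditions = cond_str, rules[-1L],
                     stringsAsFactors = FALSE)
    if (!is.null(annotations))
        df$rendered <- ruleText(model, annotations)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
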