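#' Parameters for Monte Carlo feature selection
#'
#' @param n_subsets number of random feature subsets s (default 2000).
#' @param subset_fraction fraction of features drawn into each subset
#'   (default 0.05; at least 2 features are always drawn).
#' @param n_splits number of random train/test splits t per subset
#'   (default 5).
#' @param train_fraction fraction of each class used for training
#'   (default 0.66; splits are stratified so every class appears in both
#'   parts).
#' @param u exponent on the weighted accuracy term (default 1).
#' @param v exponent on the per-node information-gain term (default 1).
#' @param n_permutations label permutations for the significance null
#'   (default 20; 0 skips significance and only ranks).
#' @param alpha significance level on the permutation p-value
#'   (default 0.05).
#' @param min_leaf minimum tree leaf size (default 2; trees are grown to
#'   purity otherwise).
#' @param seed integer seed; fixed seed makes the run reproducible.
#' @return A validated \code{McfsParams} list.
#' @examples
#' mcfsParams(n_subsets = 100, n_permutations = 5, seed = 1)
#' @export
mcfsParams <- function(n_subsets = 2000L, subset_fraction = 0.05,
                       n_splits = 5L, train_fraction = 0.66, u = 1, v = 1,
                       n_permutations = 20L, alpha = 0.05, min_leaf = 2L,
                       seed = 1L) {
    if (subset_fraction <= 0 || subset_fraction > 1)
        stop("invalid McfsParams field 'subset_fraction': need (0, 1]")
    if (train_fraction <= 0 || train_fraction >= 1)
        stop("invalid McfsParams field 'train_fraction': need (0, 1)")
    if (n_subsets * n_splits < 100)
        stop("invalid McfsParams: n_subsets * n_splits must be >= 100")
    if (n_permutations < 0) stop("invalid McfsParams field 'n_permutations'")
    if (alpha <= 0 || alpha >= 1)
        stop("invalid McfsParams field 'alpha': need (0, 1)")
    structure(list(n_subsets = as.integer(n_subsets),
                   subset_fraction = subset_fraction,
                   n_splits = as.integer(n_splits),
                   train_fraction = train_fraction, u = u, v = v,
                   n_permutations = as.integer(n_permutations),
                   alpha = alpha, min_leaf = as.integer(min_leaf),
                   seed = as.integer(seed)),
              class = "McfsParams")
}

.codeStates <- function(states) {
    m <- match(states, methStates()) - 1L
    if (anyNA(m)) stop("unknown methylation state in table")
    matrix(m, nrow(states), ncol(states))
}

.mcfsRI <- function(codes, cls_codes, n_classes, params, record = FALSE) {
    d <- ncol(codes)
    subset_size <- min(d, max(2L, ceiling(params$subset_fraction * d)))
    mcfs_engine_cpp(codes, cls_codes, n_classes, params$n_subsets,
                    subset_size, params$n_splits, params$train_fraction,
                    params$u, params$v, params$min_leaf, record)
}

#' Run Monte Carlo feature selection on a decision table
#'
#' Many small classification trees are trained on random feature subsets
#' and random stratified train/test splits. A feature's relative
#' importance (RI) accumulates, over every tree in which it splits a
#' node, the tree's weighted test accuracy (to the power \code{u}) times
#' the powered sum of its nodes' information gain scaled by node size.
#' Weighted accuracy is the unweighted mean of per-class sensitivities,
#' which compensates for class imbalance. Significance comes from a
#' permutation null: the full procedure is re-run on label-permuted
#' copies of the table, all features' null RIs are pooled, and each
#' feature's one-sided p-value is
#' \code{(1 + #null >= RI) / (1 + #null)}.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param params an [mcfsParams()] object.
#' @return A \linkS4class{FeatureImportanceResult}.
#' @examples
#' cohort <- examplePlantedCohort(seed = 1)
#' tab <- makeMulticlassTable(discretizeCohort(cohort), sampleAges(cohort),
#'                            boundaries = c(0, 30))
#' \donttest{
#' res <- runMCFS(tab, mcfsParams(n_subsets = 100, n_splits = 2,
#'                                n_permutations = 5, seed = 1))
#' head(importanceTable(res))
#' }
#' @export
runMCFS <- function(table, params = mcfsParams()) {
    stopifnot(is(table, "DecisionTable"), inherits(params, "McfsParams"))
    st <- featureStates(table)
    if (ncol(st) < 2) stop("MCFS needs at least 2 features")
    dec <- droplevels(table@decision)
    if (nlevels(dec) < 2) stop("MCFS needs at least 2 decision classes")
    codes <- .codeStates(st)
    cls <- as.integer(dec) - 1L
    nC <- nlevels(dec)

    set.seed(params$seed)
    ri <- .mcfsRI(codes, cls, nC, params)$ri
    names(ri) <- colnames(st)

    if (params$n_permutations > 0) {
        null_ri <- unlist(lapply(seq_len(params$n_permutations), function(b) {
            .mcfsRI(codes, sample(cls), nC, params)$ri
        }), use.names = FALSE)
        pval <- vapply(ri, function(r)
            (1 + sum(null_ri >= r)) / (1 + length(null_ri)), numeric(1))
        n_null <- length(null_ri)
    } else {
        pval <- rep(NA_real_, length(ri))
        n_null <- 0L
    }
    names(pval) <- names(ri)
    ri_norm <- if (any(ri > 0)) ri / max(ri) else ri
    sig <- if (n_null > 0) names(ri)[!is.na(pval) & pval < params$alpha]
           else character()
    new("FeatureImportanceResult", ri = ri, riNorm = ri_norm, pValue = pval,
        significant = sig, params = unclass(params),
        nNull = as.integer(n_null))
}

#' Weighted (class-balanced) accuracy
#'
#' The unweighted mean over classes of per-class sensitivity
#' (correct / total within each observed class). With unbalanced classes
#' this does not reward classifiers that dump everything into the
#' majority class: 90/10 classes with all-majority predictions score
#' 0.5, not 0.9.
#'
#' @param confusion either a square confusion matrix (observed classes
#'   as rows, predicted as columns) or a two-column matrix/data.frame
#'   with columns \code{correct} and \code{total} per class.
#' @return Numeric in [0, 1].
#' @examples
#' weightedAccuracy(cbind(correct = c(90, 0), total = c(90, 10)))
#' @export
weightedAccuracy <- function(confusion) {
    if (is.data.frame(confusion)) confusion <- as.matrix(confusion)
    if (!is.matrix(confusion) || nrow(confusion) == 0)
        stop("empty test split: no per-class counts")
    if (ncol(confusion) == 2 &&
        all(c("correct", "total") %in% colnames(confusion))) {
        correct <- confusion[, "correct"]
        total <- confusion[, "total"]
    } else if (nrow(confusion) == ncol(confusion)) {
        correct <- diag(confusion)
        total <- rowSums(confusion)
    } else {
        stop("confusion must be square or have 'correct'/'total' columns")
    }
    keep <- total > 0
    if (!any(keep)) stop("empty test split: all class totals are zero")
    if (any(correct[keep] > total[keep]))
        stop("correct counts exceed totals")
    mean(correct[keep] / total[keep])
}

#' Significant features for every age cut
#'
#' Runs [runMCFS()] independently on each binary decision table and
#' collects the per-cut significant-feature sets (SFA sets) together
#' with the per-cut significant-count series.
#'
#' @param tables named list of binary \linkS4class{DecisionTable}s from
#'   [makeBinaryTables()].
#' @param params an [mcfsParams()]; the same seed is used per cut, so
#'   identical tables give identical SFA sets.
#' @param keep_results keep the full per-cut
#'   \linkS4class{FeatureImportanceResult}s (memory-heavier).
#' @return List with \code{sfa} (named list of character vectors, one
#'   per cut), \code{counts} (data.frame \code{cut_age},
#'   \code{n_significant}) and, if requested, \code{results}.
#' @export
selectSignificantPerCut <- function(tables, params = mcfsParams(),
                                    keep_results = FALSE) {
    stopifnot(length(tables) >= 1)
    results <- lapply(names(tables), function(nm) {
        tryCatch(runMCFS(tables[[nm]], params),
                 error = function(e)
                     stop("MCFS failed at cut age ",
                          cutAge(tables[[nm]]), ": ",
                          conditionMessage(e), call. = FALSE))
    })
    names(results) <- names(tables)
    sfa <- lapply(results, significantFeatures)
    counts <- data.frame(
        cut_age = vapply(tables, cutAge, numeric(1)),
        n_significant = lengths(sfa), row.names = NULL)
    out <- list(sfa = sfa, counts = counts)
    if (keep_results) out$results <- results
    out
}

#' Write an importance table as TSV
#'
#' Columns \code{feature_id}, \code{ri}, \code{ri_norm}, \code{p_value},
#' \code{significant} (0/1).
#'
#' @param result a \linkS4class{FeatureImportanceResult}.
#' @param path output file.
#' @export
writeImportanceTable <- function(result, path) {
    write.table(importanceTable(result), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
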