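.newDecisionTable <- function(states_by_sample, decision, cut_age = NA_real_) {
    new("DecisionTable", states = states_by_sample,
        decision = factor(decision), cutAge = as.numeric(cut_age))
}

#' Build a decision table from a state matrix and labels
#'
#' @param states character matrix of methylation states, probes x
#'   samples (as returned by [discretizeCohort()]).
#' @param decision character/factor of per-sample class labels.
#' @param cut_age optional age cut that defined the labels.
#' @return A \linkS4class{DecisionTable} (samples as rows).
#' @export
decisionTable <- function(states, decision, cut_age = NA_real_) {
    .newDecisionTable(t(states), decision, cut_age)
}

#' Binary decision tables over sliding age cuts
#'
#' For every cut age a, samples are split into \code{youngerThan}a (age
#' < a) and \code{olderThan}a (age >= a). The default sweep uses integer
#' cuts 0..60 inclusive, i.e. 61 tables; fetal samples (negative age)
#' fall on the younger side of every cut, so the cut at 0 discerns fetal
#' from postnatal samples.
#'
#' @param states character state matrix, probes x samples.
#' @param ages numeric per-sample ages in years.
#' @param cut_ages sorted unique integer cut ages (default \code{0:60}).
#' @return Named list of \linkS4class{DecisionTable}s, one per cut age,
#'   names \code{"cut<age>"}.
#' @examples
#' cohort <- simulateCohort(cohortSpec(30, c(-0.5, 84),
#'                                     n_noise_sites = 10, seed = 5))
#' tabs <- makeBinaryTables(discretizeCohort(cohort), sampleAges(cohort))
#' length(tabs)
#' @export
makeBinaryTables <- function(states, ages, cut_ages = 0:60) {
    if (is.unsorted(cut_ages, strictly = TRUE))
        stop("cut_ages must be sorted and unique")
    if (ncol(states) != length(ages))
        stop("states must have one column per sample age")
    lapply(setNames(cut_ages, paste0("cut", cut_ages)), function(a) {
        younger <- ages < a
        if (!any(younger) || all(younger))
            stop("age cut ", a, " leaves an empty group")
        lab <- ifelse(younger, paste0("youngerThan", a),
                      paste0("olderThan", a))
        .newDecisionTable(t(states), lab, a)
    })
}

#' Multi-class decision table over age-group boundaries
#'
#' Samples are assigned to named age groups: \code{fetus} for negative
#' ages, then one group per consecutive boundary pair, with the last
#' group open-ended (\code{Age<a>plus}). The default boundaries
#' \code{c(0, 5, 28)} give the four classes \code{fetus},
#' \code{Age0-4}, \code{Age5-27} and \code{Age28plus}.
#'
#' @param states character state matrix, probes x samples.
#' @param ages numeric per-sample ages in years.
#' @param boundaries strictly increasing non-negative integer lower
#'   bounds of the postnatal groups; the first must be 0 so the
#'   partition has no gap above the fetal class.
#' @return A \linkS4class{DecisionTable}.
#' @examples
#' st <- matrix("intermediate", 2, 4,
#'              dimnames = list(c("cg1", "cg2"), NULL))
#' tab <- makeMulticlassTable(st, c(-0.5, 2, 10, 40))
#' table(decisionClasses(tab))
#' @export
makeMulticlassTable <- function(states, ages, boundaries = c(0, 5, 28)) {
    if (length(boundaries) < 1L || is.unsorted(boundaries, strictly = TRUE))
        stop("boundaries must be strictly increasing")
    if (boundaries[1L] != 0)
        stop("boundaries must start at 0 (fetal samples form their own class)")
    if (ncol(states) != length(ages))
        stop("states must have one column per sample age")
    k <- length(boundaries)
    labels_post <- c(
        if (k > 1L) paste0("Age", boundaries[-k], "-", boundaries[-1L] - 1L),
        paste0("Age", boundaries[k], "plus"))
    lab <- character(length(ages))
    lab[ages < 0] <- "fetus"
    grp <- findInterval(ages, boundaries)   # 0 => fetal (age < 0)
    lab[ages >= 0] <- labels_post[grp[ages >= 0]]
    .newDecisionTable(t(states), lab)
}

#' Age-group labels for a set of boundaries
#'
#' @inheritParams makeMulticlassTable
#' @return Character vector: \code{"fetus"} followed by the postnatal
#'   group labels in age order.
#' @export
ageGroupLabels <- function(boundaries = c(0, 5, 28)) {
    k <- length(boundaries)
    c("fetus",
      if (k > 1L) paste0("Age", boundaries[-k], "-", boundaries[-1L] - 1L),
      paste0("Age", boundaries[k], "plus"))
}

#' Write a decision table as TSV
#'
#' Layout mirrors the classic rough-set table: first column
#' \code{sample_id}, one column per probe holding the state string, and
#' a final \code{class} column.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param path output file.
#' @export
writeDecisionTable <- function(table, path) {
    stopifnot(is(table, "DecisionTable"))
    st <- featureStates(table)
    ids <- rownames(st)
    if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(nrow(st)))
    df <- data.frame(sample_id = ids, st,
                     class = as.character(table@decision),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a decision table written by [writeDecisionTable()]
#'
#' @param path TSV file.
#' @return A \linkS4class{DecisionTable}.
#' @export
readDecisionTable <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    st <- as.matrix(df[setdiff(names(df), c("sample_id", "class"))])
    rownames(st) <- df$sample_id
    .newDecisionTable(st, df$class)
}

#' Restrict a decision table to a feature subset
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param features character vector of probe ids to keep.
#' @return A \linkS4class{DecisionTable} over the selected features.
#' @export
subsetFeatures <- function(table, features) {
    stopifnot(is(table, "DecisionTable"))
    miss <- setdiff(features, colnames(table@states))
    if (length(miss))
        stop("features absent from table: ", paste(head(miss, 5),
                                                   collapse = ", "))
    .newDecisionTable(table@states[, features, drop = FALSE],
                      table@decision, table@cutAge)
}
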