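#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' The three discrete methylation states
#'
#' Beta values are discretized into three ordered states:
#' \code{unmethylated < intermediate < methylated}.
#'
#' @return Character vector of the three state names, in increasing order
#'   of methylation.
#' @examples
#' methStates()
#' @export
methStates <- function() c("unmethylated", "intermediate", "methylated")

.REGION_TAGS <- c("exonic", "intronic", "UTR5", "UTR3", "intergenic",
                  "splicing", "upstream")

#' MethylationCohort: beta values, ages and probe annotations
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"beta"}
#' (CpG probes x samples, values in [0,1]), per-sample ages in years in
#' \code{colData} (column \code{age_years}; negative values encode fetal
#' samples, flagged in \code{is_fetal}), and per-probe annotations in
#' \code{rowData} (\code{chrom}, \code{gene}, \code{region},
#' \code{nonspecific}, \code{polymorphic}).
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#' @seealso [MethylationCohort()] for the constructor, [simulateCohort()]
#'   for synthetic cohorts, [filterProbes()] and [discretizeCohort()] for
#'   preprocessing.
#' @export
setClass("MethylationCohort", contains = "SummarizedExperiment")

setValidity("MethylationCohort", function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (anyNA(b) || any(b < 0) || any(b > 1))
            msg <- c(msg, "beta values must lie in [0, 1] with no NA")
    }
    cd <- colData(object)
    if (!"age_years" %in% colnames(cd))
        msg <- c(msg, "colData column 'age_years' is required")
    rd <- rowData(object)
    need <- c("chrom", "gene", "region", "nonspecific", "polymorphic")
    miss <- setdiff(need, colnames(rd))
    if (length(miss) && nrow(object) > 0)
        msg <- c(msg, paste0("rowData columns missing: ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' DecisionTable: discretized samples with a decision class
#'
#' Rows are samples, columns are CpG features holding one of the three
#' methylation states, plus one decision-class label per sample. This is
#' the rough-set input format: classifiers and feature selection both
#' consume it.
#'
#' @slot states character matrix, samples x features, entries in
#'   \code{methStates()}.
#' @slot decision factor of per-sample class labels (>= 2 levels present).
#' @slot cutAge numeric; the age cut that produced a binary table, or
#'   \code{NA} for multi-class tables.
#' @seealso [makeBinaryTables()], [makeMulticlassTable()], [runMCFS()],
#'   [induceRules()].
#' @export
setClass("DecisionTable",
         representation(states = "matrix", decision = "factor",
                        cutAge = "numeric"))

setValidity("DecisionTable", function(object) {
    msg <- character()
    st <- object@states
    if (!is.character(st))
        msg <- c(msg, "states must be a character matrix")
    if (nrow(st) != length(object@decision))
        msg <- c(msg, "one decision label per sample row is required")
    if (anyNA(st) || !all(st %in% methStates()))
        msg <- c(msg, "states must be one of unmethylated/intermediate/methylated")
    if (anyNA(object@decision))
        msg <- c(msg, "decision labels must not be NA")
    if (nlevels(droplevels(object@decision)) < 2)
        msg <- c(msg, "at least 2 distinct decision classes are required")
    if (is.null(colnames(st)) || anyDuplicated(colnames(st)))
        msg <- c(msg, "feature columns must have unique names")
    if (length(msg)) msg else TRUE
})

#' FeatureImportanceResult: MCFS output for one decision table
#'
#' Per-feature relative importance (RI), normalized RI, a one-sided
#' permutation p-value against a label-permuted null, and the resulting
#' significant-feature set.
#'
#' @slot ri named numeric, raw relative importance (>= 0).
#' @slot riNorm named numeric, \code{ri / max(ri)} (all zero if no ri > 0).
#' @slot pValue named numeric, permutation p-values.
#' @slot significant character, features with \code{pValue < alpha}.
#' @slot params list, the [mcfsParams()] used.
#' @slot nNull integer, size of the pooled null sample.
#' @seealso [runMCFS()], [importanceTable()], [significantFeatures()].
#' @export
setClass("FeatureImportanceResult",
         representation(ri = "numeric", riNorm = "numeric",
                        pValue = "numeric", significant = "character",
                        params = "list", nNull = "integer"))

setValidity("FeatureImportanceResult", function(object) {
    msg <- character()
    if (any(object@ri < 0)) msg <- c(msg, "ri must be non-negative")
    if (length(object@ri) != length(object@riNorm) ||
        length(object@ri) != length(object@pValue))
        msg <- c(msg, "ri, riNorm and pValue must have equal length")
    if (length(object@riNorm) && any(object@ri > 0) &&
        abs(max(object@riNorm) - 1) > 1e-12)
        msg <- c(msg, "max(riNorm) must be 1 when any ri > 0")
    if (!all(object@significant %in% names(object@ri)))
        msg <- c(msg, "significant set must be a subset of the features")
    if (length(msg)) msg else TRUE
})

#' RuleModel: a set of IF-THEN classification rules
#'
#' Rules are stored as a data.frame with a list-column \code{conditions}
#' (each element a named character vector: names are probe ids, values are
#' methylation states), plus \code{decision}, \code{accuracy},
#' \code{support}, \code{n_runs} and, once [scoreRules()] has run,
#' \code{p_raw} / \code{p_bonferroni}.
#'
#' @slot rules data.frame as described above.
#' @slot classLabels character, decision classes of the source table.
#' @slot classSizes named integer, samples per class in the source table.
#' @slot nTotal integer, total samples in the source table.
#' @seealso [induceRules()], [combineModels()], [filterRules()],
#'   [classifySamples()], [ruleText()].
#' @export
setClass("RuleModel",
         representation(rules = "data.frame", classLabels = "character",
                        classSizes = "integer", nTotal = "integer"))

setValidity("RuleModel", function(object) {
    msg <- character()
    r <- object@rules
    need <- c("conditions", "decision", "accuracy", "support")
    if (!all(need %in% names(r)))
        msg <- c(msg, paste0("rules must have columns: ",
                             paste(need, collapse = ", ")))
    else {
        if (!all(r$decision %in% object@classLabels))
            msg <- c(msg, "every rule decision must be a known class label")
        if (nrow(r) && (any(r$accuracy <= 0) || any(r$accuracy > 1)))
            msg <- c(msg, "rule accuracy must lie in (0, 1]")
        if (nrow(r) && any(r$support < 1))
            msg <- c(msg, "rule support must be >= 1")
        dup <- vapply(r$conditions, function(cc) anyDuplicated(names(cc)) > 0,
                      logical(1))
        if (any(dup))
            msg <- c(msg, "a rule may not repeat a probe in its conditions")
    }
    if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: cross-validated classification summary
#'
#' @slot counts integer matrix, observed class x predicted class, with a
#'   final \code{"unclassified"} column for samples no rule fired on.
#' @slot perClassAccuracy named numeric, diagonal / row totals.
#' @slot overallAccuracy numeric, correctly classified / total
#'   (unclassified samples count as errors).
#' @seealso [crossValidate()].
#' @export
setClass("ConfusionMatrix",
         representation(counts = "matrix", perClassAccuracy = "numeric",
                        overallAccuracy = "numeric"))

#' SfaDistanceMatrix: Jaccard distances between per-cut feature sets
#'
#' @slot cutAges numeric, the ordered age cuts.
#' @slot d symmetric numeric matrix of Jaccard distances in [0,1], zero
#'   diagonal.
#' @seealso [buildDistanceMatrix()], [clusterCuts()].
#' @export
setClass("SfaDistanceMatrix",
         representation(cutAges = "numeric", d = "matrix"))

setValidity("SfaDistanceMatrix", function(object) {
    msg <- character()
    d <- object@d
    if (nrow(d) != ncol(d) || nrow(d) != length(object@cutAges))
        msg <- c(msg, "d must be square with one row per cut age")
    else {
        if (any(abs(d - t(d)) > 1e-12)) msg <- c(msg, "d must be symmetric")
        if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
        if (any(d < -1e-12) || any(d > 1 + 1e-12))
            msg <- c(msg, "distances must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' AgeGrouping: clustering of age cuts into age groups
#'
#' @slot hclust the complete-linkage \code{\link[stats]{hclust}} tree over
#'   the cut ages.
#' @slot groups list of numeric vectors, the partition of cut ages into k
#'   clusters (ordered by their youngest member).
#' @slot boundaries numeric, the youngest cut age of each group when the
#'   groups are contiguous in age.
#' @slot contiguous logical, whether every group is an unbroken age run.
#' @seealso [clusterCuts()], [exportDendrogram()].
#' @export
setClass("AgeGrouping",
         representation(hclust = "ANY", groups = "list",
                        boundaries = "numeric", contiguous = "logical"))

#' InteractionNetwork: co-occurrence graph over rule conditions
#'
#' Nodes are rule conditions (\code{probe=state}); an edge connects two
#' conditions that co-occur in at least one conjunctive rule of the class,
#' weighted by the summed \code{accuracy * support} of those rules.
#'
#' @slot classLabel character, the decision class.
#' @slot edges data.frame: \code{cond_a}, \code{cond_b}, \code{strength},
#'   \code{n_rules}, sorted by decreasing strength.
#' @slot nodes character, all conditions seen in the class's rules.
#' @seealso [buildInteractionNetwork()], [topInteractions()].
#' @export
setClass("InteractionNetwork",
         representation(classLabel = "character", edges = "data.frame",
                        nodes = "character"))

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("cond_a", "cond_b", "strength", "n_rules") %in% names(e)))
        msg <- c(msg, "edges must have cond_a, cond_b, strength, n_rules")
    else if (nrow(e) && any(e$strength <= 0))
        msg <- c(msg, "edge strength must be positive")
    if (length(msg)) msg else TRUE
})
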