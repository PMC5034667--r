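#' @rdname MethylationCohort-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname MethylationCohort-class
#' @export
setGeneric("sampleAges", function(x) standardGeneric("sampleAges"))

#' @rdname MethylationCohort-class
#' @export
setGeneric("probeAnnotations",
           function(x) standardGeneric("probeAnnotations"))

#' @rdname DecisionTable-class
#' @param x a \code{DecisionTable}.
#' @export
setGeneric("featureStates", function(x) standardGeneric("featureStates"))

#' @rdname DecisionTable-class
#' @export
setGeneric("decisionClasses", function(x) standardGeneric("decisionClasses"))

#' @rdname DecisionTable-class
#' @export
setGeneric("cutAge", function(x) standardGeneric("cutAge"))

#' @rdname FeatureImportanceResult-class
#' @param x a \code{FeatureImportanceResult}.
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname FeatureImportanceResult-class
#' @export
setGeneric("significantFeatures",
           function(x) standardGeneric("significantFeatures"))

#' @rdname RuleModel-class
#' @param x a \code{RuleModel}.
#' @export
setGeneric("modelRules", function(x) standardGeneric("modelRules"))

# ---- accessor methods ----

#' @rdname MethylationCohort-class
#' @export
setMethod("betaValues", "MethylationCohort",
          function(x) assay(x, "beta"))

#' @rdname MethylationCohort-class
#' @export
setMethod("sampleAges", "MethylationCohort",
          function(x) setNames(colData(x)$age_years, colnames(x)))

#' @rdname MethylationCohort-class
#' @export
setMethod("probeAnnotations", "MethylationCohort",
          function(x) rowData(x))

#' @rdname DecisionTable-class
#' @export
setMethod("featureStates", "DecisionTable", function(x) x@states)

#' @rdname DecisionTable-class
#' @export
setMethod("decisionClasses", "DecisionTable",
          function(x) setNames(as.character(x@decision), rownames(x@states)))

#' @rdname DecisionTable-class
#' @export
setMethod("cutAge", "DecisionTable", function(x) x@cutAge)

#' @rdname FeatureImportanceResult-class
#' @export
setMethod("importanceTable", "FeatureImportanceResult", function(x) {
    data.frame(feature_id = names(x@ri), ri = unname(x@ri),
               ri_norm = unname(x@riNorm), p_value = unname(x@pValue),
               significant = as.integer(names(x@ri) %in% x@significant),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname FeatureImportanceResult-class
#' @export
setMethod("significantFeatures", "FeatureImportanceResult",
          function(x) x@significant)

#' @rdname RuleModel-class
#' @export
setMethod("modelRules", "RuleModel", function(x) x@rules)

# ---- show methods ----

setMethod("show", "DecisionTable", function(object) {
    cls <- table(object@decision)
    cat("DecisionTable:", nrow(object@states), "samples x",
        ncol(object@states), "features\n")
    if (!is.na(object@cutAge)) cat("  binary cut at age", object@cutAge, "\n")
    cat("  classes:",
        paste(sprintf("%s (%d)", names(cls), cls), collapse = ", "), "\n")
})

setMethod("show", "FeatureImportanceResult", function(object) {
    cat("FeatureImportanceResult:", length(object@ri), "features,",
        length(object@significant), "significant at alpha =",
        object@params$alpha, "\n")
    top <- head(order(object@ri, decreasing = TRUE), 5L)
    cat("  top features:",
        paste(sprintf("%s (%.3f)", names(object@ri)[top],
                      object@riNorm[top]), collapse = ", "), "\n")
})

setMethod("show", "RuleModel", function(object) {
    cat("RuleModel:", nrow(object@rules), "rules over classes",
        paste(object@classLabels, collapse = ", "), "\n")
    if (nrow(object@rules)) {
        nc <- lengths(object@rules$conditions)
        cat("  singleton:", sum(nc == 1L), " conjunctive:", sum(nc > 1L), "\n")
        cat("  example:", ruleText(object)[1L], "\n")
    }
})

setMethod("show", "ConfusionMatrix", function(object) {
    cat("ConfusionMatrix (overall accuracy",
        sprintf("%.1f%%)\n", 100 * object@overallAccuracy))
    print(object@counts)
})

setMethod("show", "SfaDistanceMatrix", function(object) {
    cat("SfaDistanceMatrix over", length(object@cutAges), "age cuts (",
        min(object@cutAges), "..", max(object@cutAges), ")\n")
})

setMethod("show", "AgeGrouping", function(object) {
    cat("AgeGrouping:", length(object@groups), "groups",
        if (object@contiguous) "(age-contiguous)" else "(NON-contiguous)",
        "\n")
    for (g in object@groups)
        cat("  ages", min(g), "..", max(g), "\n")
})

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork for class", object@classLabel, ":",
        length(object@nodes), "conditions,", nrow(object@edges), "edges\n")
    if (nrow(object@edges))
        print(utils::head(object@edges, 3L), row.names = FALSE)
})
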