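#' Remove uninformative or unreliable probes
#'
#' Applies the three exclusion rules used for 27K-style methylation
#' arrays: (a) probes on chromosome X (avoids pseudo-autosomal artefacts
#' in mixed-sex cohorts), (b) probes flagged nonspecific or polymorphic
#' in the annotation table, and (c) probes whose sample standard
#' deviation of beta values is strictly below \code{sd_cutoff} (little
#' variation over age carries no signal). A probe failing several rules
#' is attributed to the first rule in the order chrX, flagged, low-SD;
#' the retained set is the same under any order.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param sd_cutoff beta-scale SD threshold; probes with SD strictly
#'   below it are dropped (SD exactly equal is retained). Default 0.02.
#' @return A list with elements \code{cohort} (the filtered
#'   \linkS4class{MethylationCohort}) and \code{report} (a
#'   \code{FilterReport} list: \code{n_input}, \code{n_removed_chrX},
#'   \code{n_removed_flagged}, \code{n_removed_low_sd},
#'   \code{n_retained}, \code{sd_cutoff}).
#' @examples
#' cohort <- simulateCohort(cohortSpec(12, c(-0.5, 60),
#'                                     n_noise_sites = 40, seed = 3))
#' res <- filterProbes(cohort)
#' res$report$n_retained
#' @export
filterProbes <- function(cohort, sd_cutoff = 0.02) {
    stopifnot(is(cohort, "MethylationCohort"))
    b <- betaValues(cohort)
    ann <- probeAnnotations(cohort)
    n_input <- nrow(b)
    if (n_input == 0) {
        report <- .filterReport(0L, 0L, 0L, 0L, sd_cutoff)
        return(list(cohort = cohort, report = report))
    }
    is_chrX <- ann$chrom %in% c("X", "chrX")
    is_flagged <- (ann$nonspecific | ann$polymorphic) & !is_chrX
    sds <- apply(b, 1L, sd)
    is_low_sd <- (sds < sd_cutoff) & !is_chrX & !is_flagged
    keep <- !(is_chrX | is_flagged | is_low_sd)
    report <- .filterReport(n_input, sum(is_chrX), sum(is_flagged),
                            sum(is_low_sd), sd_cutoff)
    list(cohort = cohort[keep, ], report = report)
}

.filterReport <- function(n_input, n_chrX, n_flagged, n_low_sd, sd_cutoff) {
    structure(list(n_input = as.integer(n_input),
                   n_removed_chrX = as.integer(n_chrX),
                   n_removed_flagged = as.integer(n_flagged),
                   n_removed_low_sd = as.integer(n_low_sd),
                   n_retained = as.integer(n_input - n_chrX - n_flagged -
                                           n_low_sd),
                   sd_cutoff = sd_cutoff),
              class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
    cat("Probe filter report (SD cutoff", x$sd_cutoff, "):\n")
    cat("  input probes:      ", x$n_input, "\n")
    cat("  removed chrX:      ", x$n_removed_chrX, "\n")
    cat("  removed flagged:   ", x$n_removed_flagged, "\n")
    cat("  removed low SD:    ", x$n_removed_low_sd, "\n")
    cat("  retained:          ", x$n_retained, "\n")
    invisible(x)
}

#' Write a filter report as a machine-readable key-value file
#'
#' @param report a \code{FilterReport} from [filterProbes()].
#' @param path output file; one \code{key<TAB>value} line per field.
#' @export
writeFilterReport <- function(report, path) {
    stopifnot(inherits(report, "FilterReport"))
    writeLines(paste(names(report), unlist(report), sep = "\t"), path)
    invisible(path)
}

#' Discretize beta values into three methylation states
#'
#' A beta value of 0.2 or lower is \code{unmethylated}, 0.8 or higher is
#' \code{methylated}, and values strictly between the two thresholds are
#' \code{intermediate}. The thresholds follow the standard tri-state
#' division of array beta distributions; both boundary values belong to
#' the extreme states.
#'
#' @param beta numeric vector or matrix of beta values in [0,1].
#' @param low,high the two thresholds (defaults 0.2 and 0.8).
#' @return Character vector/matrix of states (same shape as the input).
#' @examples
#' discretizeBeta(c(0.2, 0.5, 0.8))
#' @export
discretizeBeta <- function(beta, low = 0.2, high = 0.8) {
    bad <- is.na(beta) | beta < 0 | beta > 1
    if (any(bad)) {
        idx <- which(bad)
        coord <- if (is.matrix(beta))
            paste0("[", (idx - 1L) %% nrow(beta) + 1L, ",",
                   (idx - 1L) %/% nrow(beta) + 1L, "]")
        else paste0("[", idx, "]")
        stop("beta values outside [0,1] at ",
             paste(head(coord, 5L), collapse = ", "))
    }
    st <- ifelse(beta <= low, "unmethylated",
                 ifelse(beta >= high, "methylated", "intermediate"))
    if (is.matrix(beta)) {
        st <- matrix(st, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    }
    st
}

#' Discretize a whole cohort
#'
#' Elementwise [discretizeBeta()] over the cohort's beta matrix.
#'
#' @param cohort a (typically filtered) \linkS4class{MethylationCohort}.
#' @inheritParams discretizeBeta
#' @return Character matrix, probes x samples, of methylation states.
#' @examples
#' cohort <- simulateCohort(cohortSpec(8, c(0, 60), n_noise_sites = 5,
#'                                     seed = 2))
#' discretizeCohort(cohort)[, 1:3]
#' @export
discretizeCohort <- function(cohort, low = 0.2, high = 0.8) {
    stopifnot(is(cohort, "MethylationCohort"))
    b <- betaValues(cohort)
    tryCatch(discretizeBeta(b, low = low, high = high),
             error = function(e)
                 stop("discretization failed for probe/sample ",
                      conditionMessage(e), call. = FALSE))
}
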