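#' Hypergeometric right-tail p-value for a rule
#'
#' The probability that a random draw of \code{n} samples (the rule's
#' support) from a table of \code{N} samples containing \code{K}
#' members of the rule's decision class would contain at least \code{k}
#' class members. Small values mean the rule's class enrichment is
#' unlikely by chance.
#'
#' @param N total samples in the table.
#' @param K samples in the rule's decision class.
#' @param n rule support (samples matching the conditions).
#' @param k matching samples that belong to the decision class.
#' @return P(X >= k) for X ~ Hypergeometric(N, K, n).
#' @examples
#' rulePValue(N = 10, K = 5, n = 5, k = 5)  # 1/choose(10,5)
#' @export
rulePValue <- function(N, K, n, k) {
    if (any(c(N, K, n, k) < 0) || k > n || n > N || k > K || K > N)
        stop("inconsistent counts: need 0 <= k <= n <= N and k <= K <= N")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Attach hypergeometric significance to a rule model
#'
#' Computes each rule's raw right-tail hypergeometric p-value and a
#' Bonferroni-corrected value, the correction universe being all rules
#' of the model.
#'
#' @param model a \linkS4class{RuleModel} (from [combineModels()]).
#' @return The model with \code{p_raw} and \code{p_bonferroni} columns
#'   added to its rules.
#' @export
scoreRules <- function(model) {
    stopifnot(is(model, "RuleModel"))
    rules <- model@rules
    if (!nrow(rules)) {
        rules$p_raw <- numeric(0)
        rules$p_bonferroni <- numeric(0)
        model@rules <- rules
        return(model)
    }
    N <- model@nTotal
    p <- vapply(seq_len(nrow(rules)), function(i) {
        K <- model@classSizes[[rules$decision[i]]]
        n <- rules$support[i]
        k <- round(rules$accuracy[i] * n)
        rulePValue(N, K, n, k)
    }, numeric(1))
    rules$p_raw <- p
    rules$p_bonferroni <- pmin(1, p * nrow(rules))
    model@rules <- rules
    model
}

#' Filter rules by significance, accuracy and support
#'
#' Keeps rules that pass all three thresholds: Bonferroni-corrected
#' p-value below \code{alpha}, accuracy strictly above
#' \code{min_accuracy}, and support of at least half the decision-class
#' size (\code{ceiling(support_frac * class size)}).
#'
#' @param model a scored \linkS4class{RuleModel} (see [scoreRules()]; if
#'   p-values are absent they are computed first).
#' @param alpha significance threshold (default 0.05).
#' @param min_accuracy accuracy threshold, strict (default 0.75).
#' @param support_frac fraction of the decision-class size a rule's
#'   support must reach (default 0.5).
#' @param use_corrected filter on Bonferroni-corrected p-values
#'   (default) or on raw ones.
#' @return The filtered \linkS4class{RuleModel}.
#' @export
filterRules <- function(model, alpha = 0.05, min_accuracy = 0.75,
                        support_frac = 0.5, use_corrected = TRUE) {
    stopifnot(is(model, "RuleModel"))
    if (is.null(model@rules$p_raw)) model <- scoreRules(model)
    rules <- model@rules
    if (!nrow(rules)) return(model)
    p <- if (use_corrected) rules$p_bonferroni else rules$p_raw
    min_support <- ceiling(support_frac *
                           as.numeric(model@classSizes[rules$decision]))
    keep <- p < alpha & rules$accuracy > min_accuracy &
        rules$support >= min_support
    model@rules <- rules[keep, , drop = FALSE]
    rownames(model@rules) <- NULL
    model
}

#' Linear-regression cross-check of a rule's sites
#'
#' Ordinary least squares of age on the raw beta values of the probes in
#' one rule, with the overall F-test p-value. Conjunctive rules whose
#' sites are only jointly (not marginally) informative can pass the
#' rule filter while failing this linear check — the comparison marks
#' which patterns a linear model would miss.
#'
#' @param conditions a rule's named condition vector (probe -> state) or
#'   a character vector of probe ids.
#' @param betas raw beta matrix, probes x samples.
#' @param ages per-sample ages in years.
#' @param alpha significance level for the flag (default 0.05).
#' @return List: \code{f_statistic}, \code{p_value},
#'   \code{significant}.
#' @export
regressionCheck <- function(conditions, betas, ages, alpha = 0.05) {
    probes <- if (!is.null(names(conditions))) names(conditions)
              else conditions
    miss <- setdiff(probes, rownames(betas))
    if (length(miss))
        stop("probes absent from beta matrix: ",
             paste(miss, collapse = ", "))
    if (length(probes) >= length(ages) - 1L)
        stop("more sites than the regression can support (", length(probes),
             " sites, ", length(ages), " samples)")
    x <- t(betas[probes, , drop = FALSE])
    degenerate <- apply(x, 2L, function(col) sd(col) == 0)
    if (any(degenerate)) {
        warning("zero-variance site(s): ",
                paste(probes[degenerate], collapse = ", "),
                "; regression degenerate")
        x <- x[, !degenerate, drop = FALSE]
        if (ncol(x) == 0)
            return(list(f_statistic = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    }
    fit <- lm(ages ~ x)
    fs <- summary(fit)$fstatistic
    if (is.null(fs))
        return(list(f_statistic = NA_real_, p_value = NA_real_,
                    significant = FALSE))
    p <- unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
    list(f_statistic = unname(fs[1L]), p_value = p,
         significant = is.finite(p) && p < alpha)
}

#' Run the regression cross-check over every rule of a model
#'
#' @param model a \linkS4class{RuleModel}.
#' @param cohort the \linkS4class{MethylationCohort} holding the raw
#'   beta values the table was discretized from.
#' @param alpha significance level (default 0.05).
#' @return The model with \code{regression_p} and
#'   \code{regression_significant} columns added.
#' @export
regressionCheckModel <- function(model, cohort, alpha = 0.05) {
    stopifnot(is(model, "RuleModel"), is(cohort, "MethylationCohort"))
    rules <- model@rules
    b <- betaValues(cohort)
    ages <- sampleAges(cohort)
    res <- lapply(rules$conditions, function(cc)
        tryCatch(regressionCheck(cc, b, ages, alpha),
                 error = function(e) list(f_statistic = NA_real_,
                                          p_value = NA_real_,
                                          significant = FALSE)))
    rules$regression_p <- vapply(res, `[[`, numeric(1), "p_value")
    rules$regression_significant <- vapply(res, `[[`, logical(1),
                                           "significant")
    model@rules <- rules
    model
}
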