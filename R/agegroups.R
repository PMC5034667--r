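#' Jaccard distance between two feature sets
#'
#' \code{1 - |intersect| / |union|}. Two empty sets are at distance 0
#' (identically empty significant sets mean the cuts behave the same);
#' an empty set versus a non-empty one is at distance 1.
#'
#' @param a,b character vectors (treated as sets).
#' @return Numeric in [0, 1].
#' @examples
#' jaccardDistance(c("x", "y", "z"), c("y", "z", "w"))  # 0.5
#' @export
jaccardDistance <- function(a, b) {
    a <- unique(a); b <- unique(b)
    nu <- length(union(a, b))
    if (nu == 0) return(0)
    1 - length(intersect(a, b)) / nu
}

#' Pairwise Jaccard distances between per-cut significant-feature sets
#'
#' @param sfa named list of feature sets, one per age cut; names must
#'   parse as \code{"cut<age>"} or the cut ages can be given directly.
#' @param cut_ages optional numeric cut ages (defaults to parsing the
#'   list names).
#' @return An \linkS4class{SfaDistanceMatrix}.
#' @examples
#' m <- buildDistanceMatrix(list(cut1 = c("a", "b"), cut2 = c("b", "c"),
#'                               cut3 = c("a", "b")))
#' m@d
#' @export
buildDistanceMatrix <- function(sfa, cut_ages = NULL) {
    k <- length(sfa)
    if (k < 2) stop("need significant-feature sets for at least 2 cuts")
    if (is.null(cut_ages))
        cut_ages <- as.numeric(sub("^cut", "", names(sfa)))
    if (anyNA(cut_ages) || length(cut_ages) != k)
        stop("cannot determine cut ages; supply cut_ages")
    d <- matrix(0, k, k, dimnames = list(cut_ages, cut_ages))
    for (i in seq_len(k - 1)) {
        for (j in seq.int(i + 1, k)) {
            d[i, j] <- d[j, i] <- jaccardDistance(sfa[[i]], sfa[[j]])
        }
    }
    new("SfaDistanceMatrix", cutAges = as.numeric(cut_ages), d = d)
}

#' Cluster age cuts into age groups
#'
#' Complete-linkage agglomerative clustering (\code{\link[stats]{hclust}}
#' with \code{method = "complete"}, as is standard for this analysis) of
#' the cut ages by their Jaccard distances, cut into \code{k} groups.
#' Groups are reported in age order; when every group is an unbroken run
#' of ages, the youngest age of each group is returned as the derived
#' age-group boundary (the natural input for
#' [makeMulticlassTable()]). Non-contiguous groups trigger a warning and
#' no boundaries.
#'
#' @param m an \linkS4class{SfaDistanceMatrix}.
#' @param k number of groups (2 <= k <= number of cuts). The fetal class
#'   is not part of the clustering; it always remains its own class
#'   downstream, so \code{k = 3} on postnatal cuts reproduces a
#'   four-class design.
#' @return An \linkS4class{AgeGrouping}.
#' @examples
#' m <- buildDistanceMatrix(list(cut1 = "a", cut2 = "a", cut3 = "b",
#'                               cut4 = "b"))
#' clusterCuts(m, k = 2)
#' @export
clusterCuts <- function(m, k = 3L) {
    stopifnot(is(m, "SfaDistanceMatrix"))
    n <- length(m@cutAges)
    if (k < 1 || k > n) stop("k must lie in [1, number of cut ages]")
    hc <- hclust(as.dist(m@d), method = "complete")
    memb <- cutree(hc, k = k)
    groups <- split(m@cutAges, memb)
    groups <- groups[order(vapply(groups, min, numeric(1)))]
    names(groups) <- NULL
    contiguous <- all(vapply(seq_along(groups), function(i) {
        g <- sort(groups[[i]])
        # a group is contiguous if no other group's age falls inside its range
        !any(unlist(groups[-i]) > min(g) & unlist(groups[-i]) < max(g))
    }, logical(1)))
    boundaries <- if (contiguous)
        sort(vapply(groups, min, numeric(1)))
    else {
        warning("clusters are not contiguous in age; no boundaries derived")
        numeric()
    }
    new("AgeGrouping", hclust = hc, groups = groups,
        boundaries = boundaries, contiguous = contiguous)
}

#' Export a cut-age dendrogram as Newick text
#'
#' @param grouping an \linkS4class{AgeGrouping}.
#' @param path output file; merge heights become branch lengths.
#' @export
exportDendrogram <- function(grouping, path) {
    stopifnot(is(grouping, "AgeGrouping"))
    ape::write.tree(ape::as.phylo(grouping@hclust), file = path)
    invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param m an \linkS4class{SfaDistanceMatrix}.
#' @param path output file (first column \code{cut_age}).
#' @export
writeDistanceMatrix <- function(m, path) {
    stopifnot(is(m, "SfaDistanceMatrix"))
    write.table(data.frame(cut_age = m@cutAges, m@d, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
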