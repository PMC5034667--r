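#' Build the condition co-occurrence network for one class
#'
#' For every conjunctive rule of the class, each unordered pair of its
#' conditions receives the rule's \code{accuracy * support} added to
#' the pair's edge strength; a rule with c conditions contributes that
#' amount to all \code{choose(c, 2)} pairs. Singleton rules contribute
#' no edges. Nodes are conditions rendered as \code{probe=state}, so the
#' same probe in two states is two distinct nodes.
#'
#' @param model a (typically filtered) \linkS4class{RuleModel}.
#' @param class_label the decision class to build the network for.
#' @return An \linkS4class{InteractionNetwork}; a class without
#'   conjunctive rules yields an empty edge set.
#' @examples
#' rules <- data.frame(
#'     conditions = I(list(c(cgA = "unmethylated", cgB = "intermediate"))),
#'     decision = "fetus", accuracy = 0.92, support = 25L, n_runs = 1L)
#' model <- new("RuleModel", rules = rules, classLabels = c("fetus", "old"),
#'              classSizes = c(fetus = 30L, old = 25L), nTotal = 55L)
#' buildInteractionNetwork(model, "fetus")@edges
#' @export
buildInteractionNetwork <- function(model, class_label) {
    stopifnot(is(model, "RuleModel"))
    if (!class_label %in% model@classLabels)
        stop("unknown class label: ", class_label)
    rules <- model@rules[model@rules$decision == class_label, , drop = FALSE]
    nodes <- character(0)
    strength <- numeric(0)
    n_rules <- integer(0)
    pair_key <- character(0)
    pair_a <- character(0)
    pair_b <- character(0)
    for (i in seq_len(nrow(rules))) {
        cc <- rules$conditions[[i]]
        cond <- paste(names(cc), cc, sep = "=")
        nodes <- union(nodes, cond)
        if (length(cond) < 2) next
        w <- rules$accuracy[i] * rules$support[i]
        cond <- sort(cond)
        for (a in seq_len(length(cond) - 1L)) {
            for (b in seq.int(a + 1L, length(cond))) {
                key <- paste(cond[a], cond[b], sep = "\r")
                hit <- match(key, pair_key)
                if (is.na(hit)) {
                    pair_key <- c(pair_key, key)
                    pair_a <- c(pair_a, cond[a])
                    pair_b <- c(pair_b, cond[b])
                    strength <- c(strength, w)
                    n_rules <- c(n_rules, 1L)
                } else {
                    strength[hit] <- strength[hit] + w
                    n_rules[hit] <- n_rules[hit] + 1L
                }
            }
        }
    }
    edges <- data.frame(cond_a = pair_a, cond_b = pair_b,
                        strength = strength, n_rules = n_rules,
                        stringsAsFactors = FALSE)
    edges <- edges[order(-edges$strength, -edges$n_rules,
                         edges$cond_a, edges$cond_b), , drop = FALSE]
    rownames(edges) <- NULL
    new("InteractionNetwork", classLabel = class_label, edges = edges,
        nodes = sort(nodes))
}

#' Strongest interactions of a network
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param top_k how many edges to return (default 2, the usual report
#'   size); fewer are returned if the network is smaller.
#' @return The top edges by strength, ties broken by \code{n_rules}
#'   then lexicographic node ids.
#' @export
topInteractions <- function(network, top_k = 2L) {
    stopifnot(is(network, "InteractionNetwork"))
    head(network@edges, top_k)
}

#' Write interaction edges as TSV, optionally as DOT
#'
#' @param networks list of \linkS4class{InteractionNetwork}s (or one).
#' @param path output TSV (columns class, cond_a, cond_b, strength,
#'   n_rules).
#' @param dot_path optional path for a Graphviz DOT rendering of the
#'   union graph.
#' @export
writeInteractions <- function(networks, path, dot_path = NULL) {
    if (is(networks, "InteractionNetwork")) networks <- list(networks)
    df <- do.call(rbind, lapply(networks, function(nw) {
        if (!nrow(nw@edges)) return(NULL)
        data.frame(class = nw@classLabel, nw@edges,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(df))
        df <- data.frame(class = character(), cond_a = character(),
                         cond_b = character(), strength = numeric(),
                         n_rules = integer())
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dot_path)) {
        lines <- c("graph interactions {",
                   sprintf('  "%s" -- "%s" [weight=%.4g, label="%s"];',
                           df$cond_a, df$cond_b, df$strength, df$class),
                   "}")
        writeLines(lines, dot_path)
    }
    invisible(path)
}
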