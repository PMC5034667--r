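# probe-id rendering shared by rule text and annotated outputs
.renderProbeIds <- function(ids, annotations) {
    idx <- match(ids, annotations$probe_id)
    vapply(seq_along(ids), function(i) {
        j <- idx[i]
        if (is.na(j)) return(paste0(ids[i], "(NA)"))
        gene <- annotations$gene[j]
        region <- annotations$region[j]
        if (is.na(gene) || !nzchar(gene)) return(paste0(ids[i], "(NA)"))
        if (!is.na(region) && region == "intergenic")
            paste0(ids[i], "(intergenic: ", gene, ")")
        else if (is.na(region) || !nzchar(region))
            paste0(ids[i], "(", gene, ")")
        else paste0(ids[i], "(", gene, "_", region, ")")
    }, character(1))
}

#' Join probe annotations onto a per-probe output
#'
#' Left-joins the annotation table and adds a \code{rendered} column in
#' the conventional report style: \code{cgID(GENE_region)}, intergenic
#' probes as \code{cgID(intergenic: GENE1, GENE2)} (flanking genes taken
#' from the comma-separated \code{gene} field), and unannotated probes
#' as \code{cgID(NA)}.
#'
#' @param output data.frame holding a probe-id column.
#' @param annotations annotation data.frame (\code{probe_id},
#'   \code{chrom}, \code{gene}, \code{region}, ...).
#' @param probe_col name of the probe-id column (default
#'   \code{"probe_id"}, falling back to \code{"feature_id"}).
#' @return The output with annotation columns and \code{rendered} added.
#' @examples
#' ann <- data.frame(probe_id = "cg01", gene = "HAAO", region = "upstream",
#'                   chrom = "2")
#' annotateProbes(data.frame(probe_id = "cg01", ri = 1), ann)$rendered
#' @export
annotateProbes <- function(output, annotations, probe_col = NULL) {
    if (is.null(probe_col))
        probe_col <- intersect(c("probe_id", "feature_id"), names(output))[1L]
    if (is.na(probe_col) || !probe_col %in% names(output))
        stop("no probe-id column found in output")
    ids <- output[[probe_col]]
    idx <- match(ids, annotations$probe_id)
    extra <- annotations[idx, setdiff(names(annotations), "probe_id"),
                         drop = FALSE]
    rownames(extra) <- NULL
    out <- cbind(output, extra)
    out$rendered <- .renderProbeIds(ids, annotations)
    out
}

#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's tunable parameters with the three interchange
#' input files and an output directory. The single \code{seed} drives
#' named sub-streams (MCFS, under-sampling, cross-validation), so each
#' stage is independently reproducible. The configuration round-trips
#' through YAML unchanged via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @param beta_file,sample_file,probe_file the interchange TSVs (see
#'   [writeCohort()]).
#' @param out_dir run directory for all stage outputs.
#' @param sd_cutoff probe SD filter threshold (default 0.02).
#' @param low,high discretization thresholds (defaults 0.2 / 0.8).
#' @param cut_ages binary-table sweep (default \code{0:60}).
#' @param mcfs list of [mcfsParams()] arguments (seed is derived).
#' @param k number of postnatal age groups for clustering (default 3;
#'   fetus always stays its own class).
#' @param boundaries optional explicit postnatal group boundaries; if
#'   \code{NULL} they are derived from the clustering.
#' @param undersample_reps under-sampling replicates (default 100).
#' @param cv_folds cross-validation folds (default 10).
#' @param rule_alpha,min_accuracy,support_frac rule filter thresholds.
#' @param top_k interactions reported per class (default 2).
#' @param induction_method \code{"exhaustive"} or \code{"johnson"}.
#' @param seed master seed.
#' @param check_files error if the input files do not exist (default
#'   TRUE; disable to build configs ahead of the inputs).
#' @return A validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(beta_file, sample_file, probe_file, out_dir,
                           sd_cutoff = 0.02, low = 0.2, high = 0.8,
                           cut_ages = 0:60, mcfs = list(), k = 3L,
                           boundaries = NULL, undersample_reps = 100L,
                           cv_folds = 10L, rule_alpha = 0.05,
                           min_accuracy = 0.75, support_frac = 0.5,
                           top_k = 2L, induction_method = "exhaustive",
                           seed = 1L, check_files = TRUE) {
    if (check_files) {
        for (f in c(beta_file, sample_file, probe_file))
            if (!file.exists(f)) stop("input file does not exist: ", f)
    }
    if (sd_cutoff < 0 || low <= 0 || high >= 1 || low >= high)
        stop("invalid thresholds: need 0 < low < high < 1 and sd_cutoff >= 0")
    if (rule_alpha <= 0 || rule_alpha >= 1 ||
        min_accuracy < 0 || min_accuracy >= 1 ||
        support_frac <= 0 || support_frac > 1)
        stop("invalid rule-filter thresholds")
    induction_method <- match.arg(induction_method,
                                  c("exhaustive", "johnson"))
    structure(list(beta_file = beta_file, sample_file = sample_file,
                   probe_file = probe_file, out_dir = out_dir,
                   sd_cutoff = sd_cutoff, low = low, high = high,
                   cut_ages = as.integer(cut_ages), mcfs = mcfs,
                   k = as.integer(k), boundaries = boundaries,
                   undersample_reps = as.integer(undersample_reps),
                   cv_folds = as.integer(cv_folds),
                   rule_alpha = rule_alpha, min_accuracy = min_accuracy,
                   support_frac = support_frac, top_k = as.integer(top_k),
                   induction_method = induction_method,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
    stopifnot(inherits(config, "PipelineConfig"))
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path, check_files = TRUE) {
    x <- yaml::read_yaml(path)
    do.call(pipelineConfig, c(x, list(check_files = check_files)))
}

.subSeed <- function(seed, offset) as.integer((seed + offset) %% 2^30)

#' Run the full discovery pipeline
#'
#' Executes, in order: probe filtering, discretization, the binary
#' age-cut table sweep, MCFS per cut, the Jaccard distance matrix and
#' complete-linkage clustering of cuts (cut 0 is excluded from the
#' clustering — the fetal transition always forms its own class),
#' the multi-class table over the derived (or supplied) boundaries,
#' MCFS on it, restriction to its significant sites, under-sampled rule
#' induction and combination, hypergeometric scoring and filtering, the
#' regression cross-check, per-class interaction networks, and
#' stratified cross-validation. Every stage writes its artifact into
#' \code{out_dir} and appends to \code{run.log}; a failure aborts with
#' the stage name, leaving earlier outputs in place.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with every stage's in-memory result plus
#'   \code{summary} (named counts and accuracies).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$out_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    log_file <- file.path(out, "run.log")
    log <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
        cat(line, "\n", file = log_file, append = TRUE, sep = "")
        message(line)
    }
    stage <- function(name, expr) {
        log("stage ", name, " ...")
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    log("pipeline start, seed ", config$seed)
    writePipelineConfig(config, file.path(out, "config.yaml"))

    cohort <- stage("read_inputs",
        readCohort(config$beta_file, config$sample_file, config$probe_file))
    fl <- stage("filter_probes", filterProbes(cohort, config$sd_cutoff))
    writeFilterReport(fl$report, file.path(out, "filter_report.tsv"))
    cohort <- fl$cohort
    ann <- data.frame(probe_id = rownames(cohort),
                      as.data.frame(probeAnnotations(cohort)))
    ages <- sampleAges(cohort)

    states <- stage("discretize",
        discretizeCohort(cohort, config$low, config$high))
    tabs <- stage("binary_tables",
        makeBinaryTables(states, ages, config$cut_ages))
    log(length(tabs), " binary tables")

    mcfs_cut <- do.call(mcfsParams,
                        c(config$mcfs,
                          list(seed = .subSeed(config$seed, 101L))))
    sel <- stage("mcfs_per_cut", selectSignificantPerCut(tabs, mcfs_cut))
    write.table(sel$counts, file.path(out, "sfa_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    postnatal <- vapply(tabs, cutAge, numeric(1)) > 0
    dm <- stage("distance_matrix", buildDistanceMatrix(sel$sfa[postnatal]))
    writeDistanceMatrix(dm, file.path(out, "distance_matrix.tsv"))
    grouping <- stage("cluster_cuts", clusterCuts(dm, config$k))
    exportDendrogram(grouping, file.path(out, "dendrogram.nwk"))

    boundaries <- config$boundaries
    if (is.null(boundaries)) {
        if (!grouping@contiguous)
            stop("pipeline stage 'cluster_cuts' failed: non-contiguous ",
                 "age groups; supply boundaries explicitly")
        boundaries <- c(0, grouping@boundaries[-1L])
    }
    log("age-group boundaries: ", paste(boundaries, collapse = ", "))

    mtab <- stage("multiclass_table",
        makeMulticlassTable(states, ages, boundaries))
    writeDecisionTable(mtab, file.path(out, "decision_table_multiclass.tsv"))
    mcfs_multi <- do.call(mcfsParams,
                          c(config$mcfs,
                            list(seed = .subSeed(config$seed, 202L))))
    imp <- stage("mcfs_multiclass", runMCFS(mtab, mcfs_multi))
    writeImportanceTable(imp, file.path(out, "importance_multiclass.tsv"))
    sig <- significantFeatures(imp)
    if (length(sig) < 2) {
        warning("fewer than 2 significant sites; keeping all features")
        sig <- colnames(featureStates(mtab))
    }
    mtab_sig <- subsetFeatures(mtab, sig)

    reps <- stage("undersample",
        underSample(mtab_sig, config$undersample_reps,
                    seed = .subSeed(config$seed, 303L)))
    model <- stage("induce_rules",
        combineModels(lapply(reps, induceRules,
                             method = config$induction_method), mtab_sig))
    model <- stage("score_rules", scoreRules(model))
    writeRules(model, file.path(out, "rules_all.tsv"), ann)
    filtered <- stage("filter_rules",
        filterRules(model, config$rule_alpha, config$min_accuracy,
                    config$support_frac))
    filtered <- stage("regression_check",
        regressionCheckModel(filtered, cohort))
    writeRules(filtered, file.path(out, "rules_filtered.tsv"), ann)

    networks <- stage("interactions",
        lapply(setNames(nm = filtered@classLabels),
               function(cl) buildInteractionNetwork(filtered, cl)))
    writeInteractions(networks, file.path(out, "interactions.tsv"),
                      dot_path = file.path(out, "interactions.dot"))
    top <- lapply(networks, topInteractions, top_k = config$top_k)

    cv <- stage("cross_validation",
        crossValidate(mtab_sig, folds = config$cv_folds,
                      undersample_reps = config$undersample_reps,
                      seed = .subSeed(config$seed, 404L),
                      method = config$induction_method))
    write.table(data.frame(observed = rownames(cv@counts), cv@counts,
                           check.names = FALSE),
                file.path(out, "confusion_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    summary <- list(
        n_input_probes = fl$report$n_input,
        n_retained_probes = fl$report$n_retained,
        n_binary_tables = length(tabs),
        boundaries = as.numeric(boundaries),
        n_significant_multiclass = length(significantFeatures(imp)),
        n_rules_combined = nrow(modelRules(model)),
        n_rules_filtered = nrow(modelRules(filtered)),
        cv_overall_accuracy = cv@overallAccuracy,
        seed = config$seed)
    yaml::write_yaml(summary, file.path(out, "summary.yaml"))
    log("pipeline done; overall CV accuracy ",
        sprintf("%.1f%%", 100 * cv@overallAccuracy))

    invisible(list(cohort = cohort, filter_report = fl$report,
                   states = states, binary_tables = tabs, sfa = sel,
                   distance_matrix = dm, grouping = grouping,
                   boundaries = boundaries, multiclass_table = mtab_sig,
                   importance = imp, model = model, filtered = filtered,
                   networks = networks, top_interactions = top,
                   confusion = cv, summary = summary))
}
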