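#' Describe a planted age-transition CpG site
#'
#' A planted site switches its expected beta value at a chosen transition
#' age, emulating the patterns seen on real arrays where a site moves
#' e.g. from unmethylated in fetal samples to intermediate in adulthood.
#' For \code{direction = "up"} the expected beta is \code{low_state_mean}
#' before the transition age and \code{high_state_mean} from it onwards;
#' \code{direction = "down"} reverses the two.
#'
#' @param probe_id character probe identifier (cg-style).
#' @param transition_age integer years; 0 plants a birth transition
#'   (fetal samples carry negative ages).
#' @param direction \code{"up"} or \code{"down"}.
#' @param low_state_mean,high_state_mean expected beta on either side of
#'   the transition; must satisfy \code{low_state_mean < high_state_mean},
#'   both in [0,1].
#' @param noise_sd per-sample Gaussian noise SD on the beta scale (> 0).
#' @return A validated \code{PlantedSite} list.
#' @examples
#' plantedSite("cgSIG0001", 30, "up", 0.1, 0.5, 0.05)
#' @export
plantedSite <- function(probe_id, transition_age, direction = c("up", "down"),
                        low_state_mean, high_state_mean, noise_sd) {
    direction <- match.arg(direction)
    if (!is.character(probe_id) || length(probe_id) != 1L || !nzchar(probe_id))
        stop("invalid PlantedSite field 'probe_id': must be one non-empty string")
    if (!is.numeric(transition_age) || length(transition_age) != 1L)
        stop("invalid PlantedSite field 'transition_age'")
    if (!is.numeric(low_state_mean) || low_state_mean < 0 || low_state_mean > 1)
        stop("invalid PlantedSite field 'low_state_mean': must lie in [0,1]")
    if (!is.numeric(high_state_mean) || high_state_mean < 0 ||
        high_state_mean > 1)
        stop("invalid PlantedSite field 'high_state_mean': must lie in [0,1]")
    if (low_state_mean >= high_state_mean)
        stop("invalid PlantedSite: low_state_mean must be < high_state_mean")
    if (!is.numeric(noise_sd) || noise_sd <= 0)
        stop("invalid PlantedSite field 'noise_sd': must be > 0")
    structure(list(probe_id = probe_id,
                   transition_age = as.numeric(transition_age),
                   direction = direction,
                   low_state_mean = as.numeric(low_state_mean),
                   high_state_mean = as.numeric(high_state_mean),
                   noise_sd = as.numeric(noise_sd)),
              class = "PlantedSite")
}

#' Specify a synthetic methylation cohort
#'
#' Defaults mirror the prefrontal-cortex study design the package is
#' validated against: 108 samples spanning fetal to 84 years, with at
#' least a quarter of the cohort fetal. Fetal samples are encoded with a
#' single negative age (the lower end of \code{age_range}), so every age
#' cut is a plain threshold.
#'
#' @param n_samples number of samples (>= 4).
#' @param age_range numeric length-2, \code{c(min_age, max_age)} in
#'   years; a negative minimum requests fetal samples at that age.
#' @param n_noise_sites number of background (non-planted) CpG sites.
#' @param planted list of [plantedSite()] objects.
#' @param seed integer random seed; a fixed seed makes the generated
#'   cohort bit-identical across runs.
#' @param noise_site_sd per-site SD of the background sites (beta scale).
#' @param ages optional explicit per-sample ages overriding the sampled
#'   ones (length \code{n_samples}).
#' @return A validated \code{CohortSpec} list.
#' @examples
#' cohortSpec(20, c(-0.5, 60), n_noise_sites = 10, seed = 1)
#' @export
cohortSpec <- function(n_samples = 108L, age_range = c(-0.5, 84),
                       n_noise_sites = 1000L, planted = list(), seed = 1L,
                       noise_site_sd = 0.04, ages = NULL) {
    if (!is.numeric(n_samples) || n_samples < 4)
        stop("invalid CohortSpec field 'n_samples': must be >= 4")
    if (length(age_range) != 2L || age_range[1L] >= age_range[2L])
        stop("invalid CohortSpec field 'age_range': need min_age < max_age")
    if (!is.numeric(n_noise_sites) || n_noise_sites < 0)
        stop("invalid CohortSpec field 'n_noise_sites': must be >= 0")
    if (!all(vapply(planted, inherits, logical(1), "PlantedSite")))
        stop("invalid CohortSpec field 'planted': list of plantedSite()")
    ids <- vapply(planted, `[[`, character(1), "probe_id")
    if (anyDuplicated(ids))
        stop("invalid CohortSpec field 'planted': duplicate probe ids")
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("invalid CohortSpec field 'seed'")
    if (!is.numeric(noise_site_sd) || noise_site_sd <= 0)
        stop("invalid CohortSpec field 'noise_site_sd': must be > 0")
    if (!is.null(ages)) {
        if (length(ages) != n_samples)
            stop("invalid CohortSpec field 'ages': length must equal n_samples")
        if (min(ages) < age_range[1L] || max(ages) > age_range[2L])
            stop("invalid CohortSpec field 'ages': outside age_range")
    }
    structure(list(n_samples = as.integer(n_samples),
                   age_range = as.numeric(age_range),
                   n_noise_sites = as.integer(n_noise_sites),
                   planted = planted, seed = as.integer(seed),
                   noise_site_sd = as.numeric(noise_site_sd), ages = ages),
              class = "CohortSpec")
}

#' Construct a MethylationCohort
#'
#' @param betas numeric matrix, probes x samples, values in [0,1];
#'   rownames are probe ids, colnames sample ids.
#' @param ages numeric per-sample ages in years (negative = fetal).
#' @param annotations data.frame with columns \code{probe_id},
#'   \code{chrom}, \code{gene}, \code{region}, \code{nonspecific},
#'   \code{polymorphic}; one row per probe.
#' @return A \linkS4class{MethylationCohort}.
#' @export
MethylationCohort <- function(betas, ages, annotations) {
    betas <- as.matrix(betas)
    if (ncol(betas) != length(ages))
        stop("length(ages) must equal ncol(betas)")
    if (is.null(colnames(betas)))
        colnames(betas) <- sprintf("sample%03d", seq_len(ncol(betas)))
    if (nrow(betas) > 0) {
        if (is.null(rownames(betas)))
            stop("betas must have probe ids as rownames")
        idx <- match(rownames(betas), annotations$probe_id)
        if (anyNA(idx))
            stop("probes missing from annotations: ",
                 paste(head(rownames(betas)[is.na(idx)], 5L), collapse = ", "))
        annotations <- annotations[idx, , drop = FALSE]
    }
    rd <- DataFrame(annotations[setdiff(names(annotations), "probe_id")])
    rownames(rd) <- rownames(betas)
    new("MethylationCohort", SummarizedExperiment(
        assays = SimpleList(beta = betas),
        rowData = rd,
        colData = DataFrame(age_years = as.numeric(ages),
                            is_fetal = ages < 0,
                            row.names = colnames(betas))))
}

.truncate01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic methylation cohort
#'
#' Background sites draw their per-site baseline from a bimodal mixture
#' (a mode near beta 0.05, a mode near 0.9, and a uniform intermediate
#' shoulder) matching the overall beta distribution of methylation
#' arrays; planted sites switch their expected beta at their transition
#' age. Per-sample noise is Gaussian, truncated to [0,1] so a fixed seed
#' is exactly reproducible. When the age range dips below zero, at least
#' \code{ceiling(n_samples/4)} samples are fetal; postnatal ages are
#' integers sampled uniformly with both range endpoints forced present,
#' so every integer age cut splits the cohort in two.
#'
#' Noise is assigned in age-sorted order, so generation commutes with
#' shuffling the sample order (for distinct ages).
#'
#' @param spec a [cohortSpec()].
#' @return A \linkS4class{MethylationCohort} with planted probe ids
#'   carrying their annotation rows first.
#' @examples
#' sp <- cohortSpec(24, c(-0.5, 60), n_noise_sites = 50,
#'                  planted = list(plantedSite("cgSIG1", 30, "up",
#'                                             0.1, 0.5, 0.05)),
#'                  seed = 7)
#' cohort <- simulateCohort(sp)
#' dim(betaValues(cohort))
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    n <- spec$n_samples
    ages <- spec$ages
    if (is.null(ages)) {
        minA <- spec$age_range[1L]; maxA <- spec$age_range[2L]
        if (minA < 0) {
            n_fetal <- ceiling(n / 4)
            post_lo <- 0L
        } else {
            n_fetal <- 0L
            post_lo <- as.integer(ceiling(minA))
        }
        n_post <- n - n_fetal
        post_hi <- as.integer(floor(maxA))
        grid <- seq.int(post_lo, post_hi)
        post <- if (n_post <= 2L) rep(c(post_lo, post_hi), length.out = n_post)
                else c(post_lo, post_hi,
                       sample(grid, n_post - 2L, replace = TRUE))
        ages <- c(rep(minA, n_fetal), post)
    }
    ord <- order(ages)
    ages_sorted <- ages[ord]

    n_noise <- spec$n_noise_sites
    n_planted <- length(spec$planted)
    n_sites <- n_noise + n_planted
    betas <- matrix(numeric(0), nrow = 0, ncol = n)

    planted_ids <- vapply(spec$planted, `[[`, character(1), "probe_id")
    noise_ids <- if (n_noise) sprintf("cg%08d", seq_len(n_noise)) else character()
    if (n_sites > 0) {
        betas <- matrix(NA_real_, n_sites, n)
        for (i in seq_len(n_planted)) {
            ps <- spec$planted[[i]]
            before <- ages_sorted < ps$transition_age
            mu <- if (ps$direction == "up")
                      ifelse(before, ps$low_state_mean, ps$high_state_mean)
                  else ifelse(before, ps$high_state_mean, ps$low_state_mean)
            betas[i, ] <- .truncate01(rnorm(n, mu, ps$noise_sd))
        }
        for (j in seq_len(n_noise)) {
            mode <- sample(c("low", "high", "mid"), 1L,
                           prob = c(0.45, 0.35, 0.20))
            mu <- switch(mode,
                         low = min(max(rnorm(1L, 0.05, 0.03), 0.01), 0.15),
                         high = min(max(rnorm(1L, 0.90, 0.05), 0.75), 0.99),
                         mid = runif(1L, 0.25, 0.75))
            betas[n_planted + j, ] <- .truncate01(
                rnorm(n, mu, spec$noise_site_sd))
        }
        # undo the age sort so columns follow the spec's sample order
        betas <- betas[, order(ord), drop = FALSE]
        rownames(betas) <- c(planted_ids, noise_ids)
        colnames(betas) <- sprintf("sample%03d", seq_len(n))
    }

    ann <- data.frame(
        probe_id = c(planted_ids, noise_ids),
        chrom = character(n_sites), gene = character(n_sites),
        region = character(n_sites),
        nonspecific = logical(n_sites), polymorphic = logical(n_sites),
        stringsAsFactors = FALSE)
    if (n_sites > 0) {
        ann$gene <- sprintf("GENE%04d", seq_len(n_sites))
        ann$region <- sample(.REGION_TAGS, n_sites, replace = TRUE)
        if (n_planted) {
            ann$chrom[seq_len(n_planted)] <-
                as.character(sample(1:22, n_planted, replace = TRUE))
        }
        if (n_noise) {
            idx <- n_planted + seq_len(n_noise)
            ann$chrom[idx] <- sample(c(as.character(1:22), "X"), n_noise,
                                     replace = TRUE,
                                     prob = c(rep(0.96 / 22, 22), 0.04))
            ann$nonspecific[idx] <- runif(n_noise) < 0.095
            ann$polymorphic[idx] <- runif(n_noise) < 0.028
        }
    }
    MethylationCohort(betas, ages, ann)
}

#' The bundled planted-signal cohort
#'
#' The validation fixture used throughout the package: 100 samples
#' spanning fetal to 84 years (the study-like design), 200 background
#' sites, and 10 planted sites that all transition at age 30 — five
#' rising from beta 0.15 to 0.45 and five falling from 0.85 to 0.55,
#' each with per-sample noise SD 0.10. The low side of the rising sites
#' straddles the 0.2 discretization threshold (as real transitioning
#' sites do, e.g. shifts from ~0.2 to ~0.4), so a single site's
#' discretized state is informative but noisy: about a third of
#' pre-transition samples already read intermediate. Rule models must
#' therefore combine sites, and single-site rules sit near the
#' accuracy-filter boundary.
#'
#' @param seed integer seed for the generator.
#' @return A \linkS4class{MethylationCohort}.
#' @examples
#' cohort <- examplePlantedCohort(seed = 1)
#' table(sampleAges(cohort) < 30)
#' @export
examplePlantedCohort <- function(seed = 1L) {
    planted <- c(
        lapply(1:5, function(i)
            plantedSite(sprintf("cgSIGUP%03d", i), 30, "up", 0.15, 0.45, 0.10)),
        lapply(1:5, function(i)
            plantedSite(sprintf("cgSIGDN%03d", i), 30, "down", 0.55, 0.85, 0.10)))
    simulateCohort(cohortSpec(100L, c(-0.5, 84), n_noise_sites = 200L,
                              planted = planted, seed = seed))
}

#' Write / read the TSV interchange files for a cohort
#'
#' Three tab-separated files form the interchange format: the beta
#' matrix (first column \code{probe_id}, one column per sample), the
#' sample sheet (\code{sample_id}, \code{age_years}, \code{is_fetal})
#' and the probe annotation table (\code{probe_id}, \code{chrom},
#' \code{gene}, \code{region}, \code{nonspecific}, \code{polymorphic}).
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param dir output directory (created if missing).
#' @return \code{writeCohort}: the three file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    b <- betaValues(cohort)
    paths <- file.path(dir, c("betas.tsv", "samples.tsv", "probes.tsv"))
    write.table(data.frame(probe_id = rownames(b), b, check.names = FALSE),
                paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = colnames(cohort),
                           age_years = colData(cohort)$age_years,
                           is_fetal = colData(cohort)$is_fetal),
                paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(probe_id = rownames(b),
                           as.data.frame(probeAnnotations(cohort))),
                paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' @rdname writeCohort
#' @param beta_file,sample_file,probe_file the three TSV paths.
#' @return \code{readCohort}: a \linkS4class{MethylationCohort}.
#' @export
readCohort <- function(beta_file, sample_file, probe_file) {
    for (f in c(beta_file, sample_file, probe_file))
        if (!file.exists(f)) stop("input file not found: ", f)
    bd <- read.delim(beta_file, check.names = FALSE)
    betas <- as.matrix(bd[-1L])
    rownames(betas) <- bd$probe_id
    ss <- read.delim(sample_file)
    idx <- match(colnames(betas), ss$sample_id)
    if (anyNA(idx)) stop("sample sheet is missing samples present in betas")
    ann <- read.delim(probe_file)
    MethylationCohort(betas, ss$age_years[idx], ann)
}
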