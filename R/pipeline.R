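#' Assemble a pipeline configuration
#'
#' Either \code{simulate} (a list of [designSpec()] / [effectSpec()]
#' arguments) or the three input paths must be given. The platform profile
#' decides normalization (RPKM for RNA-seq counts), the expression gate and
#' the floor.
#'
#' @param profile gate profile name (see [gateProfile()]).
#' @param outDir output directory, created if needed.
#' @param simulate optional named list passed to [designSpec()] (fields
#'   \code{nGenes}, \code{nReplicates}, ...) plus an optional \code{effects}
#'   sub-list passed to [effectSpec()].
#' @param matrixPath,designPath,annotationPath input files when not
#'   simulating.
#' @param thresholds a [thresholdConfig()].
#' @param categoryRulesPath YAML rule file; \code{NULL} for the shipped
#'   default.
#' @param seed integer seed used by the simulator.
#' @param figures also render figure files (PDF) next to the tables.
#' @return a validated config list for [runPipeline()].
#' @export
pipelineConfig <- function(profile = "soybean_rnaseq",
                           outDir = tempfile("azflux_run_"),
                           simulate = NULL,
                           matrixPath = NULL, designPath = NULL,
                           annotationPath = NULL,
                           thresholds = thresholdConfig(),
                           categoryRulesPath = NULL,
                           seed = 1L,
                           figures = FALSE) {
    profile <- match.arg(profile, c("soybean_rnaseq", "tomato_microarray",
                                    "arabidopsis_readcount"))
    if (is.null(simulate) && (is.null(matrixPath) || is.null(designPath)))
        stop("either simulate parameters or matrix+design paths are required")
    for (p in c(matrixPath, designPath, annotationPath, categoryRulesPath))
        if (!is.null(p) && !file.exists(p)) stop("input path missing: ", p)
    list(profile = profile, outDir = outDir, simulate = simulate,
         matrixPath = matrixPath, designPath = designPath,
         annotationPath = annotationPath, thresholds = thresholds,
         categoryRulesPath = categoryRulesPath, seed = as.integer(seed),
         figures = isTRUE(figures))
}

.platformForProfile <- function(profile) {
    switch(profile,
           soybean_rnaseq = "rnaseq",
           tomato_microarray = "microarray",
           arabidopsis_readcount = "readcount")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the experiment; normalize (RPKM for
#' RNA-seq counts); apply the platform expression gate to unfloored values;
#' restrict to expressed genes and apply the floor; compute ratio statistics
#' and Welch-t p-values; classify genes through the >8-fold / p < 0.015
#' cascade; assign functional categories and aggregate their
#' percent-of-transcriptome profiles; serialize the heat-map panel,
#' time-course and volcano tables plus a JSON run manifest with per-stage
#' gene counts. Identical config and inputs produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()] (or a YAML file path holding one).
#' @return invisibly, a list with the intermediate objects (\code{experiment},
#'   \code{normalized}, \code{expressed}, \code{floored}, \code{diff},
#'   \code{mapping}, \code{profile}, \code{manifest}, ...).
#' @examples
#' cfg <- pipelineConfig(simulate = list(nGenes = 60), seed = 11)
#' res <- runPipeline(cfg)
#' res$manifest$counts
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- .configFromYaml(config)
    stage <- "setup"
    onFail <- function(e)
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    tryCatch({
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        gp <- gateProfile(config$profile)
        platform <- .platformForProfile(config$profile)

        stage <- "load"
        if (!is.null(config$simulate)) {
            sim <- config$simulate
            effArgs <- sim$effects %||% list()
            sim$effects <- NULL
            sim$platform <- platform
            sim$seed <- config$seed
            se <- simulateExperiment(do.call(designSpec, sim),
                                     do.call(effectSpec, effArgs))
            writeTruth(plantedTruth(se), file.path(config$outDir,
                                                   "truth.tsv"))
        } else {
            se <- readAZExperiment(config$matrixPath, config$designPath,
                                   config$annotationPath,
                                   valueKind = if (platform == "microarray")
                                       "signal" else "counts")
        }

        stage <- "normalize"
        norm <- if (valueKind(se) == "counts" && gp@valueKind == "rpkm")
            computeRPKM(se) else se
        if (valueKind(norm) != gp@valueKind)
            stop("profile '", gp@name, "' applies to ", gp@valueKind,
                 " values, matrix holds ", valueKind(norm))

        stage <- "gate"
        expressed <- applyGate(norm, gp)

        stage <- "floor"
        floored <- applyFloor(norm[expressed, ], gp@floor)
        writeExpressionMatrix(floored,
                              file.path(config$outDir,
                                        "normalized_matrix.tsv"))
        writeLines(expressed, file.path(config$outDir,
                                        "expressed_genes.txt"))

        if (platform == "readcount") {
            stage <- "differential"
            diff <- genotypeDifferential(floored)
            thr <- config$thresholds
            gt <- function(v, t) if (thr@strict) v > t else v >= t
            diff$changed_up <- gt(diff$log2_fc, thr@foldLog2)
            diff$changed_down <- gt(-diff$log2_fc, thr@foldLog2)
            diff$significant_changed <- diff$changed_up &
                diff$pvalue < thr@pvalueMax
            writeDifferentialTable(diff, file.path(config$outDir,
                                                   "differential.tsv"))
            stage <- "report"
            volcano <- buildVolcano(diff, significanceP = thr@pvalueMax)
            .writeTsv(volcano, file.path(config$outDir, "volcano.tsv"))
            if (config$figures)
                ggplot2::ggsave(file.path(config$outDir, "volcano.pdf"),
                                plotVolcano(volcano), width = 5, height = 4)
            counts <- list(
                genes = nrow(se), samples = ncol(se),
                expressed = length(expressed),
                changed_up = sum(diff$changed_up),
                changed_down = sum(diff$changed_down),
                significant_changed = sum(diff$significant_changed))
            mapping <- NULL; catProfile <- NULL
        } else {
            stage <- "differential"
            diff <- classifyGenes(differentialTable(floored),
                                  config$thresholds)
            writeDifferentialTable(diff, file.path(config$outDir,
                                                   "differential.tsv"))

            stage <- "categories"
            rules <- readCategoryRules(config$categoryRulesPath)
            mapping <- assignCategories(geneAnnotation(floored), rules)
            mapDf <- data.frame(
                gene_id = unlist(mapping, use.names = FALSE),
                category = rep(names(mapping), lengths(mapping)),
                stringsAsFactors = FALSE)
            .writeTsv(mapDf, file.path(config$outDir,
                                       "category_mapping.tsv"))
            catProfile <- suppressMessages(categoryProfile(floored, mapping))
            pct <- categoryPercent(catProfile)
            .writeTsv(data.frame(category = rownames(pct),
                                 n_genes = as.integer(
                                     categoryCounts(catProfile)),
                                 pct, check.names = FALSE),
                      file.path(config$outDir, "category_profile.tsv"))
            .writeTsv(as.data.frame(categoryDominant(catProfile)),
                      file.path(config$outDir, "category_dominant.tsv"))

            stage <- "report"
            panels <- lapply(names(mapping), function(catName) {
                g <- intersect(mapping[[catName]], rownames(diff))
                if (!length(g)) return(NULL)
                p <- suppressMessages(buildHeatmapPanel(diff, g))
                data.frame(category = catName, gene_id = rownames(p), p,
                           row.names = NULL, check.names = FALSE)
            })
            panelTab <- do.call(rbind, panels)
            .writeTsv(panelTab %||%
                          data.frame(category = character(),
                                     gene_id = character()),
                      file.path(config$outDir, "heatmap_panels.tsv"))
            prof <- lapply(names(mapping), function(catName) {
                g <- intersect(mapping[[catName]], rownames(floored))
                if (!length(g)) return(NULL)
                base <- buildTimecourseProfile(floored, g, label = catName)
                sig <- intersect(g, rownames(diff)[diff$significant_changed])
                if (length(sig))
                    base <- rbind(base,
                                  buildTimecourseProfile(
                                      floored, sig,
                                      label = paste0(catName, " (L2>3)")))
                base
            })
            profTab <- do.call(rbind, prof)
            .writeTsv(profTab %||%
                          data.frame(set = character(), tissue = character(),
                                     time_h = numeric(),
                                     percent = numeric()),
                      file.path(config$outDir, "timecourse_profiles.tsv"))
            if (config$figures && !is.null(profTab))
                ggplot2::ggsave(file.path(config$outDir, "timecourse.pdf"),
                                plotTimecourse(profTab),
                                width = 10, height = 8)
            counts <- list(
                genes = nrow(se), samples = ncol(se),
                expressed = length(expressed),
                changed_up = sum(diff$changed_up),
                changed_down = sum(diff$changed_down),
                az_specific = sum(diff$az_specific),
                significant_changed = sum(diff$significant_changed))
        }

        stage <- "manifest"
        manifest <- list(
            package = "azflux",
            version = as.character(utils::packageVersion("azflux")),
            profile = config$profile, seed = config$seed,
            thresholds = list(fold_log2 = config$thresholds@foldLog2,
                              pvalue_max = config$thresholds@pvalueMax,
                              az_specific_log2 =
                                  config$thresholds@azSpecificLog2,
                              strict = config$thresholds@strict),
            simulated = !is.null(config$simulate),
            counts = counts)
        jsonlite::write_json(manifest,
                             file.path(config$outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        invisible(list(experiment = se, normalized = norm,
                       expressed = expressed, floored = floored,
                       diff = diff, mapping = mapping,
                       categoryProfile = catProfile, manifest = manifest,
                       outDir = config$outDir))
    }, error = onFail)
}

# YAML pipeline config: top-level fields as in pipelineConfig(), with
# thresholds given as a plain mapping
.configFromYaml <- function(path) {
    y <- yaml::read_yaml(path)
    thr <- y$thresholds %||% list()
    y$thresholds <- thresholdConfig(
        foldLog2 = thr$fold_log2 %||% 3,
        pvalueMax = thr$pvalue_max %||% 0.015,
        azSpecificLog2 = thr$az_specific_log2 %||% 3,
        strict = thr$strict %||% TRUE)
    do.call(pipelineConfig, y)
}
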