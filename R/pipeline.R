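## End-to-end orchestration: synthetic inputs (or user-supplied tables)
## -> isochore map -> per-contrast expression statistics -> enrichment ->
## compartment bias and dichotomy calls -> phenotype tests, with TSV/JSON
## outputs and a reproducible run manifest.

#' Pipeline configuration
#'
#' @param design a [syntheticDesign()] describing the synthetic inputs
#' @param mcw an [mcwConfig()] shared by every MCW test in the run
#' @param gseaNPerm permutations per gene set
#' @param alpha significance threshold for the dichotomy call
#' @param windowSize isochore window size in bases
#' @param outDir output directory (created if missing); NULL to skip
#'   writing files
#' @return list of class "PipelineConfig"
#' @export
pipelineConfig <- function(design = syntheticDesign(),
                           mcw = mcwConfig(),
                           gseaNPerm = 200L,
                           alpha = 0.05,
                           windowSize = 100000L,
                           outDir = NULL) {
    structure(list(design = design, mcw = mcw,
                   gseaNPerm = as.integer(gseaNPerm), alpha = alpha,
                   windowSize = as.integer(windowSize), outDir = outDir),
              class = "PipelineConfig")
}

.writeTsv <- function(df, dir, name) {
    if (is.null(dir)) return(invisible(NULL))
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Stages, in dependency order: genome generation, isochore segmentation,
#' gene annotation and isochore assignment, count generation, then per
#' contrast: expressed-gene filtering, cpm normalization, per-gene uMCW
#' statistics, pre-ranked GSEA, compartment bMCW tests and the dichotomy
#' call; finally phenotype uMCW/mbMCW tests and the plasma PCA. All
#' randomness flows from the design and MCW seeds, so a rerun reproduces
#' identical outputs (and identical output-file hashes).
#'
#' @param config a [pipelineConfig()]
#' @return (invisibly) list with isochores, assignments, truth, and per
#'   contrast geneBias/gsea/compartment/dichotomy, plus phenotype results
#'   and the manifest
#' @export
runPipeline <- function(config = pipelineConfig()) {
    sdn <- config$design
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    message("stage: genome")
    gen <- generateGenome(sdn)
    seg <- segmentGenome(gen$genome, windowSize = config$windowSize)

    message("stage: annotation")
    ann <- generateAnnotation(gen, sdn)
    assignments <- assignGenes(ann, seg$isochores)
    keep <- chromosomeFilter(assignments$chrom)
    assignments <- assignments[keep, , drop = FALSE]
    .writeTsv(assignments, outDir, "gene_assignments.tsv")
    if (!is.null(outDir))
        writeIsochoreBed(seg$isochores, file.path(outDir, "isochores.bed"))

    message("stage: counts")
    cnt <- generateCounts(sdn, ann)
    es <- cnt$es
    sets <- generateGeneSets(cnt$truth$gene_id, cnt$truth$class, sdn)

    contrasts <- enumerateContrasts(sdn$design)
    perContrast <- list()
    for (i in seq_len(nrow(contrasts))) {
        ct <- contrasts[i, , drop = FALSE]
        message("stage: contrast ", ct$contrast_id)
        kept <- filterExpressed(es, ct)
        kept <- intersect(kept, assignments$gene_id)
        sub <- cpmNormalize(es[kept, ])
        gb <- perGeneUmcw(sub, ct, config$mcw)
        stat <- stats::setNames(gb$bias_index, gb$gene_id)
        gsea <- gseaPreranked(stat, sets, nPerm = config$gseaNPerm,
                              seed = config$mcw$seed + i)
        comp <- compartmentBmcw(stat, assignments, config$mcw)
        dich <- dichotomyCall(comp, alpha = config$alpha)
        comp$table$contrast_id <- ct$contrast_id
        gb$dichotomy <- NULL
        perContrast[[ct$contrast_id]] <-
            list(geneBias = gb, gsea = gsea, compartment = comp$table,
                 dichotomy = dich)
    }
    .writeTsv(do.call(rbind, lapply(perContrast, `[[`, "geneBias")),
              outDir, "gene_bias.tsv")
    .writeTsv(do.call(rbind, lapply(perContrast, `[[`, "compartment")),
              outDir, "compartment_bias.tsv")

    message("stage: phenotypes")
    ph <- generatePhenotypes(sdn)
    exposures <- setdiff(sdn$design$groups, sdn$design$control)
    phenoRows <- list()
    for (tr in unique(ph$traits$trait)) {
        for (sx in sdn$design$sexes) {
            tdf <- ph$traits[ph$traits$trait == tr &
                             ph$traits$sex == sx, , drop = FALSE]
            norm <- normalizeTrait(tdf$value, tdf$age_days)
            for (ex in exposures) {
                r <- umcwTest(norm[tdf$group == ex],
                              norm[tdf$group == sdn$design$control],
                              config$mcw)
                phenoRows[[length(phenoRows) + 1L]] <- data.frame(
                    trait = tr, sex = sx, exposure = ex,
                    test = "umcw", bias_index = r@biasIndex,
                    p_upper = r@pUpper, p_lower = r@pLower)
            }
        }
    }
    for (sx in sdn$design$sexes) {
        fdf <- ph$fasting[ph$fasting$sex == sx, , drop = FALSE]
        for (ex in exposures) {
            pr <- fastingPairs(fdf$mouse_id, fdf$group, fdf$pre, fdf$post,
                               exposure = ex,
                               control = sdn$design$control)
            r <- mbmcwTest(pr$x, pr$y, config$mcw)
            phenoRows[[length(phenoRows) + 1L]] <- data.frame(
                trait = "fasting_body_weight", sex = sx, exposure = ex,
                test = "mbmcw", bias_index = r@biasIndex,
                p_upper = r@pUpper, p_lower = r@pLower)
        }
    }
    phenoTab <- do.call(rbind, phenoRows)
    .writeTsv(phenoTab, outDir, "phenotype_mcw.tsv")

    panel <- cleanPlasma(ph$panel)
    pca <- lapply(stats::setNames(nm = sdn$design$sexes),
                  function(sx) metabolitePca(panel, sx))

    dichSummary <- vapply(perContrast, `[[`, character(1), "dichotomy")
    manifest <- list(
        seed = sdn$seed, mcw_seed = config$mcw$seed,
        n_contrasts = nrow(contrasts),
        n_genes = sdn$nGenes,
        dichotomy = as.list(dichSummary))
    if (!is.null(outDir)) {
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        files <- setdiff(list.files(outDir), "hashes.json")
        hashes <- tools::md5sum(file.path(outDir, files))
        names(hashes) <- files
        jsonlite::write_json(as.list(hashes),
                             file.path(outDir, "hashes.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    invisible(list(isochores = seg$isochores, assignments = assignments,
                   truth = cnt$truth, contrasts = contrasts,
                   perContrast = perContrast, phenotypes = phenoTab,
                   pca = pca, manifest = manifest))
}
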