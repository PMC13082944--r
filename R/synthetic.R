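## Synthetic-data generator: genome with a known GC-block structure,
## annotation, counts with planted isochore-class expression shifts,
## gene sets, and phenotype tables. Every artifact is deterministic under
## the design seed and ships with its ground truth, so each pipeline stage
## can be scored against what was planted.

#' Synthetic study design
#'
#' The generative blueprint for all synthetic inputs. Defaults emulate the
#' study design: 2 sexes x 2 tissues x 5 groups (DMSO control + 4
#' exposures) x 5 replicates per cell, a genome built from GC blocks that
#' realize all five isochore classes (30/39/43/50/60 \% GC), and
#' negative-binomial counts with per-class planted log2 fold changes in
#' the exposure groups.
#'
#' @param seed root seed; per-artifact streams are derived from it
#' @param nChromosomes number of chromosomes
#' @param blockLength GC-block length in bases (default 200000, two
#'   100-kb windows per block)
#' @param gcBlocks GC targets of the per-chromosome block sequence; the
#'   defaults land one block in each isochore class
#' @param gapLength length of the all-N assembly-gap block inserted in
#'   chromosome 1
#' @param nGenes number of genes placed across the genome
#' @param geneWidth gene span in bases
#' @param design exposure design, see [exposureDesign()]
#' @param plantedClassLog2fc named vector, isochore class -> log2 fold
#'   change applied to exposure-group samples of genes in that class
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0.1 is typical for bulk RNA-seq replicates
#' @param baselineMean baseline expected count per gene
#' @param nMicePerGroup mice per (sex, group) cell for phenotype tables
#' @param phenotypeEffects named list: trait -> named vector of
#'   standardized group effects
#' @param panelOutOfRangeFrac fraction of plasma measurements flagged
#'   out-of-range
#' @param nSets number of synthetic gene sets
#' @param setSizeRange size range from which gene-set sizes are drawn
#'   (capped at the gene count)
#' @return list of class "SyntheticDesign"
#' @export
syntheticDesign <- function(seed = 1L,
                            nChromosomes = 3L,
                            blockLength = 200000L,
                            gcBlocks = c(0.30, 0.39, 0.43, 0.50, 0.60),
                            gapLength = 200000L,
                            nGenes = 200L,
                            geneWidth = 5000L,
                            design = exposureDesign(),
                            plantedClassLog2fc = c(L1 = 0, L2 = 0, H1 = 0,
                                                   H2 = 0, H3 = 0),
                            nbDispersion = 0.1,
                            baselineMean = 100,
                            nMicePerGroup = 8L,
                            phenotypeEffects = list(
                                body_weight = c(TWD = 1, IAS = -1,
                                                `50TBT` = -0.5)),
                            panelOutOfRangeFrac = 0.1,
                            nSets = 30L,
                            setSizeRange = c(10L, 600L)) {
    stopifnot(all(gcBlocks >= 0 & gcBlocks <= 1),
              nbDispersion > 0, baselineMean > 0,
              design$replicates >= 2L)
    structure(list(
        seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
        blockLength = as.integer(blockLength), gcBlocks = gcBlocks,
        gapLength = as.integer(gapLength), nGenes = as.integer(nGenes),
        geneWidth = as.integer(geneWidth), design = design,
        plantedClassLog2fc = plantedClassLog2fc,
        nbDispersion = nbDispersion, baselineMean = baselineMean,
        nMicePerGroup = as.integer(nMicePerGroup),
        phenotypeEffects = phenotypeEffects,
        panelOutOfRangeFrac = panelOutOfRangeFrac,
        nSets = as.integer(nSets), setSizeRange = setSizeRange),
        class = "SyntheticDesign")
}

.randomBlock <- function(len, gc) {
    if (is.na(gc))
        return(strrep("N", len))
    p <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
    paste(sample(c("A", "T", "G", "C"), len, replace = TRUE, prob = p),
          collapse = "")
}

#' Generate a synthetic genome
#'
#' Each chromosome is a run of fixed-length blocks at the design's GC
#' targets (realized GC lands within ~0.2\% of target at 100-kb scale);
#' chromosome 1 additionally carries an all-N assembly-gap block between
#' the GC blocks. Deterministic under the design seed.
#'
#' @param sd a [syntheticDesign()]
#' @return list(genome = named DNAStringSet, blocks = data.frame with
#'   chrom, start, end (0-based half-open), gc, class — the ground truth)
#' @export
generateGenome <- function(sd) {
    withSeed(sd$seed + 101L, {
        chroms <- paste0("chr", seq_len(sd$nChromosomes))
        seqs <- character(sd$nChromosomes)
        blocks <- list()
        for (ci in seq_along(chroms)) {
            gcs <- sd$gcBlocks
            lens <- rep(sd$blockLength, length(gcs))
            if (ci == 1L && sd$gapLength > 0L) {
                at <- ceiling(length(gcs) / 2)
                gcs <- append(gcs, NA_real_, after = at)
                lens <- append(lens, sd$gapLength, after = at)
            }
            pieces <- mapply(.randomBlock, lens, gcs)
            seqs[ci] <- paste(pieces, collapse = "")
            ends <- cumsum(lens)
            blocks[[ci]] <- data.frame(
                chrom = chroms[ci], start = ends - lens, end = ends,
                gc = gcs, class = classifyGC(gcs))
        }
        genome <- Biostrings::DNAStringSet(seqs)
        names(genome) <- chroms
        list(genome = genome, blocks = do.call(rbind, blocks))
    })
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene spans uniformly over the genome's non-gap
#' blocks, each fully inside one block so its true isochore class is
#' unambiguous. Strand is random.
#'
#' @param gen output of [generateGenome()]
#' @param sd the [syntheticDesign()]
#' @return a [GenomicRanges::GRanges] with metadata gene_id, true_class
#' @export
generateAnnotation <- function(gen, sd) {
    withSeed(sd$seed + 202L, {
        b <- gen$blocks[!is.na(gen$blocks$class), , drop = FALSE]
        slotStep <- sd$geneWidth * 2L
        slots <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
            st <- seq.int(b$start[i], b$end[i] - sd$geneWidth,
                          by = slotStep)
            data.frame(chrom = b$chrom[i], start = st,
                       class = b$class[i])
        }))
        if (nrow(slots) < sd$nGenes)
            stop("genome too small for the requested gene count")
        pick <- sort(sample.int(nrow(slots), sd$nGenes))
        sl <- slots[pick, , drop = FALSE]
        gr <- GenomicRanges::GRanges(
            seqnames = sl$chrom,
            ranges = IRanges::IRanges(start = sl$start + 1L,
                                      width = sd$geneWidth),
            strand = sample(c("+", "-"), sd$nGenes, replace = TRUE))
        gr$gene_id <- sprintf("gene%04d", seq_len(sd$nGenes))
        gr$true_class <- sl$class
        gr
    })
}

#' Generate a synthetic count matrix with planted class shifts
#'
#' Emits one sample per (sex, tissue, group, replicate) cell of the design
#' — 100 samples for the default 2 x 2 x 5 x 5 — with negative-binomial
#' counts. Control-group samples sit at each gene's baseline mean;
#' exposure-group samples are shifted by 2^(planted log2 fold change) for
#' the gene's isochore class. Per-gene baselines vary log-normally around
#' the design baseline.
#'
#' @param sd the [syntheticDesign()]
#' @param annotation optional GRanges from [generateAnnotation()]; when
#'   NULL, genes are created directly with classes cycled over
#'   L1/L2/H1/H2/H3
#' @return list(es = [ExposureSet-class], truth = data.frame with gene_id,
#'   class, planted_log2fc)
#' @export
generateCounts <- function(sd, annotation = NULL) {
    withSeed(sd$seed + 303L, {
        if (is.null(annotation)) {
            geneIds <- sprintf("gene%04d", seq_len(sd$nGenes))
            classes <- rep_len(.ISOCHORE_CLASSES, sd$nGenes)
        } else {
            geneIds <- annotation$gene_id
            classes <- annotation$true_class
        }
        nG <- length(geneIds)
        dsg <- sd$design
        grid <- expand.grid(
            replicate = seq_len(dsg$replicates), group = dsg$groups,
            tissue = dsg$tissues, sex = dsg$sexes,
            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
        grid <- grid[, c("sex", "tissue", "group", "replicate")]
        grid$sample_id <- paste(grid$sex, grid$tissue, grid$group,
                                grid$replicate, sep = "_")
        lfc <- sd$plantedClassLog2fc[classes]
        lfc[is.na(lfc)] <- 0
        geneBase <- sd$baselineMean * exp(rnorm(nG, 0, 0.4))
        isExposure <- grid$group != dsg$control
        mu <- outer(geneBase, rep(1, nrow(grid)))
        mu[, isExposure] <- mu[, isExposure] * 2^lfc
        counts <- matrix(
            rnbinom(length(mu), mu = mu, size = 1 / sd$nbDispersion),
            nrow = nG,
            dimnames = list(geneIds, grid$sample_id))
        storage.mode(counts) <- "double"
        list(es = exposureSet(counts, grid),
             truth = data.frame(gene_id = geneIds, class = classes,
                                planted_log2fc = as.numeric(lfc)))
    })
}

#' Generate synthetic gene sets
#'
#' Set sizes are drawn across the configured range (capped at the gene
#' count) so both tails of the GO-style size filter get exercised; a
#' fraction of the sets is class-skewed: members drawn with 8x weight from
#' one isochore class, mirroring compartment-biased functional terms.
#'
#' @param geneIds gene ids of the universe
#' @param classes isochore class per gene (parallel to geneIds)
#' @param sd the [syntheticDesign()]
#' @param skewFraction fraction of class-skewed sets (default 0.3)
#' @return named list of gene sets; attribute "skew" records the target
#'   class of each set (NA for unskewed)
#' @export
generateGeneSets <- function(geneIds, classes, sd, skewFraction = 0.3) {
    withSeed(sd$seed + 404L, {
        nG <- length(geneIds)
        lo <- max(2L, sd$setSizeRange[1L] - 10L)
        hi <- min(sd$setSizeRange[2L], nG - 1L)
        sizes <- sample(seq.int(lo, hi), sd$nSets, replace = TRUE)
        skewed <- seq_len(sd$nSets) <= round(skewFraction * sd$nSets)
        targets <- ifelse(skewed,
                          sample(.ISOCHORE_CLASSES, sd$nSets, replace = TRUE),
                          NA_character_)
        sets <- lapply(seq_len(sd$nSets), function(k) {
            w <- rep(1, nG)
            if (!is.na(targets[k]))
                w[classes == targets[k]] <- 8
            geneIds[sample.int(nG, sizes[k], prob = w)]
        })
        names(sets) <- sprintf("set%03d", seq_len(sd$nSets))
        attr(sets, "skew") <- stats::setNames(targets, names(sets))
        sets
    })
}

#' Generate synthetic phenotype tables
#'
#' Gaussian traits with standardized group effects (the design's
#' \code{phenotypeEffects}), a pre/post fasting table with a mild common
#' weight drop, and a plasma metabolite panel (log-normal concentrations)
#' with a configurable out-of-range fraction to exercise the zeroing rule.
#'
#' @param sd the [syntheticDesign()]
#' @return list(traits, fasting, panel) of data.frames
#' @export
generatePhenotypes <- function(sd) {
    withSeed(sd$seed + 505L, {
        dsg <- sd$design
        mice <- expand.grid(
            idx = seq_len(sd$nMicePerGroup), group = dsg$groups,
            sex = dsg$sexes, stringsAsFactors = FALSE,
            KEEP.OUT.ATTRS = FALSE)
        mice$mouse_id <- sprintf("m%03d", seq_len(nrow(mice)))
        mice$age_days <- round(60 + rnorm(nrow(mice), 0, 2))
        baseW <- ifelse(mice$sex == "male", 25, 20)

        traits <- list()
        for (tr in names(sd$phenotypeEffects)) {
            eff <- sd$phenotypeEffects[[tr]]
            shift <- ifelse(mice$group %in% names(eff),
                            eff[mice$group], 0)
            sdTrait <- 2
            val <- baseW + rnorm(nrow(mice), 0, sdTrait) + shift * sdTrait
            traits[[tr]] <- data.frame(
                mouse_id = mice$mouse_id, sex = mice$sex,
                group = mice$group, age_days = mice$age_days,
                trait = tr, value = val)
        }
        traits <- do.call(rbind, traits)

        pre <- baseW + rnorm(nrow(mice), 0, 2)
        fasting <- data.frame(
            mouse_id = mice$mouse_id, sex = mice$sex, group = mice$group,
            pre = pre, post = pre - abs(rnorm(nrow(mice), 1.5, 0.4)))

        metabolites <- c("amylin", "GIP", "ghrelin", "GLP-1", "insulin",
                         "leptin", "PYY", "glucagon", "PP", "resistin",
                         "C-Peptide")
        panel <- expand.grid(mouse_id = mice$mouse_id,
                             metabolite = metabolites,
                             stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
        mi <- match(panel$mouse_id, mice$mouse_id)
        panel$sex <- mice$sex[mi]
        panel$group <- mice$group[mi]
        panel$age_days <- mice$age_days[mi]
        panel$body_weight <- round(baseW[mi] + rnorm(nrow(panel), 0, 1), 2)
        panel$value <- exp(rnorm(nrow(panel), 5, 1))
        ## out-of-range values cluster in boundary-prone metabolites (as in
        ## real panels, where a few analytes sit near the standard curve
        ## edge); the rest are fully in range, so complete-case metabolites
        ## exist for the PCA
        nBad <- round(sd$panelOutOfRangeFrac * length(metabolites) * 2.5)
        prone <- metabolites[seq_len(min(nBad, length(metabolites) - 2L))]
        pOut <- ifelse(panel$metabolite %in% prone, 0.4, 0)
        panel$in_range <- runif(nrow(panel)) >= pOut
        list(traits = traits, fasting = fasting, panel = panel)
    })
}
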