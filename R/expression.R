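## Count-table ingestion, expressed-gene filtering, cpm normalization and
## per-gene uMCW contrast statistics.

#' ExposureSet: gene x sample counts with exposure-design metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass whose
#' colData must describe the exposure design: sex, tissue, group and
#' replicate per sample, with (sex, tissue, group, replicate) unique.
#' The "counts" assay holds raw counts; [cpmNormalize()] adds a "cpm"
#' assay.
#'
#' @export
setClass("ExposureSet", contains = "SummarizedExperiment")

setValidity("ExposureSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("sex", "tissue", "group", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
    key <- paste(cd$sex, cd$tissue, cd$group, cd$replicate)
    if (anyDuplicated(key))
        return("(sex, tissue, group, replicate) must be unique per sample")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("an assay named 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0))
        return("counts must be non-negative")
    TRUE
})

#' Construct an ExposureSet
#'
#' @param counts numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids)
#' @param sampleData data.frame with columns sample_id, sex, tissue, group,
#'   replicate; rows matched to count columns by sample_id
#' @return an [ExposureSet-class]
#' @export
exposureSet <- function(counts, sampleData) {
    stopifnot(is.matrix(counts), !is.null(rownames(counts)),
              !is.null(colnames(counts)))
    idx <- match(colnames(counts), sampleData$sample_id)
    if (anyNA(idx))
        stop("every count column needs a sample_id row in sampleData")
    cd <- S4Vectors::DataFrame(sampleData[idx, , drop = FALSE],
                               row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("ExposureSet", se)
}

#' The study's exposure design
#'
#' Two sexes, two tissues (gonadal white adipose tissue and liver), a DMSO
#' control and four exposure groups (5 nM tributyltin, 50 nM tributyltin,
#' inorganic arsenic, Total Western Diet), five replicates per cell.
#'
#' @return list with sexes, tissues, groups, control, replicates
#' @export
exposureDesign <- function() {
    list(sexes = c("female", "male"),
         tissues = c("gWAT", "liver"),
         groups = c("DMSO", "5TBT", "50TBT", "IAS", "TWD"),
         control = "DMSO",
         replicates = 5L)
}

#' Enumerate exposure-versus-control contrasts
#'
#' Cartesian product of sexes x tissues x exposure groups against the fixed
#' control, in deterministic (sex, tissue, group) order. The default design
#' yields 16 contrasts (2 x 2 x 4).
#'
#' @param design list as from [exposureDesign()] (fields sexes, tissues,
#'   groups, control)
#' @return data.frame with columns contrast_id, sex, tissue, exposure,
#'   control
#' @export
enumerateContrasts <- function(design = exposureDesign()) {
    if (!design$control %in% design$groups)
        stop("control group missing from design groups")
    exposures <- setdiff(design$groups, design$control)
    grid <- expand.grid(exposure = exposures, tissue = design$tissues,
                        sex = design$sexes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(match(grid$sex, design$sexes),
                       match(grid$tissue, design$tissues),
                       match(grid$exposure, exposures)), , drop = FALSE]
    data.frame(
        contrast_id = paste(grid$sex, grid$tissue, grid$exposure,
                            sep = "_"),
        sex = grid$sex, tissue = grid$tissue,
        exposure = grid$exposure, control = design$control,
        row.names = NULL)
}

## sample ids of one contrast cell, split exposure/control
.contrastColumns <- function(es, contrast) {
    cd <- SummarizedExperiment::colData(es)
    inCell <- cd$sex == contrast$sex & cd$tissue == contrast$tissue
    list(exposure = which(inCell & cd$group == contrast$exposure),
         control = which(inCell & cd$group == contrast$control))
}

#' Expressed-gene filter for one contrast
#'
#' A gene counts as expressed in a contrast when at least \code{minCount}
#' reads map to it in at least \code{minSamples} of the contrast's
#' exposure + control samples.
#'
#' @param es an [ExposureSet-class] (raw counts)
#' @param contrast one row of [enumerateContrasts()] output (data.frame or
#'   list with sex, tissue, exposure, control)
#' @param minCount,minSamples filter thresholds (defaults 2 and 2)
#' @return character vector of kept gene ids
#' @export
filterExpressed <- function(es, contrast, minCount = 2, minSamples = 2) {
    cols <- .contrastColumns(es, contrast)
    if (!length(cols$exposure) || !length(cols$control))
        stop("contrast has no exposure or no control samples")
    cts <- SummarizedExperiment::assay(es, "counts")[,
        c(cols$exposure, cols$control), drop = FALSE]
    keep <- rowSums(cts >= minCount) >= minSamples
    rownames(cts)[keep]
}

#' Keep genes on main nuclear chromosomes
#'
#' Drops mitochondrial and Y-chromosome genes and anything on unassembled
#' segments (labels with "_", "random", "Un", or otherwise unrecognized),
#' keeping autosomes and the X chromosome so both sexes are comparable.
#'
#' @param chrom character vector of chromosome labels (with or without a
#'   "chr" prefix)
#' @return logical vector, TRUE for kept
#' @export
chromosomeFilter <- function(chrom) {
    bare <- sub("^chr", "", chrom)
    keep <- grepl("^([0-9]+|X)$", bare)
    unknown <- !keep & !grepl("^(M|MT|Y)$", bare) & !grepl("_|random|Un", chrom)
    if (any(unknown))
        warning(sprintf(
            "%d unrecognized chromosome label(s) treated as unassembled",
            sum(unknown)))
    keep
}

#' Counts-per-million normalization
#'
#' Divides each gene's raw count by the sample's total over the genes
#' present in the table and multiplies by one million, so every sample
#' column sums to 1e6. Applied after the expressed-gene filter, totals are
#' over the filtered table (the working table at that stage).
#'
#' @param es an [ExposureSet-class]
#' @return the ExposureSet with an added "cpm" assay
#' @export
cpmNormalize <- function(es) {
    cts <- SummarizedExperiment::assay(es, "counts")
    totals <- colSums(cts)
    if (any(totals <= 0))
        stop("every sample must have a positive count total")
    SummarizedExperiment::assay(es, "cpm") <-
        sweep(cts, 2L, totals, "/") * 1e6
    es
}

#' Top-n genes by cumulative raw count
#'
#' Aggregates raw counts per gene across all samples and returns the n
#' genes with the highest totals; ties at the cut are broken by gene id
#' (lexicographically smaller kept).
#'
#' @param es an [ExposureSet-class]
#' @param n number of genes to keep
#' @return character vector of gene ids
#' @export
topExpressed <- function(es, n) {
    cts <- SummarizedExperiment::assay(es, "counts")
    totals <- rowSums(cts)
    if (n > length(totals)) {
        warning("n exceeds gene count; returning all genes")
        n <- length(totals)
    }
    ord <- order(-totals, rownames(cts))
    rownames(cts)[ord][seq_len(n)]
}

#' Rescale each gene's values to [0, 1]
#'
#' Per-gene (x - min(x)) / (max(x) - min(x)) across samples; genes constant
#' across samples map to all zeros (the division-by-zero guard; affects
#' only visualization matrices).
#'
#' @param m numeric matrix, genes x samples (at least 2 samples)
#' @return matrix of the same shape with per-row values in [0, 1]
#' @export
rescale01 <- function(m) {
    stopifnot(is.matrix(m), ncol(m) >= 2L)
    lo <- apply(m, 1L, min)
    hi <- apply(m, 1L, max)
    span <- hi - lo
    out <- (m - lo) / ifelse(span == 0, 1, span)
    out[span == 0, ] <- 0
    out
}

#' Per-gene uMCW statistics for one contrast
#'
#' For every gene, runs [umcwTest()] on its cpm values, exposure group as
#' the first set, so a positive bias index means higher expression under
#' exposure. With five replicates per group the null is enumerated exactly
#' (C(10,5) = 252 rearrangements, below the 10,000 budget).
#'
#' @param es an [ExposureSet-class] carrying a "cpm" assay (filtered to
#'   expressed genes)
#' @param contrast one contrast row (sex, tissue, exposure, control)
#' @param config an [mcwConfig()]
#' @return data.frame with columns gene_id, contrast_id, bias_index,
#'   p_upper, p_lower, n_rearrangements, path
#' @export
perGeneUmcw <- function(es, contrast, config = mcwConfig()) {
    cols <- .contrastColumns(es, contrast)
    if (!length(cols$exposure) || !length(cols$control))
        stop("contrast has no exposure or no control samples")
    cpm <- SummarizedExperiment::assay(es, "cpm")
    res <- lapply(seq_len(nrow(cpm)), function(i) {
        r <- umcwTest(cpm[i, cols$exposure], cpm[i, cols$control], config)
        c(r@biasIndex, r@pUpper, r@pLower, r@nRearrangements,
          r@path == "exact")
    })
    res <- do.call(rbind, res)
    cid <- if (!is.null(contrast$contrast_id)) contrast$contrast_id
           else paste(contrast$sex, contrast$tissue, contrast$exposure,
                      sep = "_")
    data.frame(
        gene_id = rownames(cpm),
        contrast_id = cid,
        bias_index = res[, 1L],
        p_upper = res[, 2L],
        p_lower = res[, 3L],
        n_rearrangements = as.integer(res[, 4L]),
        path = ifelse(res[, 5L] == 1, "exact", "approximate"),
        row.names = NULL)
}

#' Read a gene x sample count table (TSV)
#'
#' First column gene id, remaining columns one per sample.
#'
#' @param path TSV file
#' @return numeric matrix with gene rownames and sample colnames
#' @export
readCountsTsv <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}
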