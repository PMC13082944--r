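## Isochore segmentation: fixed 100-kb windows classified by GC content,
## merged into maximal same-class runs. Classes follow the classic
## five-family scheme, L1 (AT-richest) through H3 (GC-richest).

.ISOCHORE_CLASSES <- c("L1", "L2", "H1", "H2", "H3")
.ISOCHORE_BREAKS <- c(0.37, 0.41, 0.46, 0.53)

#' Isochore class of a GC fraction
#'
#' Five classes with lower-inclusive, half-open boundaries:
#' L1 below 37\% GC, L2 in [37, 41), H1 in [41, 46), H2 in [46, 53),
#' H3 at or above 53\%.
#'
#' @param gc numeric vector of GC fractions in [0, 1]; NA allowed (returns
#'   NA, used for assembly-gap windows)
#' @return character vector of class names
#' @examples
#' classifyGC(c(0.36, 0.50, 0.41))  # L1 H2 H1
#' @export
classifyGC <- function(gc) {
    ok <- is.na(gc) | (gc >= 0 & gc <= 1)
    if (!all(ok))
        stop("GC fractions must lie in [0, 1]")
    cls <- .ISOCHORE_CLASSES[1L + findInterval(gc, .ISOCHORE_BREAKS)]
    cls[is.na(gc)] <- NA_character_
    cls
}

#' Segment a sequence into non-overlapping GC windows
#'
#' Tiles the sequence with consecutive fixed-size windows (the terminal
#' window may be shorter and is flagged). GC is computed over non-N bases;
#' the N fraction is reported separately so downstream code can treat
#' N-heavy windows as assembly gaps.
#'
#' @param sequence a [Biostrings::DNAString], character string, or a
#'   single-element [Biostrings::DNAStringSet]
#' @param windowSize window width in bases (default 100000)
#' @param chrom chromosome name attached to the windows
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   gc (fraction over non-N bases, NA for all-N windows), n_fraction,
#'   terminal (logical)
#' @export
segmentWindows <- function(sequence, windowSize = 100000L, chrom = "chr1") {
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1L)
        sequence <- sequence[[1L]]
    }
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(sequence)
    len <- length(sequence)
    if (len == 0L)
        stop("sequence must be non-empty")
    starts <- seq.int(1L, len, by = windowSize)
    ends <- pmin(starts + windowSize - 1L, len)
    v <- Biostrings::Views(sequence, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
    width <- ends - starts + 1L
    nonN <- width - freq[, "N"]
    gc <- ifelse(nonN > 0L, (freq[, "G"] + freq[, "C"]) / nonN, NA_real_)
    data.frame(
        chrom = chrom,
        start = starts - 1L,
        end = ends,
        gc = as.numeric(gc),
        n_fraction = freq[, "N"] / width,
        terminal = ends == len & width < windowSize,
        row.names = NULL)
}

#' Merge same-class windows into isochores
#'
#' Maximal runs of juxtaposed windows of the same class become one
#' isochore. Windows whose N fraction exceeds \code{gapNFraction} are
#' assembly-gap windows: they are left unclassified, break runs, and are
#' excluded from the output. Mean GC is weighted by each window's non-N
#' base count.
#'
#' @param windows data.frame as returned by [segmentWindows()] (ordered,
#'   one chromosome)
#' @param gapNFraction windows with n_fraction above this are gaps
#'   (default 0.5)
#' @return a [GenomicRanges::GRanges] (1-based coordinates) with metadata
#'   columns class, mean_gc, n_windows, isochore_id
#' @export
mergeIsochores <- function(windows, gapNFraction = 0.5) {
    stopifnot(is.data.frame(windows), nrow(windows) >= 1L)
    if (length(unique(windows$chrom)) != 1L)
        stop("windows must come from a single chromosome")
    if (is.unsorted(windows$start))
        stop("windows must be ordered by start coordinate")
    if (!all(windows$end[-nrow(windows)] == windows$start[-1L]))
        stop("windows must tile the chromosome without gaps or overlaps")
    cls <- classifyGC(windows$gc)
    cls[windows$n_fraction > gapNFraction] <- NA_character_
    runKey <- cls
    runKey[is.na(runKey)] <- "<gap>"
    r <- rle(runKey)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    keep <- r$values != "<gap>"
    if (!any(keep)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            class = character(0), mean_gc = numeric(0),
            n_windows = integer(0), isochore_id = character(0))
        return(gr)
    }
    runStart <- runStart[keep]; runEnd <- runEnd[keep]
    cls <- r$values[keep]
    chrom <- windows$chrom[1L]
    nonN <- (windows$end - windows$start) * (1 - windows$n_fraction)
    meanGc <- mapply(function(i, j) {
        w <- nonN[i:j]
        if (sum(w) == 0) return(NA_real_)
        sum(windows$gc[i:j] * w) / sum(w)
    }, runStart, runEnd)
    startBp <- windows$start[runStart]
    endBp <- windows$end[runEnd]
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = startBp + 1L, end = endBp))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        class = cls,
        mean_gc = as.numeric(meanGc),
        n_windows = runEnd - runStart + 1L,
        isochore_id = sprintf("%s_%d_%s", chrom, startBp, cls))
    gr
}

#' Segment a whole genome into isochores
#'
#' Runs [segmentWindows()] and [mergeIsochores()] per chromosome.
#'
#' @param genome a named [Biostrings::DNAStringSet]
#' @param windowSize window width in bases
#' @param gapNFraction gap threshold passed to [mergeIsochores()]
#' @return list with elements \code{windows} (data.frame over all
#'   chromosomes) and \code{isochores} (combined GRanges)
#' @export
segmentGenome <- function(genome, windowSize = 100000L, gapNFraction = 0.5) {
    stopifnot(is(genome, "DNAStringSet"), length(genome) >= 1L,
              !is.null(names(genome)))
    wins <- lapply(names(genome), function(ch)
        segmentWindows(genome[[ch]], windowSize = windowSize, chrom = ch))
    isos <- lapply(wins, mergeIsochores, gapNFraction = gapNFraction)
    list(windows = do.call(rbind, wins),
         isochores = suppressWarnings(do.call(c, isos)))
}

#' Assign genes to isochores by largest overlap
#'
#' Each gene is assigned to the single isochore with which it shares the
#' most bases; ties go to the isochore with the lower start coordinate.
#' Genes overlapping no classified isochore stay unassigned (NA), which is
#' a valid state (e.g. genes inside assembly gaps).
#'
#' @param genes a [GenomicRanges::GRanges] with a \code{gene_id} metadata
#'   column (gene span = full annotation start-end, introns included)
#' @param isochores GRanges from [mergeIsochores()]/[segmentGenome()]
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   assigned_isochore_id, assigned_class
#' @export
assignGenes <- function(genes, isochores) {
    stopifnot(is(genes, "GRanges"), is(isochores, "GRanges"))
    if (is.null(genes$gene_id))
        stop("genes must carry a gene_id metadata column")
    hits <- GenomicRanges::findOverlaps(genes, isochores)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ovl <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(genes)[q], GenomicRanges::ranges(isochores)[s]))
    ## best = widest overlap, then lower isochore start
    ord <- order(q, -ovl, GenomicRanges::start(isochores)[s])
    q <- q[ord]; s <- s[ord]
    best <- !duplicated(q)
    assignedIso <- rep(NA_character_, length(genes))
    assignedClass <- rep(NA_character_, length(genes))
    assignedIso[q[best]] <- isochores$isochore_id[s[best]]
    assignedClass[q[best]] <- isochores$class[s[best]]
    data.frame(
        gene_id = genes$gene_id,
        chrom = as.character(GenomicRanges::seqnames(genes)),
        start = GenomicRanges::start(genes) - 1L,
        end = GenomicRanges::end(genes),
        strand = as.character(GenomicRanges::strand(genes)),
        assigned_isochore_id = assignedIso,
        assigned_class = assignedClass,
        row.names = NULL)
}

#' Relative fraction of genes per isochore class
#'
#' For a gene subset (a chromosome's genes, a GO term's genes, ...)
#' against the whole transcriptome, computes per class
#' log10((x/n)/(X/N)): x subset genes overlapping isochores of the class,
#' n transcriptome genes in the class, X and N the corresponding any-class
#' totals. Classes with x = 0 yield -Inf (a sentinel, not an error).
#'
#' @param subsetIds gene ids of the subset (must be among
#'   \code{assignments$gene_id})
#' @param assignments data.frame from [assignGenes()] for the whole
#'   transcriptome; unassigned genes are ignored
#' @return data.frame with columns class, x, n, X, N, value
#' @export
relativeGeneFraction <- function(subsetIds, assignments) {
    stopifnot(all(subsetIds %in% assignments$gene_id))
    a <- assignments[!is.na(assignments$assigned_class), , drop = FALSE]
    N <- nrow(a)
    inSub <- a$gene_id %in% subsetIds
    X <- sum(inSub)
    if (N == 0L || X == 0L)
        stop("no assigned genes in the transcriptome or the subset")
    cls <- .ISOCHORE_CLASSES
    n <- vapply(cls, function(cc) sum(a$assigned_class == cc), integer(1))
    x <- vapply(cls, function(cc) sum(inSub & a$assigned_class == cc),
                integer(1))
    value <- ifelse(x > 0L & n > 0L,
                    log10((x / n) / (X / N)),
                    ifelse(x == 0L, -Inf, NA_real_))
    data.frame(class = cls, x = x, n = n, X = X, N = N, value = value,
               row.names = NULL)
}

#' Write isochores as a BED file
#'
#' BED4+2: chrom, 0-based start, end, class name, mean GC, isochore id.
#'
#' @param isochores GRanges from [mergeIsochores()]
#' @param path output file
#' @export
writeIsochoreBed <- function(isochores, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(isochores)),
        start = GenomicRanges::start(isochores) - 1L,
        end = GenomicRanges::end(isochores),
        name = isochores$class,
        mean_gc = round(isochores$mean_gc, 5),
        isochore_id = isochores$isochore_id)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene features from a GTF or BED file
#'
#' GTF input is converted from 1-based closed coordinates by the importer;
#' for GTF, rows with feature type "gene" are kept (all rows if no type
#' column is present). The gene span is the full annotated start-end,
#' introns included.
#'
#' @param path GTF or BED file
#' @param format "gtf" or "bed"; guessed from the file extension by default
#' @return a [GenomicRanges::GRanges] with a \code{gene_id} metadata column
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gtf", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gtf"
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("reading GTF/BED requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = format)
    if (format == "gtf") {
        if (!is.null(gr$type) && any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
        if (is.null(gr$gene_id))
            stop("GTF lacks gene_id attributes")
    } else {
        if (is.null(gr$name))
            stop("BED needs a name column for gene ids")
        gr$gene_id <- gr$name
    }
    gr
}
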