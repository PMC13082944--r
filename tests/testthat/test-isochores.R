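# build a chromosome string from (length, gc) blocks; gc NA = all-N gap
blockSeq <- function(lens, gcs, seed = 1) {
    withr::with_seed(seed, paste(mapply(function(l, g) {
        if (is.na(g)) return(strrep("N", l))
        p <- c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2)
        paste(sample(c("A", "T", "G", "C"), l, TRUE, prob = p),
              collapse = "")
    }, lens, gcs), collapse = ""))
}

test_that("window tiling covers the sequence with a flagged terminal", {
    s <- strrep("ACGT", 62500)  # 250 kb
    w <- segmentWindows(s)
    expect_equal(nrow(w), 3L)
    expect_equal(w$start, c(0, 100000, 200000))
    expect_equal(w$end, c(100000, 200000, 250000))
    expect_equal(w$terminal, c(FALSE, FALSE, TRUE))
    expect_equal(w$gc, rep(0.5, 3))
    expect_equal(segmentWindows(strrep("G", 1000), 1000)$gc, 1)
    expect_error(segmentWindows(""), "non-empty")
    # GC over non-N bases only; N fraction reported separately
    wn <- segmentWindows(paste0(strrep("N", 500), strrep("G", 500)), 1000)
    expect_equal(wn$gc, 1)
    expect_equal(wn$n_fraction, 0.5)
})

test_that("GC classification uses the five half-open class intervals", {
    expect_equal(classifyGC(0.36), "L1")
    expect_equal(classifyGC(0.50), "H2")
    expect_equal(classifyGC(c(0.37, 0.41, 0.46, 0.53)),
                 c("L2", "H1", "H2", "H3"))
    expect_error(classifyGC(1.2), "\\[0, 1\\]")
    # class order is monotone over a GC sweep
    sweep <- classifyGC(seq(0, 1, by = 0.01))
    expect_equal(unique(sweep), c("L1", "L2", "H1", "H2", "H3"))
    expect_true(!is.unsorted(match(sweep, c("L1", "L2", "H1", "H2", "H3"))))
})

test_that("same-class windows merge; class changes and gaps break runs", {
    mkwin <- function(classesGc, nfrac = 0) {
        n <- length(classesGc)
        data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                   end = (1:n) * 1e5, gc = classesGc,
                   n_fraction = nfrac, terminal = FALSE)
    }
    # L1 L1 H3 -> two isochores
    iso <- mergeIsochores(mkwin(c(0.30, 0.32, 0.60)))
    expect_equal(length(iso), 2L)
    expect_equal(iso$class, c("L1", "H3"))
    expect_equal(GenomicRanges::width(iso), c(200000L, 100000L))
    # no merging across a class change
    iso3 <- mergeIsochores(mkwin(c(0.30, 0.60, 0.30)))
    expect_equal(iso3$class, c("L1", "H3", "L1"))
    # a gap window breaks the run and is excluded
    gapWin <- mkwin(c(0.30, NA, 0.30), nfrac = c(0, 1, 0))
    isoG <- mergeIsochores(gapWin)
    expect_equal(length(isoG), 2L)
    expect_equal(isoG$class, c("L1", "L1"))
    expect_equal(GenomicRanges::start(isoG), c(1L, 200001L))
    expect_error(mergeIsochores(mkwin(c(0.3, 0.3))[2:1, ]), "ordered")
})

test_that("classified isochores plus gaps exactly tile the chromosome", {
    s <- blockSeq(rep(2e5, 6), c(0.30, 0.39, NA, 0.43, 0.50, 0.60))
    w <- segmentWindows(s)
    iso <- mergeIsochores(w)
    gapBases <- sum((w$end - w$start)[w$n_fraction > 0.5])
    expect_equal(sum(GenomicRanges::width(iso)) + gapBases, nchar(s))
    expect_equal(
        sum(GenomicRanges::countOverlaps(iso, iso)), length(iso))
    # merging is idempotent: re-expanding isochores to windows and merging
    # again reproduces the same isochores
    reWin <- do.call(rbind, lapply(seq_along(iso), function(i) {
        st <- seq(GenomicRanges::start(iso)[i] - 1L,
                  GenomicRanges::end(iso)[i] - 1L, by = 1e5)
        data.frame(chrom = "chr1", start = st, end = st + 1e5,
                   gc = iso$mean_gc[i], n_fraction = 0, terminal = FALSE)
    }))
    # re-insert the gap windows so the tiling is contiguous
    gapW <- w[w$n_fraction > 0.5, ]
    reWin <- rbind(reWin, gapW[, colnames(reWin)])
    reWin <- reWin[order(reWin$start), ]
    iso2 <- mergeIsochores(reWin)
    expect_equal(iso2$class, iso$class)
    expect_equal(GenomicRanges::start(iso2), GenomicRanges::start(iso))
    expect_equal(GenomicRanges::end(iso2), GenomicRanges::end(iso))
})

test_that("the five canonical GC targets realize all five classes", {
    s <- blockSeq(rep(2e5, 5), c(0.30, 0.39, 0.43, 0.50, 0.60))
    iso <- mergeIsochores(segmentWindows(s))
    expect_equal(iso$class, c("L1", "L2", "H1", "H2", "H3"))
    expect_equal(GenomicRanges::width(iso), rep(200000L, 5))
})

test_that("genes are assigned by largest overlap with a start tie-break", {
    iso <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 100001), end = c(100000, 200000)))
    iso$class <- c("L1", "H3")
    iso$isochore_id <- c("isoA", "isoB")
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(5000, 40001, 50001, 250001),
        end = c(6000, 140000, 150000, 251000)))
    genes$gene_id <- c("inA", "mostlyA", "tie", "outside")
    a <- assignGenes(genes, iso)
    expect_equal(a$assigned_isochore_id,
                 c("isoA", "isoA", "isoA", NA))  # tie -> lower start
    expect_equal(a$assigned_class[1:3], c("L1", "L1", "L1"))
    expect_true(is.na(a$assigned_class[4]))
})

test_that("relative gene fractions follow log10((x/n)/(X/N))", {
    assignments <- data.frame(
        gene_id = paste0("g", 1:20), chrom = "chr1", start = 0, end = 1,
        strand = "+", assigned_isochore_id = "i",
        assigned_class = rep(c("L1", "H3"), c(18, 2)))
    # subset distributed like the whole -> 0 everywhere it is defined
    even <- relativeGeneFraction(paste0("g", c(1:9, 19)), assignments)
    expect_equal(even$value[even$class == "L1"], 0)
    expect_equal(even$value[even$class == "H3"], 0)
    # subset all in H3, transcriptome 10% in H3 -> log10(N/n) = 1
    allH3 <- relativeGeneFraction(paste0("g", 19:20), assignments)
    expect_equal(allH3$value[allH3$class == "H3"], 1)
    expect_equal(allH3$value[allH3$class == "L1"], -Inf)  # empty sentinel
    # count identities
    expect_equal(sum(even$x), unique(even$X))
    expect_equal(sum(even$n), unique(even$N))
    expect_error(relativeGeneFraction("nope", assignments))
})

test_that("gene annotations load from GTF and BED with ids intact", {
    skip_if_not_installed("rtracklayer")
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA";',
        'chr1\tsrc\texon\t101\t150\t.\t+\t.\tgene_id "gA";',
        'chr1\tsrc\tgene\t501\t900\t.\t-\t.\tgene_id "gB";'), gtf)
    gr <- readGeneAnnotation(gtf)
    expect_equal(gr$gene_id, c("gA", "gB"))
    expect_equal(GenomicRanges::start(gr), c(101L, 501L))  # 1-based closed
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200\tgA\t0\t+",
                 "chr1\t500\t900\tgB\t0\t-"), bed)
    grb <- readGeneAnnotation(bed)
    expect_equal(grb$gene_id, c("gA", "gB"))
    expect_equal(GenomicRanges::start(grb), c(101L, 501L))
})
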