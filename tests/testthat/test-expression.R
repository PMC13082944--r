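# small ExposureSet fixture built in code
makeEs <- function(counts, groups, sex = "female", tissue = "gWAT") {
    n <- ncol(counts)
    meta <- data.frame(
        sample_id = colnames(counts), sex = sex, tissue = tissue,
        group = groups, replicate = stats::ave(seq_len(n), groups,
                                               FUN = seq_along))
    exposureSet(counts, meta)
}

test_that("contrast enumeration is the sex x tissue x exposure product", {
    cts <- enumerateContrasts()
    expect_equal(nrow(cts), 16L)
    expect_equal(unique(cts$control), "DMSO")
    expect_false("DMSO" %in% cts$exposure)
    expect_equal(cts$contrast_id[1], "female_gWAT_5TBT")
    one <- enumerateContrasts(list(sexes = "f", tissues = "t",
                                   groups = c("C", "E"), control = "C"))
    expect_equal(nrow(one), 1L)
    eight <- enumerateContrasts(list(sexes = c("f", "m"),
                                     tissues = c("a", "b"),
                                     groups = c("C", "E1", "E2"),
                                     control = "C"))
    expect_equal(nrow(eight), 8L)
    expect_error(enumerateContrasts(list(sexes = "f", tissues = "t",
                                         groups = "E", control = "C")),
                 "control")
})

test_that("expressed filter needs >= 2 reads in >= 2 contrast samples", {
    counts <- rbind(
        meets = c(2, 2, 0, 0, 0, 0),
        oneHigh = c(3, 1, 1, 1, 1, 1),
        zeros = c(0, 0, 0, 0, 0, 0),
        strong = c(9, 9, 9, 9, 9, 9))
    colnames(counts) <- paste0("s", 1:6)
    es <- makeEs(counts, rep(c("DMSO", "EXP"), each = 3))
    ct <- list(sex = "female", tissue = "gWAT", exposure = "EXP",
               control = "DMSO")
    expect_setequal(filterExpressed(es, ct), c("meets", "strong"))
    expect_error(filterExpressed(es, list(sex = "male", tissue = "gWAT",
                                          exposure = "EXP",
                                          control = "DMSO")),
                 "no exposure")
})

test_that("chromosome filter keeps autosomes and X only", {
    chroms <- c("chr1", "chr19", "chrX", "chrY", "chrM",
                "chr1_random", "chrUn_GL456210")
    expect_equal(chromosomeFilter(chroms),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
    expect_warning(chromosomeFilter("weird7"), "unassembled")
    expect_true(chromosomeFilter("X"))  # bare labels work too
})

test_that("cpm columns each total one million", {
    counts <- matrix(c(25, 75, 10, 90), nrow = 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
    es <- makeEs(counts, c("DMSO", "EXP"))
    es <- cpmNormalize(es)
    cpm <- SummarizedExperiment::assay(es, "cpm")
    expect_equal(cpm[, "s1"], c(g1 = 250000, g2 = 750000))
    expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
    bad <- makeEs(matrix(c(1, 1, 0, 0), 2,
                         dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                  c("DMSO", "EXP"))
    expect_error(cpmNormalize(bad), "positive")
    # single-gene table: cpm is 1e6 whatever the count
    one <- cpmNormalize(makeEs(matrix(c(7, 3), 1,
        dimnames = list("g", c("s1", "s2"))), c("DMSO", "EXP")))
    expect_equal(unname(SummarizedExperiment::assay(one, "cpm")[1, ]),
                 c(1e6, 1e6))
})

test_that("top-expressed ranking uses cumulative counts, id tie-break", {
    counts <- matrix(c(5, 5, 3, 2, 5, 0, 2, 0), nrow = 4,
                     dimnames = list(c("gB", "gA", "gC", "gD"),
                                     c("s1", "s2")))
    es <- makeEs(counts, c("DMSO", "EXP"))
    # totals: gB 10, gA 5, gC 5, gD 2; tie at 5 broken by gene id
    expect_equal(topExpressed(es, 2), c("gB", "gA"))
    expect_equal(topExpressed(es, 4), c("gB", "gA", "gC", "gD"))
    expect_warning(all5 <- topExpressed(es, 5), "exceeds")
    expect_equal(length(all5), 4L)
})

test_that("per-gene 0-1 rescaling maps min to 0, max to 1, constants to 0", {
    m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 0))
    r <- rescale01(m)
    expect_equal(r["a", ], c(0, 0.5, 1))
    expect_equal(r["b", ], c(0, 0, 0))
    expect_equal(r["c", ], c(0, 1, 0))
    expect_equal(unname(rescale01(rbind(c(3, 9)))), rbind(c(0, 1)))
})

test_that("per-gene uMCW bias indexes point toward the exposure group", {
    counts <- rbind(up = c(1, 2, 10, 11), flat = c(5, 6, 5, 6))
    colnames(counts) <- paste0("s", 1:4)
    es <- makeEs(counts, c("DMSO", "DMSO", "EXP", "EXP"))
    es <- cpmNormalize(es)
    ct <- list(sex = "female", tissue = "gWAT", exposure = "EXP",
               control = "DMSO")
    gb <- perGeneUmcw(es, ct)
    expect_equal(nrow(gb), 2L)
    expect_equal(gb$bias_index[gb$gene_id == "up"], 1)
    expect_equal(gb$path, c("exact", "exact"))
    # planted 2-fold shift in one class of genes -> positive median BI
    # for the affected genes (a genome-wide shift would cancel under the
    # compositional cpm normalization, so the shift is planted in H3 only)
    sdn <- miniDesign(seed = 21, nGenes = 60,
                      lfc = c(L1 = 0, L2 = 0, H1 = 0, H2 = 0, H3 = 1))
    cnt <- generateCounts(sdn)
    ses <- cpmNormalize(cnt$es)
    gb2 <- perGeneUmcw(ses, list(sex = "female", tissue = "gWAT",
                                 exposure = "EXP", control = "DMSO"))
    h3 <- cnt$truth$gene_id[cnt$truth$class == "H3"]
    expect_gt(stats::median(gb2$bias_index[gb2$gene_id %in% h3]), 0.5)
    expect_equal(unique(gb2$n_rearrangements), 252L)  # C(10,5), exact
})

test_that("count TSV round-trips through readCountsTsv", {
    counts <- matrix(1:6, 2, dimnames = list(c("g1", "g2"),
                                             c("s1", "s2", "s3")))
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(gene_id = rownames(counts), counts),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    m <- readCountsTsv(path)
    expect_equal(m, matrix(as.double(1:6), 2,
                           dimnames = list(c("g1", "g2"),
                                           c("s1", "s2", "s3"))))
})
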