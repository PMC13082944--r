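# Independent brute-force oracles for the MCW tests and the enrichment
# walk. These are written from the test construction rules directly --
# explicit sorting loops and exhaustive enumeration -- and share no code
# with the package implementation.

# signed ranks by explicit sort: zeros rank 0, nonzeros ranked ascending
# by |d| starting at 1, tied |d| all get the minimum of their would-be
# ranks, sign carried over
oracleSignedRanks <- function(d) {
    out <- numeric(length(d))
    nzIdx <- which(d != 0)
    if (!length(nzIdx)) return(out)
    av <- abs(d[nzIdx])
    ord <- order(av)
    rk <- integer(length(nzIdx))
    pos <- 1L
    i <- 1L
    while (i <= length(ord)) {
        j <- i
        while (j < length(ord) && av[ord[j + 1L]] == av[ord[i]]) j <- j + 1L
        rk[ord[i:j]] <- pos          # min of would-be ranks pos..pos+(j-i)
        pos <- pos + (j - i + 1L)
        i <- j + 1L
    }
    out[nzIdx] <- rk * sign(d[nzIdx])
    out
}

# uMCW BI for one assignment: Cartesian cross-set differences
oracleUmcwBI <- function(a, b) {
    d <- c(outer(a, b, `-`))
    sr <- oracleSignedRanks(d)
    den <- sum(abs(sr))
    if (den == 0) 0 else sum(sr) / den
}

# exhaustive uMCW: enumerate every C(nA+nB, nA) assortment
oracleUmcw <- function(a, b) {
    pool <- c(a, b)
    nA <- length(a)
    splits <- combn(length(pool), nA)
    nulls <- apply(splits, 2L, function(idx)
        oracleUmcwBI(pool[idx], pool[-idx]))
    obs <- oracleUmcwBI(a, b)
    list(bi = obs,
         pUpper = mean(nulls >= obs - 1e-9),
         pLower = mean(nulls <= obs + 1e-9))
}

# exhaustive mbMCW: joint signed ranks of pooled pair differences,
# BI = (S_x - S_y) / (most extreme S_x - S_y), null over pair reassortment
oracleMbmcw <- function(x, y) {
    dAll <- c(x[, 1] - x[, 2], y[, 1] - y[, 2])
    sr <- oracleSignedRanks(dAll)
    M <- sum(abs(sr))
    nX <- nrow(x)
    biOf <- function(idx) {
        if (M == 0) return(0)
        (sum(sr[idx]) - sum(sr[-idx])) / M
    }
    obs <- biOf(seq_len(nX))
    splits <- combn(length(sr), nX)
    nulls <- apply(splits, 2L, biOf)
    list(bi = obs,
         pUpper = mean(nulls >= obs - 1e-9),
         pLower = mean(nulls <= obs + 1e-9))
}

# exhaustive bMCW: wBI over all 2^N sign flips, sBI over all C(N, |S|)
# memberships
oracleBmcw <- function(v, subsetIdx) {
    sr <- oracleSignedRanks(v)
    n <- length(v)
    denW <- sum(abs(sr))
    wObs <- if (denW == 0) 0 else sum(sr) / denW
    signGrid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    wNull <- (signGrid %*% abs(sr)) / max(denW, 1)
    k <- length(subsetIdx)
    denS <- sum(sort(abs(sr), decreasing = TRUE)[seq_len(k)])
    sObs <- if (denS == 0) 0 else sum(sr[subsetIdx]) / denS
    mem <- combn(n, k)
    sNull <- apply(mem, 2L, function(idx)
        if (denS == 0) 0 else sum(sr[idx]) / denS)
    list(wBI = wObs,
         wPUpper = mean(wNull >= wObs - 1e-9),
         wPLower = mean(wNull <= wObs + 1e-9),
         sBI = sObs,
         sPUpper = mean(sNull >= sObs - 1e-9),
         sPLower = mean(sNull <= sObs + 1e-9))
}

# enrichment score by an explicit position-by-position walk
oracleES <- function(stat, members) {
    ord <- order(-stat, names(stat))
    stat <- stat[ord]
    hit <- names(stat) %in% members
    sumHit <- sum(abs(stat[hit]))
    nMiss <- sum(!hit)
    run <- 0
    best <- 0
    for (i in seq_along(stat)) {
        run <- run + if (hit[i]) abs(stat[[i]]) / sumHit else -1 / nMiss
        if (abs(run) > abs(best)) best <- run
    }
    best
}

# assignments table for genes whose class is known by construction
truthAssignments <- function(truth, chrom = "chr1") {
    data.frame(gene_id = truth$gene_id, chrom = chrom,
               start = 0L, end = 1L, strand = "+",
               assigned_isochore_id = paste0("iso_", truth$class),
               assigned_class = truth$class)
}

# one-contrast synthetic design used by the recovery/calibration suites:
# a single sex/tissue, control + one exposure group
miniDesign <- function(seed, nGenes, lfc = c(L1 = 0, L2 = 0, H1 = 0,
                                             H2 = 0, H3 = 0),
                       dispersion = 0.1) {
    syntheticDesign(
        seed = seed, nGenes = nGenes,
        design = list(sexes = "female", tissues = "gWAT",
                      groups = c("DMSO", "EXP"), control = "DMSO",
                      replicates = 5L),
        plantedClassLog2fc = lfc, nbDispersion = dispersion)
}
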