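## Pre-ranked gene set enrichment on uMCW bias indexes: the classic
## weighted running-sum enrichment score with a set-permutation null.

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated)
#' @return named list of character vectors (unique members)
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(ln) unique(strsplit(ln, "\t")[[1]][-(1:2)]))
    names(sets) <- vapply(lines, function(ln)
        strsplit(ln, "\t")[[1]][1], character(1), USE.NAMES = FALSE)
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output file
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Filter gene sets against a ranked-list universe
#'
#' Memberships are first intersected with the universe, then sets with at
#' least \code{minSize} and fewer than \code{maxSize} remaining members are
#' kept (the GO-BP convention: at least 15 and less than 500 genes).
#'
#' @param sets named list of character vectors
#' @param universe character vector of genes in the ranked list
#' @param minSize,maxSize inclusive lower and exclusive upper size bounds
#'   (defaults 15 and 500)
#' @return named list of filtered sets
#' @export
filterGeneSets <- function(sets, universe, minSize = 15L, maxSize = 500L) {
    sets <- lapply(sets, function(s) unique(intersect(s, universe)))
    sizes <- lengths(sets)
    out <- sets[sizes >= minSize & sizes < maxSize]
    if (!length(out))
        warning("no gene sets left after size filtering")
    out
}

#' Rank genes by statistic, highest first
#'
#' Ties in the statistic are broken by gene id so the list is strictly and
#' reproducibly ordered.
#'
#' @param stat named numeric vector (names = gene ids), e.g. per-gene uMCW
#'   bias indexes
#' @return the same vector sorted descending
#' @export
rankGenes <- function(stat) {
    stopifnot(!is.null(names(stat)), all(is.finite(stat)))
    stat[order(-stat, names(stat))]
}

#' Running-sum enrichment score
#'
#' Walks the ranked list top to bottom: positions in the set add
#' |stat|/sum(|stat| over the set) (weight exponent 1), positions outside
#' subtract 1/(N - Nset). The enrichment score is the deviation of maximal
#' magnitude, with its sign.
#'
#' @param ranked named numeric vector from [rankGenes()]
#' @param members character vector of set member gene ids (subset of the
#'   ranked genes)
#' @return enrichment score in [-1, 1]
#' @export
runningES <- function(ranked, members) {
    hit <- names(ranked) %in% members
    nh <- sum(hit)
    N <- length(ranked)
    if (nh == 0L || nh == N)
        stop("set must be a non-empty proper subset of the ranked genes")
    sumHit <- sum(abs(ranked[hit]))
    if (sumHit == 0)
        stop("all ranking statistics over the set are zero")
    inc <- ifelse(hit, abs(ranked) / sumHit, -1 / (N - nh))
    rs <- cumsum(inc)
    unname(rs[which.max(abs(rs))])
}

## ES for a membership given by index positions (fast path for the null)
.esByIndex <- function(absStat, N, idx) {
    inc <- rep(-1 / (N - length(idx)), N)
    s <- sum(absStat[idx])
    if (s == 0) return(0)
    inc[idx] <- absStat[idx] / s
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
}

#' GSEA set-permutation null, p-value and NES
#'
#' Draws \code{nPerm} random same-size memberships from the ranked list
#' (equivalent to permuting gene ranks for a fixed set), computes their
#' enrichment scores, and derives a p-value as the proportion of same-sign
#' null scores at least as extreme as the observed one (floored at
#' 1/nPerm) and a normalized score NES = es / mean(|null es| of the same
#' sign).
#'
#' @param ranked named numeric vector from [rankGenes()]
#' @param es observed enrichment score for the set
#' @param setSize number of members
#' @param nPerm number of permutations (>= 100)
#' @param seed RNG seed
#' @return list(es, nes, p, nullEs, nPerm)
#' @export
gseaNull <- function(ranked, es, setSize, nPerm = 1000L, seed = 1L) {
    stopifnot(nPerm >= 100L)
    N <- length(ranked)
    absStat <- abs(ranked)
    nullEs <- withSeed(seed, {
        vapply(seq_len(nPerm), function(i)
            .esByIndex(absStat, N, sample.int(N, setSize)), numeric(1))
    })
    sameSign <- if (es >= 0) nullEs[nullEs >= 0] else nullEs[nullEs < 0]
    if (!length(sameSign)) {
        p <- 1 / nPerm
        nes <- NA_real_
    } else {
        extreme <- sum(abs(sameSign) >= abs(es) - 1e-12)
        p <- max(extreme, 1L) / length(sameSign)
        p <- min(p, 1)
        nes <- if (mean(abs(sameSign)) > 0) es / mean(abs(sameSign))
               else NA_real_
    }
    list(es = es, nes = nes, p = p, nullEs = nullEs, nPerm = nPerm)
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Ranks genes with [rankGenes()], filters sets with [filterGeneSets()],
#' then computes per set the running-sum enrichment score, a
#' set-permutation p-value and a normalized enrichment score.
#'
#' @param stat named numeric vector of ranking statistics (per-gene uMCW
#'   bias indexes)
#' @param sets named list of gene sets
#' @param nPerm permutations per set
#' @param seed RNG seed (one stream per set, derived deterministically)
#' @param minSize,maxSize set-size bounds passed to [filterGeneSets()]
#' @return data.frame with columns set, size, es, nes, p, n_permutations
#' @export
gseaPreranked <- function(stat, sets, nPerm = 1000L, seed = 1L,
                          minSize = 15L, maxSize = 500L) {
    ranked <- rankGenes(stat)
    sets <- filterGeneSets(sets, names(ranked), minSize, maxSize)
    if (!length(sets))
        return(data.frame(set = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0), p = numeric(0),
                          n_permutations = integer(0)))
    rows <- lapply(seq_along(sets), function(k) {
        members <- sets[[k]]
        es <- runningES(ranked, members)
        nl <- gseaNull(ranked, es, length(members), nPerm = nPerm,
                       seed = seed + k)
        data.frame(set = names(sets)[k], size = length(members),
                   es = es, nes = nl$nes, p = nl$p,
                   n_permutations = nPerm)
    })
    do.call(rbind, rows)
}
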