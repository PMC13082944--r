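## Monte Carlo-Wilcoxon (MCW) rearrangement tests.
##
## All three variants share the same signed-ranking rules and the same
## two-path null machinery: when the number of potentially distinctive
## rearrangements is below the max_rearrangements budget the null is
## enumerated exhaustively ("exact" path), otherwise max_rearrangements
## uniform draws with replacement are taken ("approximate" path).

## numeric tolerance when comparing null BIs with the observed BI: BIs are
## ratios of small-integer rank sums, so 1e-9 separates genuine ties from
## floating-point noise
.BI_EPS <- 1e-9

.splitCache <- new.env(parent = emptyenv())

#' MCW test configuration
#'
#' @param maxRearrangements positive integer; the null is enumerated
#'   exhaustively when the number of potentially distinctive rearrangements
#'   is strictly less than this budget, otherwise this many Monte-Carlo
#'   draws are taken. Default 10000.
#' @param seed integer seed driving the Monte-Carlo path; results are fully
#'   deterministic given (input, config).
#' @return list of class "MCWConfig"
#' @export
mcwConfig <- function(maxRearrangements = 10000L, seed = 1L) {
    maxRearrangements <- as.integer(maxRearrangements)
    if (is.na(maxRearrangements) || maxRearrangements < 1L)
        stop("maxRearrangements must be a positive integer")
    structure(list(maxRearrangements = maxRearrangements,
                   seed = as.integer(seed)),
              class = "MCWConfig")
}

## evaluate expr under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
    expr
}

#' Signed ranks of a difference vector, MCW convention
#'
#' Differences equal to zero receive rank 0. Nonzero differences are ranked
#' ascending by absolute value starting at 1 among the nonzeros; tied
#' absolute values all receive the lowest of their would-be ranks. Each rank
#' carries the sign of its difference.
#'
#' @param differences numeric vector of finite differences
#' @return integer-valued numeric vector of signed ranks, same length
#' @examples
#' signedRanks(c(3, -1, 0, 3))  # +2 -1 0 +2
#' @export
signedRanks <- function(differences) {
    if (!length(differences))
        stop("differences must be non-empty")
    if (!all(is.finite(differences)))
        stop("differences must all be finite")
    out <- numeric(length(differences))
    nz <- differences != 0
    if (any(nz))
        out[nz] <- sign(differences[nz]) *
            rank(abs(differences[nz]), ties.method = "min")
    out
}

#' Number of potentially distinctive rearrangements for an MCW null
#'
#' @param kind one of "umcw", "mbmcw", "bmcw_whole", "bmcw_subset"
#' @param nA,nB set sizes for umcw/mbmcw (measures, respectively pairs)
#' @param n total number of elements for bmcw
#' @param subsetSize subset size for bmcw_subset
#' @return a double; may exceed .Machine$integer.max (binomials and powers
#'   overflow quickly), callers only compare it against maxRearrangements
#' @export
countRearrangements <- function(kind = c("umcw", "mbmcw", "bmcw_whole",
                                         "bmcw_subset"),
                                nA = NULL, nB = NULL, n = NULL,
                                subsetSize = NULL) {
    kind <- match.arg(kind)
    switch(kind,
        umcw = ,
        mbmcw = {
            stopifnot(nA >= 1L, nB >= 1L)
            choose(nA + nB, nA)
        },
        bmcw_whole = {
            stopifnot(n >= 1L)
            2^n
        },
        bmcw_subset = {
            stopifnot(n >= 1L, subsetSize >= 1L, subsetSize <= n)
            choose(n, subsetSize)
        })
}

## all size-k index subsets of 1..n, cached (shared across per-gene tests)
.allSplits <- function(n, k) {
    key <- paste0(n, "_", k)
    if (!is.null(.splitCache[[key]])) return(.splitCache[[key]])
    sp <- combn(n, k)
    .splitCache[[key]] <- sp
    sp
}

## BI of the unmatched test for one assignment of pooled values into sets
.umcwBI <- function(a, b) {
    d <- rep(a, times = length(b)) - rep(b, each = length(a))
    sr <- signedRanks(d)
    denom <- sum(abs(sr))
    if (denom == 0) 0 else sum(sr) / denom
}

.tailP <- function(nullBIs, observed) {
    list(pUpper = mean(nullBIs >= observed - .BI_EPS),
         pLower = mean(nullBIs <= observed + .BI_EPS))
}

#' Unmatched-measures Monte Carlo-Wilcoxon (uMCW) test
#'
#' Tests whether two sets of unmatched measures are biased in the same
#' direction. All cross-set pairs (every value of \code{a} against every
#' value of \code{b}) are formed, differences a_i - b_j are signed-ranked
#' by [signedRanks()], and the bias index is the signed-rank sum divided by
#' its value under complete bias (all a above all b). The null rearranges
#' the measure assortment between the two sets.
#'
#' BI = 1 means every measure of \code{a} exceeds every measure of \code{b};
#' BI = -1 the reverse; 0 no net bias.
#'
#' @param a,b numeric vectors of measures (non-empty, finite)
#' @param config an [mcwConfig()] list
#' @return an [MCWResult-class]
#' @examples
#' umcwTest(c(10, 11, 12), c(1, 2, 3))  # BI = 1
#' @export
umcwTest <- function(a, b, config = mcwConfig()) {
    if (!length(a) || !length(b))
        stop("both measure sets must be non-empty")
    if (!all(is.finite(a)) || !all(is.finite(b)))
        stop("measures must all be finite")
    nA <- length(a); nB <- length(b)
    pooled <- c(a, b)
    n <- nA + nB
    observed <- .umcwBI(a, b)
    total <- countRearrangements("umcw", nA = nA, nB = nB)
    if (total < config$maxRearrangements) {
        splits <- .allSplits(n, nA)
        nullBIs <- vapply(seq_len(ncol(splits)), function(j) {
            idx <- splits[, j]
            .umcwBI(pooled[idx], pooled[-idx])
        }, numeric(1))
        path <- "exact"
    } else {
        nullBIs <- withSeed(config$seed, {
            vapply(seq_len(config$maxRearrangements), function(i) {
                idx <- sample.int(n, nA)
                .umcwBI(pooled[idx], pooled[-idx])
            }, numeric(1))
        })
        path <- "approximate"
    }
    p <- .tailP(nullBIs, observed)
    MCWResult(observed, p$pUpper, p$pLower, length(nullBIs), path, "umcw")
}

#' Matched-measures bivariate Monte Carlo-Wilcoxon (mbMCW) test
#'
#' Tests whether two sets of inherently matched-paired measures are
#' differentially biased. Per-pair differences (first - second) from both
#' sets are pooled and signed-ranked jointly; the bias index is
#' (S_x - S_y) / M, where S_g is the signed-rank sum of set g and M the
#' value of S_x - S_y in the most extreme configuration (all set-x
#' differences positive and above all set-y differences), which equals the
#' sum of all absolute ranks. The null permutes the pair-to-set assignment.
#'
#' @param x,y two-column numeric matrices (or data.frames) with one
#'   matched pair (first, second) per row
#' @param config an [mcwConfig()] list
#' @return an [MCWResult-class]
#' @examples
#' mbmcwTest(rbind(c(5, 1), c(6, 1)), rbind(c(1, 5), c(1, 6)))  # BI = 1
#' @export
mbmcwTest <- function(x, y, config = mcwConfig()) {
    x <- as.matrix(x); y <- as.matrix(y)
    if (!nrow(x) || !nrow(y))
        stop("both matched sets must contain at least one pair")
    if (ncol(x) != 2L || ncol(y) != 2L)
        stop("matched sets must have exactly two columns (first, second)")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("pair members must all be finite")
    dx <- x[, 1] - x[, 2]
    dy <- y[, 1] - y[, 2]
    nX <- length(dx); nY <- length(dy); n <- nX + nY
    sr <- signedRanks(c(dx, dy))
    denom <- sum(abs(sr))
    xIdx <- seq_len(nX)
    biFor <- function(idx) {
        if (denom == 0) return(0)
        (2 * sum(sr[idx]) - sum(sr)) / denom
    }
    observed <- biFor(xIdx)
    total <- countRearrangements("mbmcw", nA = nX, nB = nY)
    if (total < config$maxRearrangements) {
        splits <- .allSplits(n, nX)
        nullBIs <- vapply(seq_len(ncol(splits)), function(j)
            biFor(splits[, j]), numeric(1))
        path <- "exact"
    } else {
        nullBIs <- withSeed(config$seed, {
            vapply(seq_len(config$maxRearrangements), function(i)
                biFor(sample.int(n, nX)), numeric(1))
        })
        path <- "approximate"
    }
    p <- .tailP(nullBIs, observed)
    MCWResult(observed, p$pUpper, p$pLower, length(nullBIs), path, "mbmcw")
}

#' Biased-measures Monte Carlo-Wilcoxon (bMCW) test
#'
#' Given per-element measures of bias (here, typically per-gene uMCW bias
#' indexes) and one or more designated subsets, computes:
#' \itemize{
#'   \item the whole-set bias index wBI = sum of signed ranks / sum of
#'     absolute ranks, with a null that rearranges the signs of all signed
#'     ranks;
#'   \item per subset, the subset bias index sBI = signed-rank sum over the
#'     subset / sum of the |S| largest absolute ranks (its value had the
#'     subset held the most positive measures), with a null that draws
#'     random same-size memberships.
#' }
#'
#' @param biasValues named (or unnamed) numeric vector of per-element bias
#'   measures; names are element ids
#' @param subsets named list; each entry a vector of element ids (when
#'   \code{biasValues} is named) or integer indices
#' @param config an [mcwConfig()] list
#' @return a [BmcwResult-class]
#' @examples
#' v <- c(e1 = 0.5, e2 = -0.2, e3 = 0.9)
#' bmcwTest(v, list(hi = c("e1", "e3")))
#' @export
bmcwTest <- function(biasValues, subsets = list(), config = mcwConfig()) {
    if (!length(biasValues))
        stop("biasValues must be non-empty")
    if (!all(is.finite(biasValues)))
        stop("biasValues must all be finite")
    n <- length(biasValues)
    ids <- names(biasValues)
    subsets <- lapply(subsets, function(s) {
        if (is.character(s)) {
            if (is.null(ids)) stop("character subsets need named biasValues")
            idx <- match(s, ids)
            if (anyNA(idx)) stop("subset contains unknown element ids")
            idx
        } else {
            s <- as.integer(s)
            if (any(s < 1L | s > n)) stop("subset index out of range")
            s
        }
    })
    bad <- vapply(subsets, function(s) length(s) < 1L || length(s) > n,
                  logical(1))
    if (any(bad)) stop("each subset must satisfy 1 <= |subset| <= N")

    sr <- signedRanks(biasValues)
    absR <- abs(sr)
    denomW <- sum(absR)

    ## whole-set index: null flips the sign of every signed rank
    wObs <- if (denomW == 0) 0 else sum(sr) / denomW
    totalW <- countRearrangements("bmcw_whole", n = n)
    if (totalW < config$maxRearrangements) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
        nullW <- as.vector(signs %*% absR)
        if (denomW > 0) nullW <- nullW / denomW
        pathW <- "exact"
    } else {
        nullW <- withSeed(config$seed, {
            m <- config$maxRearrangements
            sgn <- matrix(sample(c(-1, 1), n * m, replace = TRUE), nrow = n)
            as.vector(crossprod(sgn, absR))
        })
        if (denomW > 0) nullW <- nullW / denomW
        pathW <- "approximate"
    }
    pW <- .tailP(nullW, wObs)
    whole <- MCWResult(wObs, pW$pUpper, pW$pLower, length(nullW), pathW,
                       "bmcw_whole")

    ## subset indexes: null draws random memberships of the same size
    sortedDesc <- sort(absR, decreasing = TRUE)
    perSubset <- lapply(subsets, function(idx) {
        k <- length(idx)
        denomS <- sum(sortedDesc[seq_len(k)])
        sObs <- if (denomS == 0) 0 else sum(sr[idx]) / denomS
        totalS <- countRearrangements("bmcw_subset", n = n, subsetSize = k)
        if (totalS < config$maxRearrangements) {
            memberships <- .allSplits(n, k)
            sums <- colSums(matrix(sr[memberships], nrow = k))
            pathS <- "exact"
        } else {
            sums <- withSeed(config$seed, {
                m <- config$maxRearrangements
                draws <- vapply(seq_len(m), function(i) sample.int(n, k),
                                integer(k))
                if (k == 1L) sr[draws]
                else colSums(matrix(sr[draws], nrow = k))
            })
            pathS <- "approximate"
        }
        nullS <- if (denomS == 0) sums * 0 else sums / denomS
        pS <- .tailP(nullS, sObs)
        MCWResult(sObs, pS$pUpper, pS$pLower, length(nullS), pathS,
                  "bmcw_subset")
    })
    names(perSubset) <- names(subsets)
    new("BmcwResult", wholeSet = whole, perSubset = perSubset)
}
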