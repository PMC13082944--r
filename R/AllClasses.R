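#' @import methods
#' @importFrom stats rnbinom rnorm runif prcomp cor.test rbinom
#' @importFrom utils combn head write.table read.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MCWResult: result of a Monte Carlo-Wilcoxon test
#'
#' Holds the observed bias index (BI) of an MCW test together with its
#' rearrangement-null p-values and path metadata. The BI always lies in
#' [-1, 1]: 1 means the measures are completely biased in one direction,
#' -1 in the other. \code{pUpper} and \code{pLower} are the proportions of
#' expected-by-chance BIs that are at least as high, respectively at least
#' as low, as the observed BI; ties with the observed BI count toward both,
#' so \code{pUpper + pLower >= 1} on the exact path.
#'
#' @slot biasIndex numeric(1), the observed bias index in [-1, 1].
#' @slot pUpper numeric(1), upper-tail rearrangement p-value.
#' @slot pLower numeric(1), lower-tail rearrangement p-value.
#' @slot nRearrangements integer(1), number of null rearrangements used.
#' @slot path character(1), "exact" (full enumeration) or "approximate"
#'   (Monte-Carlo draws).
#' @slot kind character(1), which test produced the result
#'   ("umcw", "mbmcw", "bmcw_whole", "bmcw_subset").
#'
#' @seealso [umcwTest()], [mbmcwTest()], [bmcwTest()]
#' @export
setClass("MCWResult",
    representation(
        biasIndex = "numeric",
        pUpper = "numeric",
        pLower = "numeric",
        nRearrangements = "integer",
        path = "character",
        kind = "character"
    )
)

setValidity("MCWResult", function(object) {
    msg <- NULL
    if (length(object@biasIndex) != 1L || !is.finite(object@biasIndex))
        msg <- c(msg, "biasIndex must be a single finite number")
    else if (object@biasIndex < -1 - 1e-12 || object@biasIndex > 1 + 1e-12)
        msg <- c(msg, "biasIndex must lie in [-1, 1]")
    if (object@pUpper < 0 || object@pUpper > 1)
        msg <- c(msg, "pUpper must lie in [0, 1]")
    if (object@pLower < 0 || object@pLower > 1)
        msg <- c(msg, "pLower must lie in [0, 1]")
    if (!object@path %in% c("exact", "approximate"))
        msg <- c(msg, "path must be 'exact' or 'approximate'")
    if (is.null(msg)) TRUE else msg
})

MCWResult <- function(biasIndex, pUpper, pLower, nRearrangements, path, kind) {
    new("MCWResult",
        biasIndex = as.numeric(biasIndex),
        pUpper = as.numeric(pUpper),
        pLower = as.numeric(pLower),
        nRearrangements = as.integer(nRearrangements),
        path = path, kind = kind)
}

#' BmcwResult: result of a biased-measures MCW test
#'
#' Couples the whole-set bias index (wBI) with one subset bias index (sBI)
#' per designated subset, each carried as an [MCWResult-class].
#'
#' @slot wholeSet MCWResult for the whole-set bias index.
#' @slot perSubset named list of MCWResult, one per subset.
#'
#' @seealso [bmcwTest()]
#' @export
setClass("BmcwResult",
    representation(wholeSet = "MCWResult", perSubset = "list")
)

setValidity("BmcwResult", function(object) {
    ok <- vapply(object@perSubset, is, logical(1), class2 = "MCWResult")
    if (length(object@perSubset) && !all(ok))
        return("perSubset entries must all be MCWResult objects")
    if (length(object@perSubset) && is.null(names(object@perSubset)))
        return("perSubset must be a named list")
    TRUE
})

#' @describeIn MCWResult-class observed bias index
#' @param object an \code{MCWResult}
#' @export
setGeneric("biasIndex", function(object) standardGeneric("biasIndex"))
#' @describeIn MCWResult-class upper-tail p-value
#' @export
setGeneric("pUpper", function(object) standardGeneric("pUpper"))
#' @describeIn MCWResult-class lower-tail p-value
#' @export
setGeneric("pLower", function(object) standardGeneric("pLower"))
#' @describeIn MCWResult-class number of rearrangements behind the null
#' @export
setGeneric("nRearrangements", function(object) standardGeneric("nRearrangements"))
#' @describeIn MCWResult-class "exact" or "approximate"
#' @export
setGeneric("rearrangementPath", function(object) standardGeneric("rearrangementPath"))

#' @export
setMethod("biasIndex", "MCWResult", function(object) object@biasIndex)
#' @export
setMethod("pUpper", "MCWResult", function(object) object@pUpper)
#' @export
setMethod("pLower", "MCWResult", function(object) object@pLower)
#' @export
setMethod("nRearrangements", "MCWResult", function(object) object@nRearrangements)
#' @export
setMethod("rearrangementPath", "MCWResult", function(object) object@path)

#' @describeIn BmcwResult-class the whole-set (wBI) result
#' @param object a \code{BmcwResult}
#' @export
setGeneric("wholeSetResult", function(object) standardGeneric("wholeSetResult"))
#' @describeIn BmcwResult-class named list of per-subset (sBI) results
#' @export
setGeneric("subsetResults", function(object) standardGeneric("subsetResults"))

#' @export
setMethod("wholeSetResult", "BmcwResult", function(object) object@wholeSet)
#' @export
setMethod("subsetResults", "BmcwResult", function(object) object@perSubset)

setMethod("show", "MCWResult", function(object) {
    cat(sprintf("MCWResult (%s, %s path)\n", object@kind, object@path))
    cat(sprintf("  BI = %.4f\n", object@biasIndex))
    cat(sprintf("  P_upper = %.4g, P_lower = %.4g  (%d rearrangements)\n",
        object@pUpper, object@pLower, object@nRearrangements))
})

setMethod("show", "BmcwResult", function(object) {
    cat("BmcwResult\n  whole set: ")
    cat(sprintf("wBI = %.4f (P_upper %.4g, P_lower %.4g)\n",
        object@wholeSet@biasIndex, object@wholeSet@pUpper,
        object@wholeSet@pLower))
    cat(sprintf("  %d subset(s):\n", length(object@perSubset)))
    for (nm in head(names(object@perSubset), 8L)) {
        r <- object@perSubset[[nm]]
        cat(sprintf("    %s: sBI = %.4f (P_upper %.4g, P_lower %.4g)\n",
            nm, r@biasIndex, r@pUpper, r@pLower))
    }
    if (length(object@perSubset) > 8L)
        cat(sprintf("    ... and %d more\n", length(object@perSubset) - 8L))
})

#' Convert an MCWResult (or BmcwResult) to a one-row data.frame
#'
#' @param x an MCWResult or BmcwResult
#' @param ... unused
#' @return data.frame with columns kind, subset, bias_index, p_upper,
#'   p_lower, n_rearrangements, path
#' @export
mcwAsDataFrame <- function(x, ...) {
    if (is(x, "MCWResult")) {
        return(data.frame(
            kind = x@kind, subset = NA_character_,
            bias_index = x@biasIndex, p_upper = x@pUpper,
            p_lower = x@pLower, n_rearrangements = x@nRearrangements,
            path = x@path, stringsAsFactors = FALSE))
    }
    stopifnot(is(x, "BmcwResult"))
    whole <- mcwAsDataFrame(x@wholeSet)
    subs <- lapply(names(x@perSubset), function(nm) {
        df <- mcwAsDataFrame(x@perSubset[[nm]])
        df$subset <- nm
        df
    })
    do.call(rbind, c(list(whole), subs))
}
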