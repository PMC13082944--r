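## Compartment-bias analysis: bMCW tests on per-gene uMCW bias indexes
## over the whole transcriptome, isochore classes, individual isochores
## and chromosomes, plus the heterochromatin/euchromatin dichotomy call.

.AT_CLASSES <- c("L1", "L2")
.GC_CLASSES <- c("H2", "H3")

#' Compartment bMCW tests for one contrast
#'
#' Runs a single [bmcwTest()] whose measures are the per-gene uMCW bias
#' indexes of one exposure-versus-control contrast and whose subsets are
#' the isochore classes, the chromosomes, and (optionally) individual
#' isochores. Genes without an isochore assignment stay in the whole set
#' but join no class/isochore subset. Empty subsets are skipped.
#'
#' @param geneBias named numeric vector of per-gene bias indexes (names =
#'   gene ids)
#' @param assignments data.frame from [assignGenes()] covering the genes
#' @param config an [mcwConfig()]
#' @param isochoreIds optional character vector of isochore ids to test
#'   individually; alternatively set \code{minIsochoreGenes} to test every
#'   isochore holding at least that many genes
#' @param minIsochoreGenes minimum gene count for per-isochore subsets
#'   (default Inf: none unless \code{isochoreIds} given)
#' @return list with elements \code{bmcw} (the [BmcwResult-class]) and
#'   \code{table} (long data.frame: subset_kind, subset_id, bias_index,
#'   p_upper, p_lower, n_rearrangements, path)
#' @export
compartmentBmcw <- function(geneBias, assignments, config = mcwConfig(),
                            isochoreIds = NULL, minIsochoreGenes = Inf) {
    stopifnot(!is.null(names(geneBias)))
    idx <- match(names(geneBias), assignments$gene_id)
    if (anyNA(idx))
        stop("every gene in geneBias must appear in assignments")
    cls <- assignments$assigned_class[idx]
    iso <- assignments$assigned_isochore_id[idx]
    chrom <- assignments$chrom[idx]
    ids <- names(geneBias)

    subsets <- list()
    kinds <- character(0)
    for (cc in .ISOCHORE_CLASSES) {
        members <- ids[!is.na(cls) & cls == cc]
        if (length(members)) {
            subsets[[paste0("class:", cc)]] <- members
            kinds <- c(kinds, "class")
        }
    }
    for (ch in unique(chrom)) {
        members <- ids[chrom == ch]
        if (length(members)) {
            subsets[[paste0("chrom:", ch)]] <- members
            kinds <- c(kinds, "chromosome")
        }
    }
    isoTab <- table(iso[!is.na(iso)])
    wanted <- union(isochoreIds,
                    names(isoTab)[isoTab >= minIsochoreGenes])
    for (ii in wanted) {
        members <- ids[!is.na(iso) & iso == ii]
        if (length(members)) {
            subsets[[paste0("isochore:", ii)]] <- members
            kinds <- c(kinds, "isochore")
        } else {
            message("skipping empty isochore subset: ", ii)
        }
    }

    res <- bmcwTest(geneBias, subsets, config)
    tab <- mcwAsDataFrame(res)
    tab$subset_kind <- c("whole", kinds)
    tab$subset_id <- sub("^[a-z]+:", "", tab$subset)
    tab$subset_id[1L] <- "transcriptome"
    tab <- tab[, c("subset_kind", "subset_id", "bias_index", "p_upper",
                   "p_lower", "n_rearrangements", "path")]
    list(bmcw = res, table = tab)
}

#' Call the heterochromatin/euchromatin expression dichotomy
#'
#' The dichotomy is "present" when the AT-rich classes (L1, L2) and the
#' GC-rich classes (H2, H3) show subset bias indexes of opposite mean sign
#' and each side has at least one class with min(P_upper, P_lower) below
#' \code{alpha}. The direction label says which side is up: "present_GC_up"
#' when H2/H3 are positive, "present_AT_up" when L1/L2 are. H1, the
#' intermediate class, carries no constraint.
#'
#' @param report output of [compartmentBmcw()] (or its \code{table})
#' @param alpha per-class significance threshold (default 0.05)
#' @return one of "present_AT_up", "present_GC_up", "absent"
#' @export
dichotomyCall <- function(report, alpha = 0.05) {
    tab <- if (is.data.frame(report)) report else report$table
    cls <- tab[tab$subset_kind == "class", , drop = FALSE]
    need <- c(.AT_CLASSES, .GC_CLASSES)
    if (!all(need %in% cls$subset_id)) {
        warning("missing class subset(s): ",
                paste(setdiff(need, cls$subset_id), collapse = ", "))
        return("absent")
    }
    at <- cls[cls$subset_id %in% .AT_CLASSES, , drop = FALSE]
    gc <- cls[cls$subset_id %in% .GC_CLASSES, , drop = FALSE]
    atMean <- mean(at$bias_index)
    gcMean <- mean(gc$bias_index)
    if (sign(atMean) == 0 || sign(gcMean) == 0 ||
        sign(atMean) == sign(gcMean))
        return("absent")
    sigAt <- any(pmin(at$p_upper, at$p_lower) < alpha)
    sigGc <- any(pmin(gc$p_upper, gc$p_lower) < alpha)
    if (!sigAt || !sigGc)
        return("absent")
    if (gcMean > 0) "present_GC_up" else "present_AT_up"
}
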