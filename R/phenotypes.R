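## Metabolic-trait analyses: age/body-weight normalizations, matched-pair
## constructions for fasting and cage-consumption data, plasma-panel
## cleaning, PCA, Pearson correlations, litter statistics and dosing
## arithmetic.

#' Normalize a trait by age (and optionally body weight)
#'
#' Body weight is normalized by days of age (g per day old); fasting
#' glucose, tissue weights and plasma metabolites are additionally
#' normalized by body weight, giving e.g. (mg/dL)/g/days old.
#'
#' @param value trait value(s)
#' @param ageDays days of age (> 0)
#' @param bodyWeight body weight in g (> 0), or NULL for age-only
#'   normalization
#' @return normalized value(s)
#' @examples
#' normalizeTrait(30, ageDays = 60)                    # 0.5 g/day
#' normalizeTrait(120, ageDays = 60, bodyWeight = 30)  # 0.0667
#' @export
normalizeTrait <- function(value, ageDays, bodyWeight = NULL) {
    if (any(ageDays <= 0))
        stop("ageDays must be positive")
    out <- value / ageDays
    if (!is.null(bodyWeight)) {
        if (any(bodyWeight <= 0))
            stop("bodyWeight must be positive")
        out <- out / bodyWeight
    }
    out
}

## shared matched-pair builder: rows (later, earlier) per subject, split
## into exposure (x) and control (y) sets
.buildPairs <- function(subject, group, earlier, later, exposure, control,
                        what) {
    ok <- is.finite(earlier) & is.finite(later)
    if (any(!ok))
        message(sprintf("excluding %d %s(s) with an incomplete pair",
                        sum(!ok), what))
    keep <- ok & group %in% c(exposure, control)
    pairs <- cbind(first = later[keep], second = earlier[keep])
    g <- group[keep]
    x <- pairs[g == exposure, , drop = FALSE]
    y <- pairs[g == control, , drop = FALSE]
    if (!nrow(x) || !nrow(y))
        stop("no complete pairs in the exposure or the control group")
    list(x = x, y = y)
}

#' Pre/post fasting pairs for an mbMCW test
#'
#' Builds matched (post, pre) body-weight pairs per mouse, exposure group
#' as set x and control as set y, ready for [mbmcwTest()]. Differences are
#' taken as later minus earlier (post - pre), so a negative bias index
#' means the exposure group loses more weight over the fast.
#'
#' @param mouseId,group,pre,post parallel vectors, one entry per mouse
#' @param exposure,control group labels
#' @return list(x, y) of two-column matrices
#' @export
fastingPairs <- function(mouseId, group, pre, post, exposure,
                         control = "DMSO") {
    stopifnot(!anyDuplicated(mouseId[group %in% c(exposure, control)]))
    .buildPairs(mouseId, group, earlier = pre, later = post,
                exposure, control, "mouse")
}

#' Cage entry/exit consumption pairs for an mbMCW test
#'
#' Water or food amounts at cage entry and exit, paired per cage as
#' (exit, entry) — later minus earlier — exposure cages as set x. An exit
#' amount above the entry amount (a refill anomaly) is flagged with a
#' warning but kept.
#'
#' @param cageId,group,entry,exit parallel vectors, one entry per cage
#' @param exposure,control group labels
#' @return list(x, y) of two-column matrices
#' @export
consumptionPairs <- function(cageId, group, entry, exit, exposure,
                             control = "DMSO") {
    anomaly <- is.finite(entry) & is.finite(exit) & exit > entry
    if (any(anomaly))
        warning(sprintf("%d cage(s) with exit > entry (refill anomaly)",
                        sum(anomaly)))
    .buildPairs(cageId, group, earlier = entry, later = exit,
                exposure, control, "cage")
}

#' Zero out-of-range plasma measurements
#'
#' Values outside the assay's standard curve range, or that could not be
#' extrapolated (NA), are set to zero; in-range values pass through.
#'
#' @param panel data.frame with at least columns \code{value} and
#'   \code{in_range} (logical)
#' @return the panel with cleaned \code{value}
#' @export
cleanPlasma <- function(panel) {
    stopifnot(all(c("value", "in_range") %in% colnames(panel)))
    bad <- !panel$in_range | !is.finite(panel$value)
    panel$value[bad] <- 0
    panel
}

#' PCA on complete-case plasma metabolites
#'
#' Restricts to metabolites with valid (nonzero, finite) data for every
#' mouse of the requested sex, then runs a centered PCA via singular value
#' decomposition, by default with unit-variance scaling (metabolite
#' concentrations span orders of magnitude). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param panel data.frame with columns mouse_id, sex, metabolite, value
#'   (cleaned, see [cleanPlasma()])
#' @param sex which sex to analyze
#' @param scale logical, unit-variance scaling (default TRUE)
#' @return list(scores, loadings, varianceExplained, metabolites)
#' @export
metabolitePca <- function(panel, sex, scale = TRUE) {
    p <- panel[panel$sex == sex, , drop = FALSE]
    wide <- tapply(p$value, list(p$mouse_id, p$metabolite), mean)
    complete <- apply(wide, 2L, function(v) all(is.finite(v) & v > 0))
    wide <- wide[, complete, drop = FALSE]
    if (ncol(wide) < 2L)
        stop("need at least 2 complete-case metabolites")
    pc <- prcomp(wide, center = TRUE, scale. = scale)
    for (j in seq_len(ncol(pc$rotation))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    list(scores = pc$x,
         loadings = pc$rotation,
         varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
         metabolites = colnames(wide))
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y paired finite numeric vectors, n >= 3
#' @return list(r, p, n)
#' @export
pearsonR <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L,
              all(is.finite(x)), all(is.finite(y)))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Drinking-water dose in mg/kg/day and NOAEL ratio
#'
#' Converts a drinking-water concentration to a daily dose:
#' dose = concentration (mol/L) x molecular weight (g/mol) x water intake
#' (L/day) / body weight (kg), in mg/kg/day. The default molecular weight
#' is the tributyltin cation (290.06 g/mol; the chloride salt, 325.5,
#' gives the same one-significant-figure dose). The reference NOAEL
#' (no-observed-adverse-effect level) for tributyltin is 0.025 mg/kg/day.
#'
#' @param concentration_nM concentration in nmol/L
#' @param molecularWeight g/mol (default 290.06, tributyltin cation)
#' @param waterIntake_L daily water intake in L (default 0.010)
#' @param bodyWeight_kg body weight in kg (default 0.030)
#' @param noael reference NOAEL in mg/kg/day (default 0.025)
#' @return list(dose, noaelRatio); a 50 nM solution gives 0.005 mg/kg/day
#'   at one significant figure and a NOAEL ratio of 5
#' @export
doseEquivalent <- function(concentration_nM, molecularWeight = 290.06,
                           waterIntake_L = 0.010, bodyWeight_kg = 0.030,
                           noael = 0.025) {
    stopifnot(concentration_nM >= 0, molecularWeight > 0,
              waterIntake_L > 0, bodyWeight_kg > 0, noael > 0)
    doseMg <- concentration_nM * 1e-9 * molecularWeight * waterIntake_L * 1e3
    dose <- doseMg / bodyWeight_kg
    list(dose = dose,
         noaelRatio = if (dose > 0) noael / dose else Inf)
}

#' uMCW tests on litter size and sex ratio
#'
#' @param litterSize numeric vector, litter sizes
#' @param femaleFraction numeric vector, female fraction per litter
#' @param group group label per litter
#' @param exposure,control group labels to compare
#' @param config an [mcwConfig()]
#' @return list(size, sexRatio) of [MCWResult-class] objects
#' @export
litterStats <- function(litterSize, femaleFraction, group, exposure,
                        control = "DMSO", config = mcwConfig()) {
    e <- group == exposure
    c0 <- group == control
    if (!any(e) || !any(c0))
        stop("exposure or control group absent")
    list(size = umcwTest(litterSize[e], litterSize[c0], config),
         sexRatio = umcwTest(femaleFraction[e], femaleFraction[c0], config))
}
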