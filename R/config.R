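#' Simulation configuration
#'
#' `OrSimConfig` bundles every parameter of the synthetic olfactory-epithelium
#' generator. The defaults encode the study conditions the package is designed
#' around: receptor levels with median TPM 9.15e3 spanning 42.1 to 1.46e5,
#' multi-receptor cells carrying 2 to 9 receptors with mean ~2.9 (median 2),
#' total receptor output with median TPM 1.18e4 in multi- versus 1.75e4 in
#' single-receptor cells, a per-OR "set point" with less than 3-fold spread
#' between cells choosing the same OR, detection that is reliable above TPM
#' 1e3 but dropout-dominated below 1e2, and stage mixes that give an
#' immature:mature ratio of 1.45:1 in newborns and 0.13:1 in adults.
#'
#' @slot seed integer master seed; all generator randomness derives from it.
#' @slot nCells number of cells in the cohort.
#' @slot ageMix fraction of cells from newborn animals (the rest are adult).
#' @slot stageProps 2x3 matrix of stage probabilities (rows `adult`,
#'   `newborn`; columns `other`, `immature`, `mature`), each row summing to 1.
#' @slot nOrGenes,nVrGenes,nTaarGenes,nMarkerGenes,nHousekeeping,nSmallRna
#'   gene-family sizes. Receptor biotypes (OR/VR/TAAR) are treated alike by
#'   the caller; at least 3 small-RNA genes are kept so the TPM-exclusion
#'   step is exercised.
#' @slot orLevelMedian median receptor TPM for mature single-receptor cells.
#' @slot orLevelLogSd lognormal sd (log scale) of per-OR set points.
#' @slot orLevelRange numeric(2), truncation range of receptor TPM.
#' @slot multiK probability vector over k = 2..9 receptors per multi cell.
#' @slot multiTotalMedian,singleTotalMedian median total receptor TPM in
#'   multi- and (immature) single-receptor cells.
#' @slot totalLogSd lognormal sd of cell total receptor TPM.
#' @slot setpointMaxFold maximum fold difference between two cells choosing
#'   the same OR (strict).
#' @slot receptorPosProb named numeric, probability that a cell of each stage
#'   expresses at least one receptor.
#' @slot multiProb named numeric, probability that a receptor-positive cell of
#'   each stage expresses more than one receptor.
#' @slot dominanceAlpha Dirichlet concentration for splitting a multi cell's
#'   total across its receptors (small values give one dominant OR).
#' @slot markerClassCounts named integer, markers per expression-pattern class
#'   (`immature_only`, `both`, `mature_only`, `precursor_only`); must sum to
#'   `nMarkerGenes`.
#' @slot markerHighTpm,markerLowTpm,markerLevelLogSd marker mean TPM when the
#'   marker's class is "on"/"off" for a stage, and per-gene lognormal spread
#'   of the "on" level.
#' @slot hkMedianTpm,hkLevelLogSd lognormal median and sd (log scale) of
#'   housekeeping-gene relative abundances, on a nominal TPM scale before the
#'   per-cell budget rescaling (calibrated so a default cell detects ~2.8e3
#'   genes above 1 TPM).
#' @slot smallRnaWeight fraction of each cell's non-receptor budget assigned
#'   to small-RNA genes (these are excluded again during quantification).
#' @slot noiseSd lognormal measurement-noise sd (log scale); 0 disables noise.
#' @slot dropout logical, whether expression dropout is applied.
#' @slot dropoutTpmHi,dropoutTpmLo TPM anchors of the dropout curve.
#' @slot dropoutPHi,dropoutPLo dropout probability at/above `dropoutTpmHi`
#'   and at `dropoutTpmLo`; log-linear in between, extrapolated and clamped
#'   to `[dropoutPHi, 0.98]` below.
#' @slot readsPerCell read budget scaling per-receptor read depth; 0 disables
#'   read simulation entirely.
#' @slot readLength single-end read length in nt.
#' @slot mapqHigh,mapqLow the two MAPQ values emitted by the simulator.
#' @slot highMapqFraction fraction of a truly expressed receptor's reads that
#'   carry high MAPQ (assigned deterministically per read set).
#' @slot homologDecoyRate probability that a non-expressed homolog of an
#'   expressed receptor receives a mismapping decoy read pile.
#' @slot contaminationRate probability per cell of an unspliced genomic-DNA
#'   read scatter over a random non-expressed receptor.
#' @slot decoyReads,contaminationReads read counts for the two artifact modes.
#'
#' @seealso [orSimConfig()] for the user constructor.
#' @export
setClass("OrSimConfig", representation(
    seed = "integer",
    nCells = "integer",
    ageMix = "numeric",
    stageProps = "matrix",
    nOrGenes = "integer",
    nVrGenes = "integer",
    nTaarGenes = "integer",
    nMarkerGenes = "integer",
    nHousekeeping = "integer",
    nSmallRna = "integer",
    orLevelMedian = "numeric",
    orLevelLogSd = "numeric",
    orLevelRange = "numeric",
    multiK = "numeric",
    multiTotalMedian = "numeric",
    singleTotalMedian = "numeric",
    totalLogSd = "numeric",
    setpointMaxFold = "numeric",
    receptorPosProb = "numeric",
    multiProb = "numeric",
    dominanceAlpha = "numeric",
    markerClassCounts = "integer",
    markerHighTpm = "numeric",
    markerLowTpm = "numeric",
    markerLevelLogSd = "numeric",
    hkMedianTpm = "numeric",
    hkLevelLogSd = "numeric",
    smallRnaWeight = "numeric",
    noiseSd = "numeric",
    dropout = "logical",
    dropoutTpmHi = "numeric",
    dropoutTpmLo = "numeric",
    dropoutPHi = "numeric",
    dropoutPLo = "numeric",
    readsPerCell = "integer",
    readLength = "integer",
    mapqHigh = "integer",
    mapqLow = "integer",
    highMapqFraction = "numeric",
    homologDecoyRate = "numeric",
    contaminationRate = "numeric",
    decoyReads = "integer",
    contaminationReads = "integer"
))

.STAGES <- c("other", "immature", "mature")
.AGES <- c("adult", "newborn")
.MARKER_CLASSES <- c("immature_only", "both", "mature_only", "precursor_only")
.RECEPTOR_BIOTYPES <- c("OR", "VR", "TAAR")

setValidity("OrSimConfig", function(object) {
    msg <- character()
    chkProb <- function(p, what) {
        if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
            msg <<- c(msg, sprintf("%s must be non-negative and sum to 1 (within 1e-9)", what))
    }
    if (object@seed < 0L || object@seed > 2147483139L)
        msg <- c(msg, "seed must be in [0, 2^31 - 509]")
    if (object@ageMix < 0 || object@ageMix > 1)
        msg <- c(msg, "ageMix must be in [0, 1]")
    sp <- object@stageProps
    if (!identical(rownames(sp), .AGES) || !identical(colnames(sp), .STAGES))
        msg <- c(msg, "stageProps must have rows adult/newborn and columns other/immature/mature")
    else for (a in .AGES) chkProb(sp[a, ], sprintf("stageProps['%s', ]", a))
    if (length(object@multiK) != 8L || !identical(names(object@multiK), as.character(2:9)))
        msg <- c(msg, "multiK must be a probability vector named '2'..'9' (support only on 2..9)")
    else chkProb(object@multiK, "multiK")
    if (length(object@orLevelRange) != 2L ||
        !(object@orLevelRange[1] < object@orLevelMedian &&
          object@orLevelMedian < object@orLevelRange[2]))
        msg <- c(msg, "orLevelRange[1] < orLevelMedian < orLevelRange[2] required")
    if (!(object@dropoutTpmLo < object@dropoutTpmHi))
        msg <- c(msg, "dropoutTpmLo < dropoutTpmHi required")
    if (!identical(names(object@receptorPosProb), .STAGES) ||
        any(object@receptorPosProb < 0 | object@receptorPosProb > 1))
        msg <- c(msg, "receptorPosProb must be probabilities named other/immature/mature")
    if (!identical(names(object@multiProb), .STAGES) ||
        any(object@multiProb < 0 | object@multiProb > 1))
        msg <- c(msg, "multiProb must be probabilities named other/immature/mature")
    if (!identical(names(object@markerClassCounts), .MARKER_CLASSES))
        msg <- c(msg, "markerClassCounts must be named immature_only/both/mature_only/precursor_only")
    else if (sum(object@markerClassCounts) != object@nMarkerGenes)
        msg <- c(msg, "markerClassCounts must sum to nMarkerGenes")
    if (any(object@markerClassCounts < 1L))
        msg <- c(msg, "each marker class needs at least one gene")
    if (object@nSmallRna < 3L)
        msg <- c(msg, "nSmallRna must be >= 3")
    if (object@setpointMaxFold <= 1)
        msg <- c(msg, "setpointMaxFold must exceed 1")
    if (object@smallRnaWeight < 0 || object@smallRnaWeight >= 1)
        msg <- c(msg, "smallRnaWeight must be in [0, 1)")
    if (object@highMapqFraction < 0 || object@highMapqFraction > 1)
        msg <- c(msg, "highMapqFraction must be in [0, 1]")
    for (s in c("homologDecoyRate", "contaminationRate", "dropoutPHi", "dropoutPLo")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", s))
    }
    if (object@readLength < 20L)
        msg <- c(msg, "readLength must be >= 20")
    if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Constructor for [OrSimConfig-class] with defaults set to the study
#' conditions described there. The default stage-probability matrix is
#' back-solved from the observed cohort composition (adults: 4/6/46 of 56
#' cells other/immature/mature; newborns: 41/48/33 of 122), which yields the
#' anchor immature:mature ratios 0.13:1 (adult) and 1.45:1 (newborn).
#'
#' @param seed integer master seed.
#' @param nCells number of cells.
#' @param ageMix fraction of newborn cells (default 122/178).
#' @param stageProps 2x3 stage-probability matrix (see Details).
#' @param nOrGenes,nVrGenes,nTaarGenes,nMarkerGenes,nHousekeeping,nSmallRna
#'   gene-family sizes.
#' @param orLevelMedian,orLevelLogSd,orLevelRange receptor set-point
#'   distribution (median TPM 9.15e3, range 42.1 to 1.46e5).
#' @param multiK probability vector over 2..9 receptors per multi cell
#'   (default mean 2.89, median 2).
#' @param multiTotalMedian,singleTotalMedian,totalLogSd total receptor TPM
#'   distributions (medians 1.18e4 and 1.75e4).
#' @param setpointMaxFold strict bound on same-OR fold spread (default 3).
#' @param receptorPosProb,multiProb per-stage receptor-positive and
#'   multi-receptor probabilities.
#' @param dominanceAlpha Dirichlet concentration for multi-cell level splits.
#' @param markerClassCounts markers per class (default 13/8/16/7, summing to
#'   `nMarkerGenes` = 44).
#' @param markerHighTpm,markerLowTpm,markerLevelLogSd marker mean levels.
#' @param hkMedianTpm,hkLevelLogSd,smallRnaWeight background transcriptome shape.
#' @param noiseSd lognormal measurement noise sd (log scale).
#' @param dropout,dropoutTpmHi,dropoutTpmLo,dropoutPHi,dropoutPLo dropout
#'   model (reliable above TPM 1e3, dropout-dominated below 1e2).
#' @param readsPerCell,readLength read simulation budget and length (100 nt
#'   single-end).
#' @param mapqHigh,mapqLow,highMapqFraction simulated MAPQ dichotomy.
#' @param homologDecoyRate,contaminationRate,decoyReads,contaminationReads
#'   artifact-read modes (homolog mismapping piles, genomic-DNA scatter).
#' @return a validated [OrSimConfig-class] object.
#' @examples
#' cfg <- orSimConfig(seed = 1, nCells = 50)
#' cfg
#' @export
orSimConfig <- function(seed = 1L,
                        nCells = 300L,
                        ageMix = 122 / 178,
                        stageProps = rbind(
                            adult = c(4, 6, 46) / 56,
                            newborn = c(41, 48, 33) / 122
                        ),
                        nOrGenes = 200L,
                        nVrGenes = 2L,
                        nTaarGenes = 2L,
                        nMarkerGenes = 44L,
                        nHousekeeping = 10000L,
                        nSmallRna = 5L,
                        orLevelMedian = 9.15e3,
                        orLevelLogSd = 1.2,
                        orLevelRange = c(42.1, 1.46e5),
                        multiK = c(`2` = 0.65, `3` = 0.13, `4` = 0.08, `5` = 0.05,
                                   `6` = 0.04, `7` = 0.02, `8` = 0.02, `9` = 0.01),
                        multiTotalMedian = 1.18e4,
                        singleTotalMedian = 1.75e4,
                        totalLogSd = 0.35,
                        setpointMaxFold = 3,
                        receptorPosProb = c(other = 0, immature = 0.65, mature = 0.9),
                        multiProb = c(other = 0, immature = 0.57, mature = 0.04),
                        dominanceAlpha = 5,
                        markerClassCounts = c(immature_only = 13L, both = 8L,
                                              mature_only = 16L, precursor_only = 7L),
                        markerHighTpm = 600,
                        markerLowTpm = 2,
                        markerLevelLogSd = 0.5,
                        hkMedianTpm = 150,
                        hkLevelLogSd = 1.0,
                        smallRnaWeight = 0.05,
                        noiseSd = 0.4,
                        dropout = TRUE,
                        dropoutTpmHi = 1e3,
                        dropoutTpmLo = 1e2,
                        dropoutPHi = 0.02,
                        dropoutPLo = 0.6,
                        readsPerCell = 2000L,
                        readLength = 100L,
                        mapqHigh = 50L,
                        mapqLow = 0L,
                        highMapqFraction = 0.95,
                        homologDecoyRate = 0.3,
                        contaminationRate = 0.1,
                        decoyReads = 25L,
                        contaminationReads = 20L) {
    sp <- as.matrix(stageProps)
    if (is.null(colnames(sp))) colnames(sp) <- .STAGES
    if (is.null(rownames(sp))) rownames(sp) <- .AGES
    new("OrSimConfig",
        seed = as.integer(seed), nCells = as.integer(nCells), ageMix = ageMix,
        stageProps = sp,
        nOrGenes = as.integer(nOrGenes), nVrGenes = as.integer(nVrGenes),
        nTaarGenes = as.integer(nTaarGenes), nMarkerGenes = as.integer(nMarkerGenes),
        nHousekeeping = as.integer(nHousekeeping), nSmallRna = as.integer(nSmallRna),
        orLevelMedian = orLevelMedian, orLevelLogSd = orLevelLogSd,
        orLevelRange = orLevelRange,
        multiK = multiK, multiTotalMedian = multiTotalMedian,
        singleTotalMedian = singleTotalMedian, totalLogSd = totalLogSd,
        setpointMaxFold = setpointMaxFold,
        receptorPosProb = receptorPosProb[.STAGES], multiProb = multiProb[.STAGES],
        dominanceAlpha = dominanceAlpha,
        markerClassCounts = setNames(as.integer(markerClassCounts[.MARKER_CLASSES]),
                                     .MARKER_CLASSES),
        markerHighTpm = markerHighTpm, markerLowTpm = markerLowTpm,
        markerLevelLogSd = markerLevelLogSd,
        hkMedianTpm = hkMedianTpm, hkLevelLogSd = hkLevelLogSd,
        smallRnaWeight = smallRnaWeight,
        noiseSd = noiseSd, dropout = dropout,
        dropoutTpmHi = dropoutTpmHi, dropoutTpmLo = dropoutTpmLo,
        dropoutPHi = dropoutPHi, dropoutPLo = dropoutPLo,
        readsPerCell = as.integer(readsPerCell), readLength = as.integer(readLength),
        mapqHigh = as.integer(mapqHigh), mapqLow = as.integer(mapqLow),
        highMapqFraction = highMapqFraction,
        homologDecoyRate = homologDecoyRate, contaminationRate = contaminationRate,
        decoyReads = as.integer(decoyReads),
        contaminationReads = as.integer(contaminationReads))
}

#' @describeIn OrSimConfig-class compact display.
#' @param object an `OrSimConfig`.
#' @export
setMethod("show", "OrSimConfig", function(object) {
    kMean <- sum(as.numeric(names(object@multiK)) * object@multiK)
    cat("OrSimConfig\n",
        sprintf("  seed %d | %d cells (%.0f%% newborn)\n",
                object@seed, object@nCells, 100 * object@ageMix),
        sprintf("  genes: %d OR + %d VR + %d TAAR, %d markers, %d housekeeping, %d smallRNA\n",
                object@nOrGenes, object@nVrGenes, object@nTaarGenes,
                object@nMarkerGenes, object@nHousekeeping, object@nSmallRna),
        sprintf("  OR set point: median %.3g TPM in [%.3g, %.3g]; multi-k mean %.2f\n",
                object@orLevelMedian, object@orLevelRange[1], object@orLevelRange[2], kMean),
        sprintf("  dropout: %s (p %.2f at %.3g TPM -> %.2f at %.3g TPM); noise sdlog %.2f\n",
                if (object@dropout) "on" else "off", object@dropoutPLo,
                object@dropoutTpmLo, object@dropoutPHi, object@dropoutTpmHi,
                object@noiseSd),
        sep = "")
    invisible(object)
})

# Dropout probability as a function of true TPM: log-linear between the two
# anchors, flat above the high anchor, extrapolated and clamped below.
.dropoutProb <- function(tpm, config) {
    if (!config@dropout) return(rep(0, length(tpm)))
    lhi <- log10(config@dropoutTpmHi)
    llo <- log10(config@dropoutTpmLo)
    slope <- (config@dropoutPLo - config@dropoutPHi) / (llo - lhi)
    p <- config@dropoutPHi + slope * (log10(pmax(tpm, 1e-12)) - lhi)
    pmin(pmax(p, config@dropoutPHi), 0.98)
}
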