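#' @import methods
#' @importFrom stats dnorm median rlnorm rnorm runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData "rowData<-" "assay<-"
#' @importFrom S4Vectors DataFrame
NULL

#' Analysis configuration
#'
#' Holds every tunable threshold of the SIP inference chain: the
#' light/heavy/ultra-heavy (L/H/UH) buoyant-density windows, the
#' heavy-to-light ratio thresholds behind the per-taxon labeling call, the
#' twofold constant of the core/enriched/diluted KO classifier, and the
#' delta13C analytical precision that defines the assimilation-rate detection
#' limit.
#'
#' @slot densityWindows numeric 3x2 matrix (rows `L`, `H`, `UH`; columns
#'   `lower`, `upper`) of half-open density intervals in g/mL. The upper
#'   bound of the last (heaviest) window is inclusive.
#' @slot thetaUnlabeled numeric; H/L relative-abundance ratio at or below
#'   which a taxon is called unlabeled (default 0.5, a twofold decline).
#' @slot thetaLabeled numeric; H/L ratio at or above which a taxon is called
#'   labeled (default 0.8).
#' @slot foldThreshold numeric > 1; the fold constant of the KO classifier
#'   (default 2).
#' @slot deltaPrecision numeric; analytical precision of delta13C in per mil
#'   (default 0.1).
#' @slot abundanceFloor numeric; relative abundance below which L and H
#'   evidence is considered insufficient for a labeling call (default 0.001).
#' @slot minAbundance numeric; table-level inclusion filter for labeling
#'   calls (default 0.005, i.e. 0.5 %).
#' @slot seed integer; seed recorded in provenance output.
#' @slot outputPrecision integer; decimal places used by report formatters.
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig", representation(
  densityWindows  = "matrix",
  thetaUnlabeled  = "numeric",
  thetaLabeled    = "numeric",
  foldThreshold   = "numeric",
  deltaPrecision  = "numeric",
  abundanceFloor  = "numeric",
  minAbundance    = "numeric",
  seed            = "integer",
  outputPrecision = "integer"
))

setValidity("RunConfig", function(object) {
  w <- object@densityWindows
  msgs <- character()
  if (!is.numeric(w) || !identical(dim(w), c(3L, 2L)))
    msgs <- c(msgs, "densityWindows must be a numeric 3x2 matrix (L/H/UH x lower/upper)")
  else {
    if (any(w[, 2] <= w[, 1]))
      msgs <- c(msgs, "densityWindows: each upper bound must exceed its lower bound")
    if (is.unsorted(w[, 1], strictly = TRUE))
      msgs <- c(msgs, "densityWindows: windows must be ordered L < H < UH by lower bound")
    if (any(w[-3, 2] > w[-1, 1]))
      msgs <- c(msgs, "densityWindows: windows must be disjoint")
  }
  if (object@thetaUnlabeled <= 0)
    msgs <- c(msgs, "thetaUnlabeled must be positive")
  if (object@thetaUnlabeled > object@thetaLabeled)
    msgs <- c(msgs, "thetaUnlabeled must not exceed thetaLabeled")
  if (object@foldThreshold <= 1)
    msgs <- c(msgs, "foldThreshold must exceed 1")
  if (object@deltaPrecision <= 0)
    msgs <- c(msgs, "deltaPrecision must be positive")
  if (object@abundanceFloor < 0)
    msgs <- c(msgs, "abundanceFloor must be non-negative")
  if (object@minAbundance < 0)
    msgs <- c(msgs, "minAbundance must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Buoyant-density gradient profile
#'
#' One CsCl density-gradient fractionation curve: per-fraction buoyant density
#' (g/mL, strictly increasing) and 16S rRNA gene copies per mL for a single
#' sample/treatment. Treatments follow the dual-labeling incubation design
#' (`"13C+15N"`, `"13C+14N"`, `"12C+14N"`, `"13C"`).
#'
#' @slot sampleId character sample label.
#' @slot treatment character treatment label.
#' @slot fractionId character fraction identifiers, in density order.
#' @slot density numeric buoyant densities (g/mL), strictly increasing.
#' @slot copies numeric 16S rRNA gene copies per mL, non-negative.
#' @seealso [gradientProfile()], [simulateGradient()]
#' @export
setClass("GradientProfile", representation(
  sampleId   = "character",
  treatment  = "character",
  fractionId = "character",
  density    = "numeric",
  copies     = "numeric"
))

setValidity("GradientProfile", function(object) {
  msgs <- character()
  n <- length(object@density)
  if (n < 3)
    msgs <- c(msgs, "a gradient profile needs at least 3 fractions")
  if (length(object@copies) != n || length(object@fractionId) != n)
    msgs <- c(msgs, "fractionId, density and copies must have equal length")
  if (n > 1 && is.unsorted(object@density, strictly = TRUE))
    msgs <- c(msgs, "densities must be strictly increasing")
  if (any(object@copies < 0, na.rm = TRUE))
    msgs <- c(msgs, "copies must be non-negative")
  if (anyDuplicated(object@fractionId))
    msgs <- c(msgs, "fraction ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' One tracer incubation bottle
#'
#' The record needed to compute a dissolved-inorganic-carbon (DIC)
#' assimilation rate from a 13C-bicarbonate tracer incubation: particulate
#' organic carbon (POC) concentration and its delta13C at the start and end
#' of incubation, the incubation time, and the ambient and added DIC pools.
#'
#' @slot delta0,deltaT delta13C of POC at t = 0 and t (per mil vs VPDB).
#' @slot poc0,pocT POC concentration at t = 0 and t (umol C/L), positive.
#' @slot t incubation time (days), positive.
#' @slot caDic ambient DIC (umol/L), non-negative.
#' @slot csDic added (substrate) DIC (umol/L), positive.
#' @slot trueRate numeric; hidden true assimilation rate when the record was
#'   simulated (NA for measured data). Used only by recovery tests.
#' @seealso [tracerIncubation()], [simulateTracer()], [dicAssimilationRate()]
#' @export
setClass("TracerIncubation", representation(
  delta0   = "numeric",
  deltaT   = "numeric",
  poc0     = "numeric",
  pocT     = "numeric",
  t        = "numeric",
  caDic    = "numeric",
  csDic    = "numeric",
  trueRate = "numeric"
))

setValidity("TracerIncubation", function(object) {
  msgs <- character()
  if (object@poc0 <= 0 || object@pocT <= 0)
    msgs <- c(msgs, "poc0 and pocT must be positive")
  if (object@t <= 0)
    msgs <- c(msgs, "incubation time t must be positive")
  if (object@csDic <= 0)
    msgs <- c(msgs, "added DIC csDic must be positive")
  if (object@caDic < 0)
    msgs <- c(msgs, "ambient DIC caDic must be non-negative")
  if (object@delta0 <= -1000 || object@deltaT <= -1000)
    msgs <- c(msgs, "delta13C values must exceed -1000 per mil")
  if (length(msgs)) msgs else TRUE
})

#' KO abundance matrix across metagenomic libraries
#'
#' A `SummarizedExperiment` holding one assay `"abundance"`: KEGG orthologs
#' (rows) by exactly three metagenomic libraries (columns), relative
#' abundance on a per-million scale. Classification results
#' ([classifyKO()]) and planted truth from [simulateKOTable()] live in
#' `rowData`.
#'
#' @seealso [koAbundanceSet()], [classifyKO()], [summarizeCategories()]
#' @export
setClass("KOAbundanceSet", contains = "SummarizedExperiment")

setValidity("KOAbundanceSet", function(object) {
  msgs <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (ncol(a) != 3)
      msgs <- c(msgs, "exactly three libraries (columns) are required")
    if (any(a < 0, na.rm = TRUE))
      msgs <- c(msgs, "abundances must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})
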