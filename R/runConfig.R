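.defaultWindows <- function() {
  matrix(c(1.690, 1.712,
           1.715, 1.735,
           1.735, 1.760),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("L", "H", "UH"), c("lower", "upper")))
}

#' Construct an analysis configuration
#'
#' All thresholds default to the values used throughout the package: a
#' twofold fold threshold for the KO classifier, labeling-call ratio
#' thresholds (0.5, 0.8), delta13C precision 0.1 per mil, a 0.5 % taxon
#' inclusion filter, and L/H/UH density windows L = \[1.690, 1.712),
#' H = \[1.715, 1.735), UH = \[1.735, 1.760\] g/mL.
#'
#' @param densityWindows numeric 3x2 matrix (rows L/H/UH, columns
#'   lower/upper) of density intervals in g/mL; half-open except the last
#'   upper bound.
#' @param thetaUnlabeled,thetaLabeled H/L ratio thresholds for the
#'   unlabeled/labeled verdicts.
#' @param foldThreshold fold constant (> 1) of the core/enriched/diluted
#'   classifier.
#' @param deltaPrecision delta13C analytical precision (per mil); defines the
#'   rate detection limit.
#' @param abundanceFloor per-taxon evidence floor for labeling calls.
#' @param minAbundance table-level relative-abundance inclusion filter.
#' @param seed integer recorded in provenance output.
#' @param outputPrecision decimal places for formatted reports.
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- runConfig()
#' densityWindows(cfg)
#' @export
runConfig <- function(densityWindows = .defaultWindows(),
                      thetaUnlabeled = 0.5,
                      thetaLabeled = 0.8,
                      foldThreshold = 2,
                      deltaPrecision = 0.1,
                      abundanceFloor = 0.001,
                      minAbundance = 0.005,
                      seed = 1L,
                      outputPrecision = 3L) {
  if (is.null(dimnames(densityWindows)))
    dimnames(densityWindows) <- list(c("L", "H", "UH"), c("lower", "upper"))
  new("RunConfig",
      densityWindows  = densityWindows,
      thetaUnlabeled  = as.numeric(thetaUnlabeled),
      thetaLabeled    = as.numeric(thetaLabeled),
      foldThreshold   = as.numeric(foldThreshold),
      deltaPrecision  = as.numeric(deltaPrecision),
      abundanceFloor  = as.numeric(abundanceFloor),
      minAbundance    = as.numeric(minAbundance),
      seed            = as.integer(seed),
      outputPrecision = as.integer(outputPrecision))
}

#' Load a configuration file
#'
#' Reads a flat key/value YAML or JSON document; absent keys fall back to the
#' documented defaults of [runConfig()]. `density_windows` may be given as a
#' list of three `[lower, upper]` pairs named `L`, `H`, `UH`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  args <- list()
  if (!is.null(raw$density_windows)) {
    dw <- raw$density_windows
    if (is.list(dw)) dw <- do.call(rbind, dw[c("L", "H", "UH")])
    args$densityWindows <- matrix(as.numeric(dw), nrow = 3,
                                  dimnames = list(c("L", "H", "UH"),
                                                  c("lower", "upper")))
  }
  map <- c(theta_unlabeled = "thetaUnlabeled", theta_labeled = "thetaLabeled",
           fold_threshold = "foldThreshold", delta_precision = "deltaPrecision",
           abundance_floor = "abundanceFloor", min_abundance = "minAbundance",
           seed = "seed", output_precision = "outputPrecision")
  for (key in names(map))
    if (!is.null(raw[[key]])) args[[map[[key]]]] <- raw[[key]]

  unknown <- setdiff(names(raw), c("density_windows", names(map)))
  if (length(unknown))
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "))
  do.call(runConfig, args)
}

#' @describeIn runConfig Accessor for the L/H/UH density windows.
#' @param x,object a `RunConfig`.
#' @export
densityWindows <- function(x) x@densityWindows

#' @describeIn runConfig Accessor for the fold threshold.
#' @export
foldThreshold <- function(x) x@foldThreshold

#' @describeIn runConfig Accessor for the delta13C precision (per mil).
#' @export
deltaPrecision <- function(x) x@deltaPrecision

#' @rdname runConfig
#' @export
setMethod("show", "RunConfig", function(object) {
  w <- object@densityWindows
  cat("RunConfig\n")
  cat(sprintf("  windows (g/mL): L=[%.3f,%.3f) H=[%.3f,%.3f) UH=[%.3f,%.3f]\n",
              w[1, 1], w[1, 2], w[2, 1], w[2, 2], w[3, 1], w[3, 2]))
  cat(sprintf("  labeling thresholds: unlabeled <= %.2f, labeled >= %.2f\n",
              object@thetaUnlabeled, object@thetaLabeled))
  cat(sprintf("  fold threshold: %.2f   delta precision: %.2f permil\n",
              object@foldThreshold, object@deltaPrecision))
  cat(sprintf("  abundance floor: %g   min abundance: %g   seed: %d\n",
              object@abundanceFloor, object@minAbundance, object@seed))
  invisible(object)
})

# serializable flat representation, used for provenance hashing and sidecars
.configAsList <- function(config) {
  w <- config@densityWindows
  list(density_windows = list(L = as.numeric(w[1, ]), H = as.numeric(w[2, ]),
                              UH = as.numeric(w[3, ])),
       theta_unlabeled = config@thetaUnlabeled,
       theta_labeled = config@thetaLabeled,
       fold_threshold = config@foldThreshold,
       delta_precision = config@deltaPrecision,
       abundance_floor = config@abundanceFloor,
       min_abundance = config@minAbundance,
       seed = config@seed,
       output_precision = config@outputPrecision)
}
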