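#' Construct a gradient profile
#'
#' @param sampleId,treatment sample and treatment labels (treatments of the
#'   dual-labeling design: `"13C+15N"`, `"13C+14N"`, `"12C+14N"`, `"13C"`).
#' @param fractionId fraction identifiers; defaults to `F1..Fn` in density
#'   order.
#' @param density buoyant densities (g/mL), strictly increasing.
#' @param copies 16S rRNA gene copies per mL.
#' @return A validated [GradientProfile-class].
#' @examples
#' gp <- gradientProfile("WV65", "13C+15N",
#'                       density = c(1.70, 1.72, 1.74),
#'                       copies = c(100, 500, 300))
#' peakDensity(gp)
#' @export
gradientProfile <- function(sampleId, treatment = "13C+15N",
                            fractionId = NULL, density, copies) {
  if (is.null(fractionId)) fractionId <- paste0("F", seq_along(density))
  new("GradientProfile", sampleId = as.character(sampleId),
      treatment = as.character(treatment),
      fractionId = as.character(fractionId),
      density = as.numeric(density), copies = as.numeric(copies))
}

#' @describeIn gradientProfile Fraction table accessor: a `data.frame` with
#'   columns `fraction_id`, `density`, `copies`.
#' @param x a `GradientProfile`.
#' @export
fractions <- function(x) {
  stopifnot(is(x, "GradientProfile"))
  data.frame(fraction_id = x@fractionId, density = x@density,
             copies = x@copies, stringsAsFactors = FALSE)
}

#' @rdname gradientProfile
#' @param object a `GradientProfile`.
#' @export
setMethod("show", "GradientProfile", function(object) {
  cat(sprintf("GradientProfile '%s' (%s): %d fractions, density %.4f-%.4f g/mL\n",
              object@sampleId, object@treatment, length(object@density),
              min(object@density), max(object@density)))
  cat(sprintf("  peak at %.4f g/mL (%.3g copies/mL)\n",
              peakDensity(object), max(object@copies)))
  invisible(object)
})

#' Min-max normalize a gradient profile
#'
#' Rescales the copies curve affinely so the minimum maps to 0 and the
#' maximum to 1 along the gradient; densities are unchanged. Idempotent and
#' order-preserving.
#'
#' @param profile a [GradientProfile-class] with at least two distinct copy
#'   values.
#' @return The profile with `copies` in \[0, 1\].
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  rng <- range(profile@copies)
  if (diff(rng) == 0)
    stop("degenerate profile: all copy values equal, cannot min-max scale")
  initialize(profile, copies = (profile@copies - rng[1]) / diff(rng))
}

#' Density of the profile peak
#'
#' Returns the buoyant density of the maximum-copies fraction; ties are
#' broken toward the heavier density.
#'
#' @param profile a [GradientProfile-class].
#' @return Density in g/mL.
#' @export
peakDensity <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  best <- which(profile@copies == max(profile@copies))
  profile@density[max(best)]
}

# 3-point running median smoothing with endpoint passthrough
.median3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  mid <- vapply(2:(n - 1), function(i) median(x[(i - 1):(i + 1)]), numeric(1))
  c(x[1], mid, x[n])
}

#' Is a profile single-peaked?
#'
#' A profile is single-peaked if, after 3-point median smoothing, its copies
#' are non-decreasing up to the maximum and non-increasing after it.
#'
#' @param profile a [GradientProfile-class].
#' @return Logical.
#' @export
isSinglePeaked <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  y <- .median3(profile@copies)
  k <- which.max(y)
  !is.unsorted(y[seq_len(k)]) && !is.unsorted(rev(y[k:length(y)]))
}

#' Classify fractions into L/H/UH density windows
#'
#' Labels each fraction by the half-open density window `[lower, upper)`
#' containing it (a density exactly on a shared boundary belongs to the
#' upper, i.e. heavier, window; the heaviest window's upper bound is
#' inclusive). Fractions outside every window are labeled `"outside"`.
#'
#' @param profile a [GradientProfile-class].
#' @param config a [RunConfig-class] supplying `densityWindows`.
#' @return A factor of labels (`L`, `H`, `UH`, `outside`), one per fraction.
#' @export
classifyFractions <- function(profile, config = runConfig()) {
  stopifnot(is(profile, "GradientProfile"), is(config, "RunConfig"))
  w <- config@densityWindows
  lab <- rep("outside", length(profile@density))
  for (i in seq_len(nrow(w))) {
    upper <- if (i == nrow(w)) profile@density <= w[i, 2]
             else profile@density < w[i, 2]
    lab[profile@density >= w[i, 1] & upper] <- rownames(w)[i]
  }
  factor(lab, levels = c(rownames(w), "outside"))
}

#' Select the sequenced fractions of a window
#'
#' Within one density window, finds the contiguous run of `k` fractions
#' maximizing summed 16S rRNA gene copies — the fractions whose DNA would be
#' pooled for sequencing. `k` defaults to `min(3, fractions in window)`;
#' ties are broken toward heavier densities.
#'
#' @param profile a [GradientProfile-class].
#' @param window one of `"L"`, `"H"`, `"UH"`.
#' @param config a [RunConfig-class].
#' @param k number of contiguous fractions (1-3); `NULL` for the default.
#' @return A list with `window`, `fractionIds`, `densities`, `summedCopies`.
#' @export
selectFractions <- function(profile, window, config = runConfig(), k = NULL) {
  stopifnot(is(profile, "GradientProfile"))
  window <- match.arg(window, rownames(config@densityWindows))
  labels <- classifyFractions(profile, config)
  idx <- which(labels == window)
  if (!length(idx))
    stop("window '", window, "' contains no fraction")
  if (is.null(k)) k <- min(3L, length(idx))
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  if (k > length(idx))
    stop("window '", window, "' has only ", length(idx), " fraction(s)")
  # contiguity is over positions inside the window's run of the gradient;
  # enumerate all length-k runs of consecutive indices
  starts <- seq_len(length(idx) - k + 1)
  valid <- vapply(starts, function(s) all(diff(idx[s:(s + k - 1)]) == 1),
                  logical(1))
  starts <- starts[valid]
  if (!length(starts))
    stop("window '", window, "' has no contiguous run of length ", k)
  sums <- vapply(starts, function(s) sum(profile@copies[idx[s:(s + k - 1)]]),
                 numeric(1))
  s <- starts[max(which(sums == max(sums)))]  # tie -> heavier densities
  sel <- idx[s:(s + k - 1)]
  list(window = window, fractionIds = profile@fractionId[sel],
       densities = profile@density[sel], summedCopies = sum(profile@copies[sel]))
}

#' Cross-feeding control comparison
#'
#' Compares the gradient peak of the doubly labeled (13C+15N) sample against
#' the 13C-only sample. DNA that incorporated both isotopes bands heavier
#' than DNA that incorporated 13C alone, so a heavier 13C+15N peak indicates
#' the community is dominated by autotrophs assimilating both substrates and
#' that cross-feeding of labeled carbon through heterotrophs is negligible.
#'
#' @param profile13c15n the 13C+15N treatment [GradientProfile-class].
#' @param profile13c the 13C-only treatment [GradientProfile-class].
#' @return A list with `verdict` (`"negligible"` or `"suspected"`),
#'   `peak13c15n`, `peak13c` and `difference` (g/mL).
#' @export
crossfeedCheck <- function(profile13c15n, profile13c) {
  stopifnot(is(profile13c15n, "GradientProfile"),
            is(profile13c, "GradientProfile"))
  if (!isSinglePeaked(profile13c15n) || !isSinglePeaked(profile13c))
    warning("at least one profile is not single-peaked; peak comparison may be unreliable")
  p1 <- peakDensity(profile13c15n)
  p2 <- peakDensity(profile13c)
  list(verdict = if (p1 > p2) "negligible" else "suspected",
       peak13c15n = p1, peak13c = p2, difference = p1 - p2)
}
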