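# lognormal multiplicative noise with unit mean and the given coefficient of
# variation (qPCR-like error structure)
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a CsCl density gradient profile
#'
#' Each population contributes a Gaussian band of 16S rRNA gene copies
#' centered at the buoyant density implied by its GC content,
#' `1.660 + 0.098 * GC` g/mL, shifted by `shiftC13` for a fully
#' 13C-labeled population and by `shiftC13 + shiftN15` for a dually
#' (13C+15N) labeled one. Per-fraction copies are the sum of band masses,
#' degraded by lognormal multiplicative noise with the given coefficient of
#' variation.
#'
#' @param populations `data.frame` with columns `name`, `gc` (GC fraction,
#'   0-1), `state` (one of `"unlabeled"`, `"C13"`, `"C13N15"`), `abundance`
#'   (total copies/mL, >= 0) and `band_sigma` (band width, g/mL, > 0).
#' @param fractionDensities strictly increasing fraction densities (g/mL).
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed integer seed; identical seeds give identical profiles.
#' @param shiftC13,shiftN15 density shifts (g/mL) for full 13C and full 15N
#'   labeling; defaults 0.036 and 0.016, standard SIP values.
#' @param sampleId,treatment labels for the resulting profile.
#' @return A [GradientProfile-class].
#' @examples
#' pops <- data.frame(name = "A", gc = 0.40, state = "unlabeled",
#'                    abundance = 1e6, band_sigma = 0.004)
#' gp <- simulateGradient(pops, seq(1.66, 1.78, by = 0.004), noiseCv = 0,
#'                        seed = 1)
#' peakDensity(gp)  # grid point nearest 1.660 + 0.098 * 0.40
#' @export
simulateGradient <- function(populations, fractionDensities, noiseCv = 0,
                             seed = 1L, shiftC13 = 0.036, shiftN15 = 0.016,
                             sampleId = "sim", treatment = "13C+15N") {
  stopifnot(is.data.frame(populations))
  if (!nrow(populations)) stop("at least one population is required")
  need <- c("name", "gc", "state", "abundance", "band_sigma")
  missing <- setdiff(need, names(populations))
  if (length(missing))
    stop("missing population column(s): ", paste(missing, collapse = ", "))
  if (is.unsorted(fractionDensities, strictly = TRUE))
    stop("fraction densities must be strictly increasing")
  if (noiseCv < 0) stop("noiseCv must be non-negative")
  if (any(populations$gc < 0 | populations$gc > 1))
    stop("gc must lie in [0, 1]")
  if (any(populations$abundance < 0)) stop("abundance must be non-negative")
  if (any(populations$band_sigma <= 0)) stop("band_sigma must be positive")
  badState <- setdiff(populations$state, c("unlabeled", "C13", "C13N15"))
  if (length(badState))
    stop("unknown labeling state(s): ", paste(badState, collapse = ", "))

  shift <- c(unlabeled = 0, C13 = shiftC13, C13N15 = shiftC13 + shiftN15)
  centers <- 1.660 + 0.098 * populations$gc + shift[populations$state]
  # band mass per fraction bin (bin width from local grid spacing)
  d <- fractionDensities
  width <- diff(d)
  width <- c(width[1], (width[-length(width)] + width[-1]) / 2,
             width[length(width)])[seq_along(d)]
  copies <- rep(0, length(d))
  for (p in seq_len(nrow(populations)))
    copies <- copies + populations$abundance[p] *
      dnorm(d, centers[p], populations$band_sigma[p]) * width
  copies <- withr::with_seed(seed, copies * .lnoise(length(copies), noiseCv))
  gradientProfile(sampleId = sampleId, treatment = treatment,
                  density = d, copies = copies)
}

#' Simulate a tracer incubation from a known true rate
#'
#' Forward model of the DIC assimilation measurement: starting from the
#' initial POC pool and its delta13C, the true rate fixes carbon for `t`
#' days at the atom fraction of the substrate-diluted DIC pool
#' (`csDic / (caDic + csDic)` of the fixed carbon carries the tracer label,
#' taken here as pure 13C), all fixed carbon is retained in POC
#' (`POC_t = POC_0 + rate * t`), and the final atom fraction is converted
#' back to delta13C. Gaussian noise with standard deviation `deltaNoiseSd`
#' (IRMS-like, default the 0.1 per-mil analytical precision) is then added
#' to both delta values. The true rate is stored in the record for recovery
#' tests; with zero noise, [dicAssimilationRate()] returns it exactly.
#'
#' @param trueRate true assimilation rate (umol C/L/day, >= 0).
#' @param poc0 initial POC (umol C/L).
#' @param delta0 initial delta13C of POC (per mil).
#' @param t incubation time (days); default 1 (a 24-h incubation).
#' @param caDic ambient DIC (umol/L).
#' @param csDic added DIC (umol/L); default 3000 (3 mM added bicarbonate).
#' @param deltaNoiseSd Gaussian noise sd on delta13C (per mil).
#' @param seed integer seed.
#' @return A [TracerIncubation-class] with `trueRate` filled.
#' @export
simulateTracer <- function(trueRate, poc0 = 10, delta0 = -25, t = 1,
                           caDic = 2000, csDic = 3000, deltaNoiseSd = 0.1,
                           seed = 1L) {
  stopifnot(trueRate >= 0, poc0 > 0, t > 0, csDic > 0, caDic >= 0,
            deltaNoiseSd >= 0)
  n0 <- ratioToAtomFraction(deltaToRatio(delta0))
  pocT <- poc0 + trueRate * t
  nt <- (poc0 * n0 + trueRate * t * csDic / (caDic + csDic)) / pocT
  if (nt >= 1)
    stop("atom fraction overflow: parameters imply n_t >= 1")
  deltaT <- ratioToDelta(atomFractionToRatio(nt))
  eps <- withr::with_seed(seed, rnorm(2, 0, deltaNoiseSd))
  tracerIncubation(delta0 = delta0 + eps[1], deltaT = deltaT + eps[2],
                   poc0 = poc0, pocT = pocT, t = t, caDic = caDic,
                   csDic = csDic, trueRate = trueRate)
}

#' Simulate a KO table with planted core/enriched/diluted structure
#'
#' Plants known classes: core KOs are equally abundant in the three
#' libraries; a KO enriched (diluted) in library i has its abundance there
#' raised (lowered) `fold`-fold relative to both other libraries. Per-KO
#' base abundances are lognormal, scaled so the expected library total is
#' one million (abundances are on a per-million scale; exact column totals
#' are not forced, which keeps the planted fold ratios intact). Lognormal
#' multiplicative noise with coefficient of variation `noiseCv` is applied
#' entrywise. The planted class is stored in `rowData(x)$trueClass`.
#'
#' @param nCore number of core KOs.
#' @param nEnriched,nDiluted integer vectors of length 3: planted
#'   enriched/diluted KO counts per library.
#' @param fold planted fold change; must exceed the configured
#'   `foldThreshold`, otherwise the classes are not recoverable by
#'   construction.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param config a [RunConfig-class] (for `foldThreshold`).
#' @return A [KOAbundanceSet-class] with `trueClass` in `rowData`.
#' @export
simulateKOTable <- function(nCore, nEnriched = c(0, 0, 0),
                            nDiluted = c(0, 0, 0), fold = 4, noiseCv = 0,
                            seed = 1L, config = runConfig()) {
  stopifnot(nCore >= 0, length(nEnriched) == 3, length(nDiluted) == 3,
            all(nEnriched >= 0), all(nDiluted >= 0), noiseCv >= 0)
  if (fold <= config@foldThreshold)
    stop("planted fold must exceed foldThreshold (",
         config@foldThreshold, ") for classes to be recoverable")
  classes <- rep("core", nCore)
  pat <- matrix(rep(c(1, 1, 1), nCore), ncol = 3, byrow = TRUE)
  for (i in 1:3) {
    p <- c(1, 1, 1); p[i] <- fold
    pat <- rbind(pat, matrix(rep(p, nEnriched[i]), ncol = 3, byrow = TRUE))
    classes <- c(classes, rep(paste0("enriched_lib", i), nEnriched[i]))
  }
  for (i in 1:3) {
    p <- c(1, 1, 1); p[i] <- 1 / fold
    pat <- rbind(pat, matrix(rep(p, nDiluted[i]), ncol = 3, byrow = TRUE))
    classes <- c(classes, rep(paste0("diluted_lib", i), nDiluted[i]))
  }
  k <- nrow(pat)
  if (!k) stop("no KOs requested")
  withr::with_seed(seed, {
    base <- rlnorm(k, meanlog = 0, sdlog = 1)
    m <- pat * base
    m <- m * matrix(.lnoise(3 * k, noiseCv), ncol = 3)
  })
  m <- m * 1e6 / mean(colSums(m))  # per-million scale, common factor only
  koAbundanceSet(m, koIds = sprintf("KO%05d", seq_len(k)),
                 rowData = S4Vectors::DataFrame(trueClass = classes))
}

#' Simulate a taxon-by-fraction relative abundance table
#'
#' Builds the L/H/UH relative abundance pattern DNA-SIP produces: labeled
#' taxa rise from the light to the heavy and ultra-heavy fractions
#' (`uplift`-fold), unlabeled taxa decline (`decline`-fold per step).
#' Raw per-taxon band weights are multiplied by lognormal noise and each
#' fraction column is then closed to sum to 1 (relative abundances).
#' Because of this compositional closure, recovery of the planted states by
#' [callLabeling()] is guaranteed for mixtures — under the defaults, for
#' unlabeled-to-labeled weight ratios up to `(uplift - 2*decline)/decline` —
#' but not for a community that is entirely unlabeled.
#'
#' @param labeledTaxa,unlabeledTaxa character vectors of taxon names; at
#'   least one taxon in total.
#' @param seed integer seed.
#' @param uplift H (and UH) over L raw-abundance factor for labeled taxa
#'   (>= 1).
#' @param decline per-step L-to-H-to-UH decay factor for unlabeled taxa
#'   (<= 0.5, a twofold or steeper decline).
#' @param noiseCv coefficient of variation of multiplicative noise.
#' @param weights optional positive per-taxon weights (labeled first), one
#'   per taxon; default 1.
#' @return `data.frame` with columns `taxon`, `true_state`,
#'   `rel_abundance_L`, `rel_abundance_H`, `rel_abundance_UH`; each
#'   abundance column sums to 1.
#' @export
simulateFractionTaxa <- function(labeledTaxa, unlabeledTaxa = character(),
                                 seed = 1L, uplift = 4, decline = 0.25,
                                 noiseCv = 0, weights = NULL) {
  taxa <- c(labeledTaxa, unlabeledTaxa)
  if (!length(taxa)) stop("at least one taxon is required")
  if (anyDuplicated(taxa)) stop("taxon names must be unique")
  stopifnot(uplift >= 1, decline > 0, decline <= 0.5, noiseCv >= 0)
  if (is.null(weights)) weights <- rep(1, length(taxa))
  stopifnot(length(weights) == length(taxa), all(weights > 0))
  state <- c(rep("labeled", length(labeledTaxa)),
             rep("unlabeled", length(unlabeledTaxa)))
  pat <- t(vapply(state, function(s)
    if (s == "labeled") c(1, uplift, uplift)
    else c(1, decline, decline^2), numeric(3)))
  raw <- pat * weights
  raw <- withr::with_seed(seed,
    raw * matrix(.lnoise(length(raw), noiseCv), ncol = 3))
  rel <- sweep(raw, 2, colSums(raw), "/")
  data.frame(taxon = taxa, true_state = state,
             rel_abundance_L = rel[, 1], rel_abundance_H = rel[, 2],
             rel_abundance_UH = rel[, 3], row.names = NULL,
             stringsAsFactors = FALSE)
}
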