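#' VPDB 13C/12C reference ratio
#'
#' The 13C/12C ratio of the Vienna Peedee Belemnite international reference
#' material, 0.0112372, anchoring delta-notation arithmetic.
#' @export
R_VPDB <- 0.0112372

#' Delta notation to isotope ratio
#'
#' Converts a delta13C value (per mil vs VPDB) to the 13C/12C ratio:
#' `R = (delta/1000 + 1) * R_VPDB`.
#'
#' @param delta delta13C in per mil; must exceed -1000 (a ratio cannot be
#'   negative).
#' @return Numeric 13C/12C ratio(s).
#' @examples
#' deltaToRatio(0)     # the VPDB constant
#' deltaToRatio(1000)  # exact doubling
#' @export
deltaToRatio <- function(delta) {
  if (any(delta <= -1000))
    stop("delta13C must exceed -1000 per mil (non-positive ratio)")
  (delta / 1000 + 1) * R_VPDB
}

#' Isotope ratio back to delta notation
#' @param r 13C/12C ratio(s), non-negative.
#' @return delta13C in per mil vs VPDB.
#' @export
ratioToDelta <- function(r) {
  if (any(r < 0)) stop("isotope ratio must be non-negative")
  (r / R_VPDB - 1) * 1000
}

#' Isotope ratio to 13C atom fraction
#'
#' `n = R / (R + 1)`, the fraction of carbon atoms that are 13C; strictly
#' increasing in R and bounded in \[0, 1).
#'
#' @param r 13C/12C ratio(s), non-negative.
#' @return Atom fraction(s) in \[0, 1).
#' @export
ratioToAtomFraction <- function(r) {
  if (any(r < 0)) stop("isotope ratio must be non-negative")
  r / (r + 1)
}

#' 13C atom fraction back to isotope ratio
#' @param n atom fraction(s) in \[0, 1).
#' @return 13C/12C ratio(s).
#' @export
atomFractionToRatio <- function(n) {
  if (any(n < 0 | n >= 1)) stop("atom fraction must lie in [0, 1)")
  n / (1 - n)
}

#' Construct a tracer incubation record
#'
#' @param delta0,deltaT delta13C of POC at the start and end of incubation
#'   (per mil vs VPDB).
#' @param poc0,pocT POC concentration at the start and end (umol C/L).
#' @param t incubation time (days).
#' @param caDic,csDic ambient and added DIC concentration (umol/L).
#' @param trueRate hidden truth for simulated records (NA for measured data).
#' @return A validated [TracerIncubation-class].
#' @export
tracerIncubation <- function(delta0, deltaT, poc0, pocT, t, caDic, csDic,
                             trueRate = NA_real_) {
  new("TracerIncubation", delta0 = as.numeric(delta0),
      deltaT = as.numeric(deltaT), poc0 = as.numeric(poc0),
      pocT = as.numeric(pocT), t = as.numeric(t), caDic = as.numeric(caDic),
      csDic = as.numeric(csDic), trueRate = as.numeric(trueRate))
}

#' @rdname tracerIncubation
#' @param object a `TracerIncubation`.
#' @export
setMethod("show", "TracerIncubation", function(object) {
  cat("TracerIncubation\n")
  cat(sprintf("  delta13C-POC: %.3f -> %.3f permil over %.3g d\n",
              object@delta0, object@deltaT, object@t))
  cat(sprintf("  POC: %.4g -> %.4g umol C/L   DIC ambient %.4g + added %.4g umol/L\n",
              object@poc0, object@pocT, object@caDic, object@csDic))
  if (!is.na(object@trueRate))
    cat(sprintf("  simulated, true rate %.6g umol C/L/d\n", object@trueRate))
  invisible(object)
})

# rate implied by the delta13C change deltaT at measured POC; the shared core
# of the estimator and its detection limit
.rateFromDeltas <- function(delta0, deltaT, poc0, pocT, t, caDic, csDic) {
  n0 <- ratioToAtomFraction(deltaToRatio(delta0))
  nt <- ratioToAtomFraction(deltaToRatio(deltaT))
  (pocT * nt - poc0 * n0) / t * (caDic + csDic) / csDic
}

#' DIC assimilation rate from a tracer incubation
#'
#' Computes the substrate-dilution-corrected dissolved-inorganic-carbon
#' assimilation rate
#' `rate = (POC_t * n_t - POC_0 * n_0) / t * (Ca + Cs) / Cs`,
#' where the 13C atom fractions `n` are obtained from the measured delta13C
#' values via the VPDB ratio. A delta13C excess smaller than the analytical
#' precision (`deltaPrecision`, default 0.1 per mil) is below detection
#' limit: the result is flagged `bdl` and the rate that a precision-sized
#' delta shift would produce is reported as `detectionLimit`.
#'
#' @param inc a [TracerIncubation-class].
#' @param config a [RunConfig-class]; only `deltaPrecision` is used.
#' @return A list of class `"RateResult"` with elements `rate` (umol C/L/day;
#'   `NA` when `bdl`), `bdl` (logical), `detectionLimit` (umol C/L/day).
#' @examples
#' inc <- tracerIncubation(delta0 = -25, deltaT = 100, poc0 = 10, pocT = 10,
#'                         t = 1, caDic = 2000, csDic = 3000)
#' dicAssimilationRate(inc)$rate  # ~0.0229 umol C/L/day
#' @export
dicAssimilationRate <- function(inc, config = runConfig()) {
  stopifnot(is(inc, "TracerIncubation"), is(config, "RunConfig"))
  rate <- .rateFromDeltas(inc@delta0, inc@deltaT, inc@poc0, inc@pocT,
                          inc@t, inc@caDic, inc@csDic)
  dl <- .rateFromDeltas(inc@delta0, inc@delta0 + config@deltaPrecision,
                        inc@poc0, inc@pocT, inc@t, inc@caDic, inc@csDic)
  bdl <- abs(inc@deltaT - inc@delta0) < config@deltaPrecision
  if (!bdl && rate < 0) {
    if (rate < -dl)
      stop(sprintf("negative rate %.4g beyond the detection limit %.4g: inconsistent inputs",
                   rate, dl))
    bdl <- TRUE
  }
  structure(list(rate = if (bdl) NA_real_ else rate, bdl = bdl,
                 detectionLimit = dl),
            class = "RateResult")
}

#' @export
print.RateResult <- function(x, ...) {
  if (x$bdl)
    cat(sprintf("rate: BDL (detection limit %.4g umol C/L/day)\n",
                x$detectionLimit))
  else
    cat(sprintf("rate: %.6g umol C/L/day (detection limit %.4g)\n",
                x$rate, x$detectionLimit))
  invisible(x)
}

#' Average replicate rates of one incubation condition
#'
#' Mean and sample standard deviation (n - 1 denominator) over the non-BDL
#' replicates of a condition. When every replicate is below detection limit
#' the condition has no datum (`nd = TRUE`), reported as `ND`.
#'
#' @param rates either a list of `RateResult` objects (from
#'   [dicAssimilationRate()]) or a numeric vector of per-bottle rates.
#' @param bdl logical vector marking below-detection-limit bottles when
#'   `rates` is numeric; numeric entries must then be `NA` where `bdl`.
#' @return A list with `mean`, `sd` (NA when fewer than 2 replicates), `n`
#'   (non-BDL replicates used) and `nd` (all replicates BDL).
#' @examples
#' averageReplicates(c(1.43, 1.68, 1.38))        # mean 1.50 at 2 d.p.
#' averageReplicates(c(NA, NA), bdl = c(TRUE, TRUE))$nd
#' @export
averageReplicates <- function(rates, bdl = NULL) {
  if (is.list(rates) && length(rates) && inherits(rates[[1]], "RateResult")) {
    bdl <- vapply(rates, `[[`, logical(1), "bdl")
    rates <- vapply(rates, `[[`, numeric(1), "rate")
  }
  if (is.null(bdl)) bdl <- rep(FALSE, length(rates))
  stopifnot(length(bdl) == length(rates))
  keep <- !bdl & !is.na(rates)
  if (!length(rates)) stop("no replicates supplied")
  if (!any(keep))
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, nd = TRUE))
  x <- rates[keep]
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x), nd = FALSE)
}
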