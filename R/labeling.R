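#' Per-taxon 13C-incorporation call
#'
#' Formalizes the DNA-SIP interpretation rule: a taxon that assimilated the
#' 13C substrate keeps a heavy-fraction relative abundance higher than, or
#' similar to, its light-fraction abundance, while an unlabeled taxon
#' declines sharply from light to heavy. The call is made from the ratio
#' `hlRatio = H / L`: `labeled` when `hlRatio >= thetaLabeled` (default
#' 0.8), `unlabeled` when `hlRatio <= thetaUnlabeled` (default 0.5, a
#' twofold decline), `ambiguous` in between, and `insufficient` when both L
#' and H abundances fall below `abundanceFloor`. The ultra-heavy fraction,
#' when given, is reported as corroborating evidence (`uhlRatio`) but does
#' not enter the verdict.
#'
#' @param relAbundanceL,relAbundanceH relative abundance of the taxon in the
#'   light and heavy fraction, each in \[0, 1\].
#' @param relAbundanceUH optional ultra-heavy relative abundance.
#' @param config a [RunConfig-class] supplying the thresholds.
#' @param taxon taxon label carried into the result.
#' @return A list of class `"LabelingCall"` with `taxon`, `verdict` (one of
#'   `labeled`, `unlabeled`, `ambiguous`, `insufficient`), `hlRatio`
#'   (`Inf` when L is 0 and H positive) and `uhlRatio`.
#' @examples
#' cfg <- runConfig()
#' callLabeling(0.10, 0.12, config = cfg)$verdict  # labeled
#' callLabeling(0.20, 0.02, config = cfg)$verdict  # unlabeled
#' @export
callLabeling <- function(relAbundanceL, relAbundanceH, relAbundanceUH = NA,
                         config = runConfig(), taxon = NA_character_) {
  stopifnot(is(config, "RunConfig"))
  L <- relAbundanceL; H <- relAbundanceH
  if (any(c(L, H) < 0) || any(c(L, H) > 1))
    stop("relative abundances must lie in [0, 1]")
  ratio <- if (L > 0) H / L else if (H > 0) Inf else NaN
  uhl <- if (!is.na(relAbundanceUH) && L > 0) relAbundanceUH / L else NA_real_
  verdict <-
    if (L < config@abundanceFloor && H < config@abundanceFloor) "insufficient"
    else if (is.infinite(ratio) || ratio >= config@thetaLabeled) "labeled"
    else if (ratio <= config@thetaUnlabeled) "unlabeled"
    else "ambiguous"
  structure(list(taxon = taxon, verdict = verdict, hlRatio = ratio,
                 uhlRatio = uhl),
            class = "LabelingCall")
}

#' @export
print.LabelingCall <- function(x, ...) {
  cat(sprintf("%s: %s (H/L = %.3g%s)\n",
              if (is.na(x$taxon)) "<taxon>" else x$taxon, x$verdict,
              x$hlRatio,
              if (is.na(x$uhlRatio)) "" else sprintf(", UH/L = %.3g", x$uhlRatio)))
  invisible(x)
}

#' Labeling calls for a taxon table
#'
#' Applies [callLabeling()] to every taxon of a taxon-by-fraction relative
#' abundance table, after excluding taxa whose relative abundance stays
#' below `minAbundance` (default 0.005, i.e. 0.5 %) in every fraction —
#' the inclusion filter used for community heat maps.
#'
#' @param table `data.frame` with columns `taxon`, `rel_abundance_L`,
#'   `rel_abundance_H` and optionally `rel_abundance_UH`.
#' @param config a [RunConfig-class].
#' @param minAbundance inclusion threshold; overrides the config value when
#'   given.
#' @return A `data.frame` with columns `taxon`, `verdict`, `hl_ratio`,
#'   `uhl_ratio`, sorted by verdict then by descending maximum abundance.
#' @export
callLabelingTable <- function(table, config = runConfig(),
                              minAbundance = config@minAbundance) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  need <- c("taxon", "rel_abundance_L", "rel_abundance_H")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  hasUH <- "rel_abundance_UH" %in% names(table)
  ab <- cbind(table$rel_abundance_L, table$rel_abundance_H,
              if (hasUH) table$rel_abundance_UH)
  maxAb <- apply(ab, 1, max, na.rm = TRUE)
  keep <- maxAb > minAbundance
  table <- table[keep, , drop = FALSE]
  if (!nrow(table))
    return(data.frame(taxon = character(), verdict = character(),
                      hl_ratio = numeric(), uhl_ratio = numeric()))
  calls <- lapply(seq_len(nrow(table)), function(i)
    callLabeling(table$rel_abundance_L[i], table$rel_abundance_H[i],
                 if (hasUH) table$rel_abundance_UH[i] else NA,
                 config = config, taxon = table$taxon[i]))
  out <- data.frame(
    taxon = vapply(calls, `[[`, character(1), "taxon"),
    verdict = vapply(calls, `[[`, character(1), "verdict"),
    hl_ratio = vapply(calls, `[[`, numeric(1), "hlRatio"),
    uhl_ratio = vapply(calls, `[[`, numeric(1), "uhlRatio"),
    stringsAsFactors = FALSE)
  vOrder <- c(labeled = 1, ambiguous = 2, unlabeled = 3, insufficient = 4)
  out[order(vOrder[out$verdict], -maxAb[keep]), , drop = FALSE]
}
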