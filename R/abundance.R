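#' Length-normalized gene relative abundance
#'
#' Computes for every gene `k` the normalized relative abundance
#' `G_k = (r_k / L_k) / sum_i (r_i / L_i)`, where `r_k` is the number of
#' reads mapped to the gene and `L_k` its length. Length units cancel;
#' lengths are taken in nucleotides. The `g` column sums to 1; genes with no
#' mapped reads get `g = 0`.
#'
#' @param records `data.frame` with columns `gene_id`, `mapped_reads`
#'   (non-negative counts) and `length` (positive, nt); other columns (e.g.
#'   taxonomy) are carried through.
#' @return The input with a numeric column `g` added/overwritten.
#' @examples
#' normalizeGeneAbundance(data.frame(gene_id = c("a", "b"),
#'                                   mapped_reads = c(100, 50),
#'                                   length = c(200, 400)))$g  # 0.8, 0.2
#' @export
normalizeGeneAbundance <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gene_id", "mapped_reads", "length")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(records$mapped_reads < 0)) stop("mapped_reads must be non-negative")
  if (any(records$length <= 0)) stop("gene lengths must be positive")
  dens <- records$mapped_reads / records$length
  total <- sum(dens)
  if (total == 0) stop("all genes have zero mapped reads")
  records$g <- dens / total
  records
}

#' MAG relative abundance
#'
#' The relative abundance of a metagenome-assembled genome (MAG) in a
#' library: the proportion of uniquely mapped and correctly paired reads out
#' of the total reads of the metagenome.
#'
#' @param uniquePairedReads uniquely mapped, correctly paired read count(s).
#' @param totalReads total read count(s) of the metagenome, positive.
#' @return Fraction(s) in \[0, 1\].
#' @export
magRelativeAbundance <- function(uniquePairedReads, totalReads) {
  if (any(totalReads <= 0)) stop("totalReads must be positive")
  if (any(uniquePairedReads < 0) || any(uniquePairedReads > totalReads))
    stop("uniquePairedReads must lie in [0, totalReads]")
  uniquePairedReads / totalReads
}

#' Aggregate gene abundances by taxon
#'
#' Sums normalized gene abundances `g` within each taxon at a requested
#' rank. Genes whose value at that rank is `"unclassified"` can be excluded
#' (the convention used when kingdom-level unclassified reads are dropped
#' from statistical analysis); with `renormalize = TRUE` the included taxa
#' are rescaled to sum to 1.
#'
#' @param records `data.frame` with a numeric `g` column (see
#'   [normalizeGeneAbundance()]) and one column per taxonomic rank.
#' @param rank name of the taxonomy column to aggregate at (e.g. `"order"`).
#' @param excludeUnclassified drop genes labeled `"unclassified"` at `rank`.
#' @param renormalize rescale included taxa to sum to 1.
#' @return `data.frame` with columns `taxon` and `g`, sorted by descending
#'   `g`; the included total is `<= 1` unless renormalized.
#' @export
aggregateByTaxon <- function(records, rank, excludeUnclassified = FALSE,
                             renormalize = FALSE) {
  stopifnot(is.data.frame(records), "g" %in% names(records))
  if (!rank %in% names(records))
    stop("unknown rank '", rank, "': no such column")
  taxon <- as.character(records[[rank]])
  taxon[is.na(taxon)] <- "unclassified"
  g <- records$g
  if (excludeUnclassified) {
    keep <- taxon != "unclassified"
    taxon <- taxon[keep]; g <- g[keep]
  }
  if (!length(g))
    return(data.frame(taxon = character(), g = numeric()))
  agg <- tapply(g, taxon, sum)
  out <- data.frame(taxon = names(agg), g = as.numeric(agg),
                    stringsAsFactors = FALSE)
  if (renormalize) out$g <- out$g / sum(out$g)
  out[order(-out$g), , drop = FALSE]
}
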