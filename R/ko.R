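#' Construct a KO abundance set
#'
#' Wraps a KO-by-library abundance matrix in a
#' [KOAbundanceSet-class]. Abundances are expected on a per-million scale
#' within each library (as produced by standard annotation pipelines);
#' [perMillion()] rescales raw columns when needed.
#'
#' @param abundance numeric matrix, KOs in rows, exactly three libraries in
#'   columns.
#' @param koIds row (KO) identifiers; defaults to existing rownames or
#'   `KO0001..`.
#' @param libNames column (library) names; defaults to existing colnames or
#'   `lib1..lib3`.
#' @param rowData optional `DataFrame`/`data.frame` of per-KO annotation
#'   (e.g. planted truth).
#' @return A [KOAbundanceSet-class].
#' @examples
#' m <- rbind(K1 = c(100, 100, 100), K2 = c(400, 100, 100))
#' kset <- koAbundanceSet(m)
#' koCategories(classifyKO(kset))
#' @export
koAbundanceSet <- function(abundance, koIds = rownames(abundance),
                           libNames = colnames(abundance), rowData = NULL) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) != 3)
    stop("exactly three libraries (columns) are required")
  if (is.null(koIds)) koIds <- sprintf("KO%04d", seq_len(nrow(abundance)))
  if (is.null(libNames)) libNames <- paste0("lib", 1:3)
  dimnames(abundance) <- list(koIds, libNames)
  rd <- if (is.null(rowData)) S4Vectors::DataFrame(row.names = koIds)
        else S4Vectors::DataFrame(rowData, row.names = koIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), rowData = rd)
  new("KOAbundanceSet", se)
}

#' @describeIn koAbundanceSet Abundance matrix accessor.
#' @param x a `KOAbundanceSet`.
#' @export
koAbundance <- function(x) {
  stopifnot(is(x, "KOAbundanceSet"))
  SummarizedExperiment::assay(x, "abundance")
}

#' @describeIn koAbundanceSet Category accessor (factor; `NA`-free only
#'   after [classifyKO()]).
#' @export
koCategories <- function(x) {
  stopifnot(is(x, "KOAbundanceSet"))
  SummarizedExperiment::rowData(x)$category
}

#' Rescale library columns to per-million
#'
#' Divides each column by its total and multiplies by 1e6, the normalization
#' applied to raw per-library abundances before cross-library comparison.
#' Note that per-library rescaling changes cross-library ratios whenever the
#' library totals differ; apply it to complete KO tables, not to planted
#' subsets.
#'
#' @param abundance numeric matrix with libraries in columns, or a
#'   [KOAbundanceSet-class].
#' @return Same shape as the input, column sums equal to 1e6.
#' @export
perMillion <- function(abundance) {
  if (is(abundance, "KOAbundanceSet")) {
    m <- koAbundance(abundance)
    SummarizedExperiment::assay(abundance, "abundance") <-
      sweep(m, 2, colSums(m), "/") * 1e6
    return(abundance)
  }
  totals <- colSums(abundance)
  if (any(totals <= 0)) stop("every library must have positive total abundance")
  sweep(abundance, 2, totals, "/") * 1e6
}

# category of one (a1, a2, a3) triple; comparisons in multiplication form so
# zero abundances are safe. Precedence: core, then enriched, then diluted.
.classifyTriple <- function(a, fold) {
  if (all(a == 0)) stop("all-zero abundance triple cannot be classified")
  if (min(a) > 0 && max(a) < fold * min(a)) return("core")
  for (i in 1:3)
    if (a[i] >= fold * max(a[-i]) && a[i] > 0)
      return(paste0("enriched_lib", i))
  for (i in 1:3)
    if (fold * a[i] <= min(a[-i]))
      return(paste0("diluted_lib", i))
  "unclassified"
}

.categoryLevels <- function() {
  c("core", paste0("enriched_lib", 1:3), paste0("diluted_lib", 1:3),
    "unclassified")
}

#' Classify KOs as core, enriched, diluted or unclassified
#'
#' Applies the twofold rule across the three libraries to every KO:
#' \itemize{
#'   \item \emph{core} — the abundance differs by less than
#'     `foldThreshold`-fold across the three libraries (`max/min <
#'     foldThreshold`, all three positive);
#'   \item \emph{enriched} in library i — the abundance there is at least
#'     `foldThreshold`-fold higher than in each of the other two libraries;
#'   \item \emph{diluted} in library i — the abundance there is at least
#'     `foldThreshold`-fold lower than in each of the other two;
#'   \item \emph{unclassified} — none of the rules fires (the three rules do
#'     not cover all triples).
#' }
#' Comparisons are in multiplication form, so zeros are handled exactly: a
#' KO present in only one library is enriched there. When both the enriched
#' and the diluted rule could fire, enriched takes precedence.
#'
#' @param x a [KOAbundanceSet-class]; abundances are taken as given (already
#'   per-million within each library).
#' @param config a [RunConfig-class] supplying `foldThreshold`.
#' @return `x` with `rowData` columns `category` (factor) and `maxAbundance`
#'   (highest abundance across the three libraries, the quantity sized in
#'   ternary plots).
#' @export
classifyKO <- function(x, config = runConfig()) {
  stopifnot(is(x, "KOAbundanceSet"), is(config, "RunConfig"))
  m <- koAbundance(x)
  cats <- apply(m, 1, .classifyTriple, fold = config@foldThreshold)
  SummarizedExperiment::rowData(x)$category <-
    factor(cats, levels = .categoryLevels())
  SummarizedExperiment::rowData(x)$maxAbundance <- apply(m, 1, max)
  x
}

#' Barycentric ternary coordinates
#'
#' Maps each KO's abundance triple to barycentric coordinates
#' `a_i / (a1 + a2 + a3)`; rows sum to 1. A KO equally abundant everywhere
#' maps to the centroid, an enriched KO lies near its library's vertex.
#'
#' @param x a [KOAbundanceSet-class] or a numeric matrix with 3 columns.
#' @return Numeric matrix of the same row dimension, rows summing to 1.
#' @export
ternaryCoordinates <- function(x) {
  m <- if (is(x, "KOAbundanceSet")) koAbundance(x) else as.matrix(x)
  totals <- rowSums(m)
  if (any(totals <= 0)) stop("each KO needs a positive abundance sum")
  sweep(m, 1, totals, "/")
}

#' Per-category KO counts and abundance totals
#'
#' Counts the KOs in each category and sums their abundance per library; the
#' counts partition the KO set and the per-library shares across categories
#' sum to 1.
#'
#' @param x a classified [KOAbundanceSet-class] (see [classifyKO()]).
#' @return `data.frame` with one row per non-empty category: `category`,
#'   `n_ko`, per-library abundance totals and per-library shares.
#' @export
summarizeCategories <- function(x) {
  stopifnot(is(x, "KOAbundanceSet"))
  cats <- koCategories(x)
  if (is.null(cats)) stop("run classifyKO() first")
  m <- koAbundance(x)
  libTotals <- colSums(m)
  rows <- lapply(levels(droplevels(cats)), function(cc) {
    sel <- cats == cc
    tot <- colSums(m[sel, , drop = FALSE])
    df <- data.frame(category = cc, n_ko = sum(sel), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) {
      df[[paste0("abundance_", colnames(m)[j])]] <- tot[j]
      df[[paste0("share_", colnames(m)[j])]] <- tot[j] / libTotals[j]
    }
    df
  })
  do.call(rbind, rows)
}

#' Keep only high-abundance KOs
#'
#' Retains the KOs whose maximum abundance across the three libraries
#' strictly exceeds `floor` (per million) — the filter used when searching
#' enriched functions for biologically interpretable genes.
#'
#' @param x a [KOAbundanceSet-class].
#' @param floor abundance floor, per million (non-negative).
#' @return The subset `KOAbundanceSet`.
#' @export
filterHighAbundance <- function(x, floor = 1000) {
  stopifnot(is(x, "KOAbundanceSet"), floor >= 0)
  keep <- apply(koAbundance(x), 1, max) > floor
  x[keep, ]
}

#' Ternary plot of KO categories
#'
#' Draws the classified KOs in barycentric coordinates, symbol area scaled
#' by each KO's highest abundance, colored by category.
#'
#' @param x a classified [KOAbundanceSet-class].
#' @param main plot title.
#' @return Invisibly, the 2-D plotting coordinates.
#' @export
plotTernary <- function(x, main = "KO categories") {
  stopifnot(is(x, "KOAbundanceSet"))
  cats <- koCategories(x)
  if (is.null(cats)) stop("run classifyKO() first")
  b <- ternaryCoordinates(x)
  # equilateral triangle with vertices lib1 top, lib2 bottom-left, lib3 bottom-right
  vx <- c(0.5, 0, 1); vy <- c(sqrt(3) / 2, 0, 0)
  px <- b %*% vx; py <- b %*% vy
  pal <- setNames(c("grey50", "#1b9e77", "#d95f02", "#7570b3",
                    "#66a61e", "#e6ab02", "#a6761d", "black"),
                  .categoryLevels())
  maxAb <- SummarizedExperiment::rowData(x)$maxAbundance
  cex <- 0.4 + 1.6 * sqrt(maxAb / max(maxAb))
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, sqrt(3) / 2 + 0.08),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  graphics::polygon(vx, vy)
  graphics::text(vx, vy, colnames(koAbundance(x)),
                 pos = c(3, 1, 1), offset = 0.6)
  open <- grepl("^diluted", as.character(cats))
  graphics::points(px, py, cex = cex, col = pal[as.character(cats)],
                   pch = ifelse(open, 1, 19))
  invisible(cbind(x = px, y = py))
}

#' @rdname koAbundanceSet
#' @param object a `KOAbundanceSet`.
#' @export
setMethod("show", "KOAbundanceSet", function(object) {
  cat(sprintf("KOAbundanceSet: %d KOs x libraries %s\n", nrow(object),
              paste(colnames(object), collapse = ", ")))
  cats <- koCategories(object)
  if (!is.null(cats)) {
    tab <- table(droplevels(cats))
    cat("  categories:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(object)
})
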