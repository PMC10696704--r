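# FNV-1a 32-bit over a UTF-8 string; used for the config hash recorded in
# provenance sidecars. Arithmetic is in double precision (exact up to 2^53)
# with explicit modular reduction; the xor only ever touches the low byte.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    # xor of h (< 2^32) with a byte only touches the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(config = NULL, seed = NULL) {
  cfgJson <- if (is.null(config)) "{}" else
    as.character(jsonlite::toJSON(.configAsList(config), auto_unbox = TRUE,
                                  digits = NA))
  list(package = "ventSIP",
       version = as.character(packageVersion("ventSIP")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = if (is.null(seed) && !is.null(config)) config@seed else seed,
       config_hash = .fnv1a(cfgJson),
       config = if (is.null(config)) NULL else .configAsList(config))
}

#' Read a validated tab-separated table
#'
#' Reads a TSV with a single header row and checks it against an expected
#' schema. `"."` and empty cells are treated as missing; rows missing a
#' required field are rejected.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"` or `"character"`).
#' @param required character vector of columns that must be non-missing in
#'   every row (defaults to all schema columns).
#' @return A `data.frame` with columns typed per schema (extra columns are
#'   kept as read).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("fraction_id\tdensity\tcopies", "F1\t1.70\t100"), tf)
#' readTableTSV(tf, c(fraction_id = "character", density = "numeric",
#'                    copies = "numeric"))
#' @export
readTableTSV <- function(path, schema, required = names(schema)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = c(".", ""), check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(vals) & !is.na(df[[col]]))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' in column '%s' at row %d",
                     df[[col]][bad[1]], col, bad[1]))
      df[[col]] <- vals
    }
  }
  for (col in intersect(required, names(schema))) {
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("missing required value in column '%s' at row %d",
                   col, bad[1]))
  }
  df
}

#' Write a table with a provenance sidecar
#'
#' Writes `x` as a tab-separated UTF-8 table (header row, `"."` for missing
#' values) and a JSON sidecar `<path>.json` recording the package version,
#' timestamp, seed and a hash of the configuration, so every output is
#' traceable to its run.
#'
#' @param x a `data.frame`.
#' @param path output path (conventionally `.tsv`).
#' @param config optional [RunConfig-class] recorded in the sidecar.
#' @param seed optional integer seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writeTableTSV <- function(x, path, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(x))
  out <- x
  for (col in names(out)) {
    v <- out[[col]]
    v <- if (is.numeric(v)) {
      s <- vapply(v, function(z) if (is.na(z)) "." else
        format(z, digits = 17, scientific = FALSE, trim = TRUE), "")
      s
    } else {
      z <- as.character(v)
      z[is.na(z)] <- "."
      z
    }
    out[[col]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(.provenance(config, seed), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a gradient profile table
#'
#' Expects columns `fraction_id`, `density` (g/mL) and `copies`
#' (16S rRNA gene copies per mL).
#'
#' @param path TSV file path.
#' @param sampleId,treatment labels attached to the profile.
#' @return A [GradientProfile-class].
#' @export
readGradientTable <- function(path, sampleId = basename(path),
                              treatment = "13C+15N") {
  df <- readTableTSV(path, c(fraction_id = "character", density = "numeric",
                             copies = "numeric"))
  df <- df[order(df$density), , drop = FALSE]
  gradientProfile(sampleId = sampleId, treatment = treatment,
                  fractionId = df$fraction_id, density = df$density,
                  copies = df$copies)
}

#' Read a per-bottle carbon fixation rate table
#'
#' Expects columns `site`, `temperature`, `treatment`, `rate`
#' (umol C/L/day). The token `BDL` marks a below-detection-limit bottle and
#' is returned as `NA` in `rate` with `bdl = TRUE`.
#'
#' @param path TSV file path.
#' @return A `data.frame` with columns `site`, `temperature`, `treatment`,
#'   `rate` (numeric) and `bdl` (logical).
#' @export
readRateTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = c(".", ""), stringsAsFactors = FALSE)
  need <- c("site", "temperature", "treatment", "rate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  bdl <- !is.na(df$rate) & toupper(df$rate) == "BDL"
  rate <- suppressWarnings(as.numeric(df$rate))
  badIdx <- which(is.na(rate) & !is.na(df$rate) & !bdl)
  if (length(badIdx))
    stop(sprintf("parse error: non-numeric value '%s' in column 'rate' at row %d",
                 df$rate[badIdx[1]], badIdx[1]))
  data.frame(site = df$site, temperature = df$temperature,
             treatment = df$treatment, rate = rate, bdl = bdl,
             stringsAsFactors = FALSE)
}

#' Per-bottle carbon fixation rates of the two-vent incubation study
#'
#' Returns the printed per-bottle carbon fixation rates (umol C/L/day) of
#' the white-vent (WV, pH 5.6) and yellow-vent (YV, pH 2.2) temperature
#' gradient incubations shipped with the package, one row per bottle across
#' the 13C+15N, 13C+14N and 13C treatments; all three YV 65 degC bottles are
#' below detection limit.
#'
#' @return A `data.frame` as from [readRateTable()].
#' @examples
#' head(exampleRateTable())
#' @export
exampleRateTable <- function() {
  readRateTable(system.file("extdata", "vent_rates.tsv", package = "ventSIP",
                            mustWork = TRUE))
}
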