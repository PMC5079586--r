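#' Construct a per-fish length dataset
#'
#' The universal input of the package: one measured fish per row, with the
#' calendar year it was landed, a free-text label for the data source (survey,
#' monitoring programme, ...), and its total length in cm.
#'
#' @param year Integer calendar year per fish.
#' @param source Character data-source label per fish.
#' @param tl_cm Total length (cm) per fish; positive.
#' @param provenance Free-text description of where the records came from.
#' @return A data.frame of class \code{"length_dataset"} with columns
#'   \code{year}, \code{source}, \code{tl_cm} and a \code{"provenance"}
#'   attribute.
#' @export
length_dataset <- function(year, source, tl_cm, provenance = "") {
  stopifnot(length(year) == length(tl_cm))
  if (length(source) == 1L) source <- rep(source, length(year))
  df <- data.frame(year = as.integer(year), source = as.character(source),
                   tl_cm = as.numeric(tl_cm), stringsAsFactors = FALSE)
  structure(df, provenance = provenance,
            class = c("length_dataset", "data.frame"))
}

#' @export
print.length_dataset <- function(x, ...) {
  cat(sprintf("Length dataset: %d fish, years %s-%s, %d source(s)\n",
              nrow(x),
              if (nrow(x)) min(x$year) else NA, if (nrow(x)) max(x$year) else NA,
              length(unique(x$source))))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("  provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-record validation shared by the reader and the constructor checks.
# Returns a character reason per failing row ("" = keep).
.validate_records <- function(year, tl_cm, max_tl) {
  reason <- character(length(tl_cm))
  bad_num <- !is.finite(tl_cm)
  reason[bad_num] <- "unparseable length"
  nonpos <- !bad_num & tl_cm <= 0
  reason[nonpos] <- "nonpositive length"
  toolong <- !bad_num & tl_cm > max_tl
  reason[toolong] <- sprintf("length above cap (%g cm)", max_tl)
  bad_year <- (!is.finite(year) | year < 1900 | year > 2100) & !nzchar(reason)
  reason[bad_year] <- "year outside [1900, 2100]"
  reason
}

#' Read per-fish length records from a delimited text file
#'
#' Ingests a CSV (or other delimited file) of landing records, applies the
#' record-level validity rules (positive length, length at or below a hard
#' cap, plausible year), and returns both the surviving records and an
#' itemised validation report. Rows failing a rule are rejected individually
#' and counted by reason; a missing file or a missing mapped column is fatal.
#'
#' @param path Path to the delimited file (header row required, UTF-8,
#'   decimal point \code{.}).
#' @param column_map Named character vector mapping the logical fields
#'   \code{year}, \code{source}, \code{tl_cm} to the file's column names.
#' @param delim Field delimiter; default comma.
#' @param max_tl Hard upper cap on credible total length (cm); default 200,
#'   well above any reported length for the target species, so it flags
#'   data-entry errors without excluding legitimate fish.
#' @param provenance Provenance string stored on the dataset; defaults to the
#'   file path.
#' @return A list with elements \code{data} (a [length_dataset()] of the kept
#'   records, input order preserved) and \code{report} (class
#'   \code{"validation_report"}: counts read/kept/rejected and per-reason
#'   rejection counts).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(year = 2012, source = "obs", tl_cm = c(46.8, 65.3, 79)),
#'           f, row.names = FALSE)
#' read_length_records(f)$report
#' @export
read_length_records <- function(path,
                                column_map = c(year = "year", source = "source",
                                               tl_cm = "tl_cm"),
                                delim = ",", max_tl = 200,
                                provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, fileEncoding = "UTF-8")
  for (fld in c("year", "source", "tl_cm")) {
    col <- column_map[[fld]]
    if (is.null(col) || !col %in% names(raw))
      stop("mapped column not found in header: '", col %||% fld, "' (for ", fld, ")")
  }
  year <- suppressWarnings(as.numeric(raw[[column_map[["year"]]]]))
  tl <- suppressWarnings(as.numeric(raw[[column_map[["tl_cm"]]]]))
  src <- raw[[column_map[["source"]]]]
  reason <- .validate_records(year, tl, max_tl)
  keep <- !nzchar(reason)
  rejects <- table(reason[!keep])
  report <- structure(
    list(n_read = length(keep), n_kept = sum(keep),
         n_rejected = sum(!keep),
         reasons = stats::setNames(as.integer(rejects), names(rejects))),
    class = "validation_report")
  ds <- length_dataset(year[keep], src[keep], tl[keep], provenance = provenance)
  list(data = ds, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Read %d records: kept %d, rejected %d\n",
              x$n_read, x$n_kept, x$n_rejected))
  for (r in names(x$reasons))
    cat(sprintf("  %s: %d\n", r, x$reasons[[r]]))
  invisible(x)
}

#' Write a length dataset to CSV
#'
#' Full-precision round-trip companion of [read_length_records()].
#'
#' @param ds A [length_dataset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_length_records <- function(ds, path) {
  df <- as.data.frame(ds)
  df$tl_cm <- format(df$tl_cm, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-year sample size, mean and standard deviation of landed length
#'
#' @param ds A [length_dataset()].
#' @return A data.frame with one row per year present in the data:
#'   \code{year}, \code{n}, \code{mean_tl}, \code{sd_tl}. The standard
#'   deviation uses the n-1 denominator; years with a single fish report
#'   \code{NA} (undefined), never 0.
#' @export
summarize_by_year <- function(ds) {
  if (nrow(ds) == 0L) {
    warning("empty dataset: returning empty summary")
    return(data.frame(year = integer(), n = integer(),
                      mean_tl = numeric(), sd_tl = numeric()))
  }
  years <- sort(unique(ds$year))
  out <- do.call(rbind, lapply(years, function(y) {
    tl <- ds$tl_cm[ds$year == y]
    data.frame(year = y, n = length(tl), mean_tl = mean(tl),
               sd_tl = if (length(tl) > 1L) stats::sd(tl) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
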