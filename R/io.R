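#' Read a delimited expression matrix
#'
#' Reads a TSV or CSV file (autodetected from the extension, `.csv` = comma,
#' anything else = tab) with a header row of feature ids and the sample id in
#' the first column. Empty cells and the token `NA` are treated as missing.
#' Files with features in rows can be read with `transpose = TRUE`.
#'
#' @param path path to the file.
#' @param omicsLabel label stored in the returned object, e.g. `"gene"`.
#' @param transpose if `TRUE` the file holds features in rows and samples in
#'   columns; the matrix is transposed after reading.
#' @return an [OmicsMatrix-class] with missing entries as `NA`.
#' @export
readExpressionMatrix <- function(path, omicsLabel, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("expression file must have an id column plus at least one feature")
  ids <- dt[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated sample ids in ", path, ": ", paste(dup, collapse = ", "))
  feats <- colnames(dt)[-1L]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup))
    stop("duplicated feature ids in ", path, ": ", paste(dup, collapse = ", "))
  raw <- as.matrix(dt[, -1L, drop = FALSE])
  missing <- raw == "" | raw == "NA" | is.na(raw)
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!missing & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d (sample %s), column %d (%s) in %s",
                 raw[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 bad[1, 2], feats[bad[1, 2]], path))
  }
  num[missing] <- NA_real_
  dimnames(num) <- list(ids, feats)
  if (transpose) num <- t(num)
  OmicsMatrix(num, omicsLabel)
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix()]: sample ids in the first column
#' (`sample_id`), feature ids in the header, missing values written as `NA`.
#'
#' @param x an [OmicsMatrix-class] or numeric matrix with dimnames.
#' @param path output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `invisible(path)`.
#' @export
writeExpressionMatrix <- function(x, path) {
  v <- if (is(x, "OmicsMatrix")) x@values else as.matrix(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  data.table::fwrite(out, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `sample_id`, `observed_time`, `event` (TSV or CSV by
#' extension). Times must be nonnegative and events in \{0, 1\}.
#'
#' @param path path to the file.
#' @return a [SurvivalOutcome-class] in file order.
#' @export
readSurvivalTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  need <- c("sample_id", "observed_time", "event")
  if (!all(need %in% colnames(dt)))
    stop("survival table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(dt$observed_time)) || any(dt$observed_time < 0))
    stop("observed_time must be finite and nonnegative")
  if (!all(dt$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event); found: ",
         paste(unique(setdiff(dt$event, c(0, 1))), collapse = ", "))
  SurvivalOutcome(dt$observed_time, dt$event, dt$sample_id)
}

#' Write a survival table
#'
#' @param outcome a [SurvivalOutcome-class].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
writeSurvivalTable <- function(outcome, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample_id = outcome@sampleIDs,
                    observed_time = outcome@time, event = outcome@event)
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}
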