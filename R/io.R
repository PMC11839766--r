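#' Load a bundled dataset
#'
#' `"table3"` is the package's validation fixture: the 58 test sentences with
#' the expert MAP score and the score the automated protocol assigned each
#' sentence, both on the half-step STAGES grid.  It is the dataset behind the
#' package's worked agreement examples.
#'
#' @param name Fixture name; currently only `"table3"`.
#' @return A tibble with columns `id`, `text`, `map_score`, `stages_score`.
#' @examples
#' fx <- load_fixture("table3")
#' nrow(fx)
#' @export
load_fixture <- function(name = "table3") {
  if (!identical(name, "table3")) {
    abort_stagescore(sprintf("Unknown fixture `%s`.", name), "not_found")
  }
  path <- system.file("extdata", "table3_sentences.csv",
                      package = "stagescore", mustWork = TRUE)
  read_sentences(path)
}

#' Read a sentences CSV
#'
#' Parses a UTF-8 CSV with columns `id`, `text` and optional score columns
#' `map_score` and `stages_score`; scores, when present, are validated
#' against the STAGES grid.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the validated records.
#' @export
read_sentences <- function(path) {
  if (!file.exists(path)) {
    abort_stagescore(sprintf("File not found: %s", path), "not_found")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "text")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_stagescore(
      sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")),
      "format"
    )
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    dup <- unique(data$id[duplicated(data$id)])
    abort_stagescore(
      sprintf("Duplicate id(s): %s.", paste(head(dup, 5), collapse = ", ")),
      "format"
    )
  }
  if (any(is.na(data$text) | !nzchar(trimws(data$text)))) {
    abort_stagescore("Every record must have non-empty text.", "format")
  }
  for (col in intersect(c("map_score", "stages_score"), names(data))) {
    vals <- data[[col]]
    bad <- which(!is.na(vals) & !is_stages_level(vals))
    if (length(bad) > 0) {
      abort_stagescore(
        sprintf("Off-grid %s in row(s) %s: value(s) %s.", col,
                paste(head(bad, 5), collapse = ", "),
                paste(head(vals[bad], 5), collapse = ", ")),
        "invalid_level"
      )
    }
  }
  as_tibble(data)
}

#' Write scoring, agreement and calibration reports
#'
#' Writes whichever results are supplied to `out_dir`:
#' \describe{
#'   \item{`scores`}{sentence scores CSV (`scores.csv`): `id`, `median_q1`,
#'     `median_q2`, `median_q3`, `median_level`, `n_runs`.}
#'   \item{`crosstab`}{the 12 x 12 cross-tabulation with labelled rows and
#'     columns plus `Total` row and column (`crosstab.csv`).}
#'   \item{`agreement`}{agreement JSON (`agreement.json`) with keys `kappa`,
#'     `se`, `ci_low`, `ci_high`, `n`.}
#'   \item{`calibration`}{calibration CSV (`calibration.csv`), written as-is.}
#' }
#' Every tabular file round-trips through the matching reader.
#'
#' @param results A named list with any of the elements above.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a character vector of the files written.
#' @export
write_reports <- function(results, out_dir) {
  stopifnot(is.list(results))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort_stagescore(sprintf("Cannot create directory %s.", out_dir), "io")
  }
  written <- character()
  if (!is.null(results$scores)) {
    path <- file.path(out_dir, "scores.csv")
    cols <- intersect(
      c("id", "text", "map_score", "stages_score", "median_q1", "median_q2",
        "median_q3", "median_level", "n_runs"),
      names(results$scores)
    )
    readr::write_csv(results$scores[cols], path, progress = FALSE)
    written <- c(written, path)
  }
  if (!is.null(results$crosstab)) {
    path <- file.path(out_dir, "crosstab.csv")
    tab <- results$crosstab
    out <- cbind(tab, Total = rowSums(tab))
    out <- rbind(out, Total = colSums(out))
    df <- data.frame(level = rownames(out), out, check.names = FALSE)
    readr::write_csv(df, path, progress = FALSE)
    written <- c(written, path)
  }
  if (!is.null(results$agreement)) {
    path <- file.path(out_dir, "agreement.json")
    x <- results$agreement
    jsonlite::write_json(
      list(kappa = x$kappa, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
           n = x$n),
      path, auto_unbox = TRUE, digits = NA
    )
    written <- c(written, path)
  }
  if (!is.null(results$calibration)) {
    path <- file.path(out_dir, "calibration.csv")
    readr::write_csv(results$calibration, path, progress = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
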