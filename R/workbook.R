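#' Write the 13-sheet results workbook
#'
#' Serializes a completed [rasch_analysis()] as a workbook: a directory
#' bundle holding one CSV per sheet in a fixed, documented order —
#' 01 Settings, 02 Summary, 03 CTT_Items, 04 Item_Difficulties,
#' 05 Item_SEs, 06 Thurstonian_Thresholds, 07 Persons, 08 Orderedness,
#' 09 Item_Flags, 10 Person_Flags, 11 Test_Information, 12 Responses
#' (the full initial matrix), 13 Notes.  Writing is atomic: the bundle
#' is assembled in a temporary directory and moved into place, so an
#' incomplete analysis raises an error rather than leaving a partial
#' workbook.  Numeric values round-trip exactly to stored precision
#' (15 significant digits).
#'
#' @param analysis A `rasch_analysis` object.
#' @param path Directory path for the workbook (conventionally ending
#'   in `.wb`); replaced if it exists.
#' @return Invisibly, a named list of the sheet tables as written.
#' @export
write_results_workbook <- function(analysis, path) {
  required <- c("settings", "ctt", "reliability", "fit", "abilities",
                "thresholds", "orderedness", "person_flags", "test_information")
  missing <- required[!vapply(required, function(f)
    !is.null(analysis[[f]]), logical(1))]
  if (!inherits(analysis, "rasch_analysis") || length(missing)) {
    abort(paste0("incomplete analysis bundle; missing: ",
                 paste(missing, collapse = ", ")))
  }
  sheets <- workbook_sheets(analysis)
  tmp <- tempfile("wb_")
  dir.create(tmp)
  nm <- names(sheets)
  for (i in seq_along(sheets)) {
    readr::write_csv(sheets[[i]], file.path(tmp, sprintf("%02d_%s.csv", i, nm[i])),
                     progress = FALSE)
  }
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  ok <- dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(tmp, path)) {
    # cross-device fallback
    dir.create(path, recursive = TRUE)
    file.copy(list.files(tmp, full.names = TRUE), path)
    unlink(tmp, recursive = TRUE)
  }
  invisible(sheets)
}

workbook_tab_names <- c("Settings", "Summary", "CTT_Items", "Item_Difficulties",
                        "Item_SEs", "Thurstonian_Thresholds", "Persons",
                        "Orderedness", "Item_Flags", "Person_Flags",
                        "Test_Information", "Responses", "Notes")

workbook_sheets <- function(an) {
  fit <- an$fit
  ab <- an$abilities
  se_fin <- ab$se_theta[is.finite(ab$se_theta)]
  summary <- tibble::tibble(
    statistic = c("n_persons", "n_items", "alpha", "alpha_band", "deviance",
                  "n_iterations", "converged", "latent_mean", "latent_sd",
                  "min_person_se", "max_person_se", "mean_theta",
                  "n_items_flagged", "n_persons_flagged"),
    value = as.character(c(nrow(an$data$scores), length(an$data$item_ids),
                           an$reliability$alpha, an$reliability$band,
                           fit$deviance, fit$n_iterations, fit$converged,
                           fit$latent$mean, fit$latent$sd,
                           min(se_fin), max(se_fin),
                           mean(ab$theta[is.finite(ab$theta)]),
                           sum(an$ctt$flags != ""),
                           sum(an$person_flags$flags != "")))
  )
  persons <- tibble::tibble(ID = ab$person_id, Score = ab$raw_score,
                            Max = ab$max_score, Theta = ab$theta,
                            SE = ab$se_theta,
                            Flags = an$person_flags$flags)
  list(
    Settings = an$settings,
    Summary = summary,
    CTT_Items = an$ctt,
    Item_Difficulties = dplyr::select(fit$items, "item_id", "step", "delta"),
    Item_SEs = dplyr::select(fit$items, "item_id", "step", "se"),
    Thurstonian_Thresholds = an$thresholds,
    Persons = persons,
    Orderedness = an$orderedness,
    Item_Flags = dplyr::select(an$ctt, "item_id", "flags"),
    Person_Flags = an$person_flags,
    Test_Information = an$test_information,
    Responses = tibble::as_tibble(as.data.frame(an$data)),
    Notes = tibble::tibble(note = c(an$notes, an$fit$notes))
  )
}

#' Read a sheet from a results workbook
#'
#' @param path Workbook directory written by [write_results_workbook()].
#' @param sheet Sheet name (one of the 13 fixed names).
#' @return The sheet as a tibble.
#' @export
read_workbook_sheet <- function(path, sheet) {
  stopifnot(sheet %in% workbook_tab_names)
  idx <- match(sheet, workbook_tab_names)
  f <- file.path(path, sprintf("%02d_%s.csv", idx, sheet))
  if (!file.exists(f)) {
    abort(paste0("schema error: workbook at '", path, "' lacks the ", sheet, " sheet"))
  }
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}

#' Read item calibration and responses back from a results workbook
#'
#' Returns the pieces needed to re-calibrate or equate: the item (step)
#' difficulties with their standard errors and the full initial
#' response matrix.  A workbook missing a required sheet raises a
#' schema error naming it.
#'
#' @param path Workbook directory written by [write_results_workbook()].
#' @return List: `items` (calibration tibble `item_id`, `step`,
#'   `delta`, `se`), `responses` ([response_matrix()]), `persons`
#'   (persons sheet), `settings`.
#' @export
read_calibration_workbook <- function(path) {
  diffs <- read_workbook_sheet(path, "Item_Difficulties")
  ses <- read_workbook_sheet(path, "Item_SEs")
  items <- dplyr::left_join(diffs, ses, by = c("item_id", "step"))
  class(items) <- c("item_calibration", class(items))
  resp_raw <- read_workbook_sheet(path, "Responses")
  responses <- response_matrix(resp_raw)
  persons <- read_workbook_sheet(path, "Persons")
  settings <- read_workbook_sheet(path, "Settings")
  list(items = items, responses = responses, persons = persons, settings = settings)
}
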