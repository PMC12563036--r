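#' Construct a residue dataset
#'
#' A residue dataset holds the quantified measurements of one monitoring
#' campaign: one row per (sample, pesticide) detection, plus two pieces of
#' campaign metadata that the rows alone cannot carry — the total number of
#' samples analyzed (residue-free samples have no rows) and the analytical
#' limit of quantification (LOQ, mg/kg).
#'
#' @param measurements a data frame with columns `sample_id` (character),
#'   `pesticide` (canonical name) and `concentration` (mg/kg, positive).
#' @param n_samples_total number of samples analyzed, including residue-free
#'   ones; must be at least the number of distinct sample ids present.
#' @param loq limit of quantification, mg/kg (default 0.010).
#' @return an object of class `residue_dataset`.
#' @seealso [read_residues()], [censor_loq()], [summarize_residues()]
#' @export
residue_dataset <- function(measurements, n_samples_total, loq = 0.010) {
  check_positive(loq, "loq")
  check_positive(n_samples_total, "n_samples_total")
  m <- tibble::as_tibble(measurements)
  needed <- c("sample_id", "pesticide", "concentration")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols) > 0) {
    pr_abort(sprintf("Measurements missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  m <- m[needed]
  if (nrow(m) > 0) {
    if (!is.numeric(m$concentration) || anyNA(m$concentration)) {
      pr_abort("Concentrations must all be numeric and non-missing")
    }
    if (any(m$concentration <= 0)) {
      bad <- which(m$concentration <= 0)
      pr_abort(sprintf("Non-positive concentration in row(s): %s",
                       paste(bad, collapse = ", ")))
    }
    key <- paste(m$sample_id, m$pesticide, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      pr_abort(sprintf("Duplicate (sample, pesticide) pair(s): %s",
                       paste(gsub("\r", " / ", dup), collapse = "; ")))
    }
  }
  n_with <- length(unique(m$sample_id))
  if (n_samples_total < n_with) {
    pr_abort(sprintf(
      "n_samples_total (%d) is below the %d distinct samples with measurements",
      n_samples_total, n_with))
  }
  structure(list(measurements = m,
                 n_samples_total = as.integer(n_samples_total),
                 loq = loq,
                 censored_n = 0L),
            class = "residue_dataset")
}

#' @export
print.residue_dataset <- function(x, ...) {
  cat(sprintf("<residue_dataset> %d measurements, %d/%d samples with residues, LOQ %.3f mg/kg\n",
              nrow(x$measurements), length(unique(x$measurements$sample_id)),
              x$n_samples_total, x$loq))
  if (x$censored_n > 0) {
    cat(sprintf("  %d measurement(s) removed below LOQ\n", x$censored_n))
  }
  invisible(x)
}

#' Read residue measurements from CSV
#'
#' Expects columns `sample_id,pesticide,concentration_mg_kg` (a plain
#' `concentration` column is also accepted). Pesticide names are
#' canonicalized with [normalize_name()]; malformed or non-positive
#' concentrations are hard errors naming the offending data row.
#'
#' The bundled file `strawberry_residues_reconstructed.csv` transcribes every
#' published residue value of the 2023-2024 strawberry campaign (83 samples,
#' 31 active substances). The per-sample assignments of values not pinned to a
#' named sample by the study are reconstructed, not measured; see the package
#' vignette.
#'
#' @param path path to the residue CSV.
#' @param n_samples_total total samples analyzed (83 for the bundled campaign).
#' @param loq limit of quantification, mg/kg.
#' @return a [residue_dataset()].
#' @export
read_residues <- function(path, n_samples_total, loq = 0.010) {
  if (!file.exists(path)) {
    pr_abort(sprintf("Residue file not found: %s", path))
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  conc_col <- intersect(c("concentration_mg_kg", "concentration"), names(raw))
  needed <- c("sample_id", "pesticide")
  if (length(conc_col) == 0 || length(setdiff(needed, names(raw))) > 0) {
    pr_abort("Residue CSV needs columns sample_id, pesticide, concentration_mg_kg")
  }
  conc <- suppressWarnings(as.numeric(raw[[conc_col[1]]]))
  bad <- which(is.na(conc) | conc < 0)
  if (length(bad) > 0) {
    pr_abort(sprintf("Malformed or negative concentration at data row(s): %s",
                     paste(bad, collapse = ", ")))
  }
  residue_dataset(
    tibble::tibble(sample_id = raw$sample_id,
                   pesticide = normalize_name(raw$pesticide),
                   concentration = conc),
    n_samples_total = n_samples_total, loq = loq
  )
}

#' Apply limit-of-quantification censoring
#'
#' Removes measurements strictly below `loq` (a value exactly at the LOQ is
#' kept), records how many were removed, and updates the dataset's LOQ. The
#' total sample count is unchanged: a sample whose only residue is censored
#' becomes residue-free, it does not leave the campaign.
#'
#' @param dataset a [residue_dataset()].
#' @param loq censoring threshold, mg/kg.
#' @return the censored `residue_dataset`; the number of rows removed is in
#'   its `censored_n` field.
#' @export
censor_loq <- function(dataset, loq = dataset$loq) {
  stopifnot(inherits(dataset, "residue_dataset"))
  check_positive(loq, "loq")
  keep <- dataset$measurements$concentration >= loq
  out <- dataset
  out$measurements <- dataset$measurements[keep, ]
  out$loq <- loq
  out$censored_n <- dataset$censored_n + sum(!keep)
  out
}

#' Per-pesticide summary statistics
#'
#' For each pesticide, computes the detection count and the mean, minimum,
#' maximum and total concentration over the samples in which it was detected.
#' The mean over detects is the "average pesticide residue" (APR) that feeds
#' the chronic exposure model — note it is conditional on detection and so
#' sits above a mean over all samples.
#'
#' @param dataset a [residue_dataset()].
#' @param pesticide optional canonical name; if given, the summary is
#'   restricted to that substance and its absence is an error.
#' @return a tibble with columns `pesticide`, `n_detect`, `mean`, `min`,
#'   `max`, `total` (concentrations in mg/kg), sorted by pesticide.
#' @examples
#' ds <- read_residues(primorisk_example("strawberry_residues_reconstructed.csv"),
#'                     n_samples_total = 83)
#' summarize_residues(ds, "pyrimethanil")
#' @export
summarize_residues <- function(dataset, pesticide = NULL) {
  stopifnot(inherits(dataset, "residue_dataset"))
  m <- dataset$measurements
  if (!is.null(pesticide)) {
    m <- m[m$pesticide %in% pesticide, ]
    if (nrow(m) == 0) {
      pr_abort(sprintf("No detections for pesticide '%s'",
                       paste(pesticide, collapse = ", ")))
    }
  }
  if (nrow(m) == 0) {
    return(tibble::tibble(pesticide = character(), n_detect = integer(),
                          mean = numeric(), min = numeric(), max = numeric(),
                          total = numeric()))
  }
  m |>
    dplyr::group_by(.data$pesticide) |>
    dplyr::summarise(
      n_detect = dplyr::n(),
      mean = mean(.data$concentration),
      min = min(.data$concentration),
      max = max(.data$concentration),
      total = sum(.data$concentration),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$pesticide)
}

#' Load a published campaign summary table
#'
#' Reads a per-pesticide summary (class, mean, min, max, total, in mg/kg) of
#' the kind monitoring studies publish when the raw per-sample values are not
#' deposited. The bundled `campaign_summary.csv` transcribes the strawberry
#' campaign's published statistics for all 31 substances.
#'
#' @param path path to the summary CSV with columns
#'   `pesticide,class,mean_mg_kg,min_mg_kg,max_mg_kg,total_mg_kg`.
#' @return a tibble with columns `pesticide`, `pclass`, `mean`, `min`, `max`,
#'   `total`.
#' @export
load_campaign_summary <- function(path = primorisk_example("campaign_summary.csv")) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  tibble::tibble(
    pesticide = normalize_name(raw$pesticide),
    pclass = tolower(raw$class),
    mean = raw$mean_mg_kg,
    min = raw$min_mg_kg,
    max = raw$max_mg_kg,
    total = raw$total_mg_kg
  )
}

#' Concentration composition by pesticide and class
#'
#' Expresses each pesticide's total concentration as a percentage of the
#' campaign's grand total, and aggregates those shares by pesticide class.
#' Shares sum to 100 before rounding and are invariant to a uniform rescaling
#' of all concentrations.
#'
#' @param x either a [residue_dataset()] (summarized internally) or a summary
#'   tibble with columns `pesticide` and `total` (e.g. from
#'   [summarize_residues()] or [load_campaign_summary()]).
#' @param refs a `pesticide_ref` table supplying the class of every pesticide
#'   present; an unclassified pesticide is an error.
#' @return a list with tibbles `by_pesticide` (`pesticide`, `pclass`, `total`,
#'   `share_pct`) and `by_class` (`pclass`, `total`, `share_pct`).
#' @export
class_composition <- function(x, refs) {
  if (inherits(x, "residue_dataset")) {
    x <- summarize_residues(x)
  }
  stopifnot(is.data.frame(x), all(c("pesticide", "total") %in% names(x)))
  idx <- match(x$pesticide, refs$pesticide)
  if (anyNA(idx)) {
    pr_abort(sprintf("No class reference for: %s",
                     paste(x$pesticide[is.na(idx)], collapse = ", ")))
  }
  grand <- sum(x$total)
  by_pesticide <- tibble::tibble(
    pesticide = x$pesticide,
    pclass = refs$pclass[idx],
    total = x$total,
    share_pct = x$total / grand * 100
  ) |>
    dplyr::arrange(dplyr::desc(.data$share_pct))
  by_class <- by_pesticide |>
    dplyr::group_by(.data$pclass) |>
    dplyr::summarise(total = sum(.data$total),
                     share_pct = sum(.data$share_pct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share_pct))
  list(by_pesticide = by_pesticide, by_class = by_class)
}

#' Distribution of residues per sample
#'
#' How many samples carried 0, 1, 2, ... distinct residues, as a percentage of
#' all samples analyzed. Residue-free samples are inferred from
#' `n_samples_total` minus the samples with at least one measurement.
#'
#' @param dataset a [residue_dataset()].
#' @return a tibble with columns `n_residues`, `n_samples`, `pct`; `pct` sums
#'   to 100 before rounding.
#' @export
residue_count_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "residue_dataset"))
  per_sample <- table(dataset$measurements$sample_id)
  n_zero <- dataset$n_samples_total - length(per_sample)
  counts <- c(rep(0L, n_zero), as.integer(per_sample))
  tab <- table(counts)
  tibble::tibble(
    n_residues = as.integer(names(tab)),
    n_samples = as.integer(tab),
    pct = as.integer(tab) / dataset$n_samples_total * 100
  )
}
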