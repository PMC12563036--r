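#' Acute exposure: the International Estimated Short-Term Intake (IESTI)
#'
#' Estimates the residue dose ingested in a single day of high consumption of
#' one commodity. The FAO/WHO scheme selects an equation from the commodity
#' unit weight `U` (g) carried by the profile:
#'
#' * Case 1 (`U < 25 g`, e.g. strawberries):
#'   `IESTI = LP_kg * HR * PF * CF / BW`
#' * Case 2a (`U >= 25 g`, unit smaller than the large portion):
#'   `IESTI = (U_kg * HR * v + (LP_kg - U_kg) * HR) * PF * CF / BW`
#' * Case 2b (`U >= 25 g`, unit at least the large portion):
#'   `IESTI = LP_kg * HR * v * PF * CF / BW`
#'
#' where `LP_kg` is the large portion converted from g/day to kg/day, `HR` the
#' highest residue (mg/kg), `PF`/`CF` the processing and conversion factors,
#' `v` the unit-to-unit variability factor and `BW` the body weight (kg).
#'
#' @param hr highest residue, mg/kg (vectorized, >= 0).
#' @param profile a [consumption_profile()].
#' @return IESTI in mg/kg body weight; the attribute `"case_used"` records
#'   which equation applied (`"1"`, `"2a"` or `"2b"`).
#' @examples
#' iesti(0.68, load_consumption_profile())  # 0.0111 mg/kg bw
#' @export
iesti <- function(hr, profile) {
  stopifnot(inherits(profile, "consumption_profile"))
  if (any(is.na(hr)) || any(hr < 0)) {
    pr_abort("Highest residue must be non-negative")
  }
  lp_kg <- profile$large_portion / 1000
  u_kg <- profile$unit_weight / 1000
  fc <- profile$processing_factor * profile$conversion_factor /
    profile$body_weight
  v <- profile$variability_factor
  if (profile$unit_weight < 25) {
    case <- "1"
    out <- lp_kg * hr * fc
  } else if (u_kg < lp_kg) {
    case <- "2a"
    out <- (u_kg * hr * v + (lp_kg - u_kg) * hr) * fc
  } else {
    case <- "2b"
    out <- lp_kg * hr * v * fc
  }
  attr(out, "case_used") <- case
  out
}

#' Exposure as a percentage of its toxicological reference value
#'
#' `percent_arfd()` compares an IESTI to the acute reference dose,
#' `percent_adi()` a NEDI to the acceptable daily intake. Both are acceptable
#' below 100%. A substance without an established reference value cannot be
#' assessed: passing `NA` returns `NA` (reported downstream as
#' "not applicable"), never a silent zero.
#'
#' @param iesti acute exposure, mg/kg bw.
#' @param arfd acute reference dose, mg/kg bw (positive, or `NA` for "not
#'   established").
#' @return percentage at full precision, `NA` where the reference is absent.
#' @examples
#' percent_arfd(0.0111133, 0.15)  # 7.41 (2 dp)
#' @export
percent_arfd <- function(iesti, arfd) {
  if (any(arfd <= 0, na.rm = TRUE)) {
    pr_abort("ARfD must be positive when present")
  }
  as.numeric(iesti) / arfd * 100
}

#' Chronic exposure: the National Estimated Daily Intake (NEDI)
#'
#' `NEDI = APR * mean_consumption / 1000`, where APR is the average residue
#' over samples with detections (mg/kg) and mean consumption is in
#' g/kg bw/day; the division by 1000 converts grams to kilograms. Body weight
#' does not appear because the consumption figure is already per kg of body
#' weight.
#'
#' @param apr average pesticide residue, mg/kg (vectorized, >= 0).
#' @param mean_consumption mean commodity consumption, g/kg bw/day.
#' @return NEDI in mg/kg bw/day.
#' @examples
#' nedi(0.112, 0.344)  # 3.8528e-05
#' @export
nedi <- function(apr, mean_consumption) {
  check_positive(mean_consumption, "mean_consumption")
  if (any(is.na(apr)) || any(apr < 0)) {
    pr_abort("APR must be non-negative")
  }
  apr * mean_consumption / 1000
}

#' @rdname percent_arfd
#' @param nedi chronic exposure, mg/kg bw/day.
#' @param adi acceptable daily intake, mg/kg bw/day (positive, or `NA`).
#' @export
percent_adi <- function(nedi, adi) {
  if (any(adi <= 0, na.rm = TRUE)) {
    pr_abort("ADI must be positive when present")
  }
  as.numeric(nedi) / adi * 100
}

#' Acute dietary risk assessment per pesticide
#'
#' For each detected pesticide, takes the highest residue (HR) across the
#' whole campaign, computes the IESTI under the given consumption profile and
#' expresses it against the substance's ARfD. Substances without an
#' established ARfD are returned with `assessable = FALSE` and `NA`
#' percentages rather than dropped, so the report can list them as
#' "ARfD not applicable".
#'
#' @param dataset a [residue_dataset()].
#' @param refs a `pesticide_ref` table.
#' @param profile a [consumption_profile()].
#' @return a tibble with columns `pesticide`, `hr`, `case_used`, `iesti`,
#'   `arfd`, `percent_arfd`, `assessable`.
#' @examples
#' ds <- read_residues(primorisk_example("strawberry_residues_reconstructed.csv"),
#'                     n_samples_total = 83)
#' acute <- assess_acute(ds, load_reference_table(), load_consumption_profile())
#' acute[which.max(acute$percent_arfd), ]
#' @export
assess_acute <- function(dataset, refs, profile) {
  summ <- summarize_residues(dataset)
  idx <- match(summ$pesticide, refs$pesticide)
  if (anyNA(idx)) {
    pr_abort(sprintf("No reference entry for: %s",
                     paste(summ$pesticide[is.na(idx)], collapse = ", ")))
  }
  expo <- iesti(summ$max, profile)
  arfd <- refs$arfd[idx]
  tibble::tibble(
    pesticide = summ$pesticide,
    hr = summ$max,
    case_used = attr(expo, "case_used"),
    iesti = as.numeric(expo),
    arfd = arfd,
    percent_arfd = percent_arfd(expo, arfd),
    assessable = !is.na(arfd)
  )
}

#' Chronic dietary risk assessment per pesticide
#'
#' For each detected pesticide, computes the NEDI from its average residue
#' over detects (APR) and expresses it against the substance's ADI.
#' Substances without an established ADI are flagged `assessable = FALSE`.
#'
#' @inheritParams assess_acute
#' @return a tibble with columns `pesticide`, `apr`, `nedi`, `adi`,
#'   `percent_adi`, `assessable`.
#' @export
assess_chronic <- function(dataset, refs, profile) {
  summ <- summarize_residues(dataset)
  idx <- match(summ$pesticide, refs$pesticide)
  if (anyNA(idx)) {
    pr_abort(sprintf("No reference entry for: %s",
                     paste(summ$pesticide[is.na(idx)], collapse = ", ")))
  }
  ndi <- nedi(summ$mean, profile$mean_consumption)
  adi <- refs$adi[idx]
  tibble::tibble(
    pesticide = summ$pesticide,
    apr = summ$mean,
    nedi = ndi,
    adi = adi,
    percent_adi = percent_adi(ndi, adi),
    assessable = !is.na(adi)
  )
}

#' Per-sample cumulative hazard index
#'
#' A first-tier screen for the combined acute load of co-occurring residues:
#' within each sample, every residue's own concentration is treated as its
#' highest residue, converted to an IESTI under the profile, expressed as
#' %ARfD, and the percentages are summed. Residues without an established
#' ARfD cannot contribute and are counted as excluded; they are never treated
#' as zero-risk silently.
#'
#' Dose addition across substances with different modes of action is a
#' conservative screening assumption, not a toxicological prediction.
#'
#' @inheritParams assess_acute
#' @param sample_id optional character vector restricting the output to given
#'   samples; a sample with no measurements is an error.
#' @return a tibble with columns `sample_id`, `hi_percent`, `n_residues`,
#'   `n_excluded` (residues lacking an ARfD).
#' @export
hazard_index <- function(dataset, refs, profile, sample_id = NULL) {
  stopifnot(inherits(dataset, "residue_dataset"))
  m <- dataset$measurements
  if (!is.null(sample_id)) {
    missing_s <- setdiff(sample_id, m$sample_id)
    if (length(missing_s) > 0) {
      pr_abort(sprintf("No measurements for sample(s): %s",
                       paste(missing_s, collapse = ", ")))
    }
    m <- m[m$sample_id %in% sample_id, ]
  }
  idx <- match(m$pesticide, refs$pesticide)
  if (anyNA(idx)) {
    pr_abort(sprintf("No reference entry for: %s",
                     paste(unique(m$pesticide[is.na(idx)]), collapse = ", ")))
  }
  arfd <- refs$arfd[idx]
  pct <- percent_arfd(iesti(m$concentration, profile), arfd)
  tibble::tibble(sample_id = m$sample_id, pct = pct) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hi_percent = sum(.data$pct, na.rm = TRUE),
      n_residues = dplyr::n(),
      n_excluded = sum(is.na(.data$pct)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sample_id)
}
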