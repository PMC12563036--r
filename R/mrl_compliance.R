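#' Residue concentration as a percentage of its MRL
#'
#' The maximum residue limit (MRL) is a legal trade limit, not a toxicological
#' threshold; compliance is judged on the unrounded ratio. The report layer
#' rounds half-up to the nearest integer for display (so 122.5% prints as
#' 123%), but a value at exactly 100% of the MRL is compliant: exceedance is a
#' strict inequality on the full-precision ratio.
#'
#' @param concentration residue concentration, mg/kg (vectorized, >= 0).
#' @param mrl maximum residue limit, mg/kg (> 0; an absent MRL is an error —
#'   every substance authorized on the commodity has one).
#' @return concentration/MRL * 100 at full precision.
#' @examples
#' percent_mrl(0.68, 0.4)   # 170
#' percent_mrl(0.735, 0.6)  # 122.5; reported as 123%
#' @export
percent_mrl <- function(concentration, mrl) {
  if (any(is.na(mrl)) || any(mrl <= 0)) {
    pr_abort("MRL must be present and positive")
  }
  if (any(is.na(concentration)) || any(concentration < 0)) {
    pr_abort("Concentration must be non-negative")
  }
  concentration / mrl * 100
}

#' Score a campaign against maximum residue limits
#'
#' Produces one compliance record per measurement and flags the samples with
#' at least one residue strictly above 100% of its MRL as non-compliant.
#'
#' @param dataset a [residue_dataset()].
#' @param refs a `pesticide_ref` table covering every detected pesticide.
#' @return a list with `records` (tibble: `sample_id`, `pesticide`,
#'   `concentration`, `mrl`, `percent_mrl`, `exceeds`) and
#'   `noncompliant_samples` (sorted character vector).
#' @examples
#' ds <- read_residues(primorisk_example("strawberry_residues_reconstructed.csv"),
#'                     n_samples_total = 83)
#' refs <- load_reference_table()
#' assess_compliance(ds, refs)$noncompliant_samples
#' @export
assess_compliance <- function(dataset, refs) {
  stopifnot(inherits(dataset, "residue_dataset"))
  m <- dataset$measurements
  idx <- match(m$pesticide, refs$pesticide)
  if (anyNA(idx)) {
    pr_abort(sprintf("No reference entry for: %s",
                     paste(unique(m$pesticide[is.na(idx)]), collapse = ", ")))
  }
  pct <- if (nrow(m) > 0) percent_mrl(m$concentration, refs$mrl[idx]) else numeric(0)
  records <- tibble::tibble(
    sample_id = m$sample_id,
    pesticide = m$pesticide,
    concentration = m$concentration,
    mrl = refs$mrl[idx],
    percent_mrl = pct,
    exceeds = pct > 100
  )
  list(
    records = records,
    noncompliant_samples = sort(unique(records$sample_id[records$exceeds]))
  )
}
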