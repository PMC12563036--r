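# Shared fixtures and independent brute-force oracles.

fixture_dataset <- function() {
  read_residues(primorisk_example("strawberry_residues_reconstructed.csv"),
                n_samples_total = 83)
}

fixture_refs <- function() load_reference_table()

fixture_profile <- function() load_consumption_profile()

# Minimal in-memory dataset builder for targeted cases.
make_dataset <- function(sample_id, pesticide, concentration,
                         n_samples_total = length(unique(sample_id)),
                         loq = 0.010) {
  residue_dataset(
    tibble::tibble(sample_id = sample_id, pesticide = pesticide,
                   concentration = concentration),
    n_samples_total = n_samples_total, loq = loq
  )
}

# Brute-force oracles: plain loops over raw rows, independent of the
# dplyr-based implementation paths they check.
brute_summary <- function(dataset, pest) {
  v <- c()
  m <- dataset$measurements
  for (i in seq_len(nrow(m))) {
    if (m$pesticide[i] == pest) v <- c(v, m$concentration[i])
  }
  list(n = length(v), mean = sum(v) / length(v), min = min(v), max = max(v),
       total = sum(v))
}

brute_acute <- function(dataset, refs, profile, pest) {
  hr <- brute_summary(dataset, pest)$max
  ie <- (profile$large_portion / 1000) * hr * profile$processing_factor *
    profile$conversion_factor / profile$body_weight
  arfd <- refs$arfd[refs$pesticide == pest]
  list(hr = hr, iesti = ie, percent_arfd = ie / arfd * 100)
}

brute_chronic <- function(dataset, refs, profile, pest) {
  apr <- brute_summary(dataset, pest)$mean
  nd <- apr * profile$mean_consumption / 1000
  adi <- refs$adi[refs$pesticide == pest]
  list(apr = apr, nedi = nd, percent_adi = nd / adi * 100)
}
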