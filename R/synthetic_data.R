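#' Lognormal parameters from a published mean and maximum
#'
#' Monitoring papers typically print only summary statistics, so the generator
#' moment-matches a lognormal concentration law to each substance's published
#' mean and maximum: the mean is matched exactly and the maximum is treated as
#' the upper quantile `p` (default P99). Solving
#' `exp(mu + sigma^2/2) = mean` and `exp(mu + z_p * sigma) = max` gives the
#' smaller root for `sigma`. Degenerate summaries (max equal to mean, or a
#' max too extreme for a real root) fall back to a floor/cap on `sigma`.
#'
#' @param mean,max published mean and maximum concentration, mg/kg.
#' @param p quantile the maximum is assumed to represent.
#' @param sd_floor,sd_cap bounds on the log-scale standard deviation.
#' @return a list with `meanlog` and `sdlog`.
#' @export
lognormal_from_summary <- function(mean, max, p = 0.99,
                                   sd_floor = 0.2, sd_cap = 2) {
  check_positive(mean, "mean")
  check_positive(max, "max")
  z <- stats::qnorm(p)
  delta <- log(max / mean)
  disc <- z^2 - 2 * delta
  sdlog <- if (disc >= 0) z - sqrt(disc) else sd_cap
  sdlog <- min(sd_cap, base::max(sd_floor, sdlog))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Describe a synthetic monitoring campaign
#'
#' A `synthetic_config` is a seeded generative description of a campaign: per
#' pesticide, a Bernoulli detection probability per sample and a lognormal
#' concentration law (mg/kg); globally, the number of samples, the LOQ, fixed
#' co-occurrence pairs (mixed formulations make some substances appear only
#' together), and an optional upper-tail inflation that pushes a chosen
#' substance above its MRL at a given rate.
#'
#' @param pesticides a data frame with columns `pesticide`, `pclass`,
#'   `detection_prob` (0-1), `meanlog`, `sdlog` (> 0).
#' @param n_samples number of samples in the campaign (>= 1).
#' @param loq limit of quantification, mg/kg; generated concentrations never
#'   fall below it.
#' @param seed default integer seed used by [generate_residues()].
#' @param co_occurrence_pairs a data frame with columns `trigger` and
#'   `companion`: wherever the trigger is detected, the companion is forced to
#'   be detected too.
#' @param mrl_exceedance optional list `list(pesticide =, rate =, mrl =)`;
#'   each detected value of that pesticide is replaced, with probability
#'   `rate`, by a draw just above `mrl`.
#' @return an object of class `synthetic_config`.
#' @seealso [default_study_config()], [generate_residues()]
#' @export
synthetic_config <- function(pesticides, n_samples, loq = 0.010, seed = 1L,
                             co_occurrence_pairs = NULL,
                             mrl_exceedance = NULL) {
  p <- tibble::as_tibble(pesticides)
  needed <- c("pesticide", "pclass", "detection_prob", "meanlog", "sdlog")
  if (length(setdiff(needed, names(p))) > 0) {
    pr_abort(sprintf("Pesticide block needs columns: %s",
                     paste(needed, collapse = ", ")))
  }
  if (any(p$detection_prob < 0 | p$detection_prob > 1)) {
    pr_abort("Detection probabilities must lie in [0, 1]")
  }
  if (any(p$sdlog <= 0)) pr_abort("sdlog must be positive")
  if (anyDuplicated(p$pesticide)) pr_abort("Duplicate pesticide in config")
  check_positive(n_samples, "n_samples")
  check_positive(loq, "loq")
  if (!is.null(co_occurrence_pairs)) {
    co <- tibble::as_tibble(co_occurrence_pairs)
    stopifnot(all(c("trigger", "companion") %in% names(co)))
    unknown <- setdiff(c(co$trigger, co$companion), p$pesticide)
    if (length(unknown) > 0) {
      pr_abort(sprintf("Co-occurrence names not in config: %s",
                       paste(unknown, collapse = ", ")))
    }
  } else {
    co <- NULL
  }
  if (!is.null(mrl_exceedance)) {
    stopifnot(all(c("pesticide", "rate", "mrl") %in% names(mrl_exceedance)),
              mrl_exceedance$rate >= 0, mrl_exceedance$rate <= 1,
              mrl_exceedance$mrl > 0,
              mrl_exceedance$pesticide %in% p$pesticide)
  }
  structure(list(pesticides = p, n_samples = as.integer(n_samples),
                 loq = loq, seed = as.integer(seed),
                 co_occurrence_pairs = co,
                 mrl_exceedance = mrl_exceedance),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d pesticides x %d samples, LOQ %.3f, seed %d\n",
              nrow(x$pesticides), x$n_samples, x$loq, x$seed))
  invisible(x)
}

# Published per-substance detection counts of the 83-sample campaign (counts
# stated in the study text where available, otherwise total/mean from the
# campaign summary, which is integer to within 0.1 for every substance).
study_detection_counts <- function() {
  c(hexythiazox = 8, cyflumetofen = 25, tebufenpyrad = 4, bifenazate = 9,
    fenpyroximate = 1, bupirimate = 12, fluxapyroxad = 8, difenoconazole = 5,
    cyflufenamid = 2, penconazole = 4, cyprodinil = 1, fludioxonil = 2,
    ethirimol = 6, pyrimethanil = 6, fluopyram = 12, trifloxystrobin = 9,
    tetraconazole = 13, boscalid = 5, fenhexamid = 5, captan = 1,
    penthiopyrad = 2, azoxystrobin = 1, spinosad = 9, chlorantraniliprole = 3,
    flupyradifurone = 4, "lambda-cyhalothrin" = 1, spirotetramat = 2,
    spinetoram = 5, pirimicarb = 4, emamectin = 6, acetamiprid = 3)
}

#' Default configuration mirroring the strawberry monitoring campaign
#'
#' Builds a [synthetic_config()] whose parameters are the published study
#' conditions: 83 samples, LOQ 0.010 mg/kg, per-substance detection
#' probabilities equal to published detection counts over 83, lognormal
#' concentration laws moment-matched to each substance's published mean and
#' maximum ([lognormal_from_summary()]), and the two fixed co-occurrence
#' pairs the study reports (trifloxystrobin with fluopyram, difenoconazole
#' with fluxapyroxad, both from mixed formulations).
#'
#' @param seed default seed carried by the config.
#' @return a `synthetic_config`.
#' @export
default_study_config <- function(seed = 1L) {
  summ <- load_campaign_summary()
  counts <- study_detection_counts()
  idx <- match(summ$pesticide, names(counts))
  stopifnot(!anyNA(idx))
  params <- purrr::map2(summ$mean, summ$max, lognormal_from_summary)
  pesticides <- tibble::tibble(
    pesticide = summ$pesticide,
    pclass = summ$pclass,
    detection_prob = unname(counts[idx]) / 83,
    meanlog = purrr::map_dbl(params, "meanlog"),
    sdlog = purrr::map_dbl(params, "sdlog")
  )
  synthetic_config(
    pesticides, n_samples = 83, loq = 0.010, seed = seed,
    co_occurrence_pairs = tibble::tibble(
      trigger = c("trifloxystrobin", "difenoconazole"),
      companion = c("fluopyram", "fluxapyroxad")
    )
  )
}

# Deterministic 31-bit stream seed per pesticide, so adding a substance to a
# config does not perturb the draws of the others.
stream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

# Lognormal draw truncated below at loq: redraw (up to 100 attempts), then
# clamp. Redraw preserves the configured detection probability exactly.
draw_above_loq <- function(n, meanlog, sdlog, loq) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in seq_len(100)) {
    below <- x < loq
    if (!any(below)) break
    x[below] <- stats::rlnorm(sum(below), meanlog, sdlog)
  }
  pmax(x, loq)
}

#' Generate a synthetic residue dataset
#'
#' Draws a full campaign from a [synthetic_config()]: for each sample and
#' pesticide, a Bernoulli detection at the configured probability, then a
#' lognormal concentration truncated below at the LOQ (by redraw, so the
#' detection probability is preserved). Co-occurrence pairs are then enforced
#' by adding the companion wherever the trigger fired without it, and the
#' optional MRL-exceedance inflation is applied last. Each pesticide has its
#' own RNG stream derived from the seed and a stable hash of its name, so the
#' output is fully deterministic given the seed and unaffected by adding
#' unrelated substances.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed; defaults to the seed stored in the config.
#' @return a [residue_dataset()].
#' @examples
#' ds <- generate_residues(default_study_config(), seed = 42)
#' residue_count_distribution(ds)
#' @export
generate_residues <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  ids <- paste0(LETTERS[(seq_len(n) - 1L) %% 26L + 1L],
                (seq_len(n) - 1L) %/% 26L + 1L)
  p <- config$pesticides
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    set.seed(stream_seed(seed, p$pesticide[i]))
    hit <- stats::runif(n) < p$detection_prob[i]
    k <- sum(hit)
    if (k == 0) next
    conc <- draw_above_loq(k, p$meanlog[i], p$sdlog[i], config$loq)
    rows[[i]] <- tibble::tibble(sample_id = ids[hit],
                                pesticide = p$pesticide[i],
                                concentration = conc)
  }
  m <- dplyr::bind_rows(rows)
  co <- config$co_occurrence_pairs
  if (!is.null(co)) {
    for (j in seq_len(nrow(co))) {
      trig <- m$sample_id[m$pesticide == co$trigger[j]]
      have <- m$sample_id[m$pesticide == co$companion[j]]
      need <- setdiff(trig, have)
      if (length(need) > 0) {
        ci <- match(co$companion[j], p$pesticide)
        set.seed(stream_seed(seed + 7919L, co$companion[j]))
        m <- dplyr::bind_rows(m, tibble::tibble(
          sample_id = need, pesticide = co$companion[j],
          concentration = draw_above_loq(length(need), p$meanlog[ci],
                                         p$sdlog[ci], config$loq)))
      }
    }
  }
  mx <- config$mrl_exceedance
  if (!is.null(mx) && nrow(m) > 0) {
    sel <- which(m$pesticide == mx$pesticide)
    if (length(sel) > 0) {
      set.seed(stream_seed(seed + 104729L, mx$pesticide))
      flip <- stats::runif(length(sel)) < mx$rate
      m$concentration[sel[flip]] <-
        mx$mrl * stats::runif(sum(flip), 1.05, 1.60)
    }
  }
  if (nrow(m) > 0) {
    m <- dplyr::arrange(m, .data$sample_id, .data$pesticide)
  } else {
    m <- tibble::tibble(sample_id = character(), pesticide = character(),
                        concentration = numeric())
  }
  residue_dataset(m, n_samples_total = n, loq = config$loq)
}

#' Read a synthetic-campaign configuration from YAML
#'
#' The YAML mirrors [synthetic_config()]: top-level `n_samples`, `loq`,
#' `seed`, an optional `co_occurrence_pairs` list of `{trigger, companion}`
#' maps, an optional `mrl_exceedance` map, and a `pesticides` list of maps
#' with `pesticide`, `pclass`, `detection_prob`, `meanlog`, `sdlog`.
#'
#' @param path path to the YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  pest <- dplyr::bind_rows(lapply(y$pesticides, tibble::as_tibble))
  co <- if (!is.null(y$co_occurrence_pairs)) {
    dplyr::bind_rows(lapply(y$co_occurrence_pairs, tibble::as_tibble))
  }
  synthetic_config(
    pest,
    n_samples = y$n_samples,
    loq = y$loq %||% 0.010,
    seed = y$seed %||% 1L,
    co_occurrence_pairs = co,
    mrl_exceedance = y$mrl_exceedance
  )
}
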