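#' Canonical active-substance names and spelling variants
#'
#' Monitoring tables for the same campaign often mix languages and trade
#' spellings for one active substance (e.g. "Pirimentanil" vs "pyrimethanil",
#' "Lambda cialotrina" vs "lambda-cyhalothrin"). `pesticide_synonyms()` returns
#' the bundled mapping from lower-cased raw spellings to canonical names;
#' `normalize_name()` applies it.
#'
#' `normalize_name()` is idempotent: canonical names map to themselves. A name
#' that is neither canonical nor a known variant is returned lower-cased and
#' whitespace-trimmed, with a warning naming it, so unexpected substances are
#' visible but do not stop a pipeline.
#'
#' @param x character vector of raw pesticide names.
#' @return `normalize_name()`: character vector of canonical names.
#'   `pesticide_synonyms()`: named character vector (names are lower-cased raw
#'   spellings, values canonical names).
#' @examples
#' normalize_name(c("Pirimentanil", "Lambda cialotrina", "pyrimethanil"))
#' @export
normalize_name <- function(x) {
  syn <- pesticide_synonyms()
  key <- tolower(trimws(x))
  key <- gsub("\\s+", " ", key)
  out <- unname(syn[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    miss <- setdiff(unique(key[unknown]), "")
    if (length(miss) > 0) {
      rlang::warn(paste0("Unrecognized pesticide name(s), passed through ",
                         "lower-cased: ", paste(miss, collapse = ", ")))
    }
    out[unknown] <- key[unknown]
  }
  out
}

#' @rdname normalize_name
#' @export
pesticide_synonyms <- function() {
  canonical <- c(
    "hexythiazox", "cyflumetofen", "tebufenpyrad", "bifenazate",
    "fenpyroximate", "bupirimate", "fluxapyroxad", "difenoconazole",
    "cyflufenamid", "penconazole", "cyprodinil", "fludioxonil", "ethirimol",
    "pyrimethanil", "fluopyram", "trifloxystrobin", "tetraconazole",
    "boscalid", "fenhexamid", "captan", "penthiopyrad", "azoxystrobin",
    "spinosad", "chlorantraniliprole", "flupyradifurone",
    "lambda-cyhalothrin", "spirotetramat", "spinetoram", "pirimicarb",
    "emamectin", "acetamiprid"
  )
  variants <- c(
    "hexithiazox"         = "hexythiazox",
    "tebufenaprid"        = "tebufenpyrad",
    "bifenazato"          = "bifenazate",
    "bupirimato"          = "bupirimate",
    "difenconazolo"       = "difenoconazole",
    "difenoconazolo"      = "difenoconazole",
    "penconazolo"         = "penconazole",
    "etirimol"            = "ethirimol",
    "pirimentanil"        = "pyrimethanil",
    "tetraconazolo"       = "tetraconazole",
    "captano"             = "captan",
    "clorantraniliprolo"  = "chlorantraniliprole",
    "lambda cialotrina"   = "lambda-cyhalothrin",
    "lambda cyhalothrin"  = "lambda-cyhalothrin",
    "spirotetrammato"     = "spirotetramat",
    "emamectina"          = "emamectin",
    "emamectin benzoate"  = "emamectin"
  )
  c(stats::setNames(canonical, canonical), variants)
}

#' Load a toxicological reference table
#'
#' Reads per-substance regulatory constants: pesticide class, maximum residue
#' limit (MRL, mg/kg), acute reference dose (ARfD, mg/kg body weight) and
#' acceptable daily intake (ADI, mg/kg bw/day). ARfD and ADI are not
#' established for every substance; `-`, `Not applicable` or an empty field
#' load as `NA` ("not established"), which downstream assessments report as
#' not applicable rather than treating as zero or infinity.
#'
#' The expected columns are
#' `pesticide,class,mrl_mg_kg,arfd_mg_kg_bw,adi_mg_kg_bw_day`. Lines starting
#' with `#` are comments. Names are canonicalized with [normalize_name()].
#'
#' @param path path to a reference CSV. Defaults to the bundled table of the
#'   31 substances detected in the 2023-2024 strawberry monitoring campaign.
#' @return a tibble of class `pesticide_ref` with columns `pesticide`,
#'   `pclass`, `mrl`, `arfd`, `adi`.
#' @seealso [write_reference_table()], [load_consumption_profile()]
#' @export
load_reference_table <- function(path = primorisk_example("pesticide_reference.csv")) {
  if (!file.exists(path)) {
    pr_abort(sprintf("Reference table not found: %s", path))
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("pesticide", "class", "mrl_mg_kg", "arfd_mg_kg_bw",
              "adi_mg_kg_bw_day")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    pr_abort(sprintf("Reference table missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  parse_ref_num <- function(x) {
    x <- trimws(x)
    absent <- is.na(x) | x == "" | x == "-" |
      tolower(x) %in% c("not applicable", "na", "n/a")
    val <- suppressWarnings(as.numeric(x))
    bad <- !absent & is.na(val)
    if (any(bad)) {
      pr_abort(sprintf("Non-numeric reference value(s): %s",
                       paste(unique(x[bad]), collapse = ", ")))
    }
    val[absent] <- NA_real_
    val
  }
  refs <- tibble::tibble(
    pesticide = normalize_name(raw$pesticide),
    pclass = tolower(trimws(raw$class)),
    mrl = parse_ref_num(raw$mrl_mg_kg),
    arfd = parse_ref_num(raw$arfd_mg_kg_bw),
    adi = parse_ref_num(raw$adi_mg_kg_bw_day)
  )
  validate_reference_table(refs)
}

validate_reference_table <- function(refs) {
  dup <- refs$pesticide[duplicated(refs$pesticide)]
  if (length(dup) > 0) {
    pr_abort(sprintf("Duplicate canonical pesticide name(s): %s",
                     paste(unique(dup), collapse = ", ")))
  }
  bad_mrl <- which(is.na(refs$mrl) | refs$mrl <= 0)
  if (length(bad_mrl) > 0) {
    pr_abort(sprintf("Non-positive or missing MRL for row(s): %s",
                     paste(refs$pesticide[bad_mrl], collapse = ", ")))
  }
  if (any(refs$arfd <= 0, na.rm = TRUE) || any(refs$adi <= 0, na.rm = TRUE)) {
    pr_abort("ARfD and ADI must be positive when present")
  }
  ok_class <- c("fungicide", "acaricide", "insecticide")
  bad_class <- setdiff(unique(refs$pclass), ok_class)
  if (length(bad_class) > 0) {
    pr_abort(sprintf("Unknown pesticide class(es): %s",
                     paste(bad_class, collapse = ", ")))
  }
  class(refs) <- c("pesticide_ref", class(refs))
  refs
}

#' Write a reference table back to CSV
#'
#' Inverse of [load_reference_table()]: absent ARfD/ADI are written as `-`.
#' Loading the written file yields an identical table.
#'
#' @param refs a `pesticide_ref` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(refs, path) {
  fmt <- function(x) ifelse(is.na(x), "-", format(x, scientific = FALSE,
                                                  trim = TRUE))
  out <- tibble::tibble(
    pesticide = refs$pesticide,
    class = refs$pclass,
    mrl_mg_kg = fmt(refs$mrl),
    arfd_mg_kg_bw = fmt(refs$arfd),
    adi_mg_kg_bw_day = fmt(refs$adi)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Consumption profile for a population subgroup
#'
#' A consumption profile carries the population parameters that drive both
#' exposure models: body weight (kg), large portion (g/day, the high-end
#' single-day consumption used for acute exposure), mean consumption
#' (g/kg bw/day, used for chronic exposure), commodity unit weight (g, which
#' selects the IESTI case), and dimensionless processing, conversion and
#' variability factors.
#'
#' The bundled default is the "NL toddler" subgroup of the EU PRIMo model
#' (8-20 months; body weight 10.20 kg, large portion 166.70 g/day, mean
#' strawberry consumption 0.344 g/kg bw/day), the most exposure-sensitive
#' European subgroup per kg body weight for this commodity.
#'
#' @param label population-group label.
#' @param body_weight body weight, kg.
#' @param large_portion large portion, g/day.
#' @param mean_consumption mean consumption, g/kg bw/day.
#' @param unit_weight commodity unit weight, g. Below 25 g the acute
#'   assessment uses IESTI Case 1; above, Case 2a or 2b.
#' @param processing_factor,conversion_factor,variability_factor dimensionless
#'   factors; the variability factor is used only in IESTI Cases 2a/2b.
#' @return an object of class `consumption_profile`.
#' @examples
#' nl_toddler <- load_consumption_profile()
#' nl_toddler$body_weight
#' @export
consumption_profile <- function(label, body_weight, large_portion,
                                mean_consumption, unit_weight,
                                processing_factor = 1, conversion_factor = 1,
                                variability_factor = 1) {
  check_positive(body_weight, "body_weight")
  check_positive(large_portion, "large_portion")
  check_positive(mean_consumption, "mean_consumption")
  check_positive(unit_weight, "unit_weight")
  check_positive(processing_factor, "processing_factor")
  check_positive(conversion_factor, "conversion_factor")
  check_positive(variability_factor, "variability_factor")
  structure(
    list(label = as.character(label), body_weight = body_weight,
         large_portion = large_portion, mean_consumption = mean_consumption,
         unit_weight = unit_weight, processing_factor = processing_factor,
         conversion_factor = conversion_factor,
         variability_factor = variability_factor),
    class = "consumption_profile"
  )
}

#' @rdname consumption_profile
#' @param path path to a profile CSV with columns `label,body_weight_kg,
#'   large_portion_g_day,mean_consumption_g_kgbw_day,unit_weight_g,
#'   processing_factor,conversion_factor,variability_factor`. Defaults to the
#'   bundled profiles file.
#' @export
load_consumption_profile <- function(label = "NL toddler",
                                     path = primorisk_example("consumption_profiles.csv")) {
  if (!file.exists(path)) {
    pr_abort(sprintf("Consumption profile file not found: %s", path))
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  row <- raw[raw$label == label, ]
  if (nrow(row) != 1L) {
    pr_abort(sprintf("Profile '%s' not found (available: %s)", label,
                     paste(raw$label, collapse = ", ")))
  }
  consumption_profile(
    label = row$label,
    body_weight = row$body_weight_kg,
    large_portion = row$large_portion_g_day,
    mean_consumption = row$mean_consumption_g_kgbw_day,
    unit_weight = row$unit_weight_g,
    processing_factor = row$processing_factor,
    conversion_factor = row$conversion_factor,
    variability_factor = row$variability_factor
  )
}

#' @export
print.consumption_profile <- function(x, ...) {
  cat(sprintf("<consumption_profile> %s\n", x$label))
  cat(sprintf("  body weight      %.2f kg\n", x$body_weight))
  cat(sprintf("  large portion    %.2f g/day\n", x$large_portion))
  cat(sprintf("  mean consumption %.3f g/kg bw/day\n", x$mean_consumption))
  cat(sprintf("  unit weight      %.1f g (IESTI case %s)\n", x$unit_weight,
              if (x$unit_weight < 25) "1" else "2a/2b"))
  cat(sprintf("  PF %.2f  CF %.2f  variability %.2f\n", x$processing_factor,
              x$conversion_factor, x$variability_factor))
  invisible(x)
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
primorisk_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "primorisk"))
  } else {
    system.file("extdata", file, package = "primorisk", mustWork = TRUE)
  }
}
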