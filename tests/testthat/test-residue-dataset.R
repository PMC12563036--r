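test_that("the campaign fixture reads cleanly and is canonicalized", {
  ds <- fixture_dataset()
  expect_equal(nrow(ds$measurements), 149)
  expect_equal(length(unique(ds$measurements$pesticide)), 31)
  expect_equal(ds$n_samples_total, 83L)
  # mixed-language spellings in the file arrive canonical
  expect_false(any(grepl("[A-Z]", ds$measurements$pesticide)))
  expect_true("pyrimethanil" %in% ds$measurements$pesticide)
})

test_that("reading rejects malformed rows and duplicate pairs", {
  hdr <- "sample_id,pesticide,concentration_mg_kg"
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "A1,captan,0.02", "A2,captan,abc"), bad)
  expect_error(read_residues(bad, n_samples_total = 2), "row\\(s\\): 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "A1,captan,0.02", "A1,Captano,0.03"), dup)
  expect_error(read_residues(dup, n_samples_total = 2), "Duplicate")

  two <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "A1,captan,0.02", "A2,boscalid,0.05"), two)
  expect_equal(nrow(read_residues(two, n_samples_total = 5)$measurements), 2)

  expect_error(make_dataset("A1", "captan", 0.5, n_samples_total = 0),
               "n_samples_total")
})

test_that("LOQ censoring keeps the boundary, drops below, counts removals", {
  ds <- make_dataset(c("A1", "A2", "A3"), rep("captan", 3),
                     c(0.009, 0.010, 0.5), loq = 0.005)
  cen <- censor_loq(ds, 0.010)
  expect_equal(sort(cen$measurements$concentration), c(0.010, 0.5))
  expect_equal(cen$censored_n, 1L)
  expect_equal(cen$n_samples_total, ds$n_samples_total)

  # fixture values are all at or above the campaign LOQ
  fx <- censor_loq(fixture_dataset(), 0.010)
  expect_equal(fx$censored_n, 0L)

  # heavy censoring agrees with an independent linear scan
  fx2 <- censor_loq(fixture_dataset(), 0.2)
  raw <- fixture_dataset()$measurements$concentration
  expect_equal(fx2$censored_n, sum(raw < 0.2))
  expect_true(all(fx2$measurements$concentration >= 0.2))
})

test_that("per-pesticide summaries reproduce the published statistics", {
  ds <- fixture_dataset()
  pyr <- summarize_residues(ds, "pyrimethanil")
  expect_equal(pyr$n_detect, 6L)
  expect_equal(pyr$total, 3.806)
  expect_equal(round(pyr$mean, 3), 0.634)
  expect_equal(pyr$max, 2.000)

  bup <- summarize_residues(ds, "bupirimate")
  expect_equal(bup$total, 1.508)
  expect_equal(round(bup$mean, 3), 0.126)

  cap <- summarize_residues(ds, "captan")
  expect_equal(unlist(cap[c("mean", "min", "max", "total")]),
               c(mean = 0.030, min = 0.030, max = 0.030, total = 0.030))

  expect_error(summarize_residues(ds, "glyphosate"), "No detections")
})

test_that("summaries agree with a brute-force pass for every fixture pesticide", {
  ds <- fixture_dataset()
  summ <- summarize_residues(ds)
  for (i in seq_len(nrow(summ))) {
    ref <- brute_summary(ds, summ$pesticide[i])
    expect_equal(summ$n_detect[i], ref$n)
    expect_equal(summ$mean[i], ref$mean)
    expect_equal(summ$min[i], ref$min)
    expect_equal(summ$max[i], ref$max)
    expect_equal(summ$total[i], ref$total)
    expect_lt(abs(summ$total[i] - summ$mean[i] * summ$n_detect[i]), 1e-9)
    expect_true(summ$min[i] <= summ$mean[i] && summ$mean[i] <= summ$max[i])
  }
})

test_that("class composition reproduces the published campaign shares", {
  cc <- class_composition(load_campaign_summary(), fixture_refs())
  by_p <- cc$by_pesticide
  by_c <- cc$by_class
  expect_equal(sum(by_p$share_pct), 100)
  expect_equal(sum(by_c$share_pct), 100)
  expect_equal(round_half_up(by_c$share_pct[by_c$pclass == "fungicide"]), 66)
  expect_equal(round_half_up(by_p$share_pct[by_p$pesticide == "pyrimethanil"], 2), 21.60)
  expect_equal(round_half_up(by_p$share_pct[by_p$pesticide == "fluxapyroxad"], 2), 12.14)
  expect_equal(round_half_up(by_p$share_pct[by_p$pesticide == "cyflumetofen"], 2), 15.91)
})

test_that("composition shares are scale-invariant and normalize trivially", {
  summ <- load_campaign_summary()
  refs <- fixture_refs()
  scaled <- summ
  scaled$total <- scaled$total * 7.3
  expect_equal(class_composition(scaled, refs)$by_pesticide$share_pct,
               class_composition(summ, refs)$by_pesticide$share_pct)

  one <- summ[summ$pesticide == "captan", ]
  cc1 <- class_composition(one, refs)
  expect_equal(cc1$by_pesticide$share_pct, 100)
  expect_equal(cc1$by_class$share_pct, 100)

  expect_error(
    class_composition(tibble::tibble(pesticide = "glyphosate", total = 1), refs),
    "No class reference")
})

test_that("residue-count distribution counts zero-residue samples and sums to 100", {
  ds <- make_dataset(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6", "S7", "S6", "S7", "S8", "S8"),
    pesticide = c(rep("captan", 5), "boscalid", "boscalid", "captan", "captan",
                  "captan", "boscalid"),
    concentration = rep(0.05, 11), n_samples_total = 10
  )
  d <- residue_count_distribution(ds)
  expect_equal(d$pct[d$n_residues == 0], 20)
  expect_equal(d$pct[d$n_residues == 1], 50)
  expect_equal(d$pct[d$n_residues == 2], 30)

  empty <- residue_dataset(
    tibble::tibble(sample_id = character(), pesticide = character(),
                   concentration = numeric()), n_samples_total = 5)
  de <- residue_count_distribution(empty)
  expect_equal(de$pct, 100)
  expect_equal(de$n_residues, 0L)

  one <- make_dataset(rep("D2", 7), paste0("p", 1:7), rep(0.05, 7))
  expect_warning(d1 <- residue_count_distribution(one), NA)
  expect_equal(d1$n_residues, 7L)
  expect_equal(d1$pct, 100)

  fx <- residue_count_distribution(fixture_dataset())
  expect_equal(sum(fx$pct), 100)
  # integer rounding can drift by at most half a point per category
  expect_lte(abs(sum(round_half_up(fx$pct)) - 100), length(fx$pct) / 2)
})
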