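test_that("IESTI Case 1 reproduces the worked acute example", {
  prof <- fixture_profile()
  e <- iesti(0.68, prof)
  expect_equal(attr(e, "case_used"), "1")
  expect_equal(signif(as.numeric(e), 3), 0.0111)
  expect_equal(as.numeric(iesti(0, prof)), 0)
  expect_equal(as.numeric(iesti(0.133, prof)), 0.133 * 0.1667 / 10.20)
  expect_error(iesti(-1, prof), "non-negative")
})

test_that("IESTI cases 2a/2b follow the unit-weight scheme", {
  p2a <- consumption_profile("peach eater", body_weight = 60,
                             large_portion = 300, mean_consumption = 1,
                             unit_weight = 150, variability_factor = 3)
  e2a <- iesti(1, p2a)
  expect_equal(attr(e2a, "case_used"), "2a")
  expect_equal(as.numeric(e2a), (0.150 * 1 * 3 + (0.300 - 0.150) * 1) / 60)

  p2b <- consumption_profile("melon eater", body_weight = 60,
                             large_portion = 300, mean_consumption = 1,
                             unit_weight = 800, variability_factor = 3)
  e2b <- iesti(1, p2b)
  expect_equal(attr(e2b, "case_used"), "2b")
  expect_equal(as.numeric(e2b), 0.300 * 1 * 3 / 60)
})

test_that("exposure is linear in the residue and scales as 1/BW; NEDI ignores BW", {
  prof <- fixture_profile()
  expect_equal(as.numeric(iesti(0.4, prof)), 2 * as.numeric(iesti(0.2, prof)))
  heavy <- consumption_profile(prof$label, body_weight = 2 * prof$body_weight,
                               large_portion = prof$large_portion,
                               mean_consumption = prof$mean_consumption,
                               unit_weight = prof$unit_weight)
  expect_equal(as.numeric(iesti(0.4, heavy)), as.numeric(iesti(0.4, prof)) / 2)
  expect_equal(nedi(0.4, 0.344), 2 * nedi(0.2, 0.344))
})

test_that("percentage-of-reference operations reproduce the worked figures", {
  prof <- fixture_profile()
  expect_equal(round_half_up(percent_arfd(iesti(0.68, prof), 0.15), 2), 7.41)
  expect_equal(percent_arfd(0.15, 0.15), 100)
  expect_equal(round_half_up(percent_arfd(iesti(0.133, prof), 0.02), 2), 10.87)
  expect_true(is.na(percent_arfd(0.01, NA_real_)))
  expect_error(percent_arfd(0.01, -0.1), "positive")

  expect_equal(nedi(0.112, 0.344), 0.000038528)
  expect_equal(nedi(0, 0.344), 0)
  expect_equal(nedi(0.022, 0.344), 7.568e-06)
  expect_equal(round_half_up(percent_adi(0.000038528, 0.17), 3), 0.023)
  expect_equal(percent_adi(0.17, 0.17), 100)
  expect_equal(round_half_up(percent_adi(nedi(0.015, 0.344), 0.0025), 2), 0.21)
  expect_true(is.na(percent_adi(0.01, NA_real_)))
})

test_that("campaign acute assessment matches the published table structure", {
  acute <- assess_acute(fixture_dataset(), fixture_refs(), fixture_profile())
  expect_equal(sum(acute$assessable), 19)
  expect_equal(sum(!acute$assessable), 12)
  expect_true(all(acute$percent_arfd[acute$assessable] < 100))
  expect_true(all(is.na(acute$percent_arfd[!acute$assessable])))
  expect_equal(acute$case_used, rep("1", 31))

  top <- acute[which.max(acute$percent_arfd), ]
  expect_equal(top$pesticide, "tebufenpyrad")
  expect_equal(round_half_up(top$percent_arfd, 2), 10.87)

  single <- assess_acute(make_dataset("A1", "captan", 0.03),
                         fixture_refs(), fixture_profile())
  expect_equal(single$hr, 0.03)
})

test_that("campaign chronic assessment reproduces published %ADI spot values", {
  chronic <- assess_chronic(fixture_dataset(), fixture_refs(), fixture_profile())
  g <- function(p) chronic[chronic$pesticide == p, ]
  expect_equal(round_half_up(g("fluxapyroxad")$percent_adi, 2), 0.46)
  expect_equal(round_half_up(g("tebufenpyrad")$percent_adi, 2), 0.25)
  expect_equal(round_half_up(g("lambda-cyhalothrin")$percent_adi, 2), 0.21)
  expect_false(g("ethirimol")$assessable)
  expect_true(is.na(g("ethirimol")$percent_adi))
  expect_true(all(chronic$percent_adi < 100, na.rm = TRUE))
})

test_that("acute and chronic assessments agree with brute-force recomputation", {
  ds <- fixture_dataset()
  refs <- fixture_refs()
  prof <- fixture_profile()
  acute <- assess_acute(ds, refs, prof)
  chronic <- assess_chronic(ds, refs, prof)
  for (p in acute$pesticide[acute$assessable]) {
    ba <- brute_acute(ds, refs, prof, p)
    expect_equal(acute$iesti[acute$pesticide == p], ba$iesti)
    expect_equal(acute$percent_arfd[acute$pesticide == p], ba$percent_arfd)
  }
  for (p in chronic$pesticide[chronic$assessable]) {
    bc <- brute_chronic(ds, refs, prof, p)
    expect_equal(chronic$nedi[chronic$pesticide == p], bc$nedi)
    expect_equal(chronic$percent_adi[chronic$pesticide == p], bc$percent_adi)
  }
})

test_that("hazard index sums per-sample %ARfD and reports exclusions", {
  refs <- fixture_refs()
  prof <- fixture_profile()

  # two residues whose individual %ARfD are 4.25 and 4.90 sum to 9.15
  two <- make_dataset(c("Z1", "Z1"), c("fluxapyroxad", "lambda-cyhalothrin"),
                      c(0.65, 0.015))
  hi <- hazard_index(two, refs, prof)
  expect_equal(round_half_up(hi$hi_percent, 2), 9.15)
  expect_equal(hi$n_excluded, 0L)

  # a single residue: HI equals its own %ARfD
  one <- make_dataset("Z1", "tebufenpyrad", 0.133)
  hi1 <- hazard_index(one, refs, prof)
  expect_equal(hi1$hi_percent,
               percent_arfd(as.numeric(iesti(0.133, prof)), 0.02))

  # residues without an ARfD contribute nothing but are counted
  none <- make_dataset(c("Z1", "Z1"), c("pyrimethanil", "boscalid"),
                       c(0.1, 0.1))
  hi0 <- hazard_index(none, refs, prof)
  expect_equal(hi0$hi_percent, 0)
  expect_equal(hi0$n_excluded, 2L)

  expect_error(hazard_index(one, refs, prof, sample_id = "Z9"), "Z9")
})
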