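adequacy <- component_spec("fruits", "adequacy", full_score_cutoff = 200,
                           zero_score_cutoff = 0)
limit <- component_spec("sodium", "limit", full_score_cutoff = 1500,
                        zero_score_cutoff = 3000)
band <- component_spec("eggs", "range", full_score_cutoff = c(2, 4),
                       zero_score_cutoff = c(0, 8))

test_that("component scoring interpolates linearly and clamps to [0, 10]", {
  expect_equal(score_component(c(0, 100, 200, 500), adequacy),
               c(0, 5, 10, 10))
  # lower intakes of a limited component earn the full 10 points
  expect_equal(score_component(0, limit), 10)
  expect_equal(score_component(c(1500, 2250, 3000, 4000), limit),
               c(10, 5, 0, 0))
  # band components: 10 inside the band, linear ramps outside
  expect_equal(score_component(c(0, 1, 2, 3, 4, 6, 8, 10), band),
               c(0, 5, 10, 10, 10, 5, 0, 0))
  expect_error(score_component(-1, adequacy), "non-negative")
})

test_that("component scores are monotone in the stated direction", {
  x <- seq(0, 500, length.out = 101)
  expect_true(all(diff(score_component(x, adequacy)) >= 0))
  x <- seq(0, 4000, length.out = 101)
  expect_true(all(diff(score_component(x, limit)) <= 0))
  # scoring a score-consistent intake again cannot leave [0, 10]
  s <- score_component(runif(50, 0, 5000), limit)
  expect_true(all(s >= 0 & s <= 10))
})

test_that("index is the sum of 16 components, bounded and symmetric", {
  expect_equal(compute_index(rep(10, 16)), 160)
  expect_equal(compute_index(rep(0, 16)), 0)
  expect_equal(compute_index(c(rep(10, 8), rep(0, 8))), 80)
  set.seed(1)
  s <- runif(16, 0, 10)
  expect_equal(compute_index(s), compute_index(sample(s)))
  # Lipschitz: changing components moves the index by at most the sum of
  # the component moves
  s2 <- pmin(pmax(s + runif(16, -1, 1), 0), 10)
  expect_lte(abs(compute_index(s2) - compute_index(s)), sum(abs(s2 - s)))
  expect_error(compute_index(rep(5, 15)), "16 component")
  expect_error(compute_index(rep(12, 16)), "\\[0, 10\\]")
  # matrix input: one index per row
  m <- rbind(rep(10, 16), rep(0, 16))
  expect_equal(compute_index(m), c(160, 0))
})

test_that("percentile caps come from the per-country intake distribution", {
  sp <- component_spec("whole_grains", "adequacy", full_score_cutoff = 100,
                       zero_score_cutoff = 0,
                       cap_rule = list(percentile = 100))
  intakes <- data.frame(subject_id = 1:3, country = "A",
                        whole_grains = c(1, 2, 3))
  capped <- derive_caps(intakes, list(sp))
  expect_equal(capped$A[[1]]$full_score_cutoff, 3)

  set.seed(42)
  sp85 <- component_spec("sweets", "limit", full_score_cutoff = 0.1,
                         zero_score_cutoff = 0.9,
                         cap_rule = list(percentile = 85))
  x <- runif(100)
  intakes <- data.frame(subject_id = 1:100, country = "B", sweets = x)
  capped <- derive_caps(intakes, list(sp85))
  expect_equal(capped$B[[1]]$zero_score_cutoff, quantile_oracle(x, 0.85))
  expect_lt(abs(capped$B[[1]]$zero_score_cutoff - 0.85), 0.1)

  # no cap rule: spec passes through unchanged
  capped <- derive_caps(intakes, list(limit))
  expect_equal(capped$B[[1]], limit)

  # empty stratum is an error naming the stratum
  intakes$country <- factor("B", levels = c("A", "B"))
  expect_error(derive_caps(intakes, list(sp85)), "'A'")
})

test_that("exclusion filters partition records with first-match reasons", {
  rec <- data.frame(
    subject_id = paste0("S", 1:6),
    complete = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    supplement_data_present = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    energy_kcal = c(2000, 400, 2000, 2000, 3600, 4000))
  out <- apply_exclusions(rec)
  expect_equal(out$kept$subject_id, "S1")
  expect_equal(out$excluded$reason[match(paste0("S", 2:6),
                                         out$excluded$subject_id)],
               c("low_energy", "missing_supplement_data",
                 "incomplete_diet", "high_energy", "incomplete_diet"))
  # exact partition of the input
  expect_equal(sort(c(out$kept$subject_id, out$excluded$subject_id)),
               sort(rec$subject_id))
  # the energy bounds are strict: exactly 500 / 3500 kcal are kept
  border <- data.frame(subject_id = c("A", "B"), complete = TRUE,
                       supplement_data_present = TRUE,
                       energy_kcal = c(500, 3500))
  expect_equal(nrow(apply_exclusions(border)$kept), 2L)
  empty <- apply_exclusions(rec[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("example spec file loads, round-trips and scores a full diet", {
  specs <- example_component_specs()
  expect_length(specs, 16L)
  expect_setequal(vapply(specs, `[[`, character(1), "kind"),
                  c("adequacy", "limit", "range"))
  tmp <- tempfile(fileext = ".yaml")
  write_component_specs(specs, tmp)
  specs2 <- read_component_specs(tmp)
  expect_equal(specs2, specs)

  # an intake profile hitting every full-score band scores the maximum
  full <- lapply(specs, function(sp)
    if (sp$kind == "range") mean(sp$full_score_cutoff)
    else if (sp$kind == "limit") 0
    else sp$full_score_cutoff)
  names(full) <- vapply(specs, `[[`, character(1), "name")
  intakes <- cbind(data.frame(subject_id = "S1", country = "A"),
                   as.data.frame(full))
  scored <- score_intakes(intakes, specs)
  expect_equal(scored$index, 160)
})
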