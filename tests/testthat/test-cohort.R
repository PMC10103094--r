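test_that("eligibility applies strict age, one-year history, and valid zip", {
  p <- data.frame(
    person_id = 1:6,
    age = c(13, 14, 40, 40, 40, 40),
    history_days = c(400, 400, 364, 365, 400, 400),
    zip3 = c("021", "021", "021", "021", NA, ""),
    stringsAsFactors = FALSE
  )
  expect_identical(apply_eligibility(p), c(2L, 4L))
})

test_that("eligibility is monotone in age and history", {
  set.seed(42)
  p <- data.frame(
    person_id = 1:200,
    age = sample(5:90, 200, replace = TRUE),
    history_days = sample(0:1000, 200, replace = TRUE),
    zip3 = sample(c("021", NA), 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  before <- apply_eligibility(p)
  p$age <- p$age + sample(0:5, 200, replace = TRUE)
  p$history_days <- p$history_days + sample(0:100, 200, replace = TRUE)
  after <- apply_eligibility(p)
  expect_true(all(before %in% after))
})

test_that("severity binarization groups hospitalized levels and missing scores", {
  expect_identical(binarize_outcome(c(1L, 2L, 3L, 4L, 5L, NA)),
                   c(0L, 0L, 1L, 1L, 1L, 0L))
  expect_error(binarize_outcome(6L), "outside 1..5")
  expect_error(binarize_outcome(0L), "outside 1..5")
  # recomputation is stable
  lv <- c(2L, NA, 5L)
  expect_identical(binarize_outcome(lv), binarize_outcome(lv))
})

test_that("drug retention uses a strictly-greater user threshold", {
  expo <- data.frame(
    person_id = c(seq_len(5000), seq_len(5001), 1L),
    drug = c(rep("a", 5000), rep("b", 5001), "a"),
    stringsAsFactors = FALSE
  )
  expect_identical(retain_common_drugs(expo, 5000), "b")
  expect_setequal(retain_common_drugs(expo, 10), c("a", "b"))
})

test_that("nonuser cohorts follow the clean-comparator rule on a toy table", {
  tt <- toy_tables()
  elig <- apply_eligibility(tt$persons)  # 2,4,7:12
  pair <- build_nonuser_cohorts(elig, tt$exposures, "drugA",
                                retained = c("drugA", "drugB"))
  expect_setequal(pair$treated_ids, c(2L, 4L, 7L, 8L))
  # 9 uses drugB only: excluded from both arms under the clean rule;
  # 12 uses drugC which is not retained, so stays a comparator
  expect_setequal(pair$comparator_ids, c(10L, 11L, 12L))
  lit <- build_nonuser_cohorts(elig, tt$exposures, "drugA",
                               comparator = "drug_only")
  expect_true(9L %in% lit$comparator_ids)
  expect_error(build_nonuser_cohorts(elig, tt$exposures, "drugZ",
                                     retained = c("drugA")),
               "not in the retained set")
})

test_that("active-comparator cohorts exclude dual users", {
  tt <- toy_tables()
  elig <- apply_eligibility(tt$persons)
  pair <- build_active_comparator_cohorts(elig, tt$exposures,
                                          "drugA", "drugB")
  expect_setequal(pair$treated_ids, c(2L, 4L, 7L))  # 8 uses both
  expect_setequal(pair$comparator_ids, 9L)
  expect_false(8L %in% c(pair$treated_ids, pair$comparator_ids))
  expect_error(build_active_comparator_cohorts(elig, tt$exposures,
                                               "drugA", "drugA"),
               "must differ")
  expect_error(build_active_comparator_cohorts(elig, tt$exposures,
                                               "drugZ", "drugB"),
               "empty")
})

test_that("any-drug cohorts partition the eligible set without duplication", {
  tt <- toy_tables()
  elig <- apply_eligibility(tt$persons)
  pair <- build_any_drug_cohorts(elig, tt$exposures,
                                 c("drugA", "drugB"))
  expect_setequal(c(pair$treated_ids, pair$comparator_ids), elig)
  expect_length(intersect(pair$treated_ids, pair$comparator_ids), 0)
  # person 8 uses two drugs but appears once
  expect_identical(sum(pair$treated_ids == 8L), 1L)
  expect_error(build_any_drug_cohorts(elig, tt$exposures, character(0)),
               "nonempty")
})

test_that("cohort membership tables are tidy", {
  tt <- toy_tables()
  elig <- apply_eligibility(tt$persons)
  pair <- build_any_drug_cohorts(elig, tt$exposures, c("drugA", "drugB"))
  tab <- cohort_table(pair)
  expect_named(tab, c("contrast_name", "person_id", "arm"))
  expect_identical(nrow(tab),
                   length(pair$treated_ids) + length(pair$comparator_ids))
})
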