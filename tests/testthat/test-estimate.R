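test_that("unadjusted ATE matches hand arithmetic", {
  expect_equal(unadjusted_ate(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(unadjusted_ate(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_equal(unadjusted_ate(c(1, 0, 0, 1, 1, 0, 0),
                              c(1, 1, 1, 0, 0, 0, 0)), 1 / 3 - 1 / 2)
  expect_error(unadjusted_ate(c(1, 0), c(1, 1)), "nonempty")
  expect_error(unadjusted_ate(c(2, 0), c(1, 0)))
})

test_that("negating the treatment labels negates the unadjusted ATE exactly", {
  set.seed(1)
  h <- rbinom(200, 1, 0.4)
  l <- rbinom(200, 1, 0.5)
  expect_identical(unadjusted_ate(h, l), -unadjusted_ate(h, 1 - l))
})

test_that("Hajek weighting reduces to the unadjusted contrast with equal weights", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    h <- rbinom(n, 1, runif(1, 0.1, 0.9))
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    w <- rep(runif(1, 0.1, 10), n)
    expect_equal(iptw_ate(h, l, w), unadjusted_ate(h, l),
                 tolerance = 1e-12)
  }
  # one treated with outcome 1, one comparator with outcome 0 -> 1
  expect_equal(iptw_ate(c(1, 0), c(1, 0), c(7.3, 0.2)), 1)
  expect_error(iptw_ate(c(1, 0), c(1, 0), c(1, -1)), "positive")
})

test_that("Horvitz-Thompson form divides by total size, Hajek by arm weight", {
  h <- c(1, 0, 1, 0); l <- c(1, 1, 0, 0); w <- c(2, 2, 4, 4)
  expect_equal(iptw_ate(h, l, w), 0.5 - 0.5)
  expect_equal(iptw_ate(h, l, w, normalize = FALSE), 2 / 4 - 4 / 4)
})

test_that("degenerate bootstrap collapses to a width-zero interval", {
  h <- c(rep(1, 10), rep(0, 10))
  l <- c(rep(1, 10), rep(0, 10))
  es <- bootstrap_ate(h, l, B = 20, seed = 3)
  expect_equal(es$ate, 1)
  expect_equal(es$ci_low, 1)
  expect_equal(es$ci_high, 1)
  expect_equal(es$p_sign, 2 / 21)
  expect_identical(es$n_bootstrap, 20)
})

test_that("bootstrap is deterministic and keeps the point estimate inside the CI", {
  st <- tiny_study(seed = 31, n = 500)
  d <- st$data
  pair <- build_any_drug_cohorts(d$persons$person_id, d$exposures,
                                 names(st$config$drug_class_map))
  vocab <- build_vocabulary(d$code_events, d$persons)
  dm <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                              vocab = vocab)
  h <- outcome_for(d$severities, dm$person_ids)
  spec <- propensity_spec("lr", lambda = 0.01)
  a <- bootstrap_ate(h, dm$labels, dm$x, spec, B = 15, seed = 7)
  b <- bootstrap_ate(h, dm$labels, dm$x, spec, B = 15, seed = 7)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_identical(a$boot_estimates, b$boot_estimates)
  expect_lte(a$ci_low, a$ate)
  expect_gte(a$ci_high, a$ate)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
  c <- bootstrap_ate(h, dm$labels, dm$x, spec, B = 15, seed = 8)
  expect_false(identical(a$boot_estimates, c$boot_estimates))
})

test_that("negative-control suite returns one estimate per code and flags degenerate ones", {
  st <- tiny_study(seed = 32, n = 600)
  d <- st$data
  elig <- apply_eligibility(d$persons)
  pair <- build_any_drug_cohorts(elig, d$exposures,
                                 names(st$config$drug_class_map))
  vocab <- build_vocabulary(d$code_events, d$persons)
  spec <- propensity_spec("lr", lambda = 0.01)
  suite <- negative_control_suite(pair, d, nc_codes = d$nc_codes[1:2],
                                  vocab = vocab, spec = spec, B = 10,
                                  seed = 5)
  expect_length(suite, 2)
  expect_s3_class(suite[[1]], "ate_estimate")
  # the control's own code must not sit in its confounder set: rerun by
  # hand and compare
  dm <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                              vocab = vocab,
                              exclude_codes = d$nc_codes[1])
  expect_false(d$nc_codes[1] %in% colnames(dm$x))
  # a control code absent from the cohort is inestimable, not an error
  outside <- setdiff(d$persons$person_id,
                     c(pair$treated_ids, pair$comparator_ids))[1]
  d2 <- d
  d2$code_events <- rbind(
    d2$code_events,
    data.frame(person_id = outside, code = "rare_code",
               days_before_index = 5L))
  vocab2 <- build_vocabulary(d2$code_events, d2$persons)
  suite2 <- negative_control_suite(pair, d2, nc_codes = "rare_code",
                                   vocab = vocab2, spec = spec, B = 10,
                                   seed = 5)
  expect_true(is.na(suite2[[1]]$ate))
  expect_match(suite2[[1]]$note, "inestimable")
  expect_error(
    negative_control_suite(pair, d, nc_codes = "not_a_code",
                           vocab = vocab, spec = spec, B = 10, seed = 5),
    "absent from the vocabulary")
  tab <- ate_table(suite)
  expect_identical(nrow(tab), 2L)
})

test_that("comparator matrix fills ordered off-diagonal cells and flags empties", {
  st <- tiny_study(seed = 33, n = 900)
  d <- st$data
  elig <- apply_eligibility(d$persons)
  drugs <- names(st$config$drug_class_map)[1:3]
  vocab <- build_vocabulary(d$code_events, d$persons)
  cm <- comparator_matrix(elig, d, drugs, vocab,
                          spec = propensity_spec("lr", lambda = 0.01),
                          B = 5, seed = 2)
  expect_identical(dim(cm$ate), c(3L, 3L))
  expect_true(all(is.na(diag(cm$ate))))
  expect_identical(sum(!is.na(cm$ate)), 6L)
  expect_true(all(is.na(cm$significant) ==
                    is.na(cm$ate)))
  # a drug with no users leaves its row and column flagged missing
  cm2 <- comparator_matrix(elig, d, c(drugs[1:2], "ghost_drug"), vocab,
                           spec = propensity_spec("lr", lambda = 0.01),
                           B = 5, seed = 2)
  expect_true(all(is.na(cm2$ate["ghost_drug", ])))
  expect_true(all(is.na(cm2$ate[, "ghost_drug"])))
  expect_identical(sum(!is.na(cm2$ate)), 2L)
})

test_that("arm summary reports nonhospitalization rates per arm", {
  h <- c(1, 0, 0, 0, 1, 1)
  l <- c(1, 1, 1, 0, 0, 0)
  s <- arm_summary(h, l)
  expect_equal(s$rate_nonhosp[s$arm == "treated"], 2 / 3)
  expect_equal(s$rate_nonhosp[s$arm == "comparator"], 1 / 3)
  sw <- arm_summary(h, l, weights = c(1, 1, 2, 1, 1, 2))
  expect_equal(sw$rate_nonhosp_weighted[sw$arm == "treated"], 3 / 4)
})
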