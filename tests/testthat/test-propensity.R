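make_noise_design <- function(n, p, seed, treated_frac = 0.3) {
  set.seed(seed)
  x <- Matrix::rsparsematrix(n, p, density = 0.1,
                             rand.x = function(k) rep(1, k))
  colnames(x) <- paste0("f", seq_len(p))
  labels <- rbinom(n, 1, treated_frac)
  list(x = x, labels = labels)
}

test_that("propensity fits are calibrated when labels carry no signal", {
  d <- make_noise_design(5000, 50, seed = 1)
  fit <- fit_propensity(d$x, d$labels, propensity_spec("lr", lambda = 0.01))
  p <- predict_propensity(fit)
  expect_lt(abs(mean(p) - mean(d$labels)), 0.02)
  expect_true(all(p >= 0.01 & p <= 0.99))
})

test_that("L1 keeps separable data finite and inside (0,1)", {
  x <- Matrix::sparseMatrix(i = 1:40, j = rep(1, 40),
                            x = c(rep(1, 20), rep(0, 20)),
                            dims = c(40, 2))
  colnames(x) <- c("a", "b")
  labels <- c(rep(1, 20), rep(0, 20))
  fit <- fit_propensity(x, labels, propensity_spec("lr", lambda = 0.01))
  p <- predict_propensity(fit, x, eps = 1e-6)
  expect_true(all(is.finite(p) & p > 0 & p < 1))
})

test_that("propensity model separates confounded arms better than chance", {
  st <- tiny_study(seed = 21, n = 2000, codes = 100)
  d <- st$data
  pair <- build_any_drug_cohorts(d$persons$person_id, d$exposures,
                                 names(st$config$drug_class_map))
  vocab <- build_vocabulary(d$code_events, d$persons)
  dm <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                              vocab = vocab)
  fit <- fit_propensity(dm$x, dm$labels, propensity_spec("lr"))
  p <- predict_propensity(fit)
  # rank-based AUC
  r <- rank(p)
  n1 <- sum(dm$labels == 1); n0 <- sum(dm$labels == 0)
  auc <- (sum(r[dm$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_gt(auc, 0.5 + 3 * se)
})

test_that("prediction clips symmetrically and is identity inside the bounds", {
  d <- make_noise_design(500, 20, seed = 3)
  fit <- fit_propensity(d$x, d$labels, propensity_spec("lr", lambda = 0.01))
  raw <- predict_propensity(fit, d$x, eps = 1e-12)
  clipped <- predict_propensity(fit, d$x, eps = 0.4)
  expect_true(all(clipped >= 0.4 & clipped <= 0.6))
  inside <- raw > 0.4 & raw < 0.6
  expect_equal(clipped[inside], raw[inside])
  # clipping monotone: tightening eps never moves a score further from
  # its unclipped value
  e1 <- predict_propensity(fit, d$x, eps = 0.2)
  e2 <- predict_propensity(fit, d$x, eps = 0.1)
  expect_true(all(abs(e2 - raw) <= abs(e1 - raw) + 1e-15))
})

test_that("weights follow the inverse-probability form", {
  expect_equal(compute_weights(c(0.5, 0.2), c(1, 0)), c(2, 1.25))
  expect_equal(compute_weights(rep(0.5, 4), c(1, 1, 0, 0)), rep(2, 4))
  expect_error(compute_weights(c(0, 0.5), c(1, 0)), "strictly inside")
  expect_error(compute_weights(c(1, 0.5), c(1, 0)), "strictly inside")
})

test_that("fitting rejects degenerate inputs", {
  d <- make_noise_design(100, 10, seed = 4)
  expect_error(fit_propensity(d$x, rep(1, 100), propensity_spec("lr")),
               "single-class")
  xx <- as.matrix(d$x)
  xx[1, 1] <- Inf
  expect_error(fit_propensity(xx, d$labels, propensity_spec("rf")),
               "non-finite")
  expect_error(fit_propensity(d$x, d$labels[-1], propensity_spec("lr")),
               "match")
})

test_that("random-forest scores are seed-stable and schema-checked", {
  set.seed(5)
  x <- matrix(rnorm(300 * 6), 300, 6)
  colnames(x) <- paste0("e", 1:6)
  labels <- rbinom(300, 1, plogis(x[, 1]))
  spec <- propensity_spec("rf", n_trees = 50, seed = 9)
  f1 <- fit_propensity(x, labels, spec)
  f2 <- fit_propensity(x, labels, spec)
  expect_identical(predict_propensity(f1), predict_propensity(f2))
  x2 <- x
  colnames(x2) <- paste0("q", 1:6)
  expect_error(predict_propensity(f1, x2), "schema")
})

test_that("balance diagnostics: zero for identical arms, flagged for constants", {
  set.seed(6)
  base <- matrix(rnorm(50 * 4), 50, 4)
  x <- rbind(base, base)
  x <- cbind(x, const = 1)
  labels <- rep(c(1, 0), each = 50)
  bd <- balance_diagnostics(x, labels)
  expect_equal(bd$smd[1:4], rep(0, 4))
  expect_true(bd$zero_variance[5])
  expect_equal(bd$smd[5], 0)
})

test_that("oracle weights improve balance on confounded covariates", {
  st <- tiny_study(seed = 22, n = 4000, codes = 100)
  d <- st$data
  pair <- build_any_drug_cohorts(d$persons$person_id, d$exposures,
                                 names(st$config$drug_class_map))
  vocab <- build_vocabulary(d$code_events, d$persons)
  dm <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                              vocab = vocab)
  pt <- d$truth$p_treat[match(dm$person_ids, d$truth$person_id)]
  w <- compute_weights(pmin(pmax(pt, 0.01), 0.99), dm$labels)
  pre <- balance_diagnostics(dm$x, dm$labels)
  post <- balance_diagnostics(dm$x, dm$labels, w)
  expect_lt(max(abs(post$smd)), max(abs(pre$smd)))
})
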