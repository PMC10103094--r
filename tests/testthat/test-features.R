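test_that("vocabulary covers distinct codes plus observed demographic levels", {
  persons <- data.frame(
    person_id = 1:4, age = c(25, 27, 41, 44),
    gender = c("F", "M", "F", "M"), race = c("white", "black",
                                             "white", "black"),
    ethnicity = "not_hispanic", zip3 = c("021", "021", "902", "902"),
    stringsAsFactors = FALSE
  )
  events <- data.frame(person_id = c(1, 1, 2), code = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  v <- build_vocabulary(events, persons)
  # 3 codes + 2 age bins + 2 genders + 2 races + 1 ethnicity + 2 zips
  expect_length(v$keys, 12)
  expect_identical(anyDuplicated(v$keys), 0L)
  # empty event table: demographic keys only
  v0 <- build_vocabulary(events[0, ], persons)
  expect_length(v0$code_keys, 0)
  expect_length(v0$keys, 9)
})

test_that("one-hot encoding is binary presence with demographics set", {
  persons <- data.frame(
    person_id = 1:3, age = c(25, 35, 25), gender = c("F", "F", "M"),
    race = "white", ethnicity = "hispanic", zip3 = c("021", "021", NA),
    stringsAsFactors = FALSE
  )
  events <- data.frame(person_id = c(1, 1, 1, 2),
                       code = c("X", "X", "Y", "X"),
                       stringsAsFactors = FALSE)
  v <- build_vocabulary(events, persons)
  m <- one_hot_encode(1:3, events, persons, v)
  expect_identical(dim(m), c(3L, length(v$keys)))
  expect_true(all(m@x %in% 1))
  # multiplicity collapsed: person 1 has X twice but entry is 1
  expect_equal(m[1, "X"], 1)
  expect_equal(m[1, "Y"], 1)
  # row sum = distinct codes + demographic fields present
  expect_equal(sum(m[1, ]), 2 + 5)
  expect_equal(sum(m[3, ]), 0 + 4)  # no codes, missing zip
  # unseen code at transform time is ignored with a warning
  ev2 <- rbind(events, data.frame(person_id = 3, code = "ZZZ"))
  expect_warning(m2 <- one_hot_encode(1:3, ev2, persons, v), "ZZZ")
  expect_equal(sum(m2[3, ]), 4)
})

test_that("embed_patient is the exact mean over distinct representable codes", {
  emb <- random_embedding(c("a", "b", "c"), dim = 2, seed = 1)
  emb["a", ] <- c(1, 0); emb["b", ] <- c(0, 1)
  expect_equal(embed_patient("c", emb), unclass(emb)["c", ])
  expect_equal(embed_patient(c("a", "b"), emb), c(0.5, 0.5))
  expect_equal(embed_patient(c("a", "b", "b", "a"), emb), c(0.5, 0.5))
  expect_equal(embed_patient(c("a", "b", "b"), emb,
                             collapse_duplicates = FALSE),
               c(1 / 3, 2 / 3))
  # permutation invariance
  set.seed(2)
  emb2 <- random_embedding(letters[1:10], dim = 6, seed = 3)
  cds <- sample(letters[1:10], 6)
  expect_equal(embed_patient(cds, emb2), embed_patient(rev(cds), emb2))
  # scale consistency
  emb3 <- emb2 * 3
  class(emb3) <- class(emb2)
  expect_equal(embed_patient(cds, emb3), 3 * embed_patient(cds, emb2))
  # unknown codes dropped; none representable is an error
  expect_equal(embed_patient(c("a", "zz"), emb2),
               unclass(emb2)["a", ])
  expect_error(embed_patient("zz", emb2),
               class = "ehrcausal_unembeddable")
})

test_that("design matrices align rows, labels and columns in both modes", {
  st <- tiny_study(seed = 11, n = 300)
  d <- st$data
  elig <- apply_eligibility(d$persons)
  ret <- retain_common_drugs(d$exposures, 5)
  pair <- build_any_drug_cohorts(elig, d$exposures, ret)
  vocab <- build_vocabulary(d$code_events, d$persons)
  dm <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                              vocab = vocab)
  expect_identical(ncol(dm$x), length(vocab$keys))
  expect_identical(nrow(dm$x),
                   length(pair$treated_ids) + length(pair$comparator_ids))
  expect_identical(sum(dm$labels), length(pair$treated_ids))
  expect_true(all(dm$x@x == 1))
  # reproducible
  dm2 <- build_design_matrices(pair, "one_hot", d$persons,
                               d$code_events, vocab = vocab)
  expect_identical(as.matrix(dm$x), as.matrix(dm2$x))

  emb <- random_embedding(st$graph$nodes, dim = 8, seed = 5)
  dme <- build_design_matrices(pair, "embedding", d$persons,
                               d$code_events, table = emb)
  # columns: d embedding dims + observed cohort demographic levels + age
  coh <- d$persons[d$persons$person_id %in% dme$person_ids, ]
  n_lev <- function(v) {
    v <- as.character(v); v[is.na(v) | !nzchar(v)] <- ".missing"
    length(unique(v))
  }
  demo_levels <- n_lev(coh$gender) + n_lev(coh$race) +
    n_lev(coh$ethnicity) + n_lev(coh$zip3)
  expect_identical(ncol(dme$x), 8L + demo_levels + 1L)
  expect_true(all(is.finite(dme$x)))

  # excluding a code removes its column from the one-hot design
  nc <- d$nc_codes[1]
  dmx <- build_design_matrices(pair, "one_hot", d$persons, d$code_events,
                               vocab = vocab, exclude_codes = nc)
  expect_false(nc %in% colnames(dmx$x))
  expect_identical(ncol(dmx$x), length(vocab$keys) - 1L)
})

test_that("design construction rejects persons missing from the person table", {
  tt <- toy_tables()
  pair <- structure(list(contrast_name = "t", treated_ids = c(2L, 99L),
                         comparator_ids = 10:11),
                    class = "cohort_pair")
  v <- build_vocabulary(tt$code_events, tt$persons)
  expect_error(build_design_matrices(pair, "one_hot", tt$persons,
                                     tt$code_events, vocab = v),
               "missing from the persons table")
})
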