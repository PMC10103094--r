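age_bin_key <- function(age) {
  lo <- 10L * (as.integer(age) %/% 10L)
  sprintf("age=%d-%d", lo, lo + 9L)
}

demo_fields <- c("gender", "race", "ethnicity", "zip3")

# per-person demographic keys (age bin + categorical levels); missing
# values yield no key for that field
demo_keys_of <- function(persons) {
  keys <- vector("list", nrow(persons))
  age_k <- age_bin_key(persons$age)
  for (i in seq_len(nrow(persons))) {
    k <- age_k[i]
    for (f in demo_fields) {
      v <- persons[[f]][i]
      if (!is.na(v) && nzchar(as.character(v))) {
        k <- c(k, paste0(f, "=", v))
      }
    }
    keys[[i]] <- k
  }
  keys
}

#' Build the one-hot covariate vocabulary
#'
#' One key per distinct concept code observed in the event table, plus
#' one key per observed demographic level: 10-year age bins and the
#' levels of gender, race, ethnicity and 3-digit zip. The key order is
#' stable (codes sorted, then demographic keys sorted), so the index map
#' is a bijection for the lifetime of a run.
#'
#' @param code_events Data frame with `person_id`, `code`.
#' @param persons Data frame with `person_id`, `age`, `gender`, `race`,
#'   `ethnicity`, `zip3`.
#' @return An `ehr_vocabulary`: list with `keys`, `code_keys`,
#'   `demo_keys`.
#' @export
build_vocabulary <- function(code_events, persons) {
  code_keys <- sort(unique(as.character(code_events$code)))
  dk <- character(0)
  dk <- c(dk, unique(age_bin_key(persons$age)))
  for (f in demo_fields) {
    v <- persons[[f]]
    v <- unique(as.character(v[!is.na(v) & nzchar(as.character(v))]))
    if (length(v)) dk <- c(dk, paste0(f, "=", v))
  }
  demo_keys <- sort(unique(dk))
  structure(list(keys = c(code_keys, demo_keys),
                 code_keys = code_keys, demo_keys = demo_keys),
            class = "ehr_vocabulary")
}

#' @export
print.ehr_vocabulary <- function(x, ...) {
  cat("<ehr_vocabulary> ", length(x$keys), " keys (",
      length(x$code_keys), " codes + ", length(x$demo_keys),
      " demographic levels)\n", sep = "")
  invisible(x)
}

#' One-hot encode persons over a vocabulary
#'
#' Sparse binary design rows: entry 1 iff the person has at least one
#' occurrence of the code (presence, multiplicity collapsed) or matches
#' the demographic level. `counts = TRUE` switches the code block to
#' occurrence counts.
#'
#' Codes present in the events but absent from the vocabulary (unseen at
#' transform time) are ignored with one warning.
#'
#' @param ids Person ids defining the rows, in order.
#' @param code_events Event table (`person_id`, `code`).
#' @param persons Person table.
#' @param vocab An `ehr_vocabulary`.
#' @param counts Use occurrence counts instead of presence for codes.
#' @return A `Matrix::sparseMatrix` of dimension `length(ids) x
#'   length(vocab$keys)` with person ids as rownames.
#' @export
one_hot_encode <- function(ids, code_events, persons, vocab,
                           counts = FALSE) {
  stopifnot(inherits(vocab, "ehr_vocabulary"))
  nkey <- length(vocab$keys)
  ev <- code_events[code_events$person_id %in% ids, , drop = FALSE]
  i <- match(ev$person_id, ids)
  j <- match(as.character(ev$code), vocab$keys)
  if (anyNA(j)) {
    unseen <- unique(as.character(ev$code)[is.na(j)])
    warning("ignoring ", length(unseen),
            " code(s) absent from the vocabulary: ",
            paste(utils::head(unseen, 5), collapse = ", "))
    i <- i[!is.na(j)]
    j <- j[!is.na(j)]
  }
  if (counts) {
    xv <- rep(1, length(i))
  } else {
    keep <- !duplicated(cbind(i, j))
    i <- i[keep]
    j <- j[keep]
    xv <- rep(1, length(i))
  }

  prs <- persons[match(ids, persons$person_id), , drop = FALSE]
  if (anyNA(prs$person_id)) {
    stop("person(s) missing from the persons table")
  }
  dk <- demo_keys_of(prs)
  di <- rep(seq_along(ids), lengths(dk))
  dj <- match(unlist(dk), vocab$keys)
  keep <- !is.na(dj)
  m <- Matrix::sparseMatrix(
    i = c(i, di[keep]), j = c(j, dj[keep]), x = c(xv, rep(1, sum(keep))),
    dims = c(length(ids), nkey),
    dimnames = list(as.character(ids), vocab$keys)
  )
  if (!counts) m@x[] <- 1  # duplicated demo/code triplets collapse to presence
  m
}

#' Average concept embeddings into a patient vector
#'
#' The unweighted componentwise mean of the embedding vectors of a
#' person's codes. Duplicate occurrences of a code are collapsed to one
#' before averaging (the code list is treated as a set); the
#' `collapse_duplicates = FALSE` flag keeps multiplicity weighting.
#' Codes without an embedding are dropped; if no code is representable
#' the person is unembeddable and an error of class
#' `ehrcausal_unembeddable` is signalled so the caller can exclude them.
#'
#' @param codes Character vector of concept codes (the person's history).
#' @param table An `embedding_table`.
#' @param collapse_duplicates Collapse repeated codes before averaging.
#' @return Numeric vector of length `ncol(table)`.
#' @export
embed_patient <- function(codes, table, collapse_duplicates = TRUE) {
  codes <- as.character(codes)
  if (collapse_duplicates) codes <- unique(codes)
  present <- codes %in% rownames(table)
  codes <- codes[present]
  if (length(codes) == 0) {
    stop(structure(
      class = c("ehrcausal_unembeddable", "error", "condition"),
      list(message = "no representable codes for this patient",
           call = sys.call(-1))
    ))
  }
  colMeans(unclass(table)[codes, , drop = FALSE])
}

# bulk embedding of many persons; returns matrix plus exclusion report
embed_persons <- function(ids, code_events, table,
                          collapse_duplicates = TRUE) {
  ev <- code_events[code_events$person_id %in% ids, , drop = FALSE]
  known <- as.character(ev$code) %in% rownames(table)
  dropped_codes <- unique(as.character(ev$code)[!known])
  ev <- ev[known, , drop = FALSE]
  sp <- split(as.character(ev$code), factor(ev$person_id, levels = ids))
  d <- ncol(table)
  out <- matrix(NA_real_, nrow = length(ids), ncol = d,
                dimnames = list(as.character(ids), NULL))
  emb <- unclass(table)
  for (i in seq_along(ids)) {
    cds <- sp[[i]]
    if (collapse_duplicates) cds <- unique(cds)
    if (length(cds)) out[i, ] <- colMeans(emb[cds, , drop = FALSE])
  }
  ok <- !is.na(out[, 1])
  list(matrix = out, representable = ok, dropped_codes = dropped_codes)
}

#' Build design matrix and treatment labels for a cohort
#'
#' Assembles the covariate matrix for propensity modelling. In
#' `"one_hot"` mode the rows are sparse binary vectors over the full
#' vocabulary. In `"embedding"` mode each row is the averaged concept
#' embedding with one-hot demographics and a raw (decade-scaled) age
#' column appended, so both propensity models condition on the same
#' confounder set; persons with no representable code are excluded and
#' counted in the `n_unembeddable` attribute.
#'
#' `exclude_codes` removes codes from the representation (used to keep a
#' negative-control outcome out of its own confounder set).
#'
#' @param pair A `cohort_pair`.
#' @param mode `"one_hot"` or `"embedding"`.
#' @param persons,code_events Input tables.
#' @param vocab `ehr_vocabulary` (one_hot mode).
#' @param table `embedding_table` (embedding mode).
#' @param exclude_codes Codes dropped from the representation.
#' @param counts Presence (default) or counts in one_hot mode.
#' @return List with `x` (matrix; sparse in one_hot mode), `labels`
#'   (1 = treated, 0 = comparator), `person_ids` (row order).
#' @export
build_design_matrices <- function(pair, mode = c("one_hot", "embedding"),
                                  persons, code_events, vocab = NULL,
                                  table = NULL,
                                  exclude_codes = character(0),
                                  counts = FALSE) {
  mode <- match.arg(mode)
  ids <- c(pair$treated_ids, pair$comparator_ids)
  labels <- rep(c(1L, 0L), c(length(pair$treated_ids),
                             length(pair$comparator_ids)))
  if (!all(ids %in% persons$person_id)) {
    stop("cohort member(s) missing from the persons table")
  }
  ev <- code_events
  if (length(exclude_codes)) {
    ev <- ev[!(as.character(ev$code) %in% exclude_codes), , drop = FALSE]
  }

  if (mode == "one_hot") {
    if (is.null(vocab)) stop("one_hot mode requires a vocabulary")
    x <- one_hot_encode(ids, ev, persons, vocab, counts = counts)
    if (length(exclude_codes)) {
      x <- x[, !(colnames(x) %in% exclude_codes), drop = FALSE]
    }
    res <- list(x = x, labels = labels, person_ids = ids)
    attr(res, "n_unembeddable") <- 0L
    return(res)
  }

  if (is.null(table)) stop("embedding mode requires an embedding table")
  ep <- embed_persons(ids, ev, table)
  ok <- ep$representable
  ids2 <- ids[ok]
  labels2 <- labels[ok]
  if (sum(labels2 == 1) == 0 || sum(labels2 == 0) == 0) {
    stop("an arm became empty after excluding unembeddable patients")
  }
  prs <- persons[match(ids2, persons$person_id), , drop = FALSE]
  demo <- matrix(0, nrow = length(ids2), ncol = 0)
  for (f in demo_fields) {
    v <- as.character(prs[[f]])
    v[is.na(v) | !nzchar(v)] <- ".missing"
    lev <- sort(unique(v))
    mm <- outer(v, lev, "==") * 1
    colnames(mm) <- paste0(f, "=", lev)
    demo <- cbind(demo, mm)
  }
  x <- cbind(ep$matrix[ok, , drop = FALSE], demo,
             age_decades = prs$age / 10)
  colnames(x)[seq_len(ncol(table))] <- paste0("emb_", seq_len(ncol(table)))
  rownames(x) <- as.character(ids2)
  res <- list(x = x, labels = labels2, person_ids = ids2)
  attr(res, "n_unembeddable") <- sum(!ok)
  attr(res, "dropped_codes") <- ep$dropped_codes
  res
}
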