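#' Apply the study eligibility filters
#'
#' Keeps persons with age strictly over 13 years, at least one year
#' (365 days) of pre-index medical history, and a valid (non-missing,
#' non-empty) 3-digit zip code.
#'
#' @param persons Data frame with columns `person_id`, `age`,
#'   `history_days`, `zip3`.
#' @return Vector of eligible person ids (possibly empty).
#' @export
apply_eligibility <- function(persons) {
  stopifnot(all(c("person_id", "age", "history_days", "zip3") %in%
                  names(persons)))
  zip_ok <- !is.na(persons$zip3) & nzchar(trimws(as.character(persons$zip3)))
  keep <- persons$age > 13 & persons$history_days >= 365 & zip_ok
  persons$person_id[keep]
}

#' Binarize the 5-level severity score into a hospitalization outcome
#'
#' The severity scale is: 1 mild, 2 mild with emergency-department visit,
#' 3 moderate with hospitalization, 4 severe with hospitalization,
#' 5 hospital mortality. Levels 3-5 are grouped as hospitalized (1);
#' levels 1-2 are nonhospitalized (0). A missing score is treated as
#' nonhospitalized, on the grounds that a hospitalization would have been
#' recorded.
#'
#' @param level Integer vector of severity levels in 1..5, `NA` allowed.
#' @return Integer vector of 0/1 hospitalization outcomes.
#' @export
binarize_outcome <- function(level) {
  lv <- level
  bad <- !is.na(lv) & (lv < 1 | lv > 5 | lv != as.integer(lv))
  if (any(bad)) {
    stop("severity level outside 1..5: ",
         paste(utils::head(unique(lv[bad])), collapse = ", "))
  }
  out <- integer(length(lv))
  out[!is.na(lv) & lv >= 3] <- 1L
  out
}

#' Hospitalization outcome for a set of persons
#'
#' Joins the severity table on person id and binarizes; persons absent
#' from the severity table count as missing, hence nonhospitalized.
#'
#' @param severities Data frame with `person_id`, `level`.
#' @param ids Person ids, in the order the outcome vector should follow.
#' @return Named integer 0/1 vector aligned with `ids`.
#' @export
outcome_for <- function(severities, ids) {
  lv <- severities$level[match(ids, severities$person_id)]
  out <- binarize_outcome(lv)
  names(out) <- as.character(ids)
  out
}

#' Retain drugs with more than a minimum number of users
#'
#' @param exposures Data frame with `person_id`, `drug`.
#' @param min_users Threshold; a drug is kept only if its distinct user
#'   count is strictly greater. Default 5000, the full-scale study value;
#'   synthetic runs use a scaled-down threshold.
#' @return Character vector of retained drug names.
#' @export
retain_common_drugs <- function(exposures, min_users = 5000) {
  stopifnot(min_users >= 1)
  users <- tapply(exposures$person_id, exposures$drug,
                  function(x) length(unique(x)))
  sort(names(users)[users > min_users])
}

new_cohort_pair <- function(contrast_name, treated_ids, comparator_ids) {
  treated_ids <- unique(treated_ids)
  comparator_ids <- unique(comparator_ids)
  if (length(treated_ids) == 0) {
    stop("empty treated arm for contrast '", contrast_name, "'")
  }
  if (length(comparator_ids) == 0) {
    stop("empty comparator arm for contrast '", contrast_name, "'")
  }
  if (length(intersect(treated_ids, comparator_ids)) > 0) {
    stop("arms overlap for contrast '", contrast_name, "'")
  }
  structure(list(contrast_name = contrast_name,
                 treated_ids = treated_ids,
                 comparator_ids = comparator_ids),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("<cohort_pair> ", x$contrast_name, ": ",
      length(x$treated_ids), " treated vs ",
      length(x$comparator_ids), " comparator\n", sep = "")
  invisible(x)
}

#' Build user-versus-nonuser cohorts for one drug
#'
#' Treated arm: eligible users of `drug`. Comparator arm: by default the
#' clean-comparator reading — eligible persons exposed to none of the
#' retained study drugs — so that the null arm is not contaminated by
#' same-class exposure. `comparator = "drug_only"` gives the literal
#' reading (everyone not taking this particular drug).
#'
#' @param eligible Eligible person ids (from [apply_eligibility()]).
#' @param exposures Exposure table (`person_id`, `drug`).
#' @param drug Drug defining the treated arm.
#' @param retained Retained study drug set (required for the clean
#'   comparator); `drug` must belong to it.
#' @param comparator `"clean"` (default) or `"drug_only"`.
#' @return A `cohort_pair`.
#' @export
build_nonuser_cohorts <- function(eligible, exposures, drug,
                                  retained = NULL,
                                  comparator = c("clean", "drug_only")) {
  comparator <- match.arg(comparator)
  if (comparator == "clean") {
    if (is.null(retained)) {
      stop("clean comparator requires the retained drug set")
    }
    if (!drug %in% retained) {
      stop("drug '", drug, "' is not in the retained set")
    }
  }
  users <- unique(exposures$person_id[exposures$drug == drug])
  treated <- intersect(eligible, users)
  if (comparator == "clean") {
    any_users <- unique(exposures$person_id[exposures$drug %in% retained])
    comp <- setdiff(eligible, any_users)
  } else {
    comp <- setdiff(eligible, users)
  }
  new_cohort_pair(paste0(drug, "_vs_nonuser"), treated, comp)
}

#' Build active-comparator cohorts for a drug pair
#'
#' Treated arm: eligible users of `drugA` not using `drugB`; comparator
#' arm: eligible users of `drugB` not using `drugA`. Dual users are
#' excluded from both arms.
#'
#' @inheritParams build_nonuser_cohorts
#' @param drugA,drugB Distinct drug names.
#' @return A `cohort_pair`.
#' @export
build_active_comparator_cohorts <- function(eligible, exposures,
                                            drugA, drugB) {
  if (identical(drugA, drugB)) stop("drugA and drugB must differ")
  usersA <- unique(exposures$person_id[exposures$drug == drugA])
  usersB <- unique(exposures$person_id[exposures$drug == drugB])
  treated <- intersect(eligible, setdiff(usersA, usersB))
  comp <- intersect(eligible, setdiff(usersB, usersA))
  new_cohort_pair(paste0(drugA, "_vs_", drugB), treated, comp)
}

#' Build any-drug-versus-none cohorts
#'
#' Treated arm: eligible users of at least one drug in `drug_set`;
#' comparator arm: eligible users of none of them. The two arms
#' partition the eligible population.
#'
#' @inheritParams build_nonuser_cohorts
#' @param drug_set Nonempty character vector of drug names.
#' @return A `cohort_pair` with contrast name `"any_drug_vs_nonuser"`.
#' @export
build_any_drug_cohorts <- function(eligible, exposures, drug_set) {
  if (length(drug_set) == 0) stop("drug_set must be nonempty")
  users <- unique(exposures$person_id[exposures$drug %in% drug_set])
  treated <- intersect(eligible, users)
  comp <- setdiff(eligible, users)
  new_cohort_pair("any_drug_vs_nonuser", treated, comp)
}

#' Cohort membership as a tidy table
#'
#' @param pair A `cohort_pair`.
#' @return Data frame (contrast_name, person_id, arm).
#' @export
cohort_table <- function(pair) {
  data.frame(
    contrast_name = pair$contrast_name,
    person_id = c(pair$treated_ids, pair$comparator_ids),
    arm = rep(c("treated", "comparator"),
              c(length(pair$treated_ids), length(pair$comparator_ids))),
    stringsAsFactors = FALSE
  )
}
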