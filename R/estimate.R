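#' Unadjusted average treatment effect
#'
#' Difference of mean outcomes between the arms,
#' `mean(h | treated) - mean(h | comparator)`. Confounded whenever the
#' arms differ systematically; the weighted estimator [iptw_ate()] is
#' the adjusted counterpart.
#'
#' @param outcomes 0/1 outcome vector.
#' @param labels 0/1 treatment labels aligned with `outcomes`.
#' @return A single number.
#' @export
unadjusted_ate <- function(outcomes, labels) {
  labels <- as.integer(labels)
  outcomes <- as.numeric(outcomes)
  stopifnot(length(outcomes) == length(labels),
            all(outcomes %in% c(0, 1)))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both arms must be nonempty")
  }
  mean(outcomes[labels == 1L]) - mean(outcomes[labels == 0L])
}

#' Inverse-probability-weighted average treatment effect
#'
#' The Hajek (normalized) IPTW estimator:
#' `sum_T(w h) / sum_T(w) - sum_C(w h) / sum_C(w)`, where the weights
#' come from [compute_weights()]. With all-equal weights it reduces
#' exactly to [unadjusted_ate()]. `normalize = FALSE` gives the
#' Horvitz-Thompson form (sums divided by the total sample size).
#'
#' @param outcomes 0/1 outcome vector.
#' @param labels 0/1 treatment labels.
#' @param weights Positive weights aligned with the rows.
#' @param normalize Hajek normalization (default) or Horvitz-Thompson.
#' @return A single number.
#' @export
iptw_ate <- function(outcomes, labels, weights, normalize = TRUE) {
  labels <- as.integer(labels)
  outcomes <- as.numeric(outcomes)
  stopifnot(length(outcomes) == length(labels),
            length(weights) == length(labels))
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("weights must be positive and finite")
  }
  tr <- labels == 1L
  if (!any(tr) || all(tr)) stop("both arms must be nonempty")
  if (normalize) {
    sum(weights[tr] * outcomes[tr]) / sum(weights[tr]) -
      sum(weights[!tr] * outcomes[!tr]) / sum(weights[!tr])
  } else {
    n <- length(labels)
    sum(weights[tr] * outcomes[tr]) / n -
      sum(weights[!tr] * outcomes[!tr]) / n
  }
}

new_ate_estimate <- function(contrast_name, method, ate, ci_low, ci_high,
                             p_value, p_sign, p_normal,
                             n_treated, n_comparator, n_bootstrap,
                             boot_estimates = NULL, note = NA_character_) {
  structure(list(contrast_name = contrast_name, method = method,
                 ate = ate, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, p_sign = p_sign, p_normal = p_normal,
                 n_treated = n_treated, n_comparator = n_comparator,
                 n_bootstrap = n_bootstrap, note = note,
                 boot_estimates = boot_estimates),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, digits = 4, ...) {
  cat("<ate_estimate> ", x$contrast_name, " [", x$method, "]\n",
      "  ATE ", format(round(x$ate, digits)), sep = "")
  if (!is.na(x$ci_low)) {
    cat("  (95% CI ", format(round(x$ci_low, digits)), " to ",
        format(round(x$ci_high, digits)), "; P = ",
        format(signif(x$p_value, 2)), "; B = ", x$n_bootstrap, ")",
        sep = "")
  }
  cat("\n  n = ", x$n_treated, " treated / ", x$n_comparator,
      " comparator\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ate_estimate <- function(x, ...) {
  data.frame(contrast = x$contrast_name, method = x$method, ate = x$ate,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value,
             p_sign = x$p_sign, p_normal = x$p_normal,
             n_treated = x$n_treated, n_comparator = x$n_comparator,
             n_bootstrap = x$n_bootstrap, note = x$note,
             stringsAsFactors = FALSE)
}

#' Tidy table of ATE estimates
#' @param estimates A list of `ate_estimate` objects.
#' @return One data frame row per estimate.
#' @export
ate_table <- function(estimates) {
  do.call(rbind, lapply(estimates, as.data.frame))
}

# one weighted ATE on (a resample of) the design; refits the propensity
# model unless spec is NULL (unadjusted)
fit_and_estimate <- function(outcomes, labels, x, spec, eps,
                             normalize = TRUE) {
  if (is.null(spec)) return(unadjusted_ate(outcomes, labels))
  fit <- fit_propensity(x, labels, spec)
  p <- predict_propensity(fit, eps = eps)
  w <- compute_weights(p, labels)
  iptw_ate(outcomes, labels, w, normalize = normalize)
}

#' Bootstrap an ATE with per-replicate propensity refitting
#'
#' The point estimate is the full-sample (weighted or unadjusted) ATE.
#' Each of the `B` replicates resamples persons with replacement within
#' each arm (preserving arm sizes), refits the propensity model on the
#' resample, recomputes the weights and the ATE. The 95\% CI is the
#' 2.5/97.5 percentile interval of the replicate estimates, taken with
#' the (B+1) order-statistic convention (`quantile` type 6), which is
#' appropriate at moderate B.
#'
#' Two p-values are reported: `p_sign`, the two-sided sign-count
#' `2 * min(#(est <= 0) + 1, #(est >= 0) + 1) / (B + 1)` whose floor is
#' `2 / (B + 1)`; and `p_normal`, a normal approximation from the
#' bootstrap standard error, which is the headline `p_value` (a sign
#' count over B replicates cannot resolve below its floor).
#'
#' For the `"lr"` family the penalty is selected once on the full sample
#' and held fixed across replicates (reduced grid), so replicates differ
#' only through resampling. A replicate whose model fit fails is
#' redrawn, with a cap of `10 * B` total attempts.
#'
#' @param outcomes 0/1 outcome vector (design-matrix row order).
#' @param labels 0/1 treatment labels.
#' @param x Covariate matrix (`NULL` for the unadjusted estimator).
#' @param spec A [propensity_spec()], or `NULL` for unadjusted.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; fixes the full resampling plan.
#' @param eps Propensity clipping bound.
#' @param normalize Hajek (default) or Horvitz-Thompson weighting.
#' @param contrast_name,method Metadata carried into the estimate.
#' @param refit Refit the model per replicate (default, and the mode
#'   used for all reported CIs); `FALSE` reuses full-sample scores and
#'   only resamples, for quick diagnostics.
#' @return An `ate_estimate`.
#' @export
bootstrap_ate <- function(outcomes, labels, x = NULL, spec = NULL,
                          B = 100, seed = 1, eps = 0.01,
                          normalize = TRUE, contrast_name = "",
                          method = NULL, refit = TRUE) {
  stopifnot(B >= 2)
  labels <- as.integer(labels)
  outcomes <- as.numeric(outcomes)
  n_t <- sum(labels == 1L)
  n_c <- sum(labels == 0L)
  if (n_t == 0 || n_c == 0) stop("both arms must be nonempty")
  if (is.null(method)) {
    method <- if (is.null(spec)) "unadjusted"
              else if (spec$family == "lr") "one_hot_lr" else "embedding_rf"
  }

  # full-sample point estimate; for lr, freeze the selected penalty so
  # replicates do not redo the cross-validation
  point_spec <- spec
  if (!is.null(spec) && spec$family == "lr" && is.null(spec$lambda)) {
    full_fit <- fit_propensity(x, labels, spec)
    point_spec <- spec
    point_spec$lambda <- full_fit$model$s
    p_full <- predict_propensity(full_fit, eps = eps)
    point <- iptw_ate(outcomes, labels, compute_weights(p_full, labels),
                      normalize = normalize)
  } else if (!is.null(spec)) {
    full_fit <- fit_propensity(x, labels, spec)
    p_full <- predict_propensity(full_fit, eps = eps)
    point <- iptw_ate(outcomes, labels, compute_weights(p_full, labels),
                      normalize = normalize)
  } else {
    p_full <- NULL
    point <- unadjusted_ate(outcomes, labels)
  }

  idx_t <- which(labels == 1L)
  idx_c <- which(labels == 0L)
  set.seed(seed)
  est <- numeric(B)
  attempts <- 0L
  b <- 1L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B) {
      stop("bootstrap exceeded ", 10L * B, " attempts; data too degenerate")
    }
    ii <- c(idx_t[sample.int(n_t, n_t, replace = TRUE)],
            idx_c[sample.int(n_c, n_c, replace = TRUE)])
    val <- tryCatch({
      if (is.null(spec)) {
        unadjusted_ate(outcomes[ii], labels[ii])
      } else if (refit) {
        fit_and_estimate(outcomes[ii], labels[ii],
                         x[ii, , drop = FALSE], point_spec, eps,
                         normalize = normalize)
      } else {
        iptw_ate(outcomes[ii], labels[ii],
                 compute_weights(p_full[ii], labels[ii]),
                 normalize = normalize)
      }
    }, error = function(e) NULL)
    if (is.null(val) || !is.finite(val)) next
    est[b] <- val
    b <- b + 1L
  }

  # percentile interval with the (B+1) order-statistic convention
  # (quantile type 6), matching the continuity-corrected sign count;
  # the default interpolation is anti-conservative at B = 100
  qs <- unname(stats::quantile(est, c(0.025, 0.975), type = 6))
  ci_low <- min(qs[1], point)
  ci_high <- max(qs[2], point)
  p_sign <- min(1, 2 * min(sum(est <= 0) + 1, sum(est >= 0) + 1) / (B + 1))
  se <- stats::sd(est)
  p_normal <- if (is.finite(se) && se > 0) {
    2 * stats::pnorm(-abs(point) / se)
  } else {
    NA_real_
  }
  p_value <- if (is.na(p_normal)) p_sign else max(p_normal,
                                                  .Machine$double.xmin)
  new_ate_estimate(contrast_name, method, point, ci_low, ci_high,
                   p_value, p_sign, p_normal, n_t, n_c, B,
                   boot_estimates = est)
}

#' Negative-control outcome suite
#'
#' Reruns the identical estimation pipeline with each negative-control
#' code standing in for the outcome: the pseudo-outcome is presence of
#' the code in the person's history, and that code is removed from the
#' confounder representation for its own analysis (conditioning on the
#' outcome would bias it). Because the controls are believed causally
#' unaffected by the exposure, their CIs should cover zero; estimates
#' away from zero signal residual bias in the pipeline.
#'
#' @param pair A `cohort_pair`.
#' @param data A `synthetic_ehr` or list with `persons`, `code_events`.
#' @param nc_codes Negative-control code vector (default: the codes
#'   designated by the generator).
#' @param vocab `ehr_vocabulary` for the one-hot representation.
#' @param spec Propensity model specification.
#' @param B,seed,eps Bootstrap settings, see [bootstrap_ate()].
#' @return A list of `ate_estimate`, one per code, in order. A control
#'   with zero (or full) prevalence in the cohort is returned as an
#'   inestimable entry (`ate = NA`, explanatory `note`) rather than an
#'   error.
#' @export
negative_control_suite <- function(pair, data, nc_codes = data$nc_codes,
                                   vocab, spec = propensity_spec("lr"),
                                   B = 100, seed = 1, eps = 0.01) {
  if (length(nc_codes) == 0) stop("no negative-control codes supplied")
  missing_nc <- setdiff(nc_codes, vocab$code_keys)
  if (length(missing_nc)) {
    stop("negative-control code(s) absent from the vocabulary: ",
         paste(missing_nc, collapse = ", "))
  }
  out <- vector("list", length(nc_codes))
  names(out) <- nc_codes
  for (i in seq_along(nc_codes)) {
    nc <- nc_codes[i]
    dm <- build_design_matrices(pair, "one_hot", data$persons,
                                data$code_events, vocab = vocab,
                                exclude_codes = nc)
    has_code <- unique(data$code_events$person_id[
      as.character(data$code_events$code) == nc])
    h <- as.integer(dm$person_ids %in% has_code)
    if (sum(h) == 0 || sum(h) == length(h)) {
      out[[i]] <- new_ate_estimate(
        paste0(pair$contrast_name, ":nc_", nc), "one_hot_lr",
        NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
        sum(dm$labels == 1), sum(dm$labels == 0), 0L,
        note = "inestimable: degenerate control prevalence")
      next
    }
    out[[i]] <- bootstrap_ate(
      h, dm$labels, dm$x, spec, B = B, seed = seed + i, eps = eps,
      contrast_name = paste0(pair$contrast_name, ":nc_", nc))
  }
  out
}

#' Active-comparator effect matrix
#'
#' Fills every ordered off-diagonal cell (A, B) of the drug-by-drug grid
#' with the ATE of using A versus using B (dual users excluded), each
#' estimated through the full weighted pipeline; a cell is flagged
#' significant when its bootstrap CI excludes zero. Cells whose cohort
#' construction fails (an empty arm) are flagged missing. Refitting per
#' cell breaks exact antisymmetry, so `ate(A,B) ~ -ate(B,A)` is reported
#' as a diagnostic (`max_antisymmetry_gap`), not enforced.
#'
#' @param eligible Eligible person ids.
#' @param data A `synthetic_ehr` or list of input tables (`persons`,
#'   `code_events`, `exposures`, `severities`).
#' @param drugs At least two drug names.
#' @param vocab `ehr_vocabulary`.
#' @param spec Propensity model specification.
#' @param B,seed,eps Bootstrap settings.
#' @return A `comparator_matrix`: list with `drugs`, square matrices
#'   `ate` / `ci_low` / `ci_high`, logical `significant`, the per-cell
#'   `estimates` list and a tidy `table`.
#' @export
comparator_matrix <- function(eligible, data, drugs, vocab,
                              spec = propensity_spec("lr"), B = 100,
                              seed = 1, eps = 0.01) {
  if (length(drugs) < 2) stop("need at least 2 drugs")
  k <- length(drugs)
  tmpl <- matrix(NA_real_, k, k, dimnames = list(drugs, drugs))
  ate <- ci_lo <- ci_hi <- tmpl
  sig <- matrix(NA, k, k, dimnames = list(drugs, drugs))
  ests <- list()
  cell <- 0L
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      cell <- cell + 1L
      pair <- tryCatch(
        build_active_comparator_cohorts(eligible, data$exposures,
                                        drugs[a], drugs[b]),
        error = function(e) NULL)
      if (is.null(pair)) next  # inestimable cell stays NA-flagged
      dm <- build_design_matrices(pair, "one_hot", data$persons,
                                  data$code_events, vocab = vocab)
      h <- outcome_for(data$severities, dm$person_ids)
      es <- bootstrap_ate(h, dm$labels, dm$x, spec, B = B,
                          seed = seed + cell, eps = eps,
                          contrast_name = pair$contrast_name)
      ate[a, b] <- es$ate
      ci_lo[a, b] <- es$ci_low
      ci_hi[a, b] <- es$ci_high
      sig[a, b] <- es$ci_low > 0 || es$ci_high < 0
      ests[[pair$contrast_name]] <- es
    }
  }
  gap <- max(abs(ate + t(ate)), na.rm = TRUE)
  structure(list(drugs = drugs, ate = ate, ci_low = ci_lo,
                 ci_high = ci_hi, significant = sig,
                 estimates = ests, max_antisymmetry_gap = gap,
                 table = ate_table(ests)),
            class = "comparator_matrix")
}

#' @export
print.comparator_matrix <- function(x, digits = 3, ...) {
  cat("<comparator_matrix> ", length(x$drugs), " drugs, ",
      sum(!is.na(x$ate)), " estimated cells, ",
      sum(x$significant, na.rm = TRUE), " significant\n", sep = "")
  print(round(x$ate, digits))
  invisible(x)
}

#' Per-arm hospitalization summary
#'
#' The average rate of nonhospitalization in each arm, unweighted and
#' (optionally) IPTW-weighted -- the user-versus-nonuser summary panel.
#'
#' @param outcomes 0/1 hospitalization outcomes.
#' @param labels 0/1 treatment labels.
#' @param weights Optional IPTW weights.
#' @return Data frame with one row per arm.
#' @export
arm_summary <- function(outcomes, labels, weights = NULL) {
  labels <- as.integer(labels)
  if (is.null(weights)) weights <- rep(1, length(labels))
  rows <- lapply(c(treated = 1L, comparator = 0L), function(l) {
    sel <- labels == l
    data.frame(
      n = sum(sel),
      rate_nonhosp = mean(1 - outcomes[sel]),
      rate_nonhosp_weighted =
        sum(weights[sel] * (1 - outcomes[sel])) / sum(weights[sel])
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(arm = names(rows), out)
  rownames(out) <- NULL
  out
}
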