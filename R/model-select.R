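# Chi-squared model selection.
#
# Candidate models of the same process (sharing the measured data and the
# noise statistics) are each run through the constrained filter; residuals of
# the data against the filter-predicted outputs give per-candidate estimates
# of the measurement noise. Candidates whose chi-squared variance intervals
# exclude the known true variances are rejected with confidence gamma; among
# the retained, the one whose point estimates sit closest to the true
# variances is selected. Using filter state estimates (rather than model
# solutions) lets the procedure run even when initial conditions are unknown.

#' Define a model-selection candidate
#'
#' @param name identifier used in the report.
#' @param ext an [extend_state()] result; candidates with no free parameters
#'   are allowed (pure state estimation with known parameters).
#' @param filter_cfg a [filter_config()] for this candidate.
#' @returns object of class `ms_candidate`.
#' @export
candidate <- function(name, ext, filter_cfg) {
  stopifnot(is.character(name), inherits(ext, "extended_model"),
            inherits(filter_cfg, "filter_config"))
  structure(list(name = name, ext = ext, filter_cfg = filter_cfg),
            class = "ms_candidate")
}

#' Discriminate among candidate models
#'
#' Runs the constrained filter per candidate, tests each candidate's
#' filter-residual variances against the known noise variances at confidence
#' `gamma`, rejects candidates whose intervals exclude any true variance, and
#' among the retained picks the best by the sum of per-channel relative
#' absolute deviations `|S_j - sigma_j^2| / sigma_j^2`. A candidate whose
#' filter diverges is auto-rejected with a divergence annotation.
#'
#' @param candidates list of [candidate()] objects (at least one).
#' @param data a [measurement_series()] shared by all candidates.
#' @param gamma confidence coefficient (default 0.95).
#' @returns object of class `model_selection_report`: `reports` (named list of
#'   [chi2_test()] reports, `NULL` for diverged candidates), `retained`,
#'   `rejected` (character vectors), `best` (name or `NA`), `scores`,
#'   `diverged` (names), `gamma`.
#' @export
select_model <- function(candidates, data, gamma = 0.95) {
  if (!length(candidates)) stop("select_model: empty candidate list")
  if (inherits(candidates, "ms_candidate")) candidates <- list(candidates)
  stopifnot(all(vapply(candidates, inherits, logical(1), "ms_candidate")),
            inherits(data, "measurement_series"))
  names(candidates) <- vapply(candidates, `[[`, character(1), "name")

  reports <- vector("list", length(candidates))
  names(reports) <- names(candidates)
  scores <- rep(NA_real_, length(candidates))
  names(scores) <- names(candidates)
  diverged <- character(0)
  retained <- character(0)

  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    traj <- run_hekf(cand$ext, data, cand$filter_cfg)
    if (isTRUE(traj$diverged) || length(traj$steps) < length(data$times)) {
      diverged <- c(diverged, nm)
      next
    }
    pred <- predict_outputs_filter(traj, data)
    rep_c <- chi2_test(data, pred, gamma = gamma)
    reports[[nm]] <- rep_c
    scores[nm] <- sum(abs(rep_c$table$point - rep_c$table$true_variance) /
                        rep_c$table$true_variance)
    if (rep_c$overall_pass) retained <- c(retained, nm)
  }
  rejected <- setdiff(names(candidates), retained)
  best <- if (length(retained))
    retained[which.min(scores[retained])] else NA_character_

  structure(list(reports = reports, retained = retained, rejected = rejected,
                 best = best, scores = scores, diverged = diverged,
                 gamma = gamma),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("Model selection at gamma = %g\n", x$gamma))
  for (nm in names(x$reports)) {
    verdict <- if (nm %in% x$diverged) "REJECTED (filter diverged)"
      else if (nm %in% x$retained) "retained" else "REJECTED"
    cat(sprintf("-- %s: %s\n", nm, verdict))
    if (!is.null(x$reports[[nm]])) print(x$reports[[nm]])
  }
  cat(sprintf("best: %s\n", if (is.na(x$best)) "none" else x$best))
  invisible(x)
}
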