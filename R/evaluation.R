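# Method-comparison harness: per-participant RMSE against reference Ps (with
# the Method-1 large-outlier removal rule), paired Cohen's d effect sizes, and
# a tidy per-participant comparison table over the three estimators.

#' Root-mean-square error with optional Method-1 outlier removal
#'
#' `sqrt(mean((pred - ref)^2))` over paired finite values. When `outlier_cut`
#' is given (Method 1 only; default rule removes predictions above 75 cm H2O)
#' those pairs are removed before computing the RMSE.
#'
#' @param pred,ref paired predictions and references in cm H2O.
#' @param outlier_cut removal threshold on `pred` in cm H2O, or `NULL`.
#' @return RMSE in cm H2O.
#' @export
rmse_ps <- function(pred, ref, outlier_cut = NULL) {
  stopifnot(length(pred) == length(ref))
  ok <- is.finite(pred) & is.finite(ref)
  if (!is.null(outlier_cut)) ok <- ok & pred <= outlier_cut
  if (!any(ok)) stop("undefined RMSE: no pairs remain after filtering")
  sqrt(mean((pred[ok] - ref[ok])^2))
}

#' Paired Cohen's d
#'
#' `mean(a - b) / sd(a - b)` with the sample (n - 1) standard deviation.
#'
#' @param a,b paired series.
#' @return effect size d.
#' @export
cohens_d_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) stop("undefined d: zero-variance differences")
  mean(d) / s
}

#' Compare the three Ps estimation methods on a cohort
#'
#' For each participant: Method 1 RMSE over all segments (after the
#' large-outlier rule), Method 2 RMSE over all segments (the person-specific
#' line is fitted and evaluated on the same laboratory segments), and Method 3
#' RMSE as the lowest test-set RMSE from the five-fold cross-validation over
#' validity-filtered segments.
#'
#' @param cohort list of participant lists, each with `features` (data.frame
#'   containing `rms`, `spl`, `f0`, the glottal measures, `ps_ref`, `valid`),
#'   `sex`, and optional `group` and `id`.
#' @param method1_outlier_cut Method-1 removal threshold in cm H2O.
#' @param cv_seed seed for the Method 3 fold permutation.
#' @return data.frame: one row per participant with `id`, `group`,
#'   `rmse_m1`, `rmse_m2`, `rmse_m3`.
#' @export
compare_methods <- function(cohort, method1_outlier_cut = 75, cv_seed = 1) {
  rows <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    ft <- p$features
    ps <- ft$ps_ref
    ok <- is.finite(ps)
    pred1 <- ps_method1(ft$spl, ft$f0, sex = p$sex)
    r1 <- rmse_ps(pred1[ok], ps[ok], outlier_cut = method1_outlier_cut)
    m2 <- fit_method2(ft$rms[ok], ps[ok])
    r2 <- rmse_ps(predict_method2(m2, ft$rms[ok]), ps[ok])
    sel <- ok & ft$valid
    m3 <- crossvalidate_method3(ft[sel, , drop = FALSE], ps[sel],
                                seed = cv_seed + i)
    r3 <- min(m3$fold_rmses)
    data.frame(id = if (!is.null(p$id)) p$id else paste0("P", i),
               group = if (!is.null(p$group)) p$group else "synthetic",
               rmse_m1 = r1, rmse_m2 = r2, rmse_m3 = r3)
  })
  do.call(rbind, rows)
}

#' Synthesize and process a cohort of simulated participants
#'
#' Convenience wrapper for method-ordering experiments: builds one laboratory
#' session per participant (smaller protocol by default to keep runtime low),
#' processes it with the participant's true IBIF model, and returns the
#' cohort structure expected by [compare_methods()].
#'
#' @param n_participants cohort size.
#' @param oq_coef planted OQ coefficient of the Ps law (non-zero makes the Ps
#'   law depend on a non-RMS measure).
#' @param seed master seed; participant i uses `seed + i`.
#' @param n_trials,vowels,n_syllables protocol shape passed to
#'   [participant_spec()].
#' @param use_truth_segments use generator segment bounds (faster and avoids
#'   conflating segmentation error with model error).
#' @param ... further arguments to [participant_spec()].
#' @return list of participant lists (`features`, `sex`, `id`, `truth`).
#' @export
synthesize_cohort <- function(n_participants = 20, oq_coef = 0.15, seed = 1,
                              n_trials = 1, vowels = "a",
                              n_syllables = 15,
                              use_truth_segments = TRUE, ...) {
  lapply(seq_len(n_participants), function(i) {
    sex <- if (i %% 2 == 0) "female" else "male"
    spec <- participant_spec(sex = sex, oq_coef = oq_coef,
                             n_trials = n_trials, vowels = vowels,
                             n_syllables = n_syllables, seed = seed + i, ...)
    ses <- synthesize_lab_session(spec)
    ft <- process_lab_session(ses, spec$ibif_true,
                              use_truth_segments = use_truth_segments)
    list(features = ft, sex = sex, id = sprintf("SYN%02d", i),
         group = "synthetic", truth = ses$truth, spec = spec)
  })
}
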