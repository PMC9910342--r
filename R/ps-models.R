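# The three subglottal pressure estimators: Method 1, an empirical formula in
# SPL and f0; Method 2, a person-specific line on accelerometer RMS; Method 3,
# a forward stepwise multiple regression over the ten vocal function measures
# with partial-F screening and five-fold cross-validation.

KPA_TO_CMH2O <- 10.1972   # 1 kPa in cm of water at 4 degrees C

# Canonical measure order (also the stepwise tie-break order).
MEASURE_ORDER <- c("rms", "f0", "cpp", "acfl", "mfdr", "oq", "sq",
                   "h1h2", "hrf", "naq")

#' Convert kilopascals to centimeters of water
#' @param x pressure in kPa.
#' @return pressure in cm H2O.
#' @export
kpa_to_cmh2o <- function(x) x * KPA_TO_CMH2O

#' Method 1: empirical Ps from SPL and f0
#'
#' `Ps[kPa] = 0.14 + 0.06 * (f0 / foN)^2 + 10^((SPL - 88.5) / 27.3)`, where
#' `foN` is the nominal speaking f0 (120 Hz for males, 190 Hz for females).
#' The result is returned in cm H2O.
#'
#' @param spl sound pressure level, dB SPL at 15 cm.
#' @param f0 fundamental frequency in Hz (> 0).
#' @param sex `"male"` or `"female"`, setting `foN`; ignored if `foN` given.
#' @param foN nominal f0 override in Hz.
#' @param constants named list of the empirical constants (`c0`, `c1`,
#'   `spl_ref`, `spl_scale`); fixed unless explicitly overridden.
#' @return Ps in cm H2O (vectorized over `spl`/`f0`).
#' @export
ps_method1 <- function(spl, f0, sex = c("male", "female"), foN = NULL,
                       constants = method1_constants()) {
  if (is.null(foN)) {
    sex <- match.arg(sex)
    foN <- if (sex == "male") 120 else 190
  }
  stopifnot(all(f0 > 0, na.rm = TRUE), foN > 0)
  ps_kpa <- constants$c0 + constants$c1 * (f0 / foN)^2 +
    10^((spl - constants$spl_ref) / constants$spl_scale)
  kpa_to_cmh2o(ps_kpa)
}

#' Method 1 empirical constants
#' @return named list `c0` (kPa), `c1` (kPa), `spl_ref` (dB), `spl_scale` (dB).
#' @export
method1_constants <- function() {
  list(c0 = 0.14, c1 = 0.06, spl_ref = 88.5, spl_scale = 27.3)
}

#' Method 2: person-specific line between reference Ps and ACC RMS
#'
#' Ordinary least squares `Ps[cm H2O] = slope * ACCrms + intercept`, fitted
#' from vowel segments spanning the loudness range (at least 10 recommended).
#'
#' @param acc_rms accelerometer RMS per segment, cm/s^2 (middle 50 ms).
#' @param ps_ref reference Ps per segment, cm H2O.
#' @return object of class `ps_line_model` with `slope`, `intercept`, `n`,
#'   `rmse_train`.
#' @export
fit_method2 <- function(acc_rms, ps_ref) {
  ok <- is.finite(acc_rms) & is.finite(ps_ref)
  x <- acc_rms[ok]; y <- ps_ref[ok]
  if (length(x) < 2L) stop("method 2 requires at least 2 segments")
  if (length(x) < 10L) warning("method 2 fitted from fewer than 10 segments")
  if (stats::sd(x) == 0) stop("degenerate fit: zero variance in ACC RMS")
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n = length(x),
                 rmse_train = sqrt(mean(fit$residuals^2))),
            class = "ps_line_model")
}

#' Predict Ps with a Method 2 line model
#' @param model a `ps_line_model`.
#' @param acc_rms accelerometer RMS values, cm/s^2.
#' @return Ps in cm H2O.
#' @export
predict_method2 <- function(model, acc_rms) {
  stopifnot(inherits(model, "ps_line_model"))
  model$slope * acc_rms + model$intercept
}

#' Method 3: forward stepwise multiple regression with partial-F screening
#'
#' Candidates are iteratively added: at each step the candidate with the
#' smallest partial-F p-value joins the model if that p-value is below
#' `alpha`; selection stops when no candidate qualifies. Ties are broken by
#' larger partial F, then by the canonical measure order. If no measure passes
#' screening, an intercept-only model is returned with a warning.
#'
#' @param features data.frame of candidate measures per segment (any subset of
#'   `rms`, `f0`, `cpp`, `acfl`, `mfdr`, `oq`, `sq`, `h1h2`, `hrf`, `naq`);
#'   validity-filtered rows only.
#' @param ps_ref reference Ps per segment, cm H2O.
#' @param alpha entry threshold on the partial-F p-value.
#' @param direction `"forward"` (default) or `"both"` (forward entry with
#'   backward removal at `alpha`).
#' @return object of class `ps_stepwise_model` with `selected_features`,
#'   `coefficients` (named), `intercept`, `alpha`, `n`, `rmse_train`.
#' @export
fit_method3_stepwise <- function(features, ps_ref, alpha = 0.05,
                                 direction = c("forward", "both")) {
  direction <- match.arg(direction)
  features <- as.data.frame(features)
  cand_all <- intersect(MEASURE_ORDER, colnames(features))
  if (length(cand_all) == 0L) stop("no candidate measure columns found")
  ok <- is.finite(ps_ref) & Reduce(`&`, lapply(features[cand_all], is.finite))
  X <- features[ok, cand_all, drop = FALSE]
  y <- ps_ref[ok]
  n <- length(y)
  if (n < 3L) stop("too few valid segments for stepwise regression")
  cand_all <- cand_all[vapply(X, function(v) stats::sd(v) > 0, logical(1))]
  selected <- character(0)
  rss_of <- function(vars) {
    M <- cbind(1, as.matrix(X[, vars, drop = FALSE]))
    fit <- stats::lm.fit(M, y)
    sum(fit$residuals^2)
  }
  repeat {
    remaining <- setdiff(cand_all, selected)
    if (length(remaining) == 0L) break
    rss0 <- rss_of(selected)
    k0 <- length(selected)
    df1 <- n - k0 - 2L
    if (df1 < 1L) break
    stat <- t(vapply(remaining, function(v) {
      rss1 <- rss_of(c(selected, v))
      Fv <- (rss0 - rss1) / (rss1 / df1)
      if (!is.finite(Fv) || Fv < 0) Fv <- 0
      c(F = Fv, p = stats::pf(Fv, 1, df1, lower.tail = FALSE))
    }, numeric(2)))
    ord <- order(stat[, "p"], -stat[, "F"], match(remaining, cand_all))
    best <- ord[1]
    if (stat[best, "p"] >= alpha) break
    selected <- c(selected, remaining[best])
    if (direction == "both" && length(selected) > 1L) {
      # backward step: drop any member whose removal p-value exceeds alpha
      repeat {
        rss_full <- rss_of(selected)
        dfr <- n - length(selected) - 1L
        if (dfr < 1L) break
        pr <- vapply(selected, function(v) {
          rss_red <- rss_of(setdiff(selected, v))
          Fv <- (rss_red - rss_full) / (rss_full / dfr)
          stats::pf(max(Fv, 0), 1, dfr, lower.tail = FALSE)
        }, numeric(1))
        worst <- which.max(pr)
        if (pr[worst] > alpha && length(selected) > 1L) {
          selected <- selected[-worst]
        } else break
      }
    }
  }
  if (length(selected) == 0L) {
    warning("no measure passed screening; intercept-only model")
    return(structure(list(selected_features = character(0),
                          coefficients = numeric(0), intercept = mean(y),
                          alpha = alpha, n = n,
                          rmse_train = sqrt(mean((y - mean(y))^2))),
                     class = "ps_stepwise_model"))
  }
  M <- cbind(1, as.matrix(X[, selected, drop = FALSE]))
  fit <- stats::lm.fit(M, y)
  cf <- fit$coefficients
  structure(list(selected_features = selected,
                 coefficients = stats::setNames(unname(cf[-1]), selected),
                 intercept = unname(cf[1]), alpha = alpha, n = n,
                 rmse_train = sqrt(mean(fit$residuals^2))),
            class = "ps_stepwise_model")
}

#' Five-fold cross-validated Method 3
#'
#' The segments are split into `k` disjoint folds by a seeded random
#' permutation (fold sizes differ by at most one). A stepwise model is fitted
#' on each training split (80% of segments for `k = 5`) and scored by RMSE on
#' its held-out test split; the returned model is the fit from the fold with
#' the lowest test RMSE.
#'
#' @param features,ps_ref as in [fit_method3_stepwise()].
#' @param k number of folds.
#' @param seed RNG seed for the fold permutation.
#' @param alpha entry threshold.
#' @return a `ps_stepwise_model` with added `fold_rmses`, `chosen_fold`,
#'   `seed`, `folds`.
#' @export
crossvalidate_method3 <- function(features, ps_ref, k = 5, seed = 1,
                                  alpha = 0.05) {
  features <- as.data.frame(features)
  n <- length(ps_ref)
  if (n < 25L) {
    k <- max(2L, min(k, n %/% 5L))
    warning(sprintf("fewer than 25 segments; falling back to %d folds", k))
  }
  if (n < 2L * k) stop("too few segments for cross-validation")
  fold_id <- with_seed(seed, {
    perm <- sample.int(n)
    id <- integer(n)
    id[perm] <- rep(seq_len(k), length.out = n)
    id
  })
  fold_rmses <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    te <- !tr
    m <- fit_method3_stepwise(features[tr, , drop = FALSE], ps_ref[tr],
                              alpha = alpha)
    pred <- predict_ps(m, features[te, , drop = FALSE])
    fold_rmses[f] <- sqrt(mean((pred - ps_ref[te])^2, na.rm = TRUE))
    models[[f]] <- m
  }
  chosen <- which.min(fold_rmses)
  out <- models[[chosen]]
  out$fold_rmses <- fold_rmses
  out$chosen_fold <- chosen
  out$seed <- seed
  out$folds <- fold_id
  out
}

#' Predict Ps from a fitted model
#'
#' Linear combination of the selected features plus intercept (Method 3) or
#' the RMS line (Method 2). Rows with missing selected features yield `NA`;
#' negative predictions are returned unclipped (flag downstream as needed).
#'
#' @param model a `ps_stepwise_model` or `ps_line_model`.
#' @param features data.frame containing every selected feature column (for a
#'   line model, a column `rms` or a numeric vector of RMS values).
#' @return Ps in cm H2O, one value per row.
#' @export
predict_ps <- function(model, features) {
  if (inherits(model, "ps_line_model")) {
    x <- if (is.data.frame(features)) features$rms else as.numeric(features)
    if (is.null(x)) stop("line model requires an 'rms' column")
    return(predict_method2(model, x))
  }
  stopifnot(inherits(model, "ps_stepwise_model"))
  features <- as.data.frame(features)
  miss <- setdiff(model$selected_features, colnames(features))
  if (length(miss)) {
    stop("missing feature(s) required by the model: ",
         paste(miss, collapse = ", "))
  }
  if (length(model$selected_features) == 0L) {
    return(rep(model$intercept, nrow(features)))
  }
  M <- as.matrix(features[, model$selected_features, drop = FALSE])
  drop(M %*% model$coefficients) + model$intercept
}

#' Serialize a fitted Ps model to JSON
#' @param model a `ps_line_model` or `ps_stepwise_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ps_model <- function(model, path) {
  if (inherits(model, "ps_line_model")) {
    obj <- list(method = 2, slope = model$slope, intercept = model$intercept,
                n = model$n)
  } else if (inherits(model, "ps_stepwise_model")) {
    obj <- list(method = 3, features = as.list(model$coefficients),
                intercept = model$intercept, alpha = model$alpha,
                fold_rmses = model$fold_rmses, chosen_fold = model$chosen_fold,
                seed = model$seed)
  } else stop("unsupported model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Ps model serialized by [write_ps_model()]
#' @param path JSON path.
#' @return a `ps_line_model` or `ps_stepwise_model`.
#' @export
read_ps_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$method == 2) {
    structure(list(slope = obj$slope, intercept = obj$intercept, n = obj$n),
              class = "ps_line_model")
  } else {
    cf <- unlist(obj$features)
    structure(list(selected_features = names(cf),
                   coefficients = cf, intercept = obj$intercept,
                   alpha = obj$alpha, fold_rmses = obj$fold_rmses,
                   chosen_fold = obj$chosen_fold, seed = obj$seed),
              class = "ps_stepwise_model")
  }
}
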