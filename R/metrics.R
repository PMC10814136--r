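#' Root mean square error
#'
#' `sqrt(mean((y - y_hat)^2))`, the calibration/validation/prediction error
#' measure reported as RMSEC/RMSEV/RMSEP in chemometric model tables.
#'
#' @param y numeric vector of reference values.
#' @param y_hat numeric vector of predictions, same length.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stop("rmse: `y` and `y_hat` must have equal, nonzero length")
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((y_hat - y)^2) / sum((mean(y) - y)^2)`. This is the fraction of
#' target variance explained by the predictions, not a squared Pearson
#' correlation: it is negative when predictions are worse than the mean.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stop("r_squared: `y` and `y_hat` must have equal, nonzero length")
  ss_tot <- sum((mean(y) - y)^2)
  if (ss_tot == 0)
    stop("r_squared: `y` is constant; denominator undefined")
  1 - sum((y_hat - y)^2) / ss_tot
}

#' Residual prediction deviation
#'
#' `sd(y) / rmse(y, y_hat)` with the sample (n-1) standard deviation. An
#' RPD above 2 conventionally marks a calibration reliable enough for
#' quantitative use; below 1.4 the model is considered unreliable.
#'
#' @inheritParams rmse
#' @return Positive scalar; `Inf` (with a warning) when the RMSE is zero.
#' @export
rpd <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stop("rpd: `y` and `y_hat` must have equal, nonzero length")
  s <- sd(y)
  if (s == 0) stop("rpd: `y` is constant; SD undefined for the ratio")
  e <- rmse(y, y_hat)
  if (e == 0) {
    warning("rpd: zero RMSE; returning Inf")
    return(Inf)
  }
  s / e
}

#' Reliability class of an RPD value
#'
#' Classifies a residual prediction deviation: below 1.4 "unreliable",
#' 1.4 to 2.0 "reliable", above 2.0 "high". The boundary values 1.4 and 2.0
#' are assigned to the middle class.
#'
#' @param x positive numeric vector of RPD values.
#' @return Factor with levels `unreliable`, `reliable`, `high`.
#' @export
reliability_class <- function(x) {
  if (any(x <= 0)) stop("reliability_class: RPD must be positive")
  cls <- ifelse(x < 1.4, "unreliable", ifelse(x > 2.0, "high", "reliable"))
  factor(cls, levels = c("unreliable", "reliable", "high"))
}

#' Model-comparison metrics table
#'
#' Evaluates trained models on the calibration, validation and prediction
#' parts of a split and assembles the standard chemometric comparison table
#' (R2_C, RMSEC, R2_V, RMSEV, R2_P, RMSEP, RPDP), one row per model and
#' target. Scatter-plot data (measured vs predicted, with split labels) is
#' attached as an attribute for plotting.
#'
#' @param models nested named list: `models[[target]][[model_name]]` is a
#'   trained model with a [predict()] method (PLSR, SVR or neural model).
#' @param X [spectra_matrix] (or bare matrix) of predictor spectra, rows
#'   aligned with `targets`.
#' @param targets [target_table] (or data.frame with the target columns).
#' @param split [dataset_split] from [partition_screened()].
#' @return data.frame of class `metrics_report`; attribute `scatter` holds
#'   the per-sample measured/predicted pairs.
#' @export
evaluate_all <- function(models, X, targets, split) {
  Xv <- spectra_values(X)
  for (part in c("cal_idx", "val_idx", "pred_idx"))
    if (is.null(split[[part]]) || length(split[[part]]) == 0L)
      stop("evaluate_all: split is missing part ", part)
  rows <- list(); scat <- list()
  for (tg in names(models)) {
    if (!tg %in% names(targets))
      stop("evaluate_all: target column not found: ", tg)
    y <- targets[[tg]]
    for (mn in names(models[[tg]])) {
      m <- models[[tg]][[mn]]
      cell <- list(target = tg, model = mn)
      for (part in c("C", "V", "P")) {
        idx <- switch(part, C = split$cal_idx, V = split$val_idx,
                      P = split$pred_idx)
        yh <- as.numeric(predict(m, Xv[idx, , drop = FALSE]))
        cell[[paste0("R2_", part)]] <- r_squared(y[idx], yh)
        cell[[paste0("RMSE", part)]] <- rmse(y[idx], yh)
        if (part == "P") cell$RPDP <- rpd(y[idx], yh)
        scat[[length(scat) + 1L]] <- data.frame(
          target = tg, model = mn, part = part,
          measured = y[idx], predicted = yh)
      }
      rows[[length(rows) + 1L]] <- as.data.frame(cell)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("target", "model", "R2_C", "RMSEC", "R2_V", "RMSEV",
                 "R2_P", "RMSEP", "RPDP")]
  rownames(out) <- NULL
  attr(out, "scatter") <- do.call(rbind, scat)
  class(out) <- c("metrics_report", "data.frame")
  out
}
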