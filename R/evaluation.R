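#' @title Recovery and classification metrics
#' @description
#' Error metrics for coordinate recovery (MAE, MSE, MAPE — MAPE carries the
#' 100% factor) and confusion-matrix classification metrics (accuracy,
#' precision, recall, F1). Recovery errors are computed over *all*
#' `frames x 34` values of the flattened record by default; under that
#' convention zero-filling `m` of `n` strictly positive values yields the
#' analytic identity `MAPE = 100 m / n` exactly, which anchors the test
#' suite (e.g. a head-group 40-frame zero-fill of a 50-frame record gives
#' `100 * 400 / 1700 = 23.5294%`).
#' @name evaluation
NULL

#' Recovery error metrics
#'
#' `MAE = (1/n) sum |y - yhat|`, `MSE = (1/n) sum (y - yhat)^2`,
#' `MAPE = (100/n) sum |y - yhat| / |y|`. Truth values equal to 0 are
#' excluded from the MAPE sum with a message (synthetic ground truth is
#' never 0, so this is a guard, not a code path the pipeline exercises).
#'
#' @param truth ground-truth [gait_sequence].
#' @param pred predicted/recovered [gait_sequence] of the same shape.
#' @param scope `"all"` (every value of the flattened record, default) or
#'   `"missing"` (only values invisible in `mask_from`).
#' @param mask_from sequence whose visibility mask defines the missing set
#'   for `scope = "missing"`; defaults to `pred`.
#' @return a `recovery_report` data.frame row with `mae`, `mse`, `mape`,
#'   `n_values`.
#' @export
error_metrics <- function(truth, pred, scope = c("all", "missing"),
                          mask_from = pred) {
  scope <- match.arg(scope)
  y <- flatten_record(truth)
  yhat <- flatten_record(pred)
  if (length(y) != length(yhat)) stop("shape mismatch", call. = FALSE)
  if (scope == "missing") {
    vis <- mask_from$visibility
    if (!is.null(mask_from$imputed)) vis <- vis & !mask_from$imputed
    sel <- !as.vector(aperm(array(rep(vis, 2L), c(dim(vis), 2L)), c(3, 2, 1)))
    y <- y[sel]; yhat <- yhat[sel]
  }
  n <- length(y)
  if (n == 0L) {
    return(structure(data.frame(mae = 0, mse = 0, mape = 0, n_values = 0L),
                     class = c("recovery_report", "data.frame")))
  }
  err <- abs(y - yhat)
  nz <- y != 0
  if (any(!nz)) {
    message(sum(!nz), " zero truth values excluded from the MAPE denominator")
  }
  structure(data.frame(
    mae = mean(err),
    mse = mean(err^2),
    mape = 100 * sum(err[nz] / abs(y[nz])) / n,
    n_values = n
  ), class = c("recovery_report", "data.frame"))
}

#' Confusion counts from labels
#'
#' PD is the positive class.
#'
#' @param truth,pred character vectors of `"PD"` / `"HEALTHY"` labels.
#' @return named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == "PD" & pred == "PD"),
    tn = sum(truth == "HEALTHY" & pred == "HEALTHY"),
    fp = sum(truth == "HEALTHY" & pred == "PD"),
    fn = sum(truth == "PD" & pred == "HEALTHY"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/(tp+tn+fp+fn)`, precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)`, F1 `2PR/(P+R)`. Precision and recall are defined as 0 when
#' their denominator is 0 (with a message).
#'
#' @param tp,tn,fp,fn non-negative confusion counts, not all zero.
#' @return a `classification_report` data.frame row.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) { message(what, " undefined (0/0); reported as 0"); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(data.frame(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / total,
    precision = precision, recall = recall, f1 = f1
  ), class = c("classification_report", "data.frame"))
}

#' Assemble per-condition reports into one long table
#'
#' Binds report rows keyed by experimental condition into a long-format
#' table (one row per condition), sorted by key columns; duplicate keys are
#' an error. Suitable for writing as CSV.
#'
#' @param results named or unnamed list of report rows (data.frames) that
#'   already carry their key columns (e.g. `technique`, `group`,
#'   `missing_frames`, `hidden_units`, `seed`).
#' @param keys character vector of key column names present in every row.
#' @return a data.frame.
#' @export
sweep_report <- function(results, keys = c("technique", "group",
                                           "missing_frames")) {
  if (length(results) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(keys)),
                                         keys))
    return(out)
  }
  tab <- do.call(rbind, lapply(results, as.data.frame))
  missing_keys <- setdiff(keys, names(tab))
  if (length(missing_keys)) {
    stop("missing key columns: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  key_str <- do.call(paste, c(tab[keys], sep = "\r"))
  if (anyDuplicated(key_str)) {
    stop("duplicate keys: ", gsub("\r", "/", key_str[duplicated(key_str)][1]),
         call. = FALSE)
  }
  tab[do.call(order, tab[keys]), , drop = FALSE]
}
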