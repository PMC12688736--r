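# Leave-one-out evaluation with ACC / AUC / SEN / SPE.

#' Binarize TRG grades
#'
#' Maps the 4-level tumor regression grade to the binary endpoint.
#' `good_vs_poor` (default): TRG 0-1 = positive (responder) vs TRG 2-3 =
#' negative.  `pcr_vs_rest`: TRG 0 (pathological complete response) =
#' positive vs TRG 1-3 = negative.
#'
#' @param trg integer vector with values in 0:3.
#' @param scheme `"good_vs_poor"` or `"pcr_vs_rest"`.
#' @return factor with levels `c("pos", "neg")`; positive = responder.
#' @export
#' @examples
#' binarize_trg(0:3)
#' binarize_trg(0:3, "pcr_vs_rest")
binarize_trg <- function(trg, scheme = c("good_vs_poor", "pcr_vs_rest")) {
  scheme <- match.arg(scheme)
  if (any(!(trg %in% 0:3))) stop("trg values must lie in 0:3")
  pos <- if (scheme == "good_vs_poor") trg <= 1 else trg == 0
  factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
}

#' Confusion counts
#'
#' @param predicted,actual factors with levels `c("pos", "neg")`.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- factor(as.character(predicted), levels = c("pos", "neg"))
  actual <- factor(as.character(actual), levels = c("pos", "neg"))
  out <- list(TP = sum(predicted == "pos" & actual == "pos"),
              TN = sum(predicted == "neg" & actual == "neg"),
              FP = sum(predicted == "pos" & actual == "neg"),
              FN = sum(predicted == "neg" & actual == "pos"))
  class(out) <- "confusion_counts"
  out
}

#' Metrics from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`, all in percent.  An undefined denominator
#' yields `NA` with the reason recorded in the `"reason"` attribute,
#' never a silent 0.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return named numeric vector `c(ACC =, SEN =, SPE =)` in percent.
#' @export
#' @examples
#' confusion_metrics(list(TP = 3, TN = 2, FP = 1, FN = 0))
confusion_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion table")
  reason <- character(0)
  acc <- 100 * (TP + TN) / total
  if (TP + FN > 0) sen <- 100 * TP / (TP + FN)
  else { sen <- NA_real_; reason <- c(reason, "SEN undefined: no positives") }
  if (TN + FP > 0) spe <- 100 * TN / (TN + FP)
  else { spe <- NA_real_; reason <- c(reason, "SPE undefined: no negatives") }
  out <- c(ACC = acc, SEN = sen, SPE = spe)
  if (length(reason)) attr(out, "reason") <- reason
  out
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive sample scores higher
#' than a randomly chosen negative one, with ties counted 1/2.
#'
#' @param scores numeric decision scores.
#' @param labels factor with levels `c("pos", "neg")` (or logical,
#'   TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.8, 0.7), binarize_trg(c(0, 1, 2)))
auc_rank <- function(scores, labels) {
  if (is.logical(labels)) pos <- labels
  else pos <- factor(as.character(labels), levels = c("pos", "neg")) == "pos"
  if (any(is.na(pos))) stop("labels must be 'pos'/'neg' or logical")
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("single-class labels: AUC undefined")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Leave-one-out evaluation of the fusion + SVM pipeline
#'
#' Runs exactly n folds over the cohort (ordered by `patient_id`, so the
#' result is invariant to row order).  Within each fold the n-1 training
#' rows alone determine the standardization moments, the fusion parameters
#' (trained from the seeded shared initialization) and the SVM; the
#' held-out patient is then scored.  The confusion table thresholds the
#' signed decision score at 0 (score > 0 = predicted responder); AUC is
#' computed on the pooled n held-out scores.
#'
#' @param cohort a `cohort_table`.
#' @param subset integer feature indices (subset of 1:7) used as inputs.
#' @param config a [model_config()].
#' @param seed seed for the fusion-parameter initialization (the data is
#'   fixed; repeats over seeds isolate model stochasticity).
#' @return a `loocv_result` list: `counts` (`confusion_counts`), `metrics`
#'   (ACC/SEN/SPE in percent), `auc`, `scores` (per patient, named by
#'   `patient_id`), `labels`, `subset`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(n_patients = 30), seed = 1)
#' res <- loocv_evaluate(cohort, subset = c(1, 2, 5), seed = 1)
#' res$metrics
loocv_evaluate <- function(cohort, subset = 1:7, config = model_config(),
                           seed = 1) {
  if (!all(subset %in% 1:7) || length(subset) == 0)
    stop("subset must be a non-empty subset of 1:7")
  subset <- sort(unique(as.integer(subset)))
  ord <- order(cohort$patient_id)
  cohort <- cohort[ord, ]
  n <- nrow(cohort)
  if (n < 4) stop("need n >= 4 patients")
  y <- binarize_trg(cohort$trg, config$scheme)
  cls <- table(y)
  if (any(cls < 2)) {
    lone <- names(cls)[cls < 2][1]
    fold <- which(y == lone)[1]
    stop("training fold ", fold, " (patient ", cohort$patient_id[fold],
         ") would lose class '", lone, "'")
  }
  X <- .feature_matrix(cohort, subset)
  ypm <- .pos_neg_to_pm1(y)

  # one shared initialization for the full 7-feature parameter set; each
  # ablation subset takes its rows, so subsets differ only in features
  full <- init_fusion_params(7L, config, seed, features = .feature_name(1:7))
  p0 <- .subset_fusion_params(full, subset)

  lo <- .loocv_fused_cpp(X, ypm, p0$q, p0$K, p0$E, p0$B, p0$u, p0$u0,
                         as.integer(config$epochs), config$step,
                         config$lambda, p0$mode == "embed-sum")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    Ftr <- lo$train_feats[[i]]
    m <- fit_svm(Ftr, y[-i], C = config$C, gamma = config$gamma)
    scores[i] <- decision_score(m, lo$test_feats[i, ])
  }
  names(scores) <- cohort$patient_id
  predicted <- factor(ifelse(scores > 0, "pos", "neg"),
                      levels = c("pos", "neg"))
  counts <- confusion_counts(predicted, y)
  out <- list(counts = counts, metrics = confusion_metrics(counts),
              auc = auc_rank(scores, y), scores = scores, labels = y,
              subset = subset, seed = seed)
  class(out) <- "loocv_result"
  out
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> features %s | ACC %.2f%%  AUC %.3f  SEN %.2f%%  SPE %.2f%%\n",
              paste(x$subset, collapse = " + "), x$metrics[["ACC"]], x$auc,
              x$metrics[["SEN"]], x$metrics[["SPE"]]))
  invisible(x)
}

#' Repeated LOOCV with mean +/- SD reporting
#'
#' Runs [loocv_evaluate()] with E distinct fusion-initialization seeds
#' (`seed_base + 1 ... seed_base + E`; the cohort is fixed) and reports
#' each metric as mean +/- SD over the repeats (SD = 0 when E = 1).
#'
#' @param cohort a `cohort_table`.
#' @param subset integer feature indices (subset of 1:7).
#' @param config a [model_config()].
#' @param E number of repeats (>= 1); defaults to `config$E`.
#' @param seed_base base seed; defaults to `config$seed_base`.
#' @return a `metrics_report` list: `acc_mean`, `acc_sd`, `auc_mean`,
#'   `auc_sd`, `sen_mean`, `sen_sd`, `spe_mean`, `spe_sd` (ACC/SEN/SPE in
#'   percent, AUC in [0,1]), `E`, `scheme`, `per_run` data.frame.
#' @export
repeat_evaluate <- function(cohort, subset = 1:7, config = model_config(),
                            E = config$E, seed_base = config$seed_base) {
  E <- as.integer(E)
  if (is.na(E) || E < 1) stop("E must be >= 1")
  runs <- lapply(seq_len(E), function(r)
    loocv_evaluate(cohort, subset, config, seed = seed_base + r))
  per_run <- data.frame(
    seed = seed_base + seq_len(E),
    acc = vapply(runs, function(r) r$metrics[["ACC"]], 0),
    auc = vapply(runs, function(r) r$auc, 0),
    sen = vapply(runs, function(r) r$metrics[["SEN"]], 0),
    spe = vapply(runs, function(r) r$metrics[["SPE"]], 0)
  )
  msd <- function(v) if (length(v) == 1) c(mean = v, sd = 0)
                     else c(mean = mean(v), sd = sd(v))
  a <- msd(per_run$acc); u <- msd(per_run$auc)
  s <- msd(per_run$sen); p <- msd(per_run$spe)
  out <- list(acc_mean = a[["mean"]], acc_sd = a[["sd"]],
              auc_mean = u[["mean"]], auc_sd = u[["sd"]],
              sen_mean = s[["mean"]], sen_sd = s[["sd"]],
              spe_mean = p[["mean"]], spe_sd = p[["sd"]],
              E = E, scheme = config$scheme, subset = subset,
              seed_base = seed_base, per_run = per_run)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> features %s (E = %d, %s)\n  ACC %.2f +/- %.2f%%  AUC %.2f +/- %.2f  SEN %.2f +/- %.2f%%  SPE %.2f +/- %.2f%%\n",
    paste(x$subset, collapse = " + "), x$E, x$scheme,
    x$acc_mean, x$acc_sd, x$auc_mean, x$auc_sd,
    x$sen_mean, x$sen_sd, x$spe_mean, x$spe_sd))
  invisible(x)
}
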