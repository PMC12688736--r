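# Exhaustive feature-subset ablation.
#
# All 2^m - 1 non-empty subsets of the m = 7 model features are evaluated
# under an identical seed schedule (paired comparison: subsets differ only
# in their features), ranked per metric, and summarized as per-feature
# proportions among the top-K subsets.

#' Enumerate non-empty feature subsets
#'
#' All `2^m - 1` non-empty subsets of `1:m`, ordered by subset size and
#' lexicographically within size.
#'
#' @param m number of features (1 to 20).
#' @return list of integer index vectors.
#' @export
#' @examples
#' length(enumerate_subsets(7))  # 127
enumerate_subsets <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > 20)
    stop("m must lie in 1..20")
  m <- as.integer(m)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  subsets
}

#' Human-readable combination label
#'
#' Ascending feature indices joined by `" + "` (e.g. `"1 + 2 + 4 + 5 + 7"`).
#'
#' @param subset integer feature indices.
#' @return character label.
#' @export
combo_label <- function(subset) {
  paste(sort(unique(as.integer(subset))), collapse = " + ")
}

#' Run the exhaustive ablation
#'
#' Evaluates every non-empty subset of the given features with
#' [repeat_evaluate()] under one shared seed schedule.  A failing subset
#' is recorded (with its combination label and error message), not
#' dropped.  With `cache_dir` set, per-subset results are written as JSON
#' and reused on a re-run, making long ablations resumable.
#'
#' @param cohort a `cohort_table`.
#' @param config a [model_config()]; `config$E` and `config$seed_base`
#'   fix the shared schedule.
#' @param features feature indices to ablate over (default 1:7).
#' @param cache_dir optional directory for per-subset result caching.
#' @param progress print a line per completed subset.
#' @return an `ablation_results` list of per-subset records, each with
#'   `subset`, `label` and `report` (a `metrics_report`) or `error`.
#' @export
run_ablation <- function(cohort, config = model_config(), features = 1:7,
                         cache_dir = NULL, progress = FALSE) {
  subsets <- enumerate_subsets(length(features))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  results <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    subset <- features[subsets[[i]]]
    label <- combo_label(subset)
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0("mask_",
                paste(sprintf("%d", subset), collapse = "-"), ".json"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rec <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
      rep <- rec$report
      report <- structure(as.list(rep[setdiff(names(rep), "per_run")]),
                          class = "metrics_report")
      report$subset <- subset
      results[[i]] <- list(subset = subset, label = label, report = report,
                           cached = TRUE)
      next
    }
    rec <- tryCatch({
      report <- repeat_evaluate(cohort, subset, config)
      list(subset = subset, label = label, report = report)
    }, error = function(e) {
      list(subset = subset, label = label, error = conditionMessage(e))
    })
    results[[i]] <- rec
    if (!is.null(cache_file) && is.null(rec$error)) {
      rep <- rec$report
      jsonlite::write_json(
        list(label = label,
             report = rep[c("acc_mean", "acc_sd", "auc_mean", "auc_sd",
                            "sen_mean", "sen_sd", "spe_mean", "spe_sd",
                            "E", "scheme", "seed_base")]),
        cache_file, auto_unbox = TRUE, digits = NA)
    }
    if (progress)
      message(sprintf("[%3d/%3d] %s", i, length(subsets), label))
  }
  class(results) <- "ablation_results"
  results
}

#' @export
print.ablation_results <- function(x, ...) {
  cat(sprintf("<ablation_results> %d subsets (%d failed)\n", length(x),
              sum(vapply(x, function(r) !is.null(r$error), TRUE))))
  invisible(x)
}

#' Ablation results as a data.frame
#'
#' @param x an `ablation_results`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with columns `combo_label`, `size`, `acc_mean`,
#'   `acc_sd`, `auc_mean`, `auc_sd`, `sen_mean`, `sen_sd`, `spe_mean`,
#'   `spe_sd` (failed subsets carry NA metrics and an `error` column).
#' @export
as.data.frame.ablation_results <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  grab <- function(r, f) if (is.null(r$error)) r$report[[f]] else NA_real_
  out <- data.frame(
    combo_label = vapply(x, `[[`, "", "label"),
    size = vapply(x, function(r) length(r$subset), 0L),
    acc_mean = vapply(x, grab, 0, "acc_mean"),
    acc_sd   = vapply(x, grab, 0, "acc_sd"),
    auc_mean = vapply(x, grab, 0, "auc_mean"),
    auc_sd   = vapply(x, grab, 0, "auc_sd"),
    sen_mean = vapply(x, grab, 0, "sen_mean"),
    sen_sd   = vapply(x, grab, 0, "sen_sd"),
    spe_mean = vapply(x, grab, 0, "spe_mean"),
    spe_sd   = vapply(x, grab, 0, "spe_sd"),
    stringsAsFactors = FALSE
  )
  err <- vapply(x, function(r) r$error %||% NA_character_, "")
  if (any(!is.na(err))) out$error <- err
  out
}

# sortable key: lexicographic on the ascending index sequence (so e.g.
# {1,2} precedes {1,3}), used for deterministic tie-breaks
.mask_string <- function(subset, m = 7) {
  paste(sprintf("%02d", sort(subset)), collapse = "")
}

#' Rank ablation results by a metric
#'
#' Descending by the metric's mean; ties broken by smaller subset size,
#' then lexicographically on the subset mask.  Failed subsets are
#' excluded.
#'
#' @param results an `ablation_results`.
#' @param metric one of `"acc"`, `"auc"`, `"sen"`, `"spe"`.
#' @param K number of top results to keep (<= number of usable results);
#'   if fewer results exist than `K`, all are returned with a warning.
#' @return an `ablation_results` sublist of length `K`, ranked.
#' @export
rank_topk <- function(results, metric = c("acc", "auc", "sen", "spe"),
                      K = 50) {
  metric <- match.arg(metric)
  ok <- results[vapply(results, function(r) is.null(r$error), TRUE)]
  if (length(ok) == 0) stop("no usable ablation results")
  if (K > length(ok)) {
    warning("only ", length(ok), " results available; using all")
    K <- length(ok)
  }
  vals <- vapply(ok, function(r) r$report[[paste0(metric, "_mean")]], 0)
  sizes <- vapply(ok, function(r) length(r$subset), 0L)
  masks <- vapply(ok, function(r) .mask_string(r$subset), "")
  ord <- order(-vals, sizes, masks)
  out <- ok[ord[seq_len(K)]]
  class(out) <- "ablation_results"
  out
}

#' Per-feature proportions among top-K subsets
#'
#' Slot-share (default): a feature's occurrences across the top-K subset
#' masks divided by the total number of feature occurrences across those
#' masks, so shares sum to 1.  `"membership"`: the fraction of top-K
#' subsets containing the feature (does not sum to 1).
#'
#' @param topk a ranked `ablation_results` (from [rank_topk()]).
#' @param features the feature universe (default 1:7).
#' @param mode `"slot_share"` or `"membership"`.
#' @return named numeric vector of shares per feature index.
#' @export
feature_proportions <- function(topk, features = 1:7,
                                mode = c("slot_share", "membership")) {
  mode <- match.arg(mode)
  if (length(topk) == 0) stop("empty top-K list")
  occ <- stats::setNames(numeric(length(features)), as.character(features))
  for (r in topk) {
    hit <- as.character(intersect(r$subset, features))
    occ[hit] <- occ[hit] + 1
  }
  if (mode == "slot_share") occ / sum(occ) else occ / length(topk)
}

#' Proportion table over all four metrics
#'
#' Ranks the ablation results by each of ACC, AUC, SEN and SPE, takes the
#' top K, and tabulates per-feature proportions.
#'
#' @param results an `ablation_results`.
#' @param K top-K cut (default 50).
#' @param features feature universe (default 1:7).
#' @param mode passed to [feature_proportions()].
#' @return matrix, metrics x features, of shares.
#' @export
proportion_table <- function(results, K = 50, features = 1:7,
                             mode = c("slot_share", "membership")) {
  mode <- match.arg(mode)
  metrics <- c("acc", "auc", "sen", "spe")
  tab <- t(vapply(metrics, function(mt)
    feature_proportions(rank_topk(results, mt, K), features, mode),
    numeric(length(features))))
  rownames(tab) <- toupper(metrics)
  tab
}
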