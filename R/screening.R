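# Paired pre/post screening of the candidate markers.
#
# Continuous markers use the paired t-test; binary markers use McNemar's
# chi-square on the discordant pair counts (no continuity correction);
# markers with k >= 3 levels use the Stuart-Maxwell marginal-homogeneity
# test.  Markers with p < alpha become the model features.

.test_result <- function(marker, test, statistic, df, p_value, alpha,
                         note = NULL) {
  res <- list(marker = marker, test = test, statistic = statistic,
              df = df, p_value = p_value,
              significant = is.finite(p_value) && p_value < alpha,
              alpha = alpha, note = note)
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s statistic = %.4f, df = %s, p = %.4g%s\n",
              x$marker, x$test, x$statistic, format(x$df), x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired t-test on pre/post marker values
#'
#' Two-sided paired t-test of the differences `d = pre - post`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom
#' (delegates to [stats::t.test()]).
#'
#' @param pre,post numeric vectors of equal length (paired by patient).
#' @param alpha significance level used to set the `significant` flag.
#' @param marker marker name carried into the result.
#' @return a `test_result` list: `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 4), c(0, 1, 2))
paired_t_test <- function(pre, post, alpha = 0.05, marker = "marker") {
  if (length(pre) != length(post))
    stop("pre and post have different lengths (", length(pre), " vs ",
         length(post), ")")
  if (length(pre) < 2) stop("paired t-test needs n >= 2")
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("non-finite values in pre/post")
  d <- pre - post
  if (sd(d) == 0)
    stop("zero variance of paired differences for ", marker)
  tt <- stats::t.test(pre, post, paired = TRUE)
  .test_result(marker, "paired_t", unname(tt$statistic),
               unname(tt$parameter), tt$p.value, alpha)
}

#' McNemar's test from discordant pair counts
#'
#' Paired chi-square for a binary marker: `chi^2 = (b - c)^2 / (b + c)`
#' with 1 degree of freedom and no continuity correction, where `b` and
#' `c` are the two discordant cross-counts of the paired 2x2 table.
#'
#' @param b,c nonnegative discordant counts (`b + c >= 1`).
#' @param alpha significance level.
#' @param marker marker name carried into the result.
#' @return a `test_result`.
#' @export
#' @examples
#' mcnemar_test(9, 0)$statistic  # 9.000
#' mcnemar_test(9, 1)$statistic  # 6.400
mcnemar_test <- function(b, c, alpha = 0.05, marker = "marker") {
  if (b < 0 || c < 0) stop("discordant counts must be nonnegative")
  if (b + c == 0) stop("no discordant pairs for ", marker)
  tab <- matrix(c(0, c, b, 0), nrow = 2)
  mt <- stats::mcnemar.test(tab, correct = FALSE)
  .test_result(marker, "mcnemar", unname(mt$statistic),
               unname(mt$parameter), mt$p.value, alpha)
}

#' Stuart-Maxwell marginal-homogeneity test
#'
#' Paired chi-square-type test for a categorical marker with k >= 3
#' levels: with cross-table counts `n_ij` (pre level i, post level j),
#' `d_i = n_i. - n_.i` for the first k-1 levels and covariance
#' `V_ii = n_i. + n_.i - 2 n_ii`, `V_ij = -(n_ij + n_ji)`, the statistic
#' is the quadratic form `d' V^- d` referred to chi-square with
#' `df = rank(V)` (a generalized inverse is used, with a note, when V is
#' rank-deficient).  Binary markers are routed to [mcnemar_test()].
#'
#' @param pre,post vectors of equal length over a shared level set.
#' @param levels the level set; defaults to the sorted union of observed
#'   values.
#' @param alpha significance level.
#' @param marker marker name carried into the result.
#' @return a `test_result`; `note` records generalized-inverse use.
#' @export
#' @examples
#' pre  <- c(rep(0, 10), rep(1, 10), rep(2, 10))
#' post <- c(rep(0, 10), rep(0, 10), rep(2, 10))
#' marginal_homogeneity_test(pre, post, levels = 0:2)
marginal_homogeneity_test <- function(pre, post, levels = NULL,
                                      alpha = 0.05, marker = "marker") {
  if (length(pre) != length(post))
    stop("pre and post have different lengths (", length(pre), " vs ",
         length(post), ")")
  if (is.null(levels)) levels <- sort(unique(c(pre, post)))
  if (!all(pre %in% levels) || !all(post %in% levels))
    stop("values outside the declared level set for ", marker)
  k <- length(levels)
  if (k < 2) stop("need at least 2 levels for ", marker)
  if (k == 2) {
    tab <- table(factor(pre, levels = levels), factor(post, levels = levels))
    return(mcnemar_test(tab[1, 2], tab[2, 1], alpha = alpha, marker = marker))
  }
  tab <- table(factor(pre, levels = levels), factor(post, levels = levels))
  tab <- matrix(as.numeric(tab), k, k)
  d <- (rowSums(tab) - colSums(tab))[seq_len(k - 1)]
  V <- matrix(0, k - 1, k - 1)
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      V[i, j] <- if (i == j) rowSums(tab)[i] + colSums(tab)[i] - 2 * tab[i, i]
                 else -(tab[i, j] + tab[j, i])
    }
  }
  if (all(abs(d) < 1e-12) && all(abs(V) < 1e-12)) {
    return(.test_result(marker, "marginal_homogeneity", 0, 0, 1, alpha))
  }
  r <- qr(V)$rank
  note <- NULL
  if (r < k - 1) {
    Vinv <- MASS::ginv(V)
    note <- "rank-deficient covariance; generalized inverse used"
  } else {
    Vinv <- solve(V)
  }
  stat <- drop(t(d) %*% Vinv %*% d)
  p <- if (r == 0) 1 else stats::pchisq(stat, df = r, lower.tail = FALSE)
  .test_result(marker, "marginal_homogeneity", stat, r, p, alpha, note = note)
}

#' Screen candidate markers by paired pre/post tests
#'
#' Runs the marker-appropriate paired test on every candidate marker of a
#' cohort (continuous: paired t; binary: McNemar on the per-patient
#' discordant counts; k >= 3 categorical: Stuart-Maxwell) and selects the
#' markers with `p < alpha` as model features.  A marker whose test
#' degenerates (e.g. zero-variance differences, no discordant pairs) is
#' recorded as not selected, with the reason in its result.
#'
#' @param cohort a `cohort_table`.
#' @param alpha significance level (default 0.05).
#' @return a `screening_result`: `results` (one `test_result` per marker,
#'   canonical order), `table` (data.frame summary), `selected` (feature
#'   indices 1-7 of the selected markers that are model features, ordered),
#'   `selected_markers` (all selected marker names), `alpha`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(), seed = 1)
#' sf <- screen_features(cohort)
#' sf$selected
screen_features <- function(cohort, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  missing_cols <- setdiff(c(paste0("pre_", marker_names()),
                            paste0("post_", marker_names())), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing marker column(s): ",
         paste(missing_cols, collapse = ", "))
  results <- list()
  for (mk in marker_names()) {
    pre <- cohort[[paste0("pre_", mk)]]
    post <- cohort[[paste0("post_", mk)]]
    kind <- .MARKERS$kind[.MARKERS$name == mk]
    res <- tryCatch({
      if (kind == "continuous") {
        paired_t_test(pre, post, alpha = alpha, marker = mk)
      } else {
        levs <- .CAT_LEVELS[[mk]]
        if (length(levs) == 2) {
          tab <- table(factor(pre, levels = levs), factor(post, levels = levs))
          mcnemar_test(tab[1, 2], tab[2, 1], alpha = alpha, marker = mk)
        } else {
          marginal_homogeneity_test(pre, post, levels = levs,
                                    alpha = alpha, marker = mk)
        }
      }
    }, error = function(e) {
      .test_result(mk, if (kind == "continuous") "paired_t" else "paired_chisq",
                   NA_real_, NA_real_, NA_real_, alpha,
                   note = conditionMessage(e))
    })
    results[[mk]] <- res
  }
  tab <- data.frame(
    marker = marker_names(),
    feature_index = .marker_index(marker_names()),
    test = vapply(results, `[[`, "", "test"),
    statistic = vapply(results, `[[`, 0, "statistic"),
    df = vapply(results, function(r) as.numeric(r$df), 0),
    p_value = vapply(results, `[[`, 0, "p_value"),
    significant = vapply(results, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  sel_markers <- tab$marker[tab$significant]
  sel_idx <- sort(.marker_index(sel_markers))
  sel_idx <- sel_idx[!is.na(sel_idx)]
  out <- list(results = results, table = tab, selected = as.integer(sel_idx),
              selected_markers = sel_markers, alpha = alpha)
  class(out) <- "screening_result"
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> alpha = %g\n", x$alpha))
  print(x$table, digits = 4)
  cat("selected model features:",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "(none)",
      "\n")
  invisible(x)
}
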