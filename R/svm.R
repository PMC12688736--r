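# Soft-margin RBF SVM on fused features.
#
# The classifier itself is libsvm via e1071: the dual of
# min 1/2 ||w||^2 + C sum xi_i  s.t.  y_i (w . phi(x_i) + b) >= 1 - xi_i,
# with Gaussian kernel K(x, x') = exp(-gamma ||x - x'||^2).  Decision
# scores are computed directly from the stored support vectors so the
# sign convention (positive = responder) is under our control.

#' Fit a soft-margin RBF SVM
#'
#' @param x numeric matrix of (fused) features, rows = patients.
#' @param labels factor with levels `c("pos", "neg")` (see
#'   [binarize_trg()]); both classes must be present.
#' @param C regularization parameter (> 0).
#' @param gamma RBF width (> 0); `NULL` uses `1 / (d * var(x))` with
#'   `var` the variance of all entries of `x` (falling back to 1 when
#'   degenerate).
#' @return an `svm_model` list: the e1071 fit plus `C`, `gamma` and the
#'   positive-class sign `sign_flip` resolved against libsvm's label
#'   ordering.  Dual coefficients satisfy `|alpha_i y_i| <= C`.
#' @export
fit_svm <- function(x, labels, C = 1.0, gamma = NULL) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("pos", "neg"))
  if (any(is.na(labels))) stop("labels must be 'pos'/'neg'")
  if (nlevels(droplevels(labels)) < 2)
    stop("single-class input: both classes required")
  if (C <= 0) stop("C must be > 0")
  if (is.null(gamma)) {
    v <- var(as.vector(x))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1
  }
  if (gamma <= 0) stop("gamma must be > 0")
  fit <- e1071::svm(x, labels, scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = C,
                    fitted = FALSE)
  # libsvm's decision value is positive for the first training label it
  # encountered; flip so that positive always means "pos"
  first_label <- fit$levels[fit$labels[1]]
  out <- list(fit = fit, C = C, gamma = gamma,
              sign_flip = if (identical(first_label, "pos")) 1 else -1)
  class(out) <- "svm_model"
  out
}

#' Signed decision score of an SVM model
#'
#' Evaluates `sum_i alpha_i y_i K(x_i, x) - rho` over the support vectors,
#' oriented so that positive scores favor the positive (responder) class.
#'
#' @param model an `svm_model` from [fit_svm()].
#' @param x a feature row (or matrix of rows).
#' @return numeric vector of signed margins.
#' @export
decision_score <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  sv <- model$fit$SV
  co <- as.vector(model$fit$coefs)
  rho <- model$fit$rho
  g <- model$gamma
  scores <- apply(x, 1, function(row) {
    d2 <- colSums((t(sv) - row)^2)
    sum(co * exp(-g * d2)) - rho
  })
  model$sign_flip * scores
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF, C = %g, gamma = %g, %d support vectors\n",
              x$C, x$gamma, nrow(x$fit$SV)))
  invisible(x)
}
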