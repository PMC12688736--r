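# Attention-based feature fusion.
#
# Standardized scalar features z_i are lifted to value vectors
# v_i = z_i * e_i + b_i (learnable embedding e_i and offset b_i per
# feature); scaled dot-product scores between a learnable query q and
# per-feature keys k_i, softmax-normalized over the active feature subset,
# give attention weights w_i; the fused representation is the weighted sum
# of the value vectors ("embed-sum" mode, dimension d_k by default).  A
# "weighted-scalar" mode returns (w_i z_i) over the active features
# instead, for interpretability; it is the special case with e_i fixed to
# the standard basis and b_i = 0.

#' Fit per-feature standardization parameters
#'
#' Computes per-column mean and sample standard deviation from the
#' supplied (training) rows only, for the z-score transform
#' `z = (x - mu) / sigma`.
#'
#' @param values numeric matrix, patients x features (colnames kept).
#' @return a `standardization_params` list: `mean`, `sd` (named per
#'   feature).
#' @export
#' @examples
#' sp <- standardize_fit(cbind(a = c(1, 2, 3)))
#' sp$mean; sp$sd
standardize_fit <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("standardization needs >= 2 rows")
  mu <- colMeans(values)
  sigma <- apply(values, 2, sd)
  zero <- sigma <= 0
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(values)[zero] %||% which(zero), collapse = ", "))
  out <- list(mean = mu, sd = sigma)
  class(out) <- "standardization_params"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply fitted standardization parameters
#'
#' `z = (x - mu) / sigma` elementwise, using the fitted training moments;
#' never refits on the supplied rows.
#'
#' @param params a `standardization_params` from [standardize_fit()].
#' @param values matrix (or single row) over the same feature set.
#' @return standardized matrix of the same shape.
#' @export
standardize_apply <- function(params, values) {
  values <- as.matrix(values)
  if (ncol(values) != length(params$mean))
    stop("feature-set mismatch: params have ", length(params$mean),
         " features, data has ", ncol(values))
  if (!is.null(colnames(values)) && !is.null(names(params$mean)) &&
      !identical(colnames(values), names(params$mean)))
    stop("feature-set mismatch: column names differ from fitted features")
  sweep(sweep(values, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Default fusion/model configuration
#'
#' Tunable settings of the fusion + SVM pipeline: key dimension `d_k`
#' (default 8), fusion `mode` (`"embed-sum"` or `"weighted-scalar"`),
#' gradient-descent schedule (`epochs` 200, `step` 0.01, L2 `lambda`
#' 1e-3, init scale `init_sd` 0.1), SVM cost `C` (1) and kernel width
#' `gamma` (`NULL` = 1 / (d * var(fused)), computed per training fold),
#' binary endpoint `scheme`, number of repeats `E` and `seed_base`.
#'
#' @param ... named overrides of the defaults.
#' @return named list of settings.
#' @export
model_config <- function(...) {
  cfg <- list(d_k = 8L, mode = "embed-sum", epochs = 200L, step = 0.01,
              lambda = 1e-3, init_sd = 0.1, C = 1.0, gamma = NULL,
              scheme = "good_vs_poor", E = 5L, seed_base = 0L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown model_config key(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

#' Initialize fusion parameters
#'
#' Draws the learnable query, keys, value embeddings/offsets and the
#' training-time linear head from seeded normal initializations (scale
#' `config$init_sd`).  In weighted-scalar mode the value embeddings are
#' fixed (identity) and only query/keys/head are drawn.
#'
#' @param m number of features the parameter set covers.
#' @param config a [model_config()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @param features optional feature names for the m rows.
#' @return a `fusion_params` list (untrained).
#' @export
init_fusion_params <- function(m, config = model_config(), seed = 1,
                               features = NULL) {
  set.seed(as.integer(seed))
  dk <- as.integer(config$d_k)
  if (dk < 1) stop("d_k must be >= 1")
  mode <- match.arg(config$mode, c("embed-sum", "weighted-scalar"))
  dv <- if (mode == "embed-sum") dk else as.integer(m)
  s <- config$init_sd
  q <- rnorm(dk, 0, s)
  K <- matrix(rnorm(m * dk, 0, s), m, dk)
  if (mode == "embed-sum") {
    E <- matrix(rnorm(m * dv, 0, s), m, dv)
    B <- matrix(rnorm(m * dv, 0, s), m, dv)
  } else {
    E <- diag(1, m, m)
    B <- matrix(0, m, m)
  }
  u <- rnorm(dv, 0, s)
  u0 <- rnorm(1, 0, s)
  if (!is.null(features)) rownames(K) <- rownames(E) <- rownames(B) <- features
  out <- list(q = q, K = K, E = E, B = B, u = u, u0 = u0,
              d_k = dk, d_v = dv, mode = mode, features = features,
              trained = FALSE, loss = NULL)
  class(out) <- "fusion_params"
  out
}

# subset the per-feature rows of a parameter set (paired comparisons across
# ablation subsets reuse one full draw and take rows)
.subset_fusion_params <- function(params, rows) {
  p <- params
  p$K <- params$K[rows, , drop = FALSE]
  if (p$mode == "embed-sum") {
    p$E <- params$E[rows, , drop = FALSE]
    p$B <- params$B[rows, , drop = FALSE]
  } else {
    m <- length(rows)
    p$E <- diag(1, m, m)
    p$B <- matrix(0, m, m)
    p$u <- params$u[rows]
    p$d_v <- m
  }
  p$features <- params$features[rows]
  p
}

#' Attention weights over an active feature subset
#'
#' `w_i = softmax_i( q . k_i / sqrt(d_k) )` over the active features:
#' nonnegative and summing to 1.  Softmax is computed with
#' max-subtraction.
#'
#' @param params a `fusion_params`.
#' @param active integer positions (rows of the parameter set) of the
#'   active features; defaults to all.
#' @return numeric weight vector over `active`.
#' @export
#' @examples
#' p <- init_fusion_params(3, seed = 1)
#' sum(attention_weights(p))  # 1
attention_weights <- function(params, active = seq_len(nrow(params$K))) {
  if (length(active) == 0) stop("active feature subset is empty")
  s <- drop(params$K[active, , drop = FALSE] %*% params$q) / sqrt(params$d_k)
  s <- s - max(s)
  w <- exp(s)
  w / sum(w)
}

#' Fuse a standardized feature row
#'
#' Embed-sum mode: `sum_i w_i (z_i e_i + b_i)`, a d_k-vector.
#' Weighted-scalar mode: `(w_i z_i)` over the active features.
#'
#' @param params a `fusion_params` (trained or initial).
#' @param z standardized feature values for the active features (in the
#'   order of `active`).
#' @param active integer positions of the active features.
#' @return fused numeric vector.
#' @export
fuse <- function(params, z, active = seq_len(nrow(params$K))) {
  if (is.null(params$q)) stop("unfitted fusion params")
  z <- as.numeric(z)
  if (length(z) != length(active))
    stop("z has length ", length(z), " but ", length(active),
         " features are active")
  w <- attention_weights(params, active)
  if (params$mode == "weighted-scalar") return(w * z)
  v <- params$E[active, , drop = FALSE] * z + params$B[active, , drop = FALSE]
  drop(crossprod(v, w))
}

#' Fuse a standardized matrix row-wise
#'
#' @param params a `fusion_params`.
#' @param z standardized matrix (rows = patients, columns = active
#'   features).
#' @param active integer positions of the active features.
#' @return matrix of fused representations (one row per patient).
#' @export
fuse_matrix <- function(params, z, active = seq_len(nrow(params$K))) {
  z <- as.matrix(z)
  out <- apply(z, 1, function(row) fuse(params, row, active))
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}

#' Train the fusion layer
#'
#' Minimizes the L2-regularized logistic loss of a linear head on the
#' fused representation by full-batch gradient descent (step halving on
#' any loss increase, so the recorded loss trace is non-increasing within
#' tolerance).  The head is kept in the returned object for inspection but
#' downstream classification uses a fresh SVM on the frozen fused
#' features.
#'
#' @param z standardized feature matrix (training rows only).
#' @param labels binary labels: a factor with levels `c("pos", "neg")`, or
#'   anything coercible via `labels == "pos"`; both classes must be
#'   present, with >= 2 members each.
#' @param config a [model_config()].
#' @param seed seed for the parameter initialization.
#' @return a trained `fusion_params` with a `loss` trace (length
#'   `epochs + 1`).
#' @export
train_fusion <- function(z, labels, config = model_config(), seed = 1) {
  z <- as.matrix(z)
  y <- .pos_neg_to_pm1(labels)
  if (length(unique(y)) < 2) stop("single-class input: both classes required")
  if (min(table(y)) < 2) stop("need >= 2 patients per class")
  if (length(y) != nrow(z)) stop("labels and z disagree in length")
  params <- init_fusion_params(ncol(z), config, seed, features = colnames(z))
  fit <- .fusion_gd_cpp(z, y, params$q, params$K, params$E, params$B,
                        params$u, params$u0, as.integer(config$epochs),
                        config$step, config$lambda,
                        params$mode == "embed-sum")
  params$q <- drop(fit$q); params$K <- fit$K
  params$E <- fit$E; params$B <- fit$B
  params$u <- drop(fit$u); params$u0 <- fit$u0
  if (!is.null(colnames(z)))
    rownames(params$K) <- rownames(params$E) <- rownames(params$B) <- colnames(z)
  params$loss <- drop(fit$loss)
  params$trained <- TRUE
  params
}

# labels ("pos"/"neg" factor, logical, or 0/1) -> +/-1 numeric
.pos_neg_to_pm1 <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- as.character(labels)
    if (!all(lv %in% c("pos", "neg")))
      stop("labels must be 'pos'/'neg'")
    return(ifelse(lv == "pos", 1, -1))
  }
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  if (all(labels %in% c(0, 1))) return(ifelse(labels == 1, 1, -1))
  if (all(labels %in% c(-1, 1))) return(as.numeric(labels))
  stop("unrecognized label encoding")
}
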