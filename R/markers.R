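# Candidate marker catalogue.
#
# Ten baseline MRI-derived markers are screened; the seven that change
# significantly under NCRT carry the conventional feature labels 1-7 used
# throughout the ablation analysis.  Categorical encodings: N stage 0/1/2,
# T stage 2/3/4, EMVI 0 (absent) / 1 (present), CRM 0 (negative) /
# 1 (positive/threatened).

.MARKERS <- data.frame(
  name = c("circumferential_ratio", "sagittal_longest_diameter", "adc_value",
           "distance_to_anus", "lymph_node_number", "max_lymph_node_diameter",
           "n_stage", "t_stage", "emvi", "crm"),
  kind = c("continuous", "continuous", "continuous", "continuous",
           "continuous", "continuous",
           "ordinal", "ordinal", "binary", "binary"),
  feature_index = c(NA, 1L, 2L, NA, 3L, 4L, 5L, NA, 6L, 7L),
  units = c("ratio", "mm", "10^-3 mm^2/s", "mm", "count", "mm",
            "stage level", "stage level", "indicator", "indicator"),
  stringsAsFactors = FALSE
)

.CAT_LEVELS <- list(
  n_stage = 0:2,
  t_stage = 2:4,
  emvi    = 0:1,
  crm     = 0:1
)

#' Candidate marker names
#'
#' The ten baseline MRI-derived candidate markers, in canonical order
#' (six continuous, then N stage, T stage, EMVI, CRM).
#'
#' @param kind optionally restrict to `"continuous"`, `"ordinal"` or
#'   `"binary"` markers.
#' @return character vector of marker names.
#' @export
#' @examples
#' marker_names()
#' marker_names("binary")
marker_names <- function(kind = NULL) {
  if (is.null(kind)) return(.MARKERS$name)
  kind <- match.arg(kind, c("continuous", "ordinal", "binary"))
  .MARKERS$name[.MARKERS$kind == kind]
}

#' Model feature specifications
#'
#' The seven markers that enter the prediction model, with their
#' conventional integer labels: 1 sagittal longest tumor diameter, 2 ADC
#' value, 3 lymph node number, 4 maximal lymph node diameter, 5 N stage,
#' 6 EMVI, 7 CRM.
#'
#' @return data.frame with columns `index`, `name`, `kind`, `units`,
#'   ordered by `index`.
#' @export
#' @examples
#' feature_specs()
feature_specs <- function() {
  fs <- .MARKERS[!is.na(.MARKERS$feature_index),
                 c("feature_index", "name", "kind", "units")]
  names(fs)[1] <- "index"
  fs <- fs[order(fs$index), ]
  rownames(fs) <- NULL
  fs
}

# name(s) for feature indices 1-7
.feature_name <- function(index) {
  fs <- feature_specs()
  bad <- !(index %in% fs$index)
  if (any(bad)) stop("unknown feature index: ", paste(index[bad], collapse = ", "))
  fs$name[match(index, fs$index)]
}

# feature index (or NA) for marker names
.marker_index <- function(name) {
  .MARKERS$feature_index[match(name, .MARKERS$name)]
}
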