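#' Levan shape classes on the centromeric-index scale
#'
#' Chromosome shape is described by the centromeric index (C.I.), the
#' short-arm length as a percentage of total chromosome length, which by
#' construction lies in \[0, 50\]: 50 is a perfectly median centromere, 0 a
#' strictly terminal one. The conventional Levan arm-ratio bands reduce, on
#' this scale, to four half-open intervals:
#'
#' * `M`  (metacentric):    C.I. in \[37.5, 50\]
#' * `sM` (submetacentric): C.I. in \[25, 37.5)
#' * `sT` (subtelocentric): C.I. in \[12.5, 25)
#' * `T`  (telocentric):    C.I. in \[0, 12.5)
#'
#' The four intervals partition \[0, 50\]; boundaries are closed toward the
#' more metacentric class, so a C.I. of exactly 37.5 is `M`.
#'
#' @param thresholds numeric vector of the three cut points separating
#'   T/sT, sT/sM and sM/M, strictly increasing, all in (0, 50).
#' @return A data frame with one row per class: `label`, `lower`, `upper`,
#'   ordered from `M` down to `T`.
#' @seealso [classify_shape()]
#' @export
#' @examples
#' shape_classes()
shape_classes <- function(thresholds = c(12.5, 25, 37.5)) {
  validate_thresholds(thresholds)
  data.frame(
    label = c("M", "sM", "sT", "T"),
    lower = c(thresholds[3], thresholds[2], thresholds[1], 0),
    upper = c(50, thresholds[3], thresholds[2], thresholds[1]),
    stringsAsFactors = FALSE
  )
}

#' Canonical ordering of shape-class labels, most metacentric first.
#' Ancestral-state tie-breaks follow this order.
#' @keywords internal
SHAPE_LABELS <- c("M", "sM", "sT", "T")

validate_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 3L ||
      anyNA(thresholds)) {
    stop("`thresholds` must be three numeric cut points", call. = FALSE)
  }
  if (any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  if (thresholds[1] <= 0 || thresholds[3] >= 50) {
    stop("`thresholds` must lie strictly inside (0, 50)", call. = FALSE)
  }
  invisible(thresholds)
}

#' Construct a chromosome pair record
#'
#' One homologous chromosome pair summarized by its relative length (R.L.,
#' percent of the total haploid complement length) and centromeric index
#' (C.I., percent), each as mean and standard deviation over replicate
#' metaphase measurements.
#'
#' @param index 1-based rank of the pair within its karyotype.
#' @param rl_mean,rl_sd mean and SD of relative length, percent.
#' @param ci_mean,ci_sd mean and SD of centromeric index, percent.
#' @param shape optional shape label (`"M"`, `"sM"`, `"sT"`, `"T"`) as
#'   given by the source; `NA` if only to be computed.
#' @return A one-row data frame of class `chromosome_pair`.
#' @export
chromosome_pair <- function(index, rl_mean, rl_sd, ci_mean, ci_sd,
                            shape = NA_character_) {
  p <- data.frame(
    index = as.integer(index), rl_mean = as.numeric(rl_mean),
    rl_sd = as.numeric(rl_sd), ci_mean = as.numeric(ci_mean),
    ci_sd = as.numeric(ci_sd), shape = as.character(shape),
    stringsAsFactors = FALSE
  )
  validate_pairs(p)
  class(p) <- c("chromosome_pair", class(p))
  p
}

validate_pairs <- function(p, taxon = NULL) {
  where <- if (is.null(taxon)) "" else sprintf(" (taxon '%s')", taxon)
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      stop(sprintf("%s for pair(s) %s%s", msg,
                   paste(p$index[which(cond)], collapse = ", "), where),
           call. = FALSE)
    }
  }
  num_cols <- c("rl_mean", "rl_sd", "ci_mean", "ci_sd")
  for (col in num_cols) {
    if (anyNA(p[[col]])) {
      stop(sprintf("non-numeric or missing '%s'%s", col, where),
           call. = FALSE)
    }
  }
  bad(p$rl_mean <= 0 | p$rl_mean > 100, "relative length outside (0, 100]")
  bad(p$ci_mean < 0 | p$ci_mean > 50, "centromeric index outside [0, 50]")
  bad(p$rl_sd < 0 | p$ci_sd < 0, "negative standard deviation")
  known <- is.na(p$shape) | p$shape %in% SHAPE_LABELS
  bad(!known, "unknown shape label")
  invisible(p)
}

#' Construct a karyotype
#'
#' An ordered sequence of chromosome pairs for one taxon or population.
#' Pairs are expected in rank order of decreasing relative length, the
#' order in which karyotype tables are conventionally printed; relative
#' lengths must sum to 100 up to a rounding tolerance.
#'
#' @param taxon_id character scalar naming the taxon/population.
#' @param pairs a data frame with columns `index`, `rl_mean`, `rl_sd`,
#'   `ci_mean`, `ci_sd` and optionally `shape`.
#' @param nor_pair optional 1-based index of the pair carrying the
#'   nucleolar organizer region (NOR). Annotation only; nothing computes
#'   on it.
#' @param keep_order if `TRUE`, accept pairs whose `rl_mean` is not
#'   non-increasing (e.g. noisy simulated measurements) instead of
#'   rejecting them.
#' @param rl_tolerance allowed deviation of `sum(rl_mean)` from 100
#'   (default 1.0, absorbing per-pair rounding in published tables).
#' @return An object of class `karyotype`: a list with elements
#'   `taxon_id`, `pairs` (data frame), `diploid_number`, `nor_pair`.
#' @export
#' @examples
#' k <- karyotype("toy", data.frame(
#'   index = 1:2, rl_mean = c(60, 40), rl_sd = c(1, 1),
#'   ci_mean = c(40, 20), ci_sd = c(2, 2)))
#' k$diploid_number
karyotype <- function(taxon_id, pairs, nor_pair = NA_integer_,
                      keep_order = FALSE, rl_tolerance = 1.0) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$shape)) pairs$shape <- NA_character_
  needed <- c("index", "rl_mean", "rl_sd", "ci_mean", "ci_sd")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols)) {
    stop(sprintf("karyotype '%s': missing column(s) %s", taxon_id,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  pairs <- pairs[order(pairs$index), c(needed, "shape"), drop = FALSE]
  rownames(pairs) <- NULL
  if (anyDuplicated(pairs$index)) {
    stop(sprintf("karyotype '%s': duplicate pair index", taxon_id),
         call. = FALSE)
  }
  validate_pairs(pairs, taxon = taxon_id)
  if (!keep_order && is.unsorted(-pairs$rl_mean)) {
    stop(sprintf(
      "karyotype '%s': pairs not in non-increasing relative-length order %s",
      taxon_id, "(use keep_order = TRUE to accept)"), call. = FALSE)
  }
  rl_sum <- sum(pairs$rl_mean)
  if (abs(rl_sum - 100) > rl_tolerance) {
    stop(sprintf(
      "karyotype '%s': relative lengths sum to %.3f, outside 100 +/- %.2f",
      taxon_id, rl_sum, rl_tolerance), call. = FALSE)
  }
  # data-quality flag: an SD of the same magnitude as its mean is almost
  # certainly a transcription artefact, but the value is kept as printed
  odd <- pairs$rl_sd > 0.5 * pairs$rl_mean
  if (any(odd)) {
    warning(sprintf(
      "karyotype '%s': rl_sd > 0.5 * rl_mean for pair(s) %s (kept as given)",
      taxon_id, paste(pairs$index[odd], collapse = ", ")), call. = FALSE)
  }
  structure(
    list(taxon_id = taxon_id, pairs = pairs,
         diploid_number = 2L * nrow(pairs),
         nor_pair = as.integer(nor_pair)),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Karyotype of '%s': 2n = %d (%d pairs)\n",
              x$taxon_id, x$diploid_number, nrow(x$pairs)))
  if (!is.na(x$nor_pair)) cat(sprintf("  NOR-bearing pair: %d\n", x$nor_pair))
  if (all(!is.na(x$pairs$shape))) {
    cat("  formula:", format(summarize_formula(x$pairs$shape)), "\n")
  }
  print(x$pairs, ...)
  invisible(x)
}

#' Construct a karyotype formula
#'
#' Counts of chromosome pairs per shape class, e.g. `19M, 4sM, 1sT`.
#'
#' @param counts named integer vector or list; names must be shape labels.
#' @return An object of class `karyotype_formula`: a full named integer
#'   vector over `M`, `sM`, `sT`, `T` (absent classes zero).
#' @seealso [summarize_formula()], [parse_formula()]
#' @export
karyotype_formula <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) ||
      !all(names(counts) %in% SHAPE_LABELS)) {
    stop("formula counts must be named with shape labels M, sM, sT, T",
         call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    stop("repeated shape class in formula counts", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("formula counts must be non-negative integers", call. = FALSE)
  }
  full <- stats::setNames(integer(4L), SHAPE_LABELS)
  full[names(counts)] <- as.integer(counts)
  structure(full, class = "karyotype_formula")
}

#' @export
format.karyotype_formula <- function(x, ...) {
  keep <- x[x > 0]
  if (!length(keep)) return("0")
  paste(sprintf("%d%s", unname(keep), names(keep)), collapse = ", ")
}

#' @export
print.karyotype_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`==.karyotype_formula` <- function(e1, e2) {
  all(unclass(e1)[SHAPE_LABELS] == unclass(e2)[SHAPE_LABELS])
}
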