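#' Classify chromosome shape from the centromeric index
#'
#' Deterministic step function mapping a centromeric index (percent,
#' 0-50) to one of the four Levan classes. With the default cut points:
#' `M` for C.I. >= 37.5, `sM` for 25 <= C.I. < 37.5, `sT` for
#' 12.5 <= C.I. < 25, `T` below 12.5. Boundaries are closed toward the
#' more metacentric class.
#'
#' @param ci_mean numeric vector of centromeric indices in \[0, 50\].
#' @param thresholds three increasing cut points, see [shape_classes()].
#' @return Character vector of shape labels.
#' @export
#' @examples
#' classify_shape(c(22.4, 32.3, 39.0))  # sT, sM, M
classify_shape <- function(ci_mean, thresholds = c(12.5, 25, 37.5)) {
  validate_thresholds(thresholds)
  if (any(ci_mean < 0 | ci_mean > 50, na.rm = TRUE) || anyNA(ci_mean)) {
    stop("centromeric index must lie in [0, 50]", call. = FALSE)
  }
  # right-closed toward M: findInterval with left-closed bins on thresholds
  idx <- findInterval(ci_mean, thresholds) + 1L  # 1 = T ... 4 = M
  rev(SHAPE_LABELS)[idx]
}

#' Classify every pair of a karyotype
#'
#' Returns a copy of the karyotype with the `shape` column set from each
#' pair's mean centromeric index. Shape labels already present are *not*
#' overwritten silently: pairs whose given label disagrees with the
#' computed class are collected in the `label_conflicts` attribute (a
#' data frame with `index`, `given`, `computed`), a data-quality finding
#' for the caller to inspect.
#'
#' @param k a [karyotype()].
#' @inheritParams classify_shape
#' @return The karyotype with computed shapes; attribute
#'   `label_conflicts` lists disagreements with any given labels.
#' @export
classify_karyotype <- function(k, thresholds = c(12.5, 25, 37.5)) {
  stopifnot(inherits(k, "karyotype"))
  computed <- classify_shape(k$pairs$ci_mean, thresholds)
  given <- k$pairs$shape
  disagree <- !is.na(given) & given != computed
  conflicts <- data.frame(index = k$pairs$index[disagree],
                          given = given[disagree],
                          computed = computed[disagree],
                          stringsAsFactors = FALSE)
  k$pairs$shape <- computed
  attr(k, "label_conflicts") <- conflicts
  k
}

#' Summarize shape labels into a karyotype formula
#'
#' @param shapes character vector of shape labels (one per pair), e.g.
#'   a karyotype's `$pairs$shape` column.
#' @return A [karyotype_formula()]; its `format()` renders classes in the
#'   order `M`, `sM`, `sT`, `T`, omitting empty classes, e.g.
#'   `"19M, 4sM, 1sT"`.
#' @export
summarize_formula <- function(shapes) {
  if (!length(shapes)) stop("no shape labels to summarize", call. = FALSE)
  if (anyNA(shapes) || !all(shapes %in% SHAPE_LABELS)) {
    bad <- unique(shapes[is.na(shapes) | !shapes %in% SHAPE_LABELS])
    stop(sprintf("unknown shape label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  karyotype_formula(table(factor(shapes, levels = SHAPE_LABELS)))
}

#' Parse a karyotype formula string
#'
#' Accepts the conventional comma-separated `count + class` notation,
#' whitespace tolerant: `"16M, 7sM, 1T"` and `"16 M,7sM , 1 T"` parse the
#' same. Inverse of `format()` on a [karyotype_formula()].
#'
#' @param text formula string.
#' @return A [karyotype_formula()].
#' @export
#' @examples
#' parse_formula("20M, 4sM")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (!length(tokens) || any(!nzchar(tokens))) {
    stop(sprintf("malformed karyotype formula: '%s'", text), call. = FALSE)
  }
  m <- regmatches(tokens, regexec("^([0-9]+)\\s*(M|sM|sT|T)$", tokens))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    stop(sprintf("malformed formula token(s): %s",
                 paste(sQuote(tokens[!ok]), collapse = ", ")), call. = FALSE)
  }
  labels <- vapply(m, `[`, "", 3L)
  if (anyDuplicated(labels)) {
    stop(sprintf("repeated shape class in formula: '%s'", text),
         call. = FALSE)
  }
  counts <- as.integer(vapply(m, `[`, "", 2L))
  karyotype_formula(stats::setNames(counts, labels))
}

#' Positionwise karyotype difference under a homology map
#'
#' Compares the shape labels of two karyotypes pair by pair, position `i`
#' of `a` against position `map[i]` of `b`, and reports every position
#' where the labels differ. This is the observable footprint of pericentric
#' inversions / centromeric shifts: same pair, different centromere
#' position.
#'
#' @param a,b character vectors of shape labels, or [karyotype()] objects
#'   with shapes set.
#' @param map a [homology_map()] or an integer permutation (position in
#'   `a` -> position in `b`); default identity, allowed only when lengths
#'   match.
#' @return Data frame with `position` (in `a`), `from` (label in `a`),
#'   `to` (label in `b` at the mapped position), ordered by position.
#' @export
karyotype_diff <- function(a, b, map = NULL) {
  a <- shapes_of(a)
  b <- shapes_of(b)
  if (inherits(map, "homology_map")) map <- map$map
  if (is.null(map)) {
    if (length(a) != length(b)) {
      stop("identity map requires equal pair counts", call. = FALSE)
    }
    map <- seq_along(a)
  }
  if (length(map) != length(a) || length(a) != length(b) ||
      !setequal(map, seq_along(b))) {
    stop("`map` must be a bijection covering all positions of both",
         call. = FALSE)
  }
  to <- b[map]
  differ <- a != to
  data.frame(position = which(differ), from = a[differ], to = to[differ],
             stringsAsFactors = FALSE)
}

# Accept either a karyotype (with shapes set) or a bare label vector.
shapes_of <- function(x) {
  if (inherits(x, "karyotype")) {
    sh <- x$pairs$shape
    if (anyNA(sh)) {
      stop(sprintf("karyotype '%s' has unset shape labels; run %s first",
                   x$taxon_id, "classify_karyotype()"), call. = FALSE)
    }
    sh
  } else {
    as.character(x)
  }
}
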