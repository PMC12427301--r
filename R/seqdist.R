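#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length DNA sequences over
#'   `A, C, G, T, -, N` (case-insensitive).
#' @return An `alignment`: list with `ids` and `mat`, a character matrix
#'   (taxa in rows, sites in columns).
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("empty FASTA file", call. = FALSE)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  new_alignment(names(dna), seqs)
}

#' Build an alignment from named sequences
#'
#' @param ids sequence identifiers (unique).
#' @param seqs character vector of equal-length sequence strings.
#' @return An `alignment` object.
#' @export
new_alignment <- function(ids, seqs) {
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ok <- mat %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok)) {
    stop(sprintf("alignment symbol(s) outside {A,C,G,T,-,N}: %s",
                 paste(unique(mat[!ok]), collapse = ", ")), call. = FALSE)
  }
  rownames(mat) <- ids
  structure(list(ids = as.character(ids), mat = mat), class = "alignment")
}

#' Write an alignment to FASTA
#' @param aln an `alignment`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$ids),
                           apply(aln$mat, 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among *comparable* sites, i.e. those
#' where both symbols are unambiguous bases (`A`, `C`, `G`, `T`); gaps
#' and `N` are pairwise-deleted. No multiple-hit correction is applied.
#'
#' @param a,b character vectors of single symbols (or single strings) of
#'   equal length.
#' @return Numeric in \[0, 1\]; 0 with a warning if no site is comparable.
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  a <- toupper(a)
  b <- toupper(b)
  bases <- c("A", "C", "G", "T")
  comparable <- a %in% bases & b %in% bases
  if (!any(comparable)) {
    warning("no comparable sites; returning 0", call. = FALSE)
    return(0)
  }
  mean(a[comparable] != b[comparable])
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln an `alignment`.
#' @return A `distance_matrix`: list with `ids` and symmetric `mat` with
#'   zero diagonal, entries in \[0, 1\].
#' @export
p_distance_matrix <- function(aln) {
  n <- length(aln$ids)
  mat <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      mat[i, j] <- mat[j, i] <- p_distance(aln$mat[i, ], aln$mat[j, ])
    }
  }
  new_distance_matrix(aln$ids, mat)
}

#' @rdname p_distance_matrix
#' @param ids taxon names.
#' @param mat symmetric numeric matrix, zero diagonal.
#' @export
new_distance_matrix <- function(ids, mat) {
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8) || any(diag(mat) != 0) ||
      any(mat < 0)) {
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  }
  dimnames(mat) <- list(ids, ids)
  structure(list(ids = as.character(ids), mat = mat),
            class = "distance_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration, implemented here rather than
#' delegated: at each step the pair minimizing the rate-corrected
#' criterion \eqn{Q(i,j) = (r-2) d(i,j) - R_i - R_j} is joined (ties
#' broken by the smallest index pair in the current matrix), pendant
#' branch lengths follow the usual three-point formulas, and the new
#' node's distances are \eqn{(d(i,k) + d(j,k) - d(i,j)) / 2}. The last
#' three lineages are joined into one internal node, giving the familiar
#' unrooted basal trifurcation. Negative branch lengths are clamped to
#' zero with a warning.
#'
#' @param d a `distance_matrix` (or plain symmetric matrix with
#'   dimnames) over at least 3 taxa.
#' @return A `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "distance_matrix")) {
    mat <- d$mat
  } else {
    mat <- as.matrix(d)
  }
  n <- nrow(mat)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(mat)
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(x, 0), digits = 12, scientific = FALSE, trim = TRUE)
  }
  nodes <- labels  # Newick fragment per active lineage
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(mat)
    Q <- (r - 2) * mat - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]
    j <- idx[1, 2]
    li <- mat[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- mat[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], bl(li), nodes[j], bl(lj))
    dk <- (mat[i, ] + mat[j, ] - mat[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    mat <- rbind(cbind(mat[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  d12 <- mat[1, 2]; d13 <- mat[1, 3]; d23 <- mat[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], bl(l1),
                    nodes[2], bl(l2), nodes[3], bl(l3))
  if (clamped) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
  }
  ape::read.tree(text = newick)
}

# Non-trivial splits of an unrooted tree as canonical strings: for each
# internal edge, the tip set on the child side, represented by the side
# NOT containing the overall first tip (sorted, comma-joined).
tree_splits <- function(phy, all_tips = sort(phy$tip.label)) {
  n_tip <- ape::Ntip(phy)
  if (n_tip < 4L) return(character(0))
  parts <- ape::prop.part(phy)
  tiplab <- attr(parts, "labels")
  ref <- all_tips[1L]
  out <- vapply(parts, function(p) {
    side <- sort(tiplab[p])
    if (ref %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > length(all_tips) - 2L) {
      return(NA_character_)
    }
    paste(side, collapse = ",")
  }, "")
  unique(out[!is.na(out)])
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' from p-distances for each replicate, and annotates each internal
#' split of the full-data tree with the percentage of replicates whose
#' tree contains that split.
#'
#' @param aln an `alignment` with at least 4 taxa.
#' @param replicates number of bootstrap replicates (the classical
#'   choice is 1000).
#' @param seed integer seed; fixed seed gives identical supports.
#' @return The full-data NJ `phylo` tree with node labels carrying
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  n_sites <- ncol(aln$mat)
  if (is.null(n_sites) || n_sites == 0L) {
    stop("degenerate alignment: zero columns", call. = FALSE)
  }
  full <- nj_tree(p_distance_matrix(aln))
  all_tips <- sort(full$tip.label)
  target <- tree_splits(full, all_tips)
  hits <- stats::setNames(numeric(length(target)), target)
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(n_sites, n_sites, replace = TRUE)
      res <- aln
      res$mat <- aln$mat[, cols, drop = FALSE]
      rep_tree <- suppressWarnings(nj_tree(p_distance_matrix(res)))
      found <- tree_splits(rep_tree, all_tips)
      hit <- target %in% found
      hits[hit] <- hits[hit] + 1
    }
  })
  support <- 100 * hits / replicates
  annotate_splits(full, support)
}

# Write split supports onto the node labels of the full tree.
annotate_splits <- function(phy, support) {
  all_tips <- sort(phy$tip.label)
  parts <- ape::prop.part(phy)
  tiplab <- attr(parts, "labels")
  ref <- all_tips[1L]
  labs <- vapply(seq_along(parts), function(k) {
    side <- sort(tiplab[parts[[k]]])
    if (ref %in% side) side <- setdiff(all_tips, side)
    key <- paste(side, collapse = ",")
    if (key %in% names(support)) {
      format(support[[key]], digits = 4)
    } else {
      ""
    }
  }, "")
  phy$node.label <- labs
  phy
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
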