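empty_events <- function() {
  data.frame(parent = character(), child = character(), kind = character(),
             position = integer(), from = character(), to = character(),
             stringsAsFactors = FALSE)
}

event_row <- function(parent, child, kind, position, from, to) {
  data.frame(parent = parent, child = child, kind = kind,
             position = as.integer(position), from = as.character(from),
             to = as.character(to), stringsAsFactors = FALSE)
}

new_event_scenario <- function(tree, node_states, events) {
  totals <- c(
    inversion = sum(events$kind == "inversion"),
    translocation = sum(events$kind == "translocation")
  )
  structure(list(tree = tree, node_states = node_states, events = events,
                 totals = totals),
            class = "event_scenario")
}

#' @export
print.event_scenario <- function(x, ...) {
  cat(sprintf("Event scenario on %d-leaf tree: %d inversion(s), %s\n",
              ape::Ntip(x$tree), x$totals[["inversion"]],
              sprintf("%d translocation(s)", x$totals[["translocation"]])))
  if (nrow(x$events)) print(x$events, ...)
  invisible(x)
}

# Node naming used throughout: tip labels for leaves; internal nodes get
# their own label when present, otherwise "node<ape number>".
node_names_of <- function(phy) {
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  inner <- if (!is.null(phy$node.label) && all(nzchar(phy$node.label))) {
    phy$node.label
  } else {
    paste0("node", n_tip + seq_len(n_node))
  }
  c(phy$tip.label, inner)
}

#' Small parsimony for one chromosome position
#'
#' Minimum number of state changes over all internal labelings of a
#' rooted tree whose leaves carry shape-class labels, together with one
#' optimal labeling. Computed by dynamic programming over the tree
#' (Sankoff recursion with unit change cost, so multifurcations are
#' handled exactly); the optimal labeling is recovered top-down, breaking
#' ties among equally parsimonious states toward the more metacentric
#' class (`M` before `sM` before `sT` before `T`) — the all-metacentric
#' complement is the presumed primitive condition in these snails.
#'
#' @param tree a `phylo` tree (rooted; an unrooted tree is taken as
#'   rooted at its stored basal node).
#' @param leaf_states named character vector, tip label -> shape label.
#' @param alphabet state alphabet in tie-break preference order.
#' @param cost_matrix optional square change-cost matrix (rows/cols in
#'   `alphabet` order); default unit cost off-diagonal.
#' @return List with `count` (minimal changes) and `states` (named
#'   character vector over all nodes, tips included).
#' @export
#' @examples
#' tr <- read_tree(text = "((a,b),(c,d));")
#' fitch_changes(tr, c(a = "M", b = "M", c = "sT", d = "M"))$count
fitch_changes <- function(tree, leaf_states, alphabet = SHAPE_LABELS,
                          cost_matrix = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(leaf_states))) {
    miss <- setdiff(tree$tip.label, names(leaf_states))
    stop(sprintf("unlabeled leaf/leaves: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  states <- as.character(leaf_states[tree$tip.label])
  if (any(!states %in% alphabet)) {
    stop("leaf state outside the alphabet", call. = FALSE)
  }
  k <- length(alphabet)
  if (is.null(cost_matrix)) {
    cost_matrix <- matrix(1, k, k) - diag(k)
  }
  n_node <- n_tip + tree$Nnode
  S <- matrix(Inf, n_node, k)  # S[v, s]: min changes in subtree of v given s
  S[cbind(seq_len(n_tip), match(states, alphabet))] <- 0
  eo <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[r, 1L]
    child <- eo$edge[r, 2L]
    if (all(!is.finite(S[parent, ]))) S[parent, ] <- 0
    # min over child states of (child table + change cost)
    add <- apply(cost_matrix + matrix(S[child, ], k, k, byrow = TRUE),
                 1L, min)
    S[parent, ] <- S[parent, ] + add
  }
  root <- n_tip + 1L
  count <- min(S[root, ])
  # top-down backtracking, preferring earlier alphabet entries on ties
  pick <- function(scores) which(scores <= min(scores) + 1e-9)[1L]
  assigned <- integer(n_node)
  assigned[seq_len(n_tip)] <- match(states, alphabet)
  assigned[root] <- pick(S[root, ])
  po <- eo$edge[rev(seq_len(nrow(eo$edge))), , drop = FALSE]  # preorder
  for (r in seq_len(nrow(po))) {
    parent <- po[r, 1L]
    child <- po[r, 2L]
    if (child <= n_tip) next
    assigned[child] <- pick(S[child, ] + cost_matrix[assigned[parent], ])
  }
  nm <- node_names_of(tree)
  list(count = as.integer(round(count)),
       states = stats::setNames(alphabet[assigned], nm))
}

#' Modal ancestral karyotype across aligned taxa
#'
#' Per aligned position, the most common shape label across the input
#' karyotypes; ties go to the more metacentric class (`M` first), the
#' presumed primitive state.
#'
#' @param leaf_shapes list of character vectors of equal length (shape
#'   labels per taxon, aligned positionwise), or a matrix with taxa in
#'   rows.
#' @return Character vector of modal labels.
#' @export
reconstruct_root_majority <- function(leaf_shapes) {
  if (is.matrix(leaf_shapes)) {
    leaf_shapes <- split(leaf_shapes, row(leaf_shapes))
  }
  lens <- lengths(leaf_shapes)
  if (!length(leaf_shapes) || any(lens != lens[1L])) {
    stop("all taxa must be aligned to the same pair count", call. = FALSE)
  }
  mat <- do.call(rbind, leaf_shapes)
  apply(mat, 2L, function(col) {
    counts <- table(factor(col, levels = SHAPE_LABELS))
    SHAPE_LABELS[which.max(counts)]  # which.max: first (most metacentric) tie
  })
}

#' Rearrangement events along one tree edge
#'
#' Explains a child karyotype state from its parent state by the minimal
#' event list under the model: a pericentric inversion (or centromeric
#' shift — observationally identical) changes one pair's shape class; a
#' translocation fuses two pairs, removing one pair (diploid number -2)
#' without any inverse (fission) move.
#'
#' With equal pair counts the events are exactly one inversion per mapped
#' position whose labels differ. When the parent has `d` more pairs
#' (`d <= 2`), every choice of `d` parent positions lost to fusion is
#' enumerated, surviving positions are compared in order against the
#' child, and the choice minimizing the inversion count is taken
#' (lexicographically least set of lost positions on ties); the result is
#' `d` translocation events plus the residual inversions.
#'
#' @param parent_states,child_states character vectors of shape labels.
#' @param map optional [homology_map()] or permutation aligning parent to
#'   child positions (equal counts only); default identity.
#' @param parent,child node names used in the event records.
#' @return Data frame of events (`parent`, `child`, `kind`, `position`,
#'   `from`, `to`). Translocation rows carry the lost parent position and
#'   the pair-count change in `from`/`to`.
#' @export
infer_edge_events <- function(parent_states, child_states, map = NULL,
                              parent = "parent", child = "child") {
  np <- length(parent_states)
  nc <- length(child_states)
  if (nc > np) {
    stop("child has more pairs than parent: fissions are not modeled",
         call. = FALSE)
  }
  d <- np - nc
  if (d == 0L) {
    diff <- karyotype_diff(parent_states, child_states, map)
    if (!nrow(diff)) return(empty_events())
    return(event_row(parent, child, "inversion", diff$position,
                     diff$from, diff$to))
  }
  if (!is.null(map)) {
    stop("explicit homology maps are only supported for equal pair counts",
         call. = FALSE)
  }
  if (d > 2L) {
    stop(sprintf(
      "pair-count drop of %d not implemented (exhaustive search limited to 2)",
      d), call. = FALSE)
  }
  lost_sets <- utils::combn(np, d, simplify = FALSE)
  n_inv <- vapply(lost_sets, function(lost) {
    sum(parent_states[-lost] != child_states)
  }, 0L)
  lost <- lost_sets[[which.min(n_inv)]]  # which.min: lexicographically least
  ev <- do.call(rbind, lapply(seq_along(lost), function(k) {
    event_row(parent, child, "translocation", lost[k],
              from = np - k + 1L, to = np - k)
  }))
  survivors <- setdiff(seq_len(np), lost)
  differ <- which(parent_states[survivors] != child_states)
  if (length(differ)) {
    ev <- rbind(ev, event_row(parent, child, "inversion",
                              survivors[differ],
                              parent_states[survivors][differ],
                              child_states[differ]))
  }
  ev
}

#' Infer a full rearrangement scenario on a phylogeny
#'
#' Reconstructs ancestral karyotype states at every internal node and the
#' minimal per-edge event lists explaining the leaf karyotypes:
#'
#' 1. Leaves are positionally aligned. By default (`align = "index"`)
#'    the pair rank order is taken as the homology statement — the
#'    convention for conspecific karyotype tables, whose shared pair
#'    numbering *is* the homology. With `align = "match"` each leaf
#'    karyotype (morphometrics required, equal pair counts) is instead
#'    homologized to the first tip of the tree with
#'    [pair_karyotypes()], appropriate across species whose tables were
#'    ranked independently.
#' 2. Ancestral pair counts are the maximum over each node's children
#'    (fusions only ever reduce the count, so this is the parsimony
#'    optimum); each drop along an edge contributes that many
#'    translocation events.
#' 3. Per aligned position, ancestral shape labels come from
#'    [fitch_changes()] small parsimony with metacentric-first
#'    tie-breaking; each edge gets one inversion per position whose
#'    labels differ between parent and child. With unequal pair counts,
#'    positions are compared up to the shorter state vector (prefix
#'    alignment; see the package vignette for the limitation this
#'    implies).
#'
#' @param tree `phylo` tree whose tip labels name the karyotypes.
#' @param karyotypes named list of [karyotype()] objects or of character
#'   shape-label vectors, covering all tips.
#' @param align `"index"` (default) or `"match"`, see above.
#' @param window_k,shape_penalty,sd_floor,thresholds homology-matching
#'   parameters, see [pair_karyotypes()]; used when `align = "match"`.
#' @return An `event_scenario`: tree, per-node states, event table,
#'   totals by kind. Serialize with [write_scenario_report()].
#' @export
infer_scenario <- function(tree, karyotypes, align = c("index", "match"),
                           window_k = 2, shape_penalty = 1, sd_floor = 0.1,
                           thresholds = c(12.5, 25, 37.5)) {
  align <- match.arg(align)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  miss <- setdiff(tips, names(karyotypes))
  if (length(miss)) {
    stop(sprintf("no karyotype for tip(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  karyotypes <- karyotypes[tips]  # totals invariant to input order
  is_karyo <- vapply(karyotypes, inherits, TRUE, "karyotype")
  labels <- lapply(karyotypes, function(k) {
    if (inherits(k, "karyotype")) shapes_of(classify_or_keep(k, thresholds))
    else as.character(k)
  })
  counts <- lengths(labels)

  # optional positional re-alignment of morphometric karyotypes onto the
  # first tip; the default keeps the tables' own rank order
  if (align == "match" && !all(is_karyo)) {
    stop("align = \"match\" needs full karyotypes with morphometrics",
         call. = FALSE)
  }
  if (align == "match" && length(unique(counts)) > 1L) {
    stop("align = \"match\" requires equal pair counts", call. = FALSE)
  }
  if (align == "match" && length(tips) > 1L) {
    ref <- karyotypes[[1L]]
    for (t in tips[-1L]) {
      hm <- pair_karyotypes(ref, karyotypes[[t]], window_k = window_k,
                            shape_penalty = shape_penalty,
                            sd_floor = sd_floor, thresholds = thresholds)
      labels[[t]] <- labels[[t]][hm$map]
    }
  }

  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  nm <- node_names_of(tree)
  node_count <- integer(n_node)
  node_count[seq_len(n_tip)] <- counts
  eo <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[r, 1L]
    child <- eo$edge[r, 2L]
    node_count[parent] <- max(node_count[parent], node_count[child])
  }

  # per-position small parsimony over tips that still have the position
  max_n <- max(node_count)
  node_states <- matrix(NA_character_, n_node, max_n)
  for (pos in seq_len(max_n)) {
    have <- tips[counts >= pos]
    if (!length(have)) next
    if (length(have) < 2L) {
      st <- labels[[have]][pos]
      keep <- which(node_count >= pos)
      node_states[keep, pos] <- st
      next
    }
    sub <- if (length(have) == length(tips)) tree else
      ape::keep.tip(tree, have)
    leaf_states <- vapply(have, function(t) labels[[t]][pos], "")
    fit <- fitch_changes(sub, leaf_states)
    if (length(have) == length(tips)) {
      node_states[, pos] <- fit$states[nm]
    } else {
      # place subtree states on matching node names; remaining nodes that
      # carry the position inherit the subtree root state
      sub_nm <- names(fit$states)
      hit <- match(sub_nm, nm)
      ok <- !is.na(hit)
      node_states[hit[ok], pos] <- fit$states[ok]
      root_state <- fit$states[ape::Ntip(sub) + 1L]
      fill <- which(node_count >= pos & is.na(node_states[, pos]))
      node_states[fill, pos] <- root_state
    }
  }

  events <- empty_events()
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1L]
    child <- tree$edge[r, 2L]
    ps <- node_states[parent, seq_len(node_count[parent])]
    cs <- node_states[child, seq_len(node_count[child])]
    drop_n <- node_count[parent] - node_count[child]
    if (drop_n > 0L) {
      for (k in seq_len(drop_n)) {
        events <- rbind(events, event_row(
          nm[parent], nm[child], "translocation", NA_integer_,
          from = node_count[parent] - k + 1L,
          to = node_count[parent] - k))
      }
      ps <- ps[seq_len(node_count[child])]
    }
    differ <- which(ps != cs)
    if (length(differ)) {
      events <- rbind(events, event_row(nm[parent], nm[child], "inversion",
                                        differ, ps[differ], cs[differ]))
    }
  }

  states_list <- lapply(seq_len(n_node), function(v) {
    as.character(node_states[v, seq_len(node_count[v])])
  })
  names(states_list) <- nm
  new_event_scenario(tree = tree, node_states = states_list,
                     events = events)
}

# shapes from given labels when complete, otherwise classified
classify_or_keep <- function(k, thresholds) {
  if (anyNA(k$pairs$shape)) classify_karyotype(k, thresholds) else k
}
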