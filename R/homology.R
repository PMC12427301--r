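#' Morphometric distance between two chromosome pairs
#'
#' Squared z-distance on (relative length, centromeric index), with the
#' two pairs' SDs pooled in quadrature as the natural scale:
#' \deqn{cost = z_{rl}^2 + z_{ci}^2,\quad
#'       z_{rl} = \frac{rl_p - rl_q}{\sqrt{sd_{rl,p}^2 + sd_{rl,q}^2}}}
#' and analogously for the centromeric index. The cost is symmetric,
#' unitless, and zero exactly when both means agree. SDs below
#' `sd_floor` (default 0.1 percentage points) are raised to the floor so
#' degenerate noise-free inputs cannot produce infinite z-scores.
#'
#' @param p,q single chromosome pairs: one-row data frames (or lists)
#'   with `rl_mean`, `rl_sd`, `ci_mean`, `ci_sd`.
#' @param sd_floor minimum SD used in the pooling, percentage points.
#' @return Non-negative numeric scalar.
#' @export
assignment_cost <- function(p, q, sd_floor = 0.1) {
  z_rl <- (p$rl_mean - q$rl_mean) /
    sqrt(max(p$rl_sd, sd_floor)^2 + max(q$rl_sd, sd_floor)^2)
  z_ci <- (p$ci_mean - q$ci_mean) /
    sqrt(max(p$ci_sd, sd_floor)^2 + max(q$ci_sd, sd_floor)^2)
  z_rl^2 + z_ci^2
}

#' Homologize two karyotypes by SD-constrained minimum-cost matching
#'
#' Finds the bijection between the chromosome pairs of two karyotypes of
#' equal pair count that minimizes the summed [assignment_cost()], plus
#' `shape_penalty` for every assignment whose two pairs carry different
#' shape labels (a soft parsimony preference: matchings that imply fewer
#' shape changes are preferred when morphometrics allow). An assignment
#' of position `i` to position `j` is *feasible* only when the relative
#' lengths are compatible within their measurement uncertainty:
#' `|rl_a[i] - rl_b[j]| <= window_k * (rl_sd_a[i] + rl_sd_b[j])` — the
#' "shift to a nearby rank only" rule.
#'
#' Among cost-optimal matchings the result is made deterministic by
#' preferring, in order: fewest positions displaced from the identity,
#' then the lexicographically least permutation. Optimal-matching ties
#' are resolved exactly on the tight-edge subgraph of the assignment
#' duals, not by epsilon perturbation.
#'
#' @param a,b [karyotype()] objects with equal pair counts.
#' @param window_k rank-shift window in pooled-SD units (default 2).
#' @param shape_penalty cost added when matched pairs differ in shape
#'   (default 1; 0 decouples matching from shapes).
#' @param sd_floor see [assignment_cost()].
#' @param thresholds used to compute shapes for pairs lacking labels.
#' @return A `homology_map`: list with `map` (integer vector, position in
#'   `a` -> position in `b`), `cost` (per-assignment morphometric cost),
#'   `total_cost` (including shape penalties).
#' @export
pair_karyotypes <- function(a, b, window_k = 2, shape_penalty = 1,
                            sd_floor = 0.1, thresholds = c(12.5, 25, 37.5)) {
  stopifnot(inherits(a, "karyotype"), inherits(b, "karyotype"))
  if (nrow(a$pairs) != nrow(b$pairs)) {
    stop(sprintf("unequal pair counts (%d vs %d); %s", nrow(a$pairs),
                 nrow(b$pairs),
                 "fusion detection operates on formulas, not positions"),
         call. = FALSE)
  }
  if (window_k <= 0) stop("window_k must be positive", call. = FALSE)
  n <- nrow(a$pairs)
  sh_a <- a$pairs$shape
  sh_b <- b$pairs$shape
  if (anyNA(sh_a)) sh_a <- classify_shape(a$pairs$ci_mean, thresholds)
  if (anyNA(sh_b)) sh_b <- classify_shape(b$pairs$ci_mean, thresholds)

  base <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    base[i, j] <- assignment_cost(a$pairs[i, ], b$pairs[j, ], sd_floor)
  }
  penal <- shape_penalty * outer(sh_a, sh_b, `!=`)
  feasible <- abs(outer(a$pairs$rl_mean, b$pairs$rl_mean, `-`)) <=
    window_k * outer(a$pairs$rl_sd, b$pairs$rl_sd, `+`)
  cost <- base + penal
  cost[!feasible] <- ASSIGN_BIG

  if (!any(feasible)) stop("no feasible assignments at all", call. = FALSE)
  sol <- solve_assignment(cost)
  if (any(!feasible[cbind(seq_len(n), sol$assignment)])) {
    blocked <- which(!feasible[cbind(seq_len(n), sol$assignment)])
    stop(sprintf(
      "no SD-window-feasible perfect matching; blocking position(s) in a: %s",
      paste(blocked, collapse = ", ")), call. = FALSE)
  }

  # every optimal matching lives in the tight subgraph of the duals
  tol <- 1e-8 * (1 + abs(sol$cost))
  tight <- feasible &
    (cost - outer(sol$u, sol$v, `+`)) <= tol
  map <- resolve_ties(tight, sol$assignment)

  per_cost <- base[cbind(seq_len(n), map)]
  new_homology_map(map, per_cost,
                   total_cost = sum(cost[cbind(seq_len(n), map)]))
}

new_homology_map <- function(map, cost, total_cost) {
  structure(list(map = as.integer(map), cost = as.numeric(cost),
                 total_cost = as.numeric(total_cost)),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  moved <- which(x$map != seq_along(x$map))
  cat(sprintf("Homology map over %d pairs, total cost %.4g\n",
              length(x$map), x$total_cost))
  if (length(moved)) {
    cat("  displaced:",
        paste(sprintf("%d->%d", moved, x$map[moved]), collapse = ", "), "\n")
  } else {
    cat("  identity\n")
  }
  invisible(x)
}

# Deterministic selection among optimal matchings, all of which are
# perfect matchings of the 0/1 tight-edge graph: minimize the number of
# displaced positions, then pick the lexicographically least permutation,
# by sequential fixing with exact integer assignment subproblems.
resolve_ties <- function(tight, fallback) {
  n <- nrow(tight)
  if (all(diag(tight))) return(seq_len(n))  # identity is optimal
  disp <- matrix(1, n, n)
  diag(disp) <- 0
  disp[!tight] <- ASSIGN_BIG
  d_star <- solve_assignment(disp)$cost
  if (d_star >= ASSIGN_BIG) return(fallback)  # cannot happen; safety net
  map <- integer(n)
  used <- rep(FALSE, n)
  spent <- 0
  for (i in seq_len(n)) {
    cand <- which(tight[i, ] & !used)  # ascending: lexicographically least
    for (j in cand) {
      add <- as.numeric(i != j)
      rest_i <- setdiff(seq_len(n), seq_len(i))
      rest_j <- which(!used & seq_len(n) != j)
      rest <- if (length(rest_i)) {
        solve_assignment(disp[rest_i, rest_j, drop = FALSE])$cost
      } else 0
      if (spent + add + rest <= d_star + 0.5) {
        map[i] <- j
        used[j] <- TRUE
        spent <- spent + add
        break
      }
    }
    if (map[i] == 0L) return(fallback)  # safety net
  }
  map
}
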