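# Shared fixtures and independent oracles for the test suite.

table1_path <- function() {
  system.file("extdata", "trochoidea_caroni_karyotypes.tsv",
              package = "karyevol")
}

# the bundled published table; the Palermo SD anomaly warning is expected
table1_karyotypes <- function() {
  suppressWarnings(read_karyotype_table(table1_path()))
}

# random karyotype pair for matching tests: perturbed copies of a common
# decreasing relative-length profile
random_karyotype <- function(n, taxon = "x", jitter = 0.3) {
  w <- sort(stats::runif(n, 1, 8), decreasing = TRUE)
  rl <- 100 * w / sum(w)
  suppressWarnings(karyotype(taxon, data.frame(
    index = seq_len(n), rl_mean = rl,
    rl_sd = stats::runif(n, 0.2, 1.2),
    ci_mean = stats::runif(n, 0, 50), ci_sd = stats::runif(n, 0.5, 3),
    stringsAsFactors = FALSE), keep_order = TRUE))
}

perturbed_copy <- function(k, taxon = "y", jitter = 0.3) {
  p <- k$pairs
  rl <- pmax(p$rl_mean + stats::rnorm(nrow(p), 0, jitter), 0.1)
  rl <- 100 * rl / sum(rl)
  suppressWarnings(karyotype(taxon, data.frame(
    index = p$index, rl_mean = rl,
    rl_sd = stats::runif(nrow(p), 0.2, 1.2),
    ci_mean = pmin(pmax(p$ci_mean + stats::rnorm(nrow(p), 0, 2), 0), 50),
    ci_sd = stats::runif(nrow(p), 0.5, 3),
    stringsAsFactors = FALSE), keep_order = TRUE))
}

# all permutations of 1..n (n <= 8), cached
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- setdiff(seq_len(n), k)
      cbind(k, matrix(rest[sub], nrow(sub)))
    }))
  }
  dimnames(res) <- NULL
  .perm_cache[[key]] <- res
  res
}

# independent recomputation of the matching costs from the stated formula
oracle_cost_matrix <- function(a, b, shape_penalty = 1, sd_floor = 0.1) {
  pa <- a$pairs; pb <- b$pairs
  n <- nrow(pa)
  sh_a <- ifelse(is.na(pa$shape), classify_shape(pa$ci_mean), pa$shape)
  sh_b <- ifelse(is.na(pb$shape), classify_shape(pb$ci_mean), pb$shape)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    zr <- (pa$rl_mean[i] - pb$rl_mean[j]) /
      sqrt(max(pa$rl_sd[i], sd_floor)^2 + max(pb$rl_sd[j], sd_floor)^2)
    zc <- (pa$ci_mean[i] - pb$ci_mean[j]) /
      sqrt(max(pa$ci_sd[i], sd_floor)^2 + max(pb$ci_sd[j], sd_floor)^2)
    C[i, j] <- zr^2 + zc^2 + shape_penalty * (sh_a[i] != sh_b[j])
  }
  C
}

oracle_feasible <- function(a, b, window_k = 2) {
  abs(outer(a$pairs$rl_mean, b$pairs$rl_mean, `-`)) <=
    window_k * outer(a$pairs$rl_sd, b$pairs$rl_sd, `+`)
}

# exhaustive matching oracle with the documented tie-breaks:
# min cost, then fewest displacements, then lexicographically least
oracle_best_matching <- function(a, b, window_k = 2, shape_penalty = 1) {
  C <- oracle_cost_matrix(a, b, shape_penalty)
  feas <- oracle_feasible(a, b, window_k)
  n <- nrow(C)
  P <- all_perms(n)
  ok <- rep(TRUE, nrow(P))
  cost <- numeric(nrow(P))
  for (i in seq_len(n)) {
    ok <- ok & feas[cbind(i, P[, i])]
    cost <- cost + C[cbind(i, P[, i])]
  }
  if (!any(ok)) return(NULL)
  P <- P[ok, , drop = FALSE]
  cost <- cost[ok]
  tied <- which(cost <= min(cost) + 1e-9)
  P <- P[tied, , drop = FALSE]
  disp <- rowSums(P != matrix(seq_len(n), nrow(P), n, byrow = TRUE))
  P <- P[disp == min(disp), , drop = FALSE]
  P[do.call(order, as.data.frame(P))[1L], ]
}

# exact branch-and-bound minimum matching cost, independent of the
# Hungarian implementation: most-constrained rows first, candidates
# sorted by cost, lower bound = sum over remaining rows of their
# cheapest still-available candidate, incumbent from the identity.
oracle_bb_min_cost <- function(C, feas) {
  n <- nrow(C)
  C2 <- C
  C2[!feas] <- Inf
  ord <- order(rowSums(feas))
  cand <- lapply(ord, function(r) {
    j <- which(feas[r, ])
    j[order(C2[r, j])]
  })
  costs <- lapply(seq_len(n), function(k) C2[ord[k], cand[[k]]])
  best <- if (all(diag(feas))) sum(diag(C2)) else Inf
  avail <- rep(TRUE, n)
  row_lb <- function(k) {
    for (m in seq_along(cand[[k]])) {
      if (avail[cand[[k]][m]]) return(costs[[k]][m])
    }
    Inf
  }
  rec <- function(k, acc) {
    if (k > n) { best <<- min(best, acc); return(invisible()) }
    tail_lb <- 0
    if (k < n) {
      for (m in (k + 1L):n) tail_lb <- tail_lb + row_lb(m)
    }
    if (!is.finite(tail_lb)) return(invisible())
    for (m in seq_along(cand[[k]])) {
      j <- cand[[k]][m]
      if (!avail[j]) next
      new_acc <- acc + costs[[k]][m]
      if (new_acc + tail_lb >= best - 1e-12) break  # sorted: no better left
      avail[j] <<- FALSE
      rec(k + 1L, new_acc)
      avail[j] <<- TRUE
    }
  }
  rec(1L, 0)
  best
}

# exhaustive small-parsimony oracle: minimum changes over all internal
# labelings of a rooted tree
oracle_parsimony_min <- function(phy, leaf_states,
                                 alphabet = c("M", "sM", "sT", "T")) {
  n_tip <- ape::Ntip(phy)
  n_int <- phy$Nnode
  states <- match(leaf_states[phy$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_along(alphabet)), n_int)))
  edges <- phy$edge
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(states, grid[g, ])
    ch <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    best <- min(best, ch)
  }
  best
}

node_labels_for <- function(phy) {
  c(phy$tip.label, paste0("node", ape::Ntip(phy) + seq_len(phy$Nnode)))
}

random_shape_vector <- function(n) {
  sample(c("M", "sM", "sT", "T"), n, replace = TRUE,
         prob = c(0.6, 0.2, 0.1, 0.1))
}

tiny_alignment <- function() {
  new_alignment(c("a", "b", "c", "d"),
                c("ACGTACGTAC", "ACGTACGTTT", "ACGAACCTAC", "TCGAACCTAC"))
}
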