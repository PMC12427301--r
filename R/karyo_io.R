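#' Read a karyotype morphometric table
#'
#' Karyotype tables are tab-separated with a header row. Required columns:
#' `taxon`, `pair`, `rl_mean`, `rl_sd`, `ci_mean`, `ci_sd`; an optional
#' `shape` column carries shape labels as given by the source (kept
#' verbatim, never recomputed here). One karyotype is returned per
#' distinct taxon, pairs ordered by their 1-based `pair` index.
#'
#' @param path path to a TSV file.
#' @param keep_order,rl_tolerance passed to [karyotype()].
#' @param nor_pair optional named integer vector, taxon -> NOR-bearing
#'   pair index, attached as annotation.
#' @return A named list of [karyotype()] objects (possibly empty).
#' @export
#' @examples
#' path <- system.file("extdata", "trochoidea_caroni_karyotypes.tsv",
#'                     package = "karyevol")
#' ks <- read_karyotype_table(path)
#' names(ks)
read_karyotype_table <- function(path, keep_order = FALSE,
                                 rl_tolerance = 1.0, nor_pair = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  needed <- c("taxon", "pair", "rl_mean", "rl_sd", "ci_mean", "ci_sd")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("karyotype table '%s': missing required column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(stats::setNames(list(), character(0)))
  for (col in c("pair", "rl_mean", "rl_sd", "ci_mean", "ci_sd")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(val) || any(!nzchar(tab[[col]]))) {
      stop(sprintf("karyotype table '%s': non-numeric value in column '%s'",
                   path, col), call. = FALSE)
    }
    tab[[col]] <- val
  }
  if (is.null(tab$shape)) tab$shape <- NA_character_
  tab$shape[!nzchar(trimws(tab$shape)) | is.na(tab$shape)] <- NA_character_
  tab$shape <- ifelse(is.na(tab$shape), NA_character_, trimws(tab$shape))
  dup <- duplicated(tab[c("taxon", "pair")])
  if (any(dup)) {
    stop(sprintf("karyotype table '%s': duplicate (taxon, pair) %s",
                 path, paste(unique(sprintf("(%s, %d)", tab$taxon[dup],
                                            tab$pair[dup])), collapse = " ")),
         call. = FALSE)
  }
  taxa <- unique(tab$taxon)
  out <- lapply(taxa, function(tx) {
    rows <- tab[tab$taxon == tx, , drop = FALSE]
    karyotype(
      taxon_id = tx,
      pairs = data.frame(index = as.integer(rows$pair),
                         rl_mean = rows$rl_mean, rl_sd = rows$rl_sd,
                         ci_mean = rows$ci_mean, ci_sd = rows$ci_sd,
                         shape = rows$shape, stringsAsFactors = FALSE),
      nor_pair = if (!is.null(nor_pair) && tx %in% names(nor_pair))
        nor_pair[[tx]] else NA_integer_,
      keep_order = keep_order, rl_tolerance = rl_tolerance
    )
  })
  stats::setNames(out, taxa)
}

#' Write karyotypes back to a TSV table
#'
#' Inverse of [read_karyotype_table()]; a read/write/read cycle yields
#' identical karyotypes.
#'
#' @param karyotypes a list of [karyotype()] objects.
#' @param path output path.
#' @export
write_karyotype_table <- function(karyotypes, path) {
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  rows <- do.call(rbind, lapply(karyotypes, function(k) {
    data.frame(taxon = k$taxon_id, pair = k$pairs$index,
               rl_mean = k$pairs$rl_mean, rl_sd = k$pairs$rl_sd,
               ci_mean = k$pairs$ci_mean, ci_sd = k$pairs$ci_sd,
               shape = ifelse(is.na(k$pairs$shape), "", k$pairs$shape),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(taxon = character(), pair = integer(),
                       rl_mean = numeric(), rl_sd = numeric(),
                       ci_mean = numeric(), ci_sd = numeric(),
                       shape = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree from a Newick file
#'
#' Thin validated wrapper around [ape::read.tree()]. Internal node labels
#' are read as support values when numeric; branch lengths are optional.
#'
#' @param path path to a Newick file (trailing semicolon required).
#' @param text alternatively, a Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("could not parse Newick tree (unbalanced parentheses or malformed?)",
         call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("tree has duplicate leaf labels", call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label))) {
    stop("tree has an empty leaf label", call. = FALSE)
  }
  if (ape::Ntip(tr) < 2L) stop("tree needs at least 2 leaves", call. = FALSE)
  tr
}

#' Serialize an event scenario to a JSON report
#'
#' The report is deterministic for a fixed scenario: keys appear in a
#' fixed order, events are sorted (edge, kind, position), numbers are
#' written in full precision, and there are no timestamps. The report
#' carries the tree (Newick), per-node karyotype states (pair count and
#' shape labels), the event list, and totals by event kind.
#'
#' @param scenario an `event_scenario`, see [infer_scenario()].
#' @param path output path; use `NULL` to return the JSON string.
#' @return `path` invisibly (or the JSON string when `path` is `NULL`).
#' @seealso [read_scenario_report()]
#' @export
write_scenario_report <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "event_scenario"))
  ev <- scenario$events
  ord <- order(ev$parent, ev$child, ev$kind,
               suppressWarnings(as.numeric(ev$position)))
  ev <- ev[ord, , drop = FALSE]
  ev_list <- lapply(seq_len(nrow(ev)), function(i) {
    list(parent = ev$parent[i], child = ev$child[i], kind = ev$kind[i],
         position = if (is.na(ev$position[i])) NULL else
           as.integer(ev$position[i]),
         from = ev$from[i], to = ev$to[i])
  })
  node_names <- sort(names(scenario$node_states))
  states <- lapply(node_names, function(nm) {
    sh <- scenario$node_states[[nm]]
    list(pair_count = length(sh), shapes = as.list(sh))
  })
  names(states) <- node_names
  report <- list(
    tree = ape::write.tree(scenario$tree),
    node_states = states,
    events = ev_list,
    totals = list(
      inversion = unname(scenario$totals[["inversion"]]),
      translocation = unname(scenario$totals[["translocation"]])
    )
  )
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  con <- file(path, open = "wb")  # binary: byte-stable across platforms
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  invisible(path)
}

#' Read back a JSON scenario report
#'
#' @param path path written by [write_scenario_report()].
#' @return An `event_scenario` equivalent to the one written.
#' @export
read_scenario_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ev <- rep$events
  events <- if (length(ev)) {
    data.frame(
      parent = vapply(ev, `[[`, "", "parent"),
      child = vapply(ev, `[[`, "", "child"),
      kind = vapply(ev, `[[`, "", "kind"),
      position = vapply(ev, function(e)
        if (is.null(e$position)) NA_integer_ else as.integer(e$position), 0L),
      from = vapply(ev, function(e) as.character(e$from), ""),
      to = vapply(ev, function(e) as.character(e$to), ""),
      stringsAsFactors = FALSE)
  } else empty_events()
  states <- lapply(rep$node_states, function(s)
    as.character(unlist(s$shapes)))
  new_event_scenario(
    tree = read_tree(text = rep$tree),
    node_states = states,
    events = events
  )
}
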