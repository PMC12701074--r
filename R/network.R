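# XL-PPI network assembly and interrogation. Edges are unordered protein
# pairs from inter-protein linkages; intra-protein linkages contribute nodes
# (self-evidence) but never edges.

normalize_pairs <- function(a, b) {
  tibble::tibble(p1 = pmin(a, b), p2 = pmax(a, b))
}

#' Build the XL-PPI network from unique linkages
#'
#' One edge per unordered inter-protein pair; the node set is all
#' cross-linked proteins including intra-only ones. Ambiguous linkages
#' (shared peptides) are excluded by default, echoing the
#' unique-peptides-only convention; include them with
#' `include_ambiguous = TRUE` (ambiguity is then propagated to the edge).
#'
#' @param linkages Linkage tibble from [collapse_to_unique_linkages()]
#'   (FDR-filtered).
#' @param include_ambiguous Logical (default FALSE).
#' @return A `kcx_network`: list with `edges` (tibble: `p1`, `p2`,
#'   `n_linkages`, `linkers`, `replicates`, `ambiguous`) and `nodes`
#'   (tibble: `protein`, `n_linkages`, `intra_only`). Rebuilding from a
#'   permuted linkage list yields an identical network.
#' @export
build_network <- function(linkages, include_ambiguous = FALSE) {
  lk <- linkages
  if (!include_ambiguous && nrow(lk)) {
    lk <- dplyr::filter(lk, !.data$ambiguous)
  }
  if (!nrow(lk)) {
    return(structure(list(
      edges = tibble::tibble(p1 = character(), p2 = character(),
                             n_linkages = integer(), linkers = list(),
                             replicates = list(), ambiguous = logical()),
      nodes = tibble::tibble(protein = character(), n_linkages = integer(),
                             intra_only = logical())
    ), class = "kcx_network"))
  }
  reps_of <- function(sup) {
    unique(unlist(purrr::map(sup, function(s) unique(s$replicate))))
  }
  inter <- dplyr::filter(lk, !.data$intra)
  edges <- if (nrow(inter)) {
    d <- dplyr::bind_cols(normalize_pairs(inter$protein_a, inter$protein_b),
                          inter["linkers"],
                          tibble::tibble(support = inter$support,
                                         amb = inter$ambiguous))
    dplyr::summarise(
      dplyr::group_by(d, .data$p1, .data$p2),
      n_linkages = dplyr::n(),
      linkers = list(sort(unique(unlist(.data$linkers)))),
      replicates = list(sort(reps_of(.data$support))),
      ambiguous = any(.data$amb),
      .groups = "drop"
    )
  } else {
    tibble::tibble(p1 = character(), p2 = character(), n_linkages = integer(),
                   linkers = list(), replicates = list(), ambiguous = logical())
  }
  edges <- dplyr::arrange(edges, .data$p1, .data$p2)
  node_ids <- sort(unique(c(lk$protein_a, lk$protein_b)))
  nodes <- tibble::tibble(
    protein = node_ids,
    n_linkages = vapply(node_ids, function(p) {
      sum(lk$protein_a == p | lk$protein_b == p)
    }, integer(1)),
    intra_only = vapply(node_ids, function(p) {
      !any((lk$protein_a == p | lk$protein_b == p) & !lk$intra)
    }, logical(1))
  )
  structure(list(edges = edges, nodes = nodes), class = "kcx_network")
}

#' @export
print.kcx_network <- function(x, ...) {
  cat(sprintf("<kcx_network> %d proteins, %d interactions\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Overlap of the XL edge set with a reference edge set
#'
#' Set intersection on normalized (sorted, de-duplicated) unordered pairs;
#' identifier namespaces must be reconciled by the caller.
#'
#' @param network A `kcx_network` or an edge tibble with `p1`, `p2`.
#' @param reference A data frame with two id columns (first two columns are
#'   used) naming reference interactions.
#' @param name Reference set name carried into the output.
#' @return A one-row tibble: `reference`, `n_edges`, `shared`, `novel`,
#'   `fraction_shared` (shared + novel = n_edges; fraction in `[0, 1]`).
#' @export
overlap_with <- function(network, reference, name = "reference") {
  edges <- if (inherits(network, "kcx_network")) network$edges else network
  ref <- tibble::as_tibble(reference)
  refp <- dplyr::distinct(normalize_pairs(as.character(ref[[1]]),
                                          as.character(ref[[2]])))
  key <- function(d) paste(d$p1, d$p2, sep = "\r")
  shared <- sum(key(edges) %in% key(refp))
  tibble::tibble(
    reference = name, n_edges = nrow(edges), shared = shared,
    novel = nrow(edges) - shared,
    fraction_shared = if (nrow(edges)) shared / nrow(edges) else NA_real_
  )
}

#' Subunit recovery of annotated complexes
#'
#' For each complex with at least one member among the cross-linked proteins,
#' the recovered fraction is `|members in nodes| / |members|`. The
#' "over half" count uses a strict `> 0.5`.
#'
#' @param network A `kcx_network` or a character vector of node proteins.
#' @param complexes Data frame with columns `complex` and `protein`
#'   (long format, one row per member).
#' @param bins Histogram bin breaks on the recovered fraction.
#' @return A list with `per_complex` (tibble: `complex`, `n_members`,
#'   `n_recovered`, `fraction`), `histogram` (counts per bin; sums to the
#'   number of identified complexes) and `frac_over_half`.
#' @export
complex_coverage <- function(network, complexes,
                             bins = seq(0, 1, by = 0.25)) {
  nodes <- if (inherits(network, "kcx_network")) network$nodes$protein
  else as.character(network)
  cx <- tibble::as_tibble(complexes)
  per <- dplyr::summarise(
    dplyr::group_by(cx, .data$complex),
    n_members = dplyr::n_distinct(.data$protein),
    n_recovered = dplyr::n_distinct(.data$protein[.data$protein %in% nodes]),
    .groups = "drop"
  )
  per$fraction <- per$n_recovered / per$n_members
  per <- dplyr::filter(per, .data$n_recovered >= 1)
  h <- if (nrow(per)) {
    table(cut(per$fraction, bins, include.lowest = TRUE))
  } else {
    table(cut(numeric(), bins, include.lowest = TRUE))
  }
  list(per_complex = per,
       histogram = tibble::tibble(bin = names(h), n = as.integer(h)),
       frac_over_half = if (nrow(per)) mean(per$fraction > 0.5) else NA_real_)
}

#' Multi-linker concordance of linkages and edges
#'
#' @param linkages Linkage tibble with `linkers` list column.
#' @return A list with `linkage_counts` and `edge_counts`: tibbles of
#'   `(n_linkers, n)` whose counts partition the totals (edge-level linkers
#'   are the union over the edge's linkages).
#' @export
linker_concordance <- function(linkages) {
  nl <- lengths(purrr::map(linkages$linkers, unique))
  linkage_counts <- dplyr::count(tibble::tibble(n_linkers = nl),
                                 .data$n_linkers)
  inter <- dplyr::filter(linkages, !.data$intra)
  edge_counts <- if (nrow(inter)) {
    d <- dplyr::bind_cols(normalize_pairs(inter$protein_a, inter$protein_b),
                          inter["linkers"])
    e <- dplyr::summarise(dplyr::group_by(d, .data$p1, .data$p2),
                          n_linkers = dplyr::n_distinct(unlist(.data$linkers)),
                          .groups = "drop")
    dplyr::count(e, .data$n_linkers)
  } else {
    tibble::tibble(n_linkers = integer(), n = integer())
  }
  list(linkage_counts = linkage_counts, edge_counts = edge_counts)
}

#' Export a network to GraphML
#'
#' @param network A `kcx_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    d = dplyr::mutate(network$edges,
                      linkers = purrr::map_chr(.data$linkers, paste, collapse = ";"),
                      replicates = purrr::map_chr(.data$replicates, paste,
                                                  collapse = ";")),
    directed = FALSE,
    vertices = network$nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
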