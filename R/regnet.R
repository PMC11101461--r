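#' Filter interaction records for network construction
#'
#' Keeps TF->miRNA records whose TF is an essential gene and whose miRNA is
#' high-rank, and miRNA->gene records whose miRNA is high-rank and whose
#' target is an essential gene; drops `evidence = "other"` (only ChIP-seq
#' level-2 and literature-curated interactions are trusted) and
#' `context = "normal"` (normal-cell-line interactions are excluded).
#'
#' @param records tibble of interaction records (`source`, `target`, `kind`,
#'   `sign`, `evidence`, `context`); see [interaction_records()].
#' @param highrank_mirnas character vector of selected miRNA IDs.
#' @param essential_genes character vector of essential gene symbols.
#' @return filtered records tibble.
#' @export
filter_interactions <- function(records, highrank_mirnas, essential_genes) {
  if (length(highrank_mirnas) == 0 || length(essential_genes) == 0) {
    abort("highrank_mirnas and essential_genes must be nonempty")
  }
  records |>
    filter(.data$evidence != "other", .data$context != "normal") |>
    filter(
      (.data$kind == "tf_mirna" &
         .data$source %in% essential_genes &
         .data$target %in% highrank_mirnas) |
        (.data$kind == "mirna_target" &
           .data$source %in% highrank_mirnas &
           .data$target %in% essential_genes)
    )
}

# Merge a vector of signs on parallel edges: a specific sign (activation /
# repression) overrides generic "regulation"; conflicting specific signs are
# flagged ambiguous.
merge_signs <- function(signs) {
  specific <- unique(signs[signs %in% c("activation", "repression")])
  if (length(specific) == 0) list(sign = "regulation", ambiguous = FALSE)
  else if (length(specific) == 1) list(sign = specific, ambiguous = FALSE)
  else list(sign = "ambiguous", ambiguous = TRUE)
}

#' Build the TF-gene-miRNA regulatory network
#'
#' Directed signed graph from filtered interaction records. Self-loops are
#' dropped, parallel edges are collapsed (specific signs beat generic
#' "regulation"; conflicting activation/repression is flagged ambiguous), and
#' each node gets a role: sources of TF->miRNA edges are TFs, miRNAs come
#' from either table's miRNA slot, and remaining targets are genes. A symbol
#' acting both as TF and as miRNA target keeps the TF role.
#'
#' @param records filtered interaction records.
#' @return a `regulatory_network`: list with `nodes` (tibble `name`, `role`),
#'   `edges` (tibble `source`, `target`, `kind`, `sign`, `ambiguous`) and
#'   `graph` (directed igraph with the same attributes).
#' @export
build_network <- function(records) {
  if (nrow(records) == 0) {
    warn("no interaction records: returning an empty network")
    nodes <- tibble(name = character(0), role = character(0))
    edges <- tibble(source = character(0), target = character(0),
                    kind = character(0), sign = character(0),
                    ambiguous = logical(0))
    g <- igraph::make_empty_graph(directed = TRUE)
    return(structure(list(nodes = nodes, edges = edges, graph = g),
                     class = "regulatory_network"))
  }
  records <- filter(records, .data$source != .data$target)
  edges <- records |>
    group_by(.data$source, .data$target) |>
    summarise(
      kind = .data$kind[1],
      merged = list(merge_signs(.data$sign)),
      .groups = "drop"
    ) |>
    mutate(
      sign = purrr::map_chr(.data$merged, "sign"),
      ambiguous = purrr::map_lgl(.data$merged, "ambiguous")
    ) |>
    select(-"merged") |>
    arrange(.data$source, .data$target)
  tf <- unique(edges$source[edges$kind == "tf_mirna"])
  mir <- unique(c(edges$target[edges$kind == "tf_mirna"],
                  edges$source[edges$kind == "mirna_target"]))
  all_nodes <- unique(c(edges$source, edges$target))
  role <- ifelse(all_nodes %in% tf, "TF",
                 ifelse(all_nodes %in% mir, "miRNA", "gene"))
  nodes <- tibble(name = sort(all_nodes)) |>
    mutate(role = role[match(.data$name, all_nodes)])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  counts <- table(factor(x$nodes$role, levels = c("TF", "gene", "miRNA")))
  cat(sprintf(
    "<regulatory_network> %d nodes (%d TF, %d gene, %d miRNA), %d edges\n",
    nrow(x$nodes), counts[["TF"]], counts[["gene"]], counts[["miRNA"]],
    nrow(x$edges)
  ))
  invisible(x)
}

#' Maximal clique centrality (MCC) scores
#'
#' On the undirected simple projection of the network, the MCC of a node is
#' the sum of `(|C| - 1)!` over all maximal cliques `C` containing it, with
#' `|C| >= 2` (isolated nodes score 0). Maximal cliques are enumerated
#' exactly (Bron-Kerbosch with pivoting). For a node contained in no
#' triangle, every incident edge is its own maximal 2-clique and the score
#' reduces to the node's degree.
#'
#' @param net a [build_network()] result.
#' @return tibble (class `hub_scores`) with `node`, `role`, `mcc`, `degree`,
#'   `rank`, sorted by rank.
#' @export
mcc_scores <- function(net) {
  if (nrow(net$nodes) == 0) abort("network is empty")
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  g <- igraph::simplify(g)
  score <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  deg <- igraph::degree(g)
  out <- tibble(
    node = names(score),
    role = net$nodes$role[match(names(score), net$nodes$name)],
    mcc = unname(score),
    degree = unname(deg[names(score)])
  ) |>
    arrange(desc(.data$mcc), desc(.data$degree), .data$node) |>
    mutate(rank = row_number())
  structure(out, class = c("hub_scores", class(tibble())))
}

#' Top hub nodes by MCC
#'
#' @param scores a [mcc_scores()] tibble.
#' @param n number of hubs to keep (default 10); all nodes if fewer exist.
#'   Ties are broken by degree, then by symbol order.
#' @return the first `n` rows of the ranked hub table.
#' @export
top_hubs <- function(scores, n = 10) {
  head(scores, n)
}

#' Export a network as SIF
#'
#' One line per edge: `source<TAB>sign<TAB>target`.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  readr::write_tsv(
    net$edges |> transmute(.data$source, interaction = .data$sign, .data$target),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Export a network as GraphML (role and sign attributes included)
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
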