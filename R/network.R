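#' Construct a typed regulatory network
#'
#' Builds the tripartite propagation substrate used throughout the package:
#' transcription factors (TFs), regulatory regions (enhancers/peaks) and
#' target genes, linked by weighted, layered edges. Region nodes carry a
#' genomic interval (0-based half-open); genes may carry one through a
#' separate annotation table.
#'
#' Duplicate `(source, target, layer)` edges are collapsed by summing their
#' importance. Node kinds are taken from `nodes` when given, otherwise
#' inferred from the edge layers (`tf-region`, `region-gene`, `tf-gene`);
#' region intervals are parsed from canonical `"chrom:start-end"` ids when
#' no node table provides them.
#'
#' @param edges Data frame with columns `source`, `target`, `importance`
#'   (non-negative finite), `layer` (one of `"tf-region"`, `"region-gene"`,
#'   `"tf-gene"`).
#' @param nodes Optional data frame with columns `id`, `kind` and optionally
#'   `chrom`, `start`, `end`, `strand`. When given, every edge endpoint must
#'   appear in it.
#' @return An object of class `regulatory_network`: a list with tibbles
#'   `$nodes` (`id`, `kind`, `chrom`, `start`, `end`, `strand`) and
#'   `$edges` (`source`, `target`, `importance`, `layer`).
#' @examples
#' edges <- tibble::tibble(
#'   source = c("TF1", "chr1:100-200"),
#'   target = c("chr1:100-200", "g1"),
#'   importance = c(1, 0.5),
#'   layer = c("tf-region", "region-gene")
#' )
#' net <- regulatory_network(edges)
#' net$nodes
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("source", "target", "importance", "layer")
  missing_col <- setdiff(required, names(edges))
  if (length(missing_col) > 0) {
    abort(sprintf("edge table is missing column(s): %s",
                  paste(missing_col, collapse = ", ")),
          class = "osteoatlas_format_error")
  }
  bad_layer <- setdiff(unique(edges$layer), c("tf-region", "region-gene", "tf-gene"))
  if (length(bad_layer) > 0) {
    abort(sprintf("unknown edge layer(s): %s", paste(bad_layer, collapse = ", ")),
          class = "osteoatlas_value_error")
  }
  if (any(!is.finite(edges$importance)) || any(edges$importance < 0)) {
    abort("edge importance must be finite and >= 0",
          class = "osteoatlas_value_error")
  }
  if (any(edges$source == edges$target)) {
    abort("self-loops are not allowed", class = "osteoatlas_value_error")
  }

  edges <- edges |>
    dplyr::group_by(.data$source, .data$target, .data$layer) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop") |>
    dplyr::select("source", "target", "importance", "layer")

  if (is.null(nodes)) {
    nodes <- infer_node_table(edges)
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!all(c("id", "kind") %in% names(nodes))) {
      abort("node table must have columns id and kind",
            class = "osteoatlas_format_error")
    }
    if (anyDuplicated(nodes$id)) {
      abort("node ids must be unique", class = "osteoatlas_integrity_error")
    }
    endpoints <- union(edges$source, edges$target)
    unknown <- setdiff(endpoints, nodes$id)
    if (length(unknown) > 0) {
      abort(sprintf("edge endpoint(s) not in node table: %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "osteoatlas_integrity_error")
    }
    for (col in c("chrom", "strand")) {
      if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
    }
    for (col in c("start", "end")) {
      if (!col %in% names(nodes)) nodes[[col]] <- NA_integer_
    }
    nodes <- nodes[, c("id", "kind", "chrom", "start", "end", "strand")]
  }

  bad_kind <- setdiff(unique(nodes$kind), c("TF", "gene", "region"))
  if (length(bad_kind) > 0) {
    abort(sprintf("node kind must be TF, gene or region; got: %s",
                  paste(bad_kind, collapse = ", ")),
          class = "osteoatlas_value_error")
  }

  # region nodes without an interval: parse from canonical chrom:start-end id
  need <- nodes$kind == "region" & is.na(nodes$chrom)
  if (any(need)) {
    parsed <- parse_region_id(nodes$id[need])
    nodes$chrom[need] <- parsed$chrom
    nodes$start[need] <- parsed$start
    nodes$end[need] <- parsed$end
  }
  reg <- nodes$kind == "region"
  if (any(reg & (is.na(nodes$chrom) | is.na(nodes$start) | is.na(nodes$end)))) {
    abort("every region node needs an interval (chrom:start-end id or node table)",
          class = "osteoatlas_value_error")
  }
  has_iv <- !is.na(nodes$start) & !is.na(nodes$end)
  if (any(nodes$start[has_iv] < 0 | nodes$start[has_iv] >= nodes$end[has_iv])) {
    abort("intervals must satisfy 0 <= start < end (0-based half-open)",
          class = "osteoatlas_value_error")
  }

  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

infer_node_table <- function(edges) {
  src_kind <- ifelse(edges$layer == "region-gene", "region", "TF")
  tgt_kind <- ifelse(edges$layer == "tf-region", "region", "gene")
  kinds <- tibble::tibble(
    id = c(edges$source, edges$target),
    kind = c(src_kind, tgt_kind)
  ) |>
    dplyr::distinct() |>
    # a node can look like both a TF (source of tf-*) and a gene (target of
    # *-gene), e.g. a TF regulated by another TF: resolve TF > region > gene
    dplyr::mutate(rank = match(.data$kind, c("TF", "region", "gene"))) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("id", "kind")
  tibble::tibble(
    id = kinds$id, kind = kinds$kind,
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_
  )
}

parse_region_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  ok <- lengths(m) == 4
  if (!all(ok)) {
    abort(sprintf(
      "region id(s) not in 'chrom:start-end' form and no interval given: %s",
      paste(head(ids[!ok], 5), collapse = ", ")),
      class = "osteoatlas_value_error")
  }
  tibble::tibble(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4))
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf(
    "<regulatory_network> %d nodes (%s), %d edges\n",
    nrow(x$nodes),
    paste(sprintf("%s: %d", names(kinds), as.integer(kinds)), collapse = ", "),
    nrow(x$edges)))
  invisible(x)
}

#' Read a regulatory network from edge-list (and optional node) TSV files
#'
#' @param path Tab-delimited edge list with header columns `source`,
#'   `target`, `importance`, `layer`.
#' @param node_path Optional tab-delimited node table with columns `id`,
#'   `kind` and optionally `chrom`, `start`, `end`, `strand`.
#' @return A [regulatory_network()].
#' @export
read_network <- function(path, node_path = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nodes <- NULL
  if (!is.null(node_path)) {
    nodes <- readr::read_tsv(node_path, show_col_types = FALSE, progress = FALSE)
  }
  regulatory_network(edges, nodes)
}

#' Write a (sub)network with node scores to TSV and JSON
#'
#' Emits `<prefix>_nodes.tsv` (id, kind, interval columns, score),
#' `<prefix>_edges.tsv` and a single JSON document `<prefix>.json`. Nodes
#' without a score get an empty score field (not 0). The TSV pair
#' round-trips through [read_network()] losslessly for nodes and edges.
#'
#' @param net A [regulatory_network()].
#' @param scores Optional data frame `(node, score)`; `node` must be a
#'   subset of the network's node ids.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_subnetwork <- function(net, scores = NULL, prefix) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes <- net$nodes
  if (!is.null(scores)) {
    scores <- tibble::as_tibble(scores)
    unknown <- setdiff(scores$node, nodes$id)
    if (length(unknown) > 0) {
      abort(sprintf("score for unknown node(s): %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "osteoatlas_integrity_error")
    }
    nodes <- dplyr::left_join(nodes, scores, by = c(id = "node"))
  } else {
    nodes$score <- NA_real_
  }
  paths <- c(
    nodes = paste0(prefix, "_nodes.tsv"),
    edges = paste0(prefix, "_edges.tsv"),
    json = paste0(prefix, ".json")
  )
  readr::write_tsv(nodes, paths[["nodes"]], na = "", progress = FALSE)
  readr::write_tsv(net$edges, paths[["edges"]], na = "", progress = FALSE)
  doc <- list(
    nodes = purrr::pmap(
      list(nodes$id, nodes$kind, nodes$score),
      function(id, kind, score) {
        out <- list(id = id, kind = kind)
        if (!is.na(score)) out$score <- score
        out
      }),
    edges = purrr::pmap(
      list(net$edges$source, net$edges$target, net$edges$importance,
           net$edges$layer),
      function(s, t, w, l) list(source = s, target = t, importance = w, layer = l))
  )
  jsonlite::write_json(doc, paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Connected components of a node subset
#'
#' Treats edges as undirected, induces the subgraph on `node_subset` and
#' returns its connected components, sorted by decreasing size with ties
#' broken by the lexicographically smallest member.
#'
#' @param net A [regulatory_network()].
#' @param node_subset Character vector of node ids (subset of the network).
#' @return List of character vectors (each sorted), one per component.
#' @export
network_components <- function(net, node_subset) {
  stopifnot(inherits(net, "regulatory_network"))
  unknown <- setdiff(node_subset, net$nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf("node subset contains unknown id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "osteoatlas_integrity_error")
  }
  node_subset <- unique(node_subset)
  if (length(node_subset) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = FALSE,
    vertices = net$nodes$id)
  sub <- igraph::induced_subgraph(g, node_subset)
  comp <- igraph::components(sub)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(unname(parts), sort)
  ord <- order(-lengths(parts), vapply(parts, `[`, "", 1))
  parts[ord]
}

#' Read genomic intervals from a BED3+ file
#'
#' @param path BED file (tab-delimited, no header): chrom, start, end and an
#'   optional name column. Coordinates are 0-based half-open.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`; missing
#'   names default to `"chrom:start-end"`.
#' @export
read_bed <- function(path) {
  # base read.table: BED3 and BED4 rows may be mixed in one file
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           comment.char = "#", quote = "",
                           colClasses = "character")
  if (ncol(raw) < 3) {
    abort("BED file needs at least 3 columns (chrom, start, end)",
          class = "osteoatlas_format_error")
  }
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]])),
    name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_
  )
  if (any(!is.finite(out$start) | !is.finite(out$end))) {
    abort(sprintf("non-numeric coordinates at line %d of %s",
                  which(!is.finite(out$start) | !is.finite(out$end))[1], path),
          class = "osteoatlas_format_error")
  }
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 out$start < 0 | out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid interval (need 0 <= start < end) at line %d of %s",
                  bad[1], path),
          class = "osteoatlas_value_error")
  }
  out$name <- ifelse(
    is.na(out$name) | out$name == "",
    sprintf("%s:%d-%d", out$chrom, out$start, out$end), out$name)
  out
}

#' Read a gene annotation table
#'
#' Accepts either a BED4 file (name column = gene id) or a TSV with header
#' columns `gene`, `chrom`, `start`, `end` and optionally `strand`.
#' Coordinates are 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @return Tibble `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene", strsplit(first, "\t")[[1]][1], fixed = TRUE)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing_col <- setdiff(c("gene", "chrom", "start", "end"), names(tab))
    if (length(missing_col) > 0) {
      abort(sprintf("gene table is missing column(s): %s",
                    paste(missing_col, collapse = ", ")),
            class = "osteoatlas_format_error")
    }
    if (!"strand" %in% names(tab)) tab$strand <- NA_character_
    tab <- tab[, c("gene", "chrom", "start", "end", "strand")]
  } else {
    bed <- read_bed(path)
    tab <- tibble::tibble(gene = bed$name, chrom = bed$chrom,
                          start = bed$start, end = bed$end,
                          strand = NA_character_)
  }
  if (anyDuplicated(tab$gene)) {
    abort("gene ids must be unique in the annotation",
          class = "osteoatlas_integrity_error")
  }
  if (any(tab$start >= tab$end)) {
    abort("gene intervals must satisfy start < end",
          class = "osteoatlas_value_error")
  }
  tab
}
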