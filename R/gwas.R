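#' Read GWAS summary statistics
#'
#' Reads delimited summary statistics into a validated table. Rows with a
#' p-value outside (0, 1] or unparsable are dropped with a message giving
#' the count. Duplicate variant ids keep the record with the smallest p
#' (with a warning).
#'
#' @param path Delimited text file with a header.
#' @param column_map Named character vector mapping the roles `variant`,
#'   `chrom`, `pos`, `p` to column names in the file.
#' @param delim Field delimiter (default tab).
#' @return Tibble `variant`, `chrom`, `pos` (1-based), `p`.
#' @export
read_gwas <- function(path,
                      column_map = c(variant = "variant", chrom = "chrom",
                                     pos = "pos", p = "p"),
                      delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_col <- setdiff(unname(column_map[c("variant", "chrom", "pos", "p")]),
                         names(raw))
  if (length(missing_col) > 0) {
    abort(sprintf("GWAS file is missing mapped column(s): %s",
                  paste(missing_col, collapse = ", ")),
          class = "osteoatlas_format_error")
  }
  g <- tibble::tibble(
    variant = as.character(raw[[column_map[["variant"]]]]),
    chrom = as.character(raw[[column_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    p = suppressWarnings(as.numeric(raw[[column_map[["p"]]]]))
  )
  bad <- !is.finite(g$p) | g$p <= 0 | g$p > 1 | !is.finite(g$pos) | g$pos < 1
  if (any(bad)) {
    inform(sprintf("dropped %d row(s) with invalid p-value or position",
                   sum(bad)))
    g <- g[!bad, ]
  }
  if (anyDuplicated(g$variant)) {
    warn("duplicate variant ids: keeping the smallest p per variant")
    g <- g |>
      dplyr::group_by(.data$variant) |>
      dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  g
}

#' Score SNPs from p-values
#'
#' The raw per-SNP score is \eqn{s = -\log_{10}(p)}; the LD-weighted score
#' starts equal to it and is updated by [apply_ld_weighting()].
#'
#' @param gwas Tibble as returned by [read_gwas()].
#' @return Tibble `variant`, `score`, `score_ld`.
#' @export
score_snps <- function(gwas) {
  stopifnot(all(c("variant", "p") %in% names(gwas)))
  s <- -log10(gwas$p)
  tibble::tibble(variant = gwas$variant, score = s, score_ld = s)
}

#' Construct an LD block
#'
#' @param variants Character vector of variant ids.
#' @param r2 Square matrix of pairwise r-squared values for those variants:
#'   symmetric, unit diagonal, entries in \[0, 1\].
#' @return An `ld_block` object.
#' @export
ld_block <- function(variants, r2) {
  r2 <- as.matrix(r2)
  n <- length(variants)
  if (!all(dim(r2) == c(n, n))) {
    abort("r2 must be a square matrix matching the variant list",
          class = "osteoatlas_value_error")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort("r2 entries must be finite and in [0, 1]",
          class = "osteoatlas_value_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    abort("r2 matrix must be symmetric", class = "osteoatlas_value_error")
  }
  if (max(abs(diag(r2) - 1)) > 1e-8) {
    abort("r2 diagonal must be exactly 1", class = "osteoatlas_value_error")
  }
  dimnames(r2) <- list(variants, variants)
  structure(list(variants = variants, r2 = r2), class = "ld_block")
}

#' Read LD blocks from a concatenated text file
#'
#' Format, repeated per block: a header line `block_id<TAB>n`, then `n`
#' lines `variant_id<TAB>r2_1<TAB>...<TAB>r2_n` giving that variant's row of
#' the within-block r-squared matrix.
#'
#' @param path Path to the LD block file.
#' @return List of [ld_block()] objects, named by block id.
#' @export
read_ld_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\t")[[1]]
    if (length(hdr) != 2) {
      abort(sprintf("malformed LD block header at line %d", i),
            class = "osteoatlas_format_error")
    }
    n <- as.integer(hdr[2])
    body <- lines[(i + 1):(i + n)]
    parts <- strsplit(body, "\t")
    variants <- vapply(parts, `[`, "", 1)
    r2 <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    blocks[[hdr[1]]] <- ld_block(variants, r2)
    i <- i + n + 1
  }
  seen <- unlist(lapply(blocks, `[[`, "variants"))
  if (anyDuplicated(seen)) {
    abort("a variant appears in more than one LD block",
          class = "osteoatlas_integrity_error")
  }
  blocks
}

#' Write LD blocks in the concatenated text format of [read_ld_blocks()]
#'
#' @param blocks Named list of [ld_block()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(blocks)) {
    b <- blocks[[id]]
    writeLines(sprintf("%s\t%d", id, length(b$variants)), con)
    rows <- vapply(seq_along(b$variants), function(i) {
      paste(c(b$variants[i], format(b$r2[i, ], digits = 15)), collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Smooth SNP scores across linkage-disequilibrium blocks
#'
#' Within each block the LD-weighted score is the r-squared-normalized
#' weighted mean of the block members' raw scores:
#' \eqn{s'_i = \sum_j r^2_{ij} s_j / \sum_j r^2_{ij}} (the sum includes
#' \eqn{i} itself since \eqn{r^2_{ii} = 1}). Variants in no block keep
#' their raw score. The result is a convex combination, so every weighted
#' score lies within the block's raw score range.
#'
#' @param scores Tibble from [score_snps()].
#' @param blocks List of [ld_block()] objects. Block variants missing from
#'   `scores` are ignored with a warning.
#' @return `scores` with `score_ld` updated.
#' @export
apply_ld_weighting <- function(scores, blocks) {
  s <- setNames(scores$score, scores$variant)
  out <- setNames(scores$score, scores$variant)
  for (b in blocks) {
    present <- b$variants[b$variants %in% names(s)]
    if (length(present) < length(b$variants)) {
      warn(sprintf("%d LD block variant(s) absent from scores; ignored",
                   length(b$variants) - length(present)))
    }
    if (length(present) == 0) next
    r2 <- b$r2[present, present, drop = FALSE]
    sv <- s[present]
    out[present] <- as.numeric(r2 %*% sv) / rowSums(r2)
  }
  scores$score_ld <- unname(out[scores$variant])
  scores
}

#' Map LD-weighted SNP scores onto network nodes
#'
#' A SNP at 1-based position `pos` overlaps a 0-based half-open interval
#' `[start, end)` iff `start <= pos - 1 < end`. Gene (and TF) nodes collect
#' SNPs overlapping their annotation extended by `window_bp` on both sides;
#' region nodes collect SNPs overlapping their own interval. The node seed
#' is the aggregate (default maximum) of the collected LD-weighted scores;
#' nodes collecting no SNP are absent from the result.
#'
#' @param scores Tibble from [score_snps()] / [apply_ld_weighting()].
#' @param gwas Tibble from [read_gwas()] (provides chrom/pos per variant).
#' @param net A [regulatory_network()].
#' @param genes Gene annotation tibble (`gene`, `chrom`, `start`, `end`);
#'   matched to gene/TF node ids. Unmatched network genes receive no seed.
#' @param window_bp Symmetric pad around gene bodies, in bp (default 10000).
#' @param aggregate One of `"max"` (default), `"sum"`, `"mean"`.
#' @param context Context label stored on the seed (e.g. the trait name).
#' @return Node seed: tibble `node`, `score` with attribute `context`.
#' @export
map_scores_to_nodes <- function(scores, gwas, net, genes, window_bp = 10000,
                                aggregate = c("max", "sum", "mean"),
                                context = "trait") {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(net, "regulatory_network"), window_bp >= 0)
  snp <- dplyr::inner_join(
    scores[, c("variant", "score_ld")],
    gwas[, c("variant", "chrom", "pos")], by = "variant")
  snp$pos0 <- snp$pos - 1L  # 0-based index of the variant base

  # target intervals: gene/TF nodes via the annotation (padded), region
  # nodes via their own interval
  gene_nodes <- net$nodes$id[net$nodes$kind %in% c("gene", "TF")]
  gtab <- genes[genes$gene %in% gene_nodes, , drop = FALSE]
  targets <- dplyr::bind_rows(
    tibble::tibble(node = gtab$gene, chrom = gtab$chrom,
                   start = pmax(0L, gtab$start - as.integer(window_bp)),
                   end = gtab$end + as.integer(window_bp)),
    with(net$nodes[net$nodes$kind == "region", ],
         tibble::tibble(node = id, chrom = chrom, start = start, end = end))
  )
  if (nrow(targets) == 0 || nrow(snp) == 0) {
    return(new_node_seed(tibble::tibble(node = character(), score = numeric()),
                         context))
  }
  hits <- dplyr::inner_join(snp, targets, by = "chrom",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$pos0, .data$pos0 < .data$end)
  agg_fun <- switch(aggregate, max = max, sum = sum, mean = mean)
  seed <- hits |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(score = agg_fun(.data$score_ld), .groups = "drop") |>
    dplyr::arrange(.data$node)
  new_node_seed(seed, context)
}

new_node_seed <- function(tbl, context) {
  stopifnot(all(c("node", "score") %in% names(tbl)))
  if (any(!is.finite(tbl$score)) || any(tbl$score < 0)) {
    abort("seed scores must be finite and >= 0",
          class = "osteoatlas_value_error")
  }
  attr(tbl, "context") <- context
  tbl
}
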