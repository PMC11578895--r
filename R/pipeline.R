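# file-to-file pipeline runners behind the command-line interface;
# each reads the documented on-disk formats, runs the engines, and writes
# outputs atomically (temp file in the target directory, then rename)

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read GWAS summary statistics TSV
#' @param gwas Tibble `variant`, `chrom`, `pos`, `p`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas_tsv <- function(gwas, path) {
  write_atomic(path, function(p) readr::write_tsv(gwas, p, progress = FALSE))
}

#' Write a cell-by-gene count matrix as dense CSV (cells in rows)
#' @param m A [cell_matrix()] or plain matrix with dimnames.
#' @param path Output path; a `cell` id column is prepended.
#' @return Invisibly, `path`.
#' @export
write_counts_csv <- function(m, path) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else as.matrix(m)
  tab <- dplyr::bind_cols(tibble::tibble(cell = rownames(counts)),
                          tibble::as_tibble(counts))
  write_atomic(path, function(p) readr::write_csv(tab, p, progress = FALSE))
}

#' Read a dense CSV count matrix written by [write_counts_csv()]
#' @param path Counts CSV (first column `cell`).
#' @param labels_path Optional TSV `cell`, `label`.
#' @param modality `"reference"` or `"iss"`.
#' @return A [cell_matrix()].
#' @export
read_counts_csv <- function(path, labels_path = NULL,
                            modality = c("reference", "iss")) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(tab[, -1])
  rownames(counts) <- tab[[1]]
  labels <- NULL
  if (!is.null(labels_path)) {
    lt <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
    labels <- setNames(as.character(lt$label), lt$cell)
  }
  cell_matrix(counts, labels = labels, modality = match.arg(modality))
}

run_log <- function(out_dir, params) {
  log <- c(list(package = "osteoatlas",
                version = as.character(utils::packageVersion("osteoatlas")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           params)
  write_atomic(file.path(out_dir, "run_log.json"), function(p)
    jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA))
}

#' Generate the full synthetic fixture set on disk
#'
#' Writes every input the other pipelines read: network edge list, gene
#' BED, GWAS TSV, LD block file, reference/ISS counts and labels, the
#' annotated label image with its JSON legend, Visium-style spot
#' coordinates, and the planted-module ground truth.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param spec Optional [synthetic_spec()] (overrides `seed`).
#' @return Invisibly, a named vector of the file paths written.
#' @export
run_simulate <- function(out_dir, seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- synthetic_spec(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grn <- simulate_grn(spec)
  gw <- simulate_gwas(spec, grn$network, grn$planted)
  # expression covers the network's gene ids (plus extra transcriptome-only
  # genes) so marker seeds land on nodes; the planted genes lead cluster
  # C1's program, coupling the trait and cluster arms of the synthesis
  net_genes <- grn$network$nodes$id[grn$network$nodes$kind == "gene"]
  extra <- if (spec$n_expr_genes > length(net_genes)) {
    sprintf("x%d", seq_len(spec$n_expr_genes - length(net_genes)))
  } else character()
  planted_genes <- intersect(grn$planted, net_genes)
  gene_ids <- c(net_genes, extra)
  quota <- ceiling(length(gene_ids) / spec$n_clusters)
  other_net <- setdiff(net_genes, planted_genes)
  pool <- setdiff(extra, character())
  programs <- vector("list", spec$n_clusters)
  names(programs) <- sprintf("C%d", seq_len(spec$n_clusters))
  # C1 owns the planted genes; the remaining network genes are spread over
  # the other clusters; transcriptome-only genes fill every program
  programs[[1]] <- planted_genes
  spread <- split(other_net, rep_len(seq_len(spec$n_clusters - 1),
                                     length(other_net)))
  for (i in seq_len(spec$n_clusters - 1)) programs[[i + 1]] <- spread[[i]]
  for (i in seq_len(spec$n_clusters)) {
    need <- max(0, quota - length(programs[[i]]))
    take <- head(pool, need)
    pool <- setdiff(pool, take)
    programs[[i]] <- c(programs[[i]], take)
  }
  if (length(pool) > 0) programs[[spec$n_clusters]] <-
    c(programs[[spec$n_clusters]], pool)
  expr <- simulate_expression(spec, gene_ids = gene_ids, programs = programs)
  img <- simulate_label_image(spec)

  paths <- c(
    network = file.path(out_dir, "network_edges.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    gwas = file.path(out_dir, "gwas.tsv"),
    ld = file.path(out_dir, "ld_blocks.txt"),
    ref_counts = file.path(out_dir, "ref_counts.csv"),
    ref_labels = file.path(out_dir, "ref_labels.tsv"),
    iss_counts = file.path(out_dir, "iss_counts.csv"),
    image = file.path(out_dir, "image.png"),
    legend = file.path(out_dir, "legend.json"),
    visium = file.path(out_dir, "visium_spots.csv"),
    planted = file.path(out_dir, "planted_nodes.txt"))

  write_atomic(paths[["network"]], function(p)
    readr::write_tsv(grn$network$edges, p, progress = FALSE))
  write_atomic(paths[["genes"]], function(p)
    readr::write_tsv(with(gw$genes, tibble::tibble(chrom, start, end, gene)),
                     p, col_names = FALSE, progress = FALSE))
  write_gwas_tsv(gw$gwas, paths[["gwas"]])
  write_atomic(paths[["ld"]], function(p) write_ld_blocks(gw$ld_blocks, p))
  write_counts_csv(expr$ref, paths[["ref_counts"]])
  write_atomic(paths[["ref_labels"]], function(p)
    readr::write_tsv(tibble::tibble(cell = names(expr$ref$labels),
                                    label = unname(expr$ref$labels)),
                     p, progress = FALSE))
  write_counts_csv(expr$iss, paths[["iss_counts"]])
  write_label_image(img, paths[["image"]], paths[["legend"]])
  vis <- withr::with_seed(child_seed(spec$seed, 4), {
    ext_x <- ncol(img$pixels) * img$pixel_size
    ext_y <- nrow(img$pixels) * img$pixel_size
    n_vis <- 50
    tibble::tibble(barcode = sprintf("BC%03d", seq_len(n_vis)),
                   x = runif(n_vis, 0, ext_x), y = runif(n_vis, 0, ext_y))
  })
  write_atomic(paths[["visium"]], function(p)
    readr::write_csv(vis, p, progress = FALSE))
  write_atomic(paths[["planted"]], function(p) writeLines(grn$planted, p))
  run_log(out_dir, list(command = "simulate", seed = spec$seed,
                        spec = unclass(spec)[setdiff(names(spec), "")]))
  invisible(paths)
}

#' Run the GWAS-to-cell-cluster propagation pipeline file-to-file
#'
#' Reads a network edge list, GWAS summary statistics, LD blocks, gene
#' annotations and a labelled count matrix; scores and LD-weights SNPs,
#' maps them onto network nodes, propagates trait and per-cluster marker
#' seeds with permutation z-scores, combines them by per-node minimum and
#' extracts enriched subnetworks.
#'
#' @param network_file,gwas_file,ld_file,genes_file Input paths (see the
#'   respective readers).
#' @param counts_file,labels_file Reference expression (dense CSV) and
#'   cluster labels TSV used for marker scores; both `NULL` skips the
#'   cluster arm and reports trait propagation only.
#' @param out_dir Output directory.
#' @param config A [propagation_config()].
#' @param window_bp Gene window for SNP-to-node mapping.
#' @param context Trait label used in output names.
#' @return Invisibly, a list with the trait result, per-cluster combined
#'   scores and subnetworks.
#' @export
run_snp2cell <- function(network_file, gwas_file, ld_file, genes_file,
                         counts_file = NULL, labels_file = NULL,
                         out_dir, config = propagation_config(),
                         window_bp = 10000, context = "trait") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- read_network(network_file)
  gwas <- read_gwas(gwas_file)
  blocks <- read_ld_blocks(ld_file)
  genes <- read_gene_annotation(genes_file)

  scores <- apply_ld_weighting(score_snps(gwas), blocks)
  seed <- map_scores_to_nodes(scores, gwas, net, genes, window_bp = window_bp,
                              context = context)
  tm <- build_transition(net)
  trait_res <- permutation_zscores(tm, seed, config, context = context)
  write_atomic(file.path(out_dir, sprintf("scores_%s.tsv", context)),
               function(p) readr::write_tsv(trait_res, p, progress = FALSE))

  combined_all <- list(); subnets <- list()
  if (!is.null(counts_file)) {
    ref <- read_counts_csv(counts_file, labels_file, modality = "reference")
    marker_seeds <- compute_marker_scores(ref$counts, ref$labels,
                                          gene_universe = net$nodes$id)
    for (cl in names(marker_seeds)) {
      if (nrow(marker_seeds[[cl]]) == 0 || sum(marker_seeds[[cl]]$score) <= 0) {
        warn(sprintf("cluster %s has no positive marker seed on the network; skipped", cl))
        next
      }
      cl_res <- permutation_zscores(tm, marker_seeds[[cl]], config,
                                    context = cl)
      write_atomic(file.path(out_dir, sprintf("scores_%s.tsv", cl)),
                   function(p) readr::write_tsv(cl_res, p, progress = FALSE))
      combined <- combine_min(trait_res, cl_res)
      combined_all[[cl]] <- combined
      write_atomic(file.path(out_dir, sprintf("combined_%s_%s.tsv", context, cl)),
                   function(p) readr::write_tsv(combined, p, progress = FALSE))
      sn <- extract_subnetworks(net, combined, z_thresh = config$z_thresh)
      subnets[[cl]] <- sn
      write_atomic(file.path(out_dir, sprintf("subnetworks_%s_%s.tsv", context, cl)),
                   function(p) readr::write_tsv(sn, p, progress = FALSE))
      if (nrow(sn) > 0) {
        write_subnetwork(
          subset_network(net, sn$node),
          tibble::tibble(node = sn$node, score = sn$score),
          file.path(out_dir, sprintf("subnetwork_%s_%s", context, cl)))
      }
    }
  }
  run_log(out_dir, list(command = "snp2cell", context = context,
                        window_bp = window_bp, config = unclass(config)))
  invisible(list(trait = trait_res, combined = combined_all,
                 subnetworks = subnets))
}

#' Restrict a network to a node subset (keeping internal edges)
#' @param net A [regulatory_network()].
#' @param node_ids Nodes to keep.
#' @return A [regulatory_network()] on the subset.
#' @export
subset_network <- function(net, node_ids) {
  nodes <- net$nodes[net$nodes$id %in% node_ids, , drop = FALSE]
  edges <- net$edges[net$edges$source %in% node_ids &
                       net$edges$target %in% node_ids, , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' Run reference-to-ISS imputation and label transfer file-to-file
#'
#' @param ref_counts_file,ref_labels_file Reference counts CSV and labels
#'   TSV.
#' @param iss_counts_file ISS panel counts CSV.
#' @param out_dir Output directory.
#' @param k Number of nearest neighbours (default 15).
#' @return Invisibly, a list with the neighbour map, transferred labels
#'   and imputed counts.
#' @export
run_isspatch <- function(ref_counts_file, ref_labels_file, iss_counts_file,
                         out_dir, k = 15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- read_counts_csv(ref_counts_file, ref_labels_file, "reference")
  iss <- read_counts_csv(iss_counts_file, modality = "iss")
  panel <- shared_panel(ref, iss)
  nmap <- knn_match(normalize_panel(iss, panel), normalize_panel(ref, panel),
                    k = k)
  labels <- transfer_labels(nmap, ref$labels)
  missing_genes <- setdiff(colnames(ref$counts), panel)
  imputed <- if (length(missing_genes) > 0) {
    impute_counts(nmap, ref, missing_genes)
  } else NULL

  write_atomic(file.path(out_dir, "neighbor_map.tsv"), function(p)
    readr::write_tsv(nmap, p, progress = FALSE))
  write_atomic(file.path(out_dir, "labels.tsv"), function(p)
    readr::write_tsv(labels, p, progress = FALSE))
  if (!is.null(imputed)) write_counts_csv(imputed,
                                          file.path(out_dir, "imputed_counts.csv"))
  run_log(out_dir, list(command = "isspatch", k = k,
                        n_panel = length(panel),
                        n_imputed_genes = length(missing_genes)))
  invisible(list(neighbors = nmap, labels = labels, imputed = imputed))
}

#' Run the tissue-axis annotation pipeline file-to-file
#'
#' Builds the 15-um hexagonal grid over the image extent, migrates the
#' raster annotations, computes per-structure distance features, the
#' origin-target axis, and maps everything onto the Visium spots.
#'
#' @param image_file,legend_file Label image PNG and JSON legend.
#' @param visium_file CSV `barcode`, `x`, `y` (micrometres).
#' @param out_dir Output directory.
#' @param axis Optional `c(origin, target)` structure names.
#' @param diameter,spacing Grid geometry in micrometres.
#' @param max_dist Visium matching cut-off in micrometres.
#' @return Invisibly, a list with the grid annotation and the Visium
#'   annotation tibbles.
#' @export
run_organaxis <- function(image_file, legend_file, visium_file, out_dir,
                          axis = NULL, diameter = 15, spacing = 15,
                          max_dist = 15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img <- read_label_image(image_file, legend_file)
  ext <- c(0, ncol(img$pixels) * img$pixel_size,
           0, nrow(img$pixels) * img$pixel_size)
  grid <- build_hex_grid(ext, diameter = diameter, spacing = spacing)
  ann <- migrate_labels(img, grid)
  for (lev in sort(unique(img$legend$level))) {
    dd <- structure_distances(grid, img, level = lev)
    ann <- dplyr::left_join(ann, dd[, setdiff(names(dd), c("x", "y"))],
                            by = "spot")
  }
  if (!is.null(axis)) ann <- compute_axis(ann, axis[1], axis[2])
  vis <- readr::read_csv(visium_file, show_col_types = FALSE, progress = FALSE)
  vis_ann <- map_to_visium(ann, vis, max_dist = max_dist)

  write_atomic(file.path(out_dir, "grid_annotation.csv"), function(p)
    readr::write_csv(ann, p, progress = FALSE))
  write_atomic(file.path(out_dir, "visium_annotation.csv"), function(p)
    readr::write_csv(vis_ann, p, progress = FALSE))
  run_log(out_dir, list(command = "organaxis", diameter = diameter,
                        spacing = spacing, max_dist = max_dist,
                        axis = if (is.null(axis)) NULL else
                          paste(axis, collapse = ":")))
  invisible(list(grid_annotation = ann, visium_annotation = vis_ann))
}
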