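#' Specification for the synthetic fixture generators
#'
#' One object holds every knob of the synthetic data: a tripartite
#' TF-region-gene network with a planted disease module, LD-blocked GWAS
#' summary statistics whose signal SNPs hit the planted nodes, clustered
#' negative-binomial expression with a targeted ISS panel, and a toy
#' annotated label image. Identical spec + seed gives bitwise-identical
#' output.
#'
#' @param seed Integer RNG seed fanned out to each generator.
#' @param n_tf,n_region,n_gene Node counts of the regulatory network.
#' @param mean_degree Average extra edges per node beyond the spanning
#'   TF-region-gene attachment.
#' @param module_size Number of nodes in the planted (connected) module.
#' @param n_background_snps Background SNPs with uniform p-values.
#' @param signal_snps_per_node Signal SNPs placed in each planted node's
#'   interval.
#' @param signal_shape Beta(shape, 1) shape for signal p-values; smaller
#'   means stronger signal.
#' @param block_size,block_r2 LD block size and constant within-block
#'   r-squared.
#' @param n_clusters,cells_per_cluster Expression design.
#' @param markers_per_cluster Marker genes upregulated per cluster.
#' @param nb_mu,nb_dispersion Negative-binomial baseline mean and size.
#' @param fold_change Marker up-regulation fold change.
#' @param n_expr_genes Genes in the droplet reference.
#' @param panel_size Genes on the targeted ISS panel (default 155).
#' @param image_size Label image canvas in pixels `c(rows, cols)`.
#' @param image_pixel_size Micrometres per pixel.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_tf = 8, n_region = 40, n_gene = 80,
                           mean_degree = 2.5,
                           module_size = 20,
                           n_background_snps = 300,
                           signal_snps_per_node = 3,
                           signal_shape = 0.05,
                           block_size = 5, block_r2 = 0.6,
                           n_clusters = 5, cells_per_cluster = 50,
                           markers_per_cluster = 10,
                           nb_mu = 5, nb_dispersion = 20,
                           fold_change = 4,
                           n_expr_genes = 400, panel_size = 155,
                           image_size = c(100, 100),
                           image_pixel_size = 1) {
  stopifnot(n_tf >= 1, n_region >= 1, n_gene >= 1, module_size >= 1,
            module_size <= n_tf + n_region + n_gene,
            block_size >= 1, block_r2 >= 0, block_r2 <= 1,
            n_clusters >= 2, cells_per_cluster >= 3,
            markers_per_cluster >= 1, fold_change > 0,
            panel_size <= n_expr_genes, image_pixel_size > 0)
  spec <- as.list(environment())
  structure(spec, class = "synthetic_spec")
}

# deterministic child seeds, kept within 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# genomic layout shared by the GRN and GWAS generators: every node gets a
# 1 kb slot on chr1, slots 25 kb apart so 10 kb gene windows never overlap
node_slot <- function(i) {
  start <- 10000L + (i - 1L) * 25000L
  c(start = start, end = start + 1000L)
}

#' Generate a tripartite regulatory network with a planted module
#'
#' Regions attach to TFs and genes to regions by preferential attachment
#' (plus a few direct TF-gene links); extra edges are added up to the
#' requested mean degree and the graph is made connected. A connected
#' planted module of `module_size` nodes is chosen by breadth-first
#' growth and recorded. Region node ids carry their genomic interval in
#' canonical `chrom:start-end` form.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `network` (a [regulatory_network()]) and `planted`
#'   (character vector of node ids).
#' @export
simulate_grn <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(child_seed(spec$seed, 1), {
    tf_ids <- sprintf("TF%d", seq_len(spec$n_tf))
    slot_i <- spec$n_tf + spec$n_gene + seq_len(spec$n_region)
    region_ids <- vapply(slot_i, function(i) {
      s <- node_slot(i)
      sprintf("chr1:%d-%d", s[["start"]], s[["end"]])
    }, "")
    gene_ids <- sprintf("g%d", seq_len(spec$n_gene))

    # spanning attachment: each region picks a TF, each gene a region,
    # preferentially towards already-busy parents
    pick_pref <- function(deg) sample.int(length(deg), 1, prob = deg + 1)
    tf_deg <- numeric(spec$n_tf)
    reg_parent <- integer(spec$n_region)
    for (i in seq_len(spec$n_region)) {
      reg_parent[i] <- pick_pref(tf_deg)
      tf_deg[reg_parent[i]] <- tf_deg[reg_parent[i]] + 1
    }
    reg_deg <- numeric(spec$n_region)
    gene_parent <- integer(spec$n_gene)
    for (i in seq_len(spec$n_gene)) {
      gene_parent[i] <- pick_pref(reg_deg)
      reg_deg[gene_parent[i]] <- reg_deg[gene_parent[i]] + 1
    }
    edges <- dplyr::bind_rows(
      tibble::tibble(source = tf_ids[reg_parent], target = region_ids,
                     layer = "tf-region"),
      tibble::tibble(source = region_ids[gene_parent], target = gene_ids,
                     layer = "region-gene"))

    # extra edges up to the requested mean degree, plus direct TF-gene links
    n_nodes <- spec$n_tf + spec$n_region + spec$n_gene
    n_extra <- max(0, round(spec$mean_degree * n_nodes / 2) - nrow(edges))
    if (n_extra > 0) {
      extra <- lapply(seq_len(n_extra), function(i) {
        kind <- sample(c("tf-region", "region-gene", "tf-gene"), 1,
                       prob = c(0.4, 0.4, 0.2))
        switch(kind,
          "tf-region" = c(sample(tf_ids, 1), sample(region_ids, 1), kind),
          "region-gene" = c(sample(region_ids, 1), sample(gene_ids, 1), kind),
          "tf-gene" = c(sample(tf_ids, 1), sample(gene_ids, 1), kind))
      })
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(source = vapply(extra, `[`, "", 1),
                       target = vapply(extra, `[`, "", 2),
                       layer = vapply(extra, `[`, "", 3)))
      edges <- dplyr::distinct(edges, .data$source, .data$target, .data$layer)
    }
    edges$importance <- runif(nrow(edges), min = 0.05, max = 1)

    # connect any stray components through tf-region bridges
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       directed = FALSE,
                                       vertices = c(tf_ids, region_ids, gene_ids))
    comp <- igraph::components(g)
    while (comp$no > 1) {
      main <- which.max(comp$csize)
      other <- which(comp$membership != main)[1]
      tf_main <- intersect(names(comp$membership)[comp$membership == main], tf_ids)[1]
      node_other <- names(comp$membership)[other]
      bridge_region <- if (node_other %in% region_ids) node_other else
        intersect(names(comp$membership)[comp$membership == comp$membership[other]],
                  region_ids)[1]
      if (is.na(bridge_region)) {
        # the stray component has no region: bridge via a main-component region
        bridge <- tibble::tibble(
          source = intersect(names(comp$membership)[comp$membership == main],
                             region_ids)[1],
          target = node_other, layer = "region-gene",
          importance = runif(1, 0.05, 1))
        if (node_other %in% tf_ids) {
          bridge <- tibble::tibble(source = node_other, target = bridge$source,
                                   layer = "tf-region",
                                   importance = bridge$importance)
        }
      } else {
        bridge <- tibble::tibble(source = tf_main, target = bridge_region,
                                 layer = "tf-region",
                                 importance = runif(1, 0.05, 1))
      }
      edges <- dplyr::bind_rows(edges, bridge)
      g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                         directed = FALSE,
                                         vertices = c(tf_ids, region_ids, gene_ids))
      comp <- igraph::components(g)
    }

    net <- regulatory_network(edges)
    # planted module: a regulon — a TF, its regions, and each region's
    # target genes, added region-by-region so genes dominate; connected by
    # construction, growing through further TFs only if one regulon is
    # too small
    adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), names)
    names(adj) <- igraph::V(g)$name
    kinds0 <- setNames(net$nodes$kind, net$nodes$id)
    start <- sample(tf_ids, 1)
    visited <- start
    tf_queue <- start
    while (length(visited) < spec$module_size && length(tf_queue) > 0) {
      tf <- tf_queue[1]
      tf_queue <- tf_queue[-1]
      if (!tf %in% visited) visited <- c(visited, tf)
      if (length(visited) >= spec$module_size) break
      regions <- setdiff(adj[[tf]][kinds0[adj[[tf]]] == "region"], visited)
      for (r in sample(regions)) {
        if (length(visited) >= spec$module_size) break
        visited <- c(visited, r)
        tgt <- setdiff(adj[[r]][kinds0[adj[[r]]] == "gene"], visited)
        take <- head(tgt, spec$module_size - length(visited))
        visited <- c(visited, take)
        next_tfs <- setdiff(adj[[r]][kinds0[adj[[r]]] == "TF"],
                            c(visited, tf_queue))
        tf_queue <- c(tf_queue, next_tfs)
      }
    }
    planted <- head(visited, spec$module_size)
    # cohesion: a disease regulon is densely wired, so tie each module gene
    # to at least two module regions and every module region to a module TF
    kinds <- setNames(net$nodes$kind, net$nodes$id)
    p_genes <- planted[kinds[planted] == "gene"]
    p_regions <- planted[kinds[planted] == "region"]
    p_tfs <- planted[kinds[planted] == "TF"]
    add <- list()
    if (length(p_regions) >= 2) {
      for (gn in p_genes) {
        linked <- edges$source[edges$target == gn & edges$source %in% p_regions]
        need <- 2 - length(linked)
        if (need > 0) {
          cand <- setdiff(p_regions, linked)
          pick <- sample(cand, min(need, length(cand)))
          add <- c(add, lapply(pick, function(r)
            tibble::tibble(source = r, target = gn, layer = "region-gene",
                           importance = runif(1, 0.05, 1))))
        }
      }
    }
    if (length(p_tfs) >= 1) {
      for (r in p_regions) {
        linked <- edges$source[edges$target == r & edges$source %in% p_tfs]
        if (length(linked) == 0) {
          add <- c(add, list(tibble::tibble(
            source = sample(p_tfs, 1), target = r, layer = "tf-region",
            importance = runif(1, 0.05, 1))))
        }
      }
    }
    if (length(add) > 0) {
      edges <- dplyr::bind_rows(c(list(edges), add))
      net <- regulatory_network(edges)
    }
    list(network = net, planted = planted)
  })
}

#' Generate GWAS summary statistics and LD blocks for a network
#'
#' Genes and TFs are laid out on a toy genome in non-overlapping slots
#' (regions already carry intervals in their ids). Background SNPs get
#' Uniform(0, 1) p-values at random genome positions; when `effect` is on,
#' each planted node additionally receives signal SNPs inside its interval
#' with Beta(`signal_shape`, 1) p-values (concentrated near 0). SNPs are
#' partitioned by position into LD blocks with constant within-block
#' r-squared.
#'
#' @param spec A [synthetic_spec()].
#' @param net The [regulatory_network()] from [simulate_grn()].
#' @param planted Planted node ids from [simulate_grn()].
#' @param effect Place elevated signal on the planted nodes? Off gives a
#'   fully null GWAS for calibration checks.
#' @return List with `gwas` (tibble), `ld_blocks` (list of [ld_block()])
#'   and `genes` (gene annotation tibble covering gene and TF nodes).
#' @export
simulate_gwas <- function(spec, net, planted, effect = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(net, "regulatory_network"),
            all(planted %in% net$nodes$id))
  withr::with_seed(child_seed(spec$seed, 2), {
    nodes <- net$nodes
    gt <- nodes[nodes$kind %in% c("gene", "TF"), , drop = FALSE]
    slots <- t(vapply(seq_len(nrow(gt)), node_slot, c(start = 0L, end = 0L)))
    genes <- tibble::tibble(gene = gt$id, chrom = "chr1",
                            start = slots[, "start"], end = slots[, "end"],
                            strand = "+")
    genome_end <- max(c(genes$end, nodes$end), na.rm = TRUE) + 10000L

    pos_bg <- sort(sample.int(genome_end, spec$n_background_snps))
    gwas <- tibble::tibble(
      variant = sprintf("rs%d", seq_along(pos_bg)),
      chrom = "chr1", pos = pos_bg, p = runif(length(pos_bg)))

    intervals <- dplyr::bind_rows(
      genes[, c("gene", "start", "end")] |> dplyr::rename(node = "gene"),
      nodes[nodes$kind == "region", c("id", "start", "end")] |>
        dplyr::rename(node = "id"))
    hit <- intervals[intervals$node %in% planted, , drop = FALSE]
    if (nrow(hit) > 0) {
      sig <- purrr::pmap_dfr(hit, function(node, start, end) {
        pos <- start + sample.int(end - start, spec$signal_snps_per_node,
                                  replace = TRUE)
        p <- if (effect) stats::rbeta(length(pos), spec$signal_shape, 1)
             else runif(length(pos))
        tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                       p = pmax(p, 1e-300))
      })
      sig$variant <- sprintf("rs%d", nrow(gwas) + seq_len(nrow(sig)))
      gwas <- dplyr::bind_rows(gwas, sig[, names(gwas)])
    }
    gwas <- dplyr::arrange(gwas, .data$pos)

    n_snp <- nrow(gwas)
    block_of <- ceiling(seq_len(n_snp) / spec$block_size)
    blocks <- lapply(split(gwas$variant, block_of), function(v) {
      r2 <- matrix(spec$block_r2, length(v), length(v))
      diag(r2) <- 1
      ld_block(v, r2)
    })
    names(blocks) <- sprintf("block%d", seq_along(blocks))
    list(gwas = gwas, ld_blocks = blocks, genes = genes)
  })
}

#' Generate clustered negative-binomial expression with an ISS panel
#'
#' Draws a droplet-style reference (all genes, labelled clusters) and an
#' independent targeted ISS dataset restricted to the panel. Every gene
#' belongs to exactly one cluster's expression program and is
#' up-regulated by `fold_change` in that cluster, emulating the global
#' cluster structure of real transcriptomes that neighbour-based
#' imputation exploits; `markers_per_cluster` genes of each program are
#' guaranteed onto the panel. ISS cells are fresh draws from the same
#' cluster parameters (never copies of reference cells), with their true
#' labels returned separately.
#'
#' @param spec A [synthetic_spec()].
#' @param gene_ids Optional gene ids (default `g1..gN`); useful to share
#'   ids with a simulated network.
#' @param programs Optional named list partitioning `gene_ids` into one
#'   expression program per cluster; default splits the gene list into
#'   consecutive equal blocks.
#' @return List with `ref` and `iss` ([cell_matrix()] objects; ISS labels
#'   withheld), `iss_truth` (named character vector), `panel`,
#'   `marker_sets` (the per-cluster panel markers), and `iss_full` (the
#'   ISS cells' full-transcriptome counts, for held-out validation of
#'   imputation).
#' @export
simulate_expression <- function(spec, gene_ids = NULL, programs = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(child_seed(spec$seed, 3), {
    if (is.null(gene_ids)) {
      gene_ids <- sprintf("g%d", seq_len(spec$n_expr_genes))
    }
    n_gene <- length(gene_ids)
    clusters <- sprintf("C%d", seq_len(spec$n_clusters))
    if (is.null(programs)) {
      programs <- split(gene_ids,
                        sort(rep_len(seq_len(spec$n_clusters), n_gene)))
      names(programs) <- clusters
    }
    stopifnot(setequal(unlist(programs), gene_ids))
    program_of <- setNames(rep(names(programs), lengths(programs)),
                           unlist(programs))
    marker_sets <- lapply(programs, function(g)
      g[seq_len(min(spec$markers_per_cluster, length(g)))])
    base_mu <- stats::rgamma(n_gene, shape = 4, rate = 4 / spec$nb_mu)
    names(base_mu) <- gene_ids

    draw <- function(cl, n_cells, genes) {
      mu <- base_mu[genes]
      mk <- program_of[genes] == cl
      mu[mk] <- mu[mk] * spec$fold_change
      m <- matrix(rnbinom(n_cells * length(genes),
                          mu = rep(mu, each = n_cells),
                          size = spec$nb_dispersion),
                  nrow = n_cells)
      colnames(m) <- genes
      m
    }

    ref_counts <- do.call(rbind, lapply(clusters, function(cl)
      draw(cl, spec$cells_per_cluster, gene_ids)))
    rownames(ref_counts) <- sprintf("ref%d", seq_len(nrow(ref_counts)))
    ref_labels <- rep(clusters, each = spec$cells_per_cluster)
    keep <- rowSums(ref_counts) > 0
    ref <- cell_matrix(ref_counts[keep, , drop = FALSE],
                       labels = ref_labels[keep], modality = "reference")

    # panel: guaranteed markers of every program, topped up with the most
    # expressed remaining genes
    markers <- unique(unlist(marker_sets))
    filler <- setdiff(gene_ids[order(-base_mu)], markers)
    panel <- sort(c(markers, filler)[seq_len(min(spec$panel_size, n_gene))])

    iss_full <- do.call(rbind, lapply(clusters, function(cl)
      draw(cl, spec$cells_per_cluster, gene_ids)))
    rownames(iss_full) <- sprintf("iss%d", seq_len(nrow(iss_full)))
    iss_truth <- setNames(rep(clusters, each = spec$cells_per_cluster),
                          rownames(iss_full))
    iss_counts <- iss_full[, panel, drop = FALSE]
    keep <- rowSums(iss_counts) > 0
    iss <- cell_matrix(iss_counts[keep, , drop = FALSE], modality = "iss")

    list(ref = ref, iss = iss, iss_truth = iss_truth[rownames(iss$counts)],
         panel = panel, marker_sets = marker_sets,
         iss_full = iss_full[rownames(iss$counts), , drop = FALSE])
  })
}

#' Generate a toy annotated label image
#'
#' Renders named structures onto an integer raster with an unambiguous
#' legend. The default scene is the two-band axis fixture: a "suture"
#' band along the left edge and a "bone" band along the right edge (both
#' level 1), so the axis between them increases strictly with x.
#'
#' @param spec A [synthetic_spec()].
#' @param structures List of structure descriptions, each a list with
#'   `name`, `level`, `value` and either `cols = c(from, to)` /
#'   `rows = c(from, to)` (a band) or `center = c(row, col)`, `radius`
#'   (a disc), in pixels.
#' @return A [label_image()].
#' @export
simulate_label_image <- function(spec, structures = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  if (is.null(structures)) {
    band_w <- max(2, round(nc * 0.08))
    structures <- list(
      list(name = "suture", level = 1, value = 1, cols = c(1, band_w)),
      list(name = "bone", level = 1, value = 2, cols = c(nc - band_w + 1, nc)))
  }
  pixels <- matrix(0L, nr, nc)
  legend <- tibble::tibble(value = integer(), name = character(),
                           level = integer())
  for (s in structures) {
    mask <- matrix(FALSE, nr, nc)
    if (!is.null(s$cols) || !is.null(s$rows)) {
      rows <- if (is.null(s$rows)) c(1, nr) else s$rows
      cols <- if (is.null(s$cols)) c(1, nc) else s$cols
      mask[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
    } else {
      idx <- expand.grid(i = seq_len(nr), j = seq_len(nc))
      mask[cbind(idx$i, idx$j)] <-
        (idx$i - s$center[1])^2 + (idx$j - s$center[2])^2 <= s$radius^2
    }
    if (any(pixels[mask] != 0)) {
      abort(sprintf("structure '%s' overlaps an existing structure", s$name),
            class = "osteoatlas_value_error")
    }
    pixels[mask] <- as.integer(s$value)
    legend <- dplyr::bind_rows(
      legend, tibble::tibble(value = as.integer(s$value), name = s$name,
                             level = as.integer(s$level)))
  }
  label_image(pixels, spec$image_pixel_size, legend)
}
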