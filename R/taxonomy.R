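#' Sub-cluster (genus) and species assignment from nucleotide similarity
#'
#' Sub-clusters are connected components of the graph joining genome pairs
#' with similarity at or above `genus_threshold` (single linkage, the
#' behaviour of the intergenomic-similarity demarcation convention);
#' species are components at `species_threshold` within each sub-cluster,
#' so species always nest inside sub-clusters. Numbering is deterministic:
#' sub-clusters ordered by size (descending), ties by smallest member
#' genome_id.
#'
#' @param sim `phage_similarity` object or symmetric similarity matrix with
#'   diagonal 100 and genome_id dimnames.
#' @param genus_threshold Percent similarity for genus membership (default 65).
#' @param species_threshold Percent similarity for species membership
#'   (default 95).
#' @return Tibble: `genome_id`, `subcluster_id` (integer), `species_id`
#'   (character, `"<subcluster>.<n>"`).
#' @export
assign_subclusters <- function(sim, genus_threshold = 65,
                               species_threshold = 95) {
  m <- if (inherits(sim, "phage_similarity")) sim$matrix else sim
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("similarity matrix must be symmetric")
  ids <- rownames(m)
  sub_comp <- threshold_components(m, genus_threshold)
  sub_rank <- rank_partition(sub_comp, ids)
  species <- character(length(ids))
  for (sc in unique(sub_comp)) {
    sel <- sub_comp == sc
    sp_comp <- threshold_components(m[sel, sel, drop = FALSE],
                                    species_threshold)
    sp_rank <- rank_partition(sp_comp, ids[sel])
    species[sel] <- paste0(sub_rank[sel][1], ".", sp_rank)
  }
  tibble(genome_id = ids, subcluster_id = sub_rank, species_id = species)
}

threshold_components <- function(m, threshold) {
  adj <- (m >= threshold)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# renumber component labels: by size desc, then smallest member id
rank_partition <- function(comp, ids) {
  sizes <- table(comp)
  smallest <- tapply(ids, comp, function(x) sort(x)[1])
  lev <- names(sizes)[order(-as.integer(sizes), smallest)]
  match(as.character(comp), lev)
}

#' Cluster (subfamily) assignment from shared protein content
#'
#' Complete-linkage hierarchical clustering on distance
#' `100 - shared_percent`, cut at `100 - cluster_threshold`. Every
#' sub-cluster must fall wholly inside one cluster; if the cut splits a
#' sub-cluster, the offending clusters are merged (a warning is logged).
#' Cluster letters are assigned by size (descending), ties by smallest
#' member genome_id; within each cluster sub-clusters are numbered the same
#' way, giving labels such as "A1". A genome alone in both its sub-cluster
#' and its cluster is a singleton (a single-species genus).
#'
#' @param shared `phage_shared` object or symmetric shared-percent matrix.
#' @param subclusters Output of [assign_subclusters()].
#' @param cluster_threshold Minimum percent shared proteins for cluster
#'   membership (default 30).
#' @return Object of class `phage_taxonomy`: list with `assignments`
#'   (tibble: `genome_id`, `species_id`, `subcluster_id`, `cluster_id`,
#'   `label`, `singleton`), `dendrogram` (the hclust object), and the
#'   thresholds used.
#' @export
assign_clusters <- function(shared, subclusters, cluster_threshold = 30) {
  m <- if (inherits(shared, "phage_shared")) shared$matrix else shared
  ids <- rownames(m)
  if (!setequal(ids, subclusters$genome_id)) {
    stop("matrix and sub-cluster partition cover different genome sets")
  }
  sub <- subclusters$subcluster_id[match(ids, subclusters$genome_id)]
  d <- stats::as.dist(100 - m)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, h = 100 - cluster_threshold)
  # enforce sub-cluster atomicity: merge clusters split across a sub-cluster
  repeat {
    merged <- FALSE
    for (sc in unique(sub)) {
      cls <- unique(cl[sub == sc])
      if (length(cls) > 1) {
        warning("sub-cluster ", sc, " split by the dendrogram cut; ",
                "merging clusters to keep it atomic")
        cl[cl %in% cls] <- cls[1]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  cl_rank <- rank_partition(cl, ids)
  # cluster letters A, B, ... then AA, AB, ... beyond 26
  letters_for <- function(k) {
    if (k <= 26) LETTERS[k]
    else paste0(LETTERS[(k - 1) %/% 26], LETTERS[(k - 1) %% 26 + 1])
  }
  cluster_letter <- vapply(cl_rank, letters_for, character(1))
  # number sub-clusters within each cluster: size desc, then smallest id
  label <- character(length(ids))
  for (k in unique(cl_rank)) {
    sel <- cl_rank == k
    within_rank <- rank_partition(sub[sel], ids[sel])
    label[sel] <- paste0(cluster_letter[sel], within_rank)
  }
  sub_sizes <- table(sub)
  cl_sizes <- table(cl_rank)
  singleton <- (as.integer(sub_sizes[as.character(sub)]) == 1L) &
    (as.integer(cl_sizes[as.character(cl_rank)]) == 1L)
  assignments <- tibble(
    genome_id = ids,
    species_id = subclusters$species_id[match(ids, subclusters$genome_id)],
    subcluster_id = sub,
    cluster_id = ifelse(singleton, "SINGLETON", cluster_letter),
    label = label,
    singleton = singleton
  )
  structure(
    list(assignments = assignments, dendrogram = hc,
         thresholds = list(cluster = cluster_threshold)),
    class = "phage_taxonomy"
  )
}

#' @export
print.phage_taxonomy <- function(x, ...) {
  a <- x$assignments
  cat("Two-tier taxonomy over", nrow(a), "genomes:",
      dplyr::n_distinct(a$cluster_id[!a$singleton]), "clusters,",
      dplyr::n_distinct(a$subcluster_id), "sub-clusters,",
      sum(a$singleton), "singletons\n")
  invisible(x)
}

#' One-line summary of a taxonomy
#'
#' @param x A `phage_taxonomy` object.
#' @param ... Unused.
#' @return One-row tibble: genome, species, sub-cluster, cluster and
#'   singleton counts.
#' @export
glance.phage_taxonomy <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_genomes = nrow(a),
    n_species = dplyr::n_distinct(a$species_id),
    n_subclusters = dplyr::n_distinct(a$subcluster_id),
    n_clusters = dplyr::n_distinct(a$cluster_id[!a$singleton]),
    n_singletons = sum(a$singleton)
  )
}

#' Per-genome taxonomy assignments as a tibble
#'
#' @param x A `phage_taxonomy` object.
#' @param ... Unused.
#' @return The assignments tibble.
#' @export
tidy.phage_taxonomy <- function(x, ...) {
  x$assignments
}

#' Core / accessory / unique pangenome partition per cluster
#'
#' Within each cluster, a protein group is core when it has at least one
#' member in every cluster genome, accessory when present in two or more
#' but not all, and its proteins are unique when the group occurs in a
#' single genome of the cluster. Unique proteins are counted per protein,
#' core and accessory per group, and every in-cluster group falls in
#' exactly one class. `n_core_exclusive` counts core groups with no member
#' outside the cluster. Clusters of one genome report `NA` core/accessory
#' (single-genome clusters have no meaningful core), with all proteins
#' unique or shared-elsewhere. Genomes flagged as partial are kept in the
#' cluster but excluded from the all-members requirement for core groups.
#'
#' @param taxonomy `phage_taxonomy` object (or its assignments tibble).
#' @param groups Output of [build_groups()].
#' @param partial_genomes Character vector of genome_ids with incomplete
#'   assemblies, excluded from core counting.
#' @return Tibble per cluster: `cluster_id`, `n_genomes`, `n_core`,
#'   `n_accessory`, `n_unique`, `n_core_exclusive`.
#' @export
pangenome_partition <- function(taxonomy, groups,
                                partial_genomes = character()) {
  a <- if (inherits(taxonomy, "phage_taxonomy")) {
    taxonomy$assignments
  } else taxonomy
  stopifnot(nrow(a) >= 1)
  group_genomes <- dplyr::distinct(as_tibble(groups),
                                   .data$group_id, .data$genome_id)
  cluster_of <- stats::setNames(a$cluster_id, a$genome_id)
  out <- list()
  singles <- a$genome_id[a$singleton]
  cluster_ids <- unique(a$cluster_id[!a$singleton])
  units <- c(stats::setNames(
    lapply(cluster_ids, function(k) a$genome_id[a$cluster_id == k]),
    cluster_ids
  ), stats::setNames(lapply(singles, identity), singles))
  for (k in names(units)) {
    members <- units[[k]]
    full <- setdiff(members, partial_genomes)
    if (length(full) == 0) full <- members
    in_cluster <- dplyr::filter(groups, .data$genome_id %in% members)
    if (nrow(in_cluster) == 0) {
      out[[k]] <- tibble(cluster_id = k, n_genomes = length(members),
                         n_core = NA_integer_, n_accessory = NA_integer_,
                         n_unique = 0L, n_core_exclusive = NA_integer_)
      next
    }
    occ <- dplyr::distinct(in_cluster, .data$group_id, .data$genome_id) %>%
      dplyr::group_by(.data$group_id) %>%
      dplyr::summarise(
        n_occ = dplyr::n(),
        n_occ_full = sum(.data$genome_id %in% full),
        .groups = "drop"
      )
    if (length(members) == 1) {
      grp_one <- occ$group_id
      outside <- group_genomes %>%
        dplyr::filter(.data$group_id %in% grp_one,
                      !(.data$genome_id %in% members))
      uniq_groups <- setdiff(grp_one, outside$group_id)
      n_unique <- sum(in_cluster$group_id %in% uniq_groups)
      out[[k]] <- tibble(cluster_id = k, n_genomes = 1L,
                         n_core = NA_integer_, n_accessory = NA_integer_,
                         n_unique = as.integer(n_unique),
                         n_core_exclusive = NA_integer_)
      next
    }
    core_groups <- occ$group_id[occ$n_occ_full == length(full) &
                                  occ$n_occ >= 2]
    acc_groups <- occ$group_id[occ$n_occ >= 2 &
                                 !(occ$group_id %in% core_groups)]
    uniq_groups <- occ$group_id[occ$n_occ == 1]
    n_unique <- sum(in_cluster$group_id %in% uniq_groups)
    outside <- group_genomes %>%
      dplyr::filter(.data$group_id %in% core_groups,
                    !(.data$genome_id %in% members))
    out[[k]] <- tibble(
      cluster_id = k, n_genomes = length(members),
      n_core = length(core_groups), n_accessory = length(acc_groups),
      n_unique = as.integer(n_unique),
      n_core_exclusive = length(setdiff(core_groups, outside$group_id))
    )
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$cluster_id)
}

#' Convenience end-to-end classification
#'
#' Runs [similarity_matrix()], [build_groups()], [shared_content()],
#' [assign_subclusters()] and [assign_clusters()] with the standard
#' thresholds.
#'
#' @param genomes Annotated genome tibble.
#' @param genus_threshold,species_threshold,cluster_threshold Demarcation
#'   thresholds (percent), defaults 65 / 95 / 30.
#' @param min_identity,min_coverage Protein grouping thresholds.
#' @param params [align_params()].
#' @param backend Alignment backend.
#' @return List: `similarity`, `groups`, `shared`, `taxonomy`, `pangenome`.
#' @export
classify_genomes <- function(genomes, genus_threshold = 65,
                             species_threshold = 95, cluster_threshold = 30,
                             min_identity = 0.35, min_coverage = 0.50,
                             params = align_params(),
                             backend = c("internal", "blastn")) {
  backend <- match.arg(backend)
  sim <- similarity_matrix(genomes, params, backend)
  cds <- cds_table(genomes)
  groups <- build_groups(cds, min_identity, min_coverage)
  shared <- shared_content(cds, groups)
  subclusters <- assign_subclusters(sim, genus_threshold, species_threshold)
  taxonomy <- assign_clusters(shared, subclusters, cluster_threshold)
  pangenome <- pangenome_partition(taxonomy, groups)
  list(similarity = sim, groups = groups, shared = shared,
       taxonomy = taxonomy, pangenome = pangenome)
}

#' Write taxonomy and pangenome report TSVs
#'
#' Emits the per-genome assignment table and the per-cluster summary in the
#' conventional report shape, with deterministic row order. Re-running on
#' identical input produces byte-identical files.
#'
#' @param taxonomy `phage_taxonomy` object.
#' @param summaries Output of [pangenome_partition()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_taxonomy_report <- function(taxonomy, summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- dplyr::arrange(taxonomy$assignments, .data$genome_id)
  p1 <- file.path(dir, "taxonomy.tsv")
  readr::write_tsv(a, p1)
  p2 <- file.path(dir, "pangenome_summary.tsv")
  s <- dplyr::arrange(summaries, .data$cluster_id)
  readr::write_tsv(s, p2, na = "N/A")
  invisible(c(p1, p2))
}
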