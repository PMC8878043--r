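#' Configuration for a synthetic phage population
#'
#' Defines a planted two-tier taxonomy: `n_clusters` clusters (subfamilies),
#' each with `genera_per_cluster` genera of `genomes_per_genus` genomes,
#' plus `n_singletons` unrelated genomes. Genomes carry `genes_per_genome`
#' protein-coding genes drawn from a family pool: a fraction
#' `intra_cluster_shared_gene_frac` of each genome's genes is the cluster
#' core (present in every cluster member); of the remainder, 80% are
#' genus-shared accessory families and 20% are genome-private. A fraction
#' `inter_cluster_shared_gene_frac` of each cluster's families is drawn
#' from a pool common to all clusters, the rest from a cluster-private
#' pool. Genera diverge from their cluster ancestor at
#' `inter_genus_divergence` substitutions per site and genomes from their
#' genus ancestor at `intra_genus_divergence`, so the expected pairwise
#' nucleotide identity of aligned genes within a genus is
#' `(1 - intra_genus_divergence)^2`.
#'
#' @param n_clusters,genera_per_cluster,genomes_per_genus Planted taxonomy
#'   shape.
#' @param gene_pool_size Number of ancestral gene families available.
#' @param genes_per_genome Genes per genome.
#' @param mean_gene_len_nt Mean gene length (nt, multiple of 3 enforced).
#' @param intra_genus_divergence,inter_genus_divergence Per-site
#'   substitution probabilities in `[0, 0.75]`.
#' @param inter_cluster_shared_gene_frac,intra_cluster_shared_gene_frac
#'   Gene-sharing fractions in `[0, 1]`.
#' @param n_singletons Number of unrelated singleton genomes.
#' @param rng_seed Integer seed; the output is fully determined by it.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_clusters = 3, genera_per_cluster = 2,
                              genomes_per_genus = 3, gene_pool_size = 400,
                              genes_per_genome = 20, mean_gene_len_nt = 900,
                              intra_genus_divergence = 0.02,
                              inter_genus_divergence = 0.12,
                              inter_cluster_shared_gene_frac = 0.1,
                              intra_cluster_shared_gene_frac = 0.5,
                              n_singletons = 2, rng_seed = 42) {
  stopifnot(
    intra_genus_divergence >= 0, intra_genus_divergence <= 0.75,
    inter_genus_divergence >= 0, inter_genus_divergence <= 0.75,
    inter_cluster_shared_gene_frac >= 0, inter_cluster_shared_gene_frac <= 1,
    intra_cluster_shared_gene_frac >= 0, intra_cluster_shared_gene_frac <= 1,
    n_clusters >= 0, genera_per_cluster >= 1, genomes_per_genus >= 1,
    n_singletons >= 0, genes_per_genome >= 1, gene_pool_size >= 1
  )
  if (genes_per_genome > gene_pool_size) {
    stop("genes_per_genome exceeds gene_pool_size")
  }
  structure(
    list(n_clusters = n_clusters, genera_per_cluster = genera_per_cluster,
         genomes_per_genus = genomes_per_genus,
         gene_pool_size = gene_pool_size,
         genes_per_genome = genes_per_genome,
         mean_gene_len_nt = mean_gene_len_nt,
         intra_genus_divergence = intra_genus_divergence,
         inter_genus_divergence = inter_genus_divergence,
         inter_cluster_shared_gene_frac = inter_cluster_shared_gene_frac,
         intra_cluster_shared_gene_frac = intra_cluster_shared_gene_frac,
         n_singletons = n_singletons, rng_seed = rng_seed),
    class = "population_config"
  )
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

# random gene: ATG + sense codons + TAA; length ~ mean +/- 20%, multiple of 3
random_gene <- function(mean_len) {
  n_cod <- max(10L, round(stats::runif(1, 0.8, 1.2) * mean_len / 3))
  paste0("ATG", paste(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# per-site substitution at rate d with no reading-frame constraint
# (intergenic sequence)
mutate_plain <- function(seq, d) {
  if (d <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < d)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

# per-site substitution at rate d, keeping start/stop codons fixed and
# rejecting substitutions that create an in-frame stop
mutate_gene <- function(gene, d) {
  if (d <= 0) return(gene)
  bases <- strsplit(gene, "")[[1]]
  n <- length(bases)
  mutable <- setdiff(seq_len(n), c(1:3, (n - 2):n))
  hit <- mutable[stats::runif(length(mutable)) < d]
  for (i in hit) {
    old <- bases[i]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    cod_start <- i - ((i - 1) %% 3)
    cod <- bases[cod_start:(cod_start + 2)]
    cod[(i - cod_start) + 1] <- new
    if (!(paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA"))) {
      bases[i] <- new
    }
  }
  paste(bases, collapse = "")
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(20:200, 1), replace = TRUE),
        collapse = "")
}

#' Simulate a phage population with planted taxonomy
#'
#' Deterministic for a fixed `rng_seed`. Gene families are random codon
#' sequences without internal stops; gain/loss is modelled by family
#' subsetting; substitutions are uniform point changes that never create an
#' in-frame stop, so translated proteins stay valid orthologs. Genes are
#' separated by random 20-200 bp intergenic spacers drawn independently per
#' genome.
#'
#' @param config A [population_config()].
#' @return List of class `phage_population`: `genomes` (annotated genome
#'   tibble), `truth` (tibble: `genome_id`, `cluster`, `genus`, `species`),
#'   `gene_truth` (tibble: `protein_id`, `genome_id`, `family`), `config`,
#'   and `expected_identity` (expected aligned-gene identity within a
#'   genus).
#' @export
simulate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(config$rng_seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  pool <- vapply(seq_len(cfg$gene_pool_size),
                 function(i) random_gene(cfg$mean_gene_len_nt), character(1))
  family_ids <- sprintf("F%04d", seq_len(cfg$gene_pool_size))

  n_core <- round(cfg$intra_cluster_shared_gene_frac * cfg$genes_per_genome)
  n_rest <- cfg$genes_per_genome - n_core
  n_genus_acc <- round(0.8 * n_rest)
  n_private <- n_rest - n_genus_acc

  # split the family pool: one shared pool for cross-cluster families,
  # disjoint private pools per cluster/singleton
  n_units <- cfg$n_clusters + cfg$n_singletons
  pool_idx <- sample.int(cfg$gene_pool_size)
  n_shared_pool <- max(
    if (cfg$inter_cluster_shared_gene_frac > 0) {
      ceiling(cfg$inter_cluster_shared_gene_frac * cfg$genes_per_genome) + 2L
    } else 0L, 0L)
  shared_pool <- pool_idx[seq_len(n_shared_pool)]
  rest_pool <- pool_idx[-seq_len(max(n_shared_pool, 0L))]
  private_pools <- if (n_units > 0) {
    unit_of <- rep(seq_len(n_units),
                   each = ceiling(length(rest_pool) / n_units))
    unname(split(rest_pool, unit_of[seq_along(rest_pool)]))
  } else list()

  genomes <- list()
  truth <- list()
  gene_truth <- list()

  # Genomes within a genus share a layout (gene order, strands, ancestral
  # intergenic spacers), so the zero-divergence limit yields identical
  # genomes; spacers then diverge at the same per-site rate as genes.
  emit_genome <- function(genome_id, fam_idx, gene_seqs, layout, d_spacer,
                          cluster, genus, species) {
    stopifnot(length(fam_idx) == length(gene_seqs))
    ord <- layout$ord
    spacers <- vapply(layout$spacers, mutate_plain, character(1),
                      d = d_spacer)
    seq_parts <- character(0)
    cds_rows <- list()
    pos <- 0L
    for (k in seq_along(ord)) {
      sp <- spacers[k]
      seq_parts <- c(seq_parts, sp)
      pos <- pos + nchar(sp)
      g <- gene_seqs[ord[k]]
      strand <- layout$strands[k]
      gseq <- if (strand == "+") g else revcomp(g)
      seq_parts <- c(seq_parts, gseq)
      aa <- translate_table11(substr(g, 1, nchar(g) - 3))
      substr(aa, 1, 1) <- "M"
      pid <- paste0(genome_id, "_", sprintf("%04d", k))
      cds_rows[[k]] <- tibble(
        genome_id = genome_id, cds_index = k,
        start = pos, end = pos + nchar(g), strand = strand,
        protein_id = pid, aa_sequence = aa
      )
      gene_truth[[length(gene_truth) + 1L]] <<- tibble(
        protein_id = pid, genome_id = genome_id,
        family = family_ids[fam_idx[ord[k]]]
      )
      pos <- pos + nchar(g)
    }
    seq_parts <- c(seq_parts, spacers[length(spacers)])
    seq <- paste(seq_parts, collapse = "")
    cds <- dplyr::bind_rows(cds_rows)
    genomes[[length(genomes) + 1L]] <<- genome_row(
      genome_id, paste("synthetic phage", genome_id), seq, cds
    )
    truth[[length(truth) + 1L]] <<- tibble(
      genome_id = genome_id, cluster = cluster, genus = genus,
      species = species
    )
  }

  new_layout <- function(n_slots) {
    list(
      ord = sample(n_slots),
      strands = sample(c("+", "-"), n_slots, replace = TRUE),
      spacers = replicate(n_slots + 1L, random_spacer())
    )
  }

  for (ci in seq_len(cfg$n_clusters)) {
    priv <- private_pools[[ci]]
    # cluster core families: mix of shared-pool and cluster-private picks
    n_from_shared <- min(round(cfg$inter_cluster_shared_gene_frac *
                                 cfg$genes_per_genome), length(shared_pool))
    core_fams <- c(
      if (n_from_shared > 0) shared_pool[seq_len(n_from_shared)] else integer(0),
      priv[seq_len(n_core - n_from_shared)]
    )
    used <- n_core - n_from_shared
    cluster_anc <- stats::setNames(pool[core_fams], core_fams)

    for (gi in seq_len(cfg$genera_per_cluster)) {
      acc_fams <- priv[used + seq_len(n_genus_acc)]
      used <- used + n_genus_acc
      # genus ancestor: cluster core diverged + genus accessory from pool
      genus_core <- vapply(cluster_anc, mutate_gene,
                           character(1), d = cfg$inter_genus_divergence)
      genus_acc <- vapply(pool[acc_fams], mutate_gene,
                          character(1), d = cfg$inter_genus_divergence)
      layout <- new_layout(cfg$genes_per_genome)
      for (mi in seq_len(cfg$genomes_per_genus)) {
        priv_fams <- priv[used + seq_len(n_private)]
        used <- used + n_private
        fam_idx <- c(core_fams, acc_fams, priv_fams)
        anc <- c(genus_core, genus_acc,
                 vapply(pool[priv_fams], mutate_gene, character(1),
                        d = cfg$inter_genus_divergence))
        gene_seqs <- vapply(anc, mutate_gene, character(1),
                            d = cfg$intra_genus_divergence)
        genome_id <- sprintf("C%02dG%02dM%02d", ci, gi, mi)
        emit_genome(genome_id, fam_idx, gene_seqs, layout,
                    d_spacer = cfg$intra_genus_divergence,
                    cluster = sprintf("cluster_%02d", ci),
                    genus = sprintf("genus_%02d_%02d", ci, gi),
                    species = sprintf("species_%02d_%02d_%02d", ci, gi, mi))
      }
    }
  }

  for (si in seq_len(cfg$n_singletons)) {
    priv <- private_pools[[cfg$n_clusters + si]]
    fam_idx <- priv[seq_len(min(cfg$genes_per_genome, length(priv)))]
    gene_seqs <- pool[fam_idx]
    genome_id <- sprintf("SNG%02d", si)
    emit_genome(genome_id, fam_idx, gene_seqs,
                new_layout(length(fam_idx)), d_spacer = 0,
                cluster = sprintf("singleton_%02d", si),
                genus = sprintf("singleton_%02d", si),
                species = sprintf("singleton_%02d", si))
  }

  structure(
    list(
      genomes = dplyr::bind_rows(genomes),
      truth = dplyr::bind_rows(truth),
      gene_truth = dplyr::bind_rows(gene_truth),
      config = cfg,
      expected_identity = (1 - cfg$intra_genus_divergence)^2
    ),
    class = "phage_population"
  )
}

#' @export
print.phage_population <- function(x, ...) {
  cat("Synthetic phage population:", nrow(x$genomes), "genomes,",
      nrow(x$gene_truth), "genes,",
      dplyr::n_distinct(x$truth$cluster), "planted taxa at cluster level\n")
  invisible(x)
}

# deterministic GFF3 for the CDS annotations (1-based inclusive coordinates)
write_cds_gff3 <- function(genomes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genomes))) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              genomes$genome_id[i], genomes$length_bp[i]))
  }
  cds <- cds_table(genomes)
  if (nrow(cds) > 0) {
    rc <- to_report_coords(cds$start, cds$end)
    lines <- c(lines, sprintf(
      "%s\tphagetax\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
      cds$genome_id, rc$start, rc$end, cds$strand, cds$protein_id
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic population to disk as a reusable fixture
#'
#' Emits genome FASTA, protein FASTA, CDS GFF3 and truth TSVs. Regenerating
#' with the same seed yields byte-identical files.
#'
#' @param population Output of [simulate_population()].
#' @param outdir Output directory.
#' @param overwrite Overwrite an existing directory? Default `FALSE`.
#' @return Tibble of written paths, invisibly.
#' @export
write_fixture <- function(population, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && !overwrite) {
    stop("output directory exists: ", outdir, " (use overwrite = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- population$genomes
  paths <- c(
    genomes = file.path(outdir, "genomes.fasta"),
    proteins = file.path(outdir, "proteins.faa"),
    gff = file.path(outdir, "cds.gff3"),
    truth = file.path(outdir, "truth.tsv"),
    gene_truth = file.path(outdir, "gene_truth.tsv")
  )
  write_genome_fasta(g, paths["genomes"])
  write_protein_fasta(g, paths["proteins"])
  write_cds_gff3(g, paths["gff"])
  readr::write_tsv(population$truth, paths["truth"])
  readr::write_tsv(population$gene_truth, paths["gene_truth"])
  invisible(tibble(name = names(paths), path = unname(paths)))
}
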