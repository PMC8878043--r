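#' Pipeline run configuration
#'
#' Bundles the input locations and every demarcation threshold of the
#' pipeline. Defaults mirror the standard demarcation values: species 95%,
#' genus 65% nucleotide similarity, cluster 30% shared proteins, protein
#' grouping at 35% identity / 50% coverage, minimum ORF 120 nt.
#'
#' @param input Path to a genome FASTA or GenBank flat file (or vector of
#'   paths), or `NULL` when `genomes` are passed to [run_pipeline()]
#'   directly.
#' @param format Input format, `"fasta"` or `"genbank"`.
#' @param outdir Output directory.
#' @param species_threshold,genus_threshold,cluster_threshold Demarcation
#'   thresholds (percent).
#' @param min_identity,min_coverage Protein grouping thresholds (fractions).
#' @param min_orf_nt Minimum ORF length for unannotated genomes.
#' @param backend Alignment backend (`"internal"` or `"blastn"`).
#' @param call_orfs Call ORFs when a genome has no CDS annotations.
#' @param partial_genomes Genome ids excluded from core-genome counting.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, format = "fasta", outdir = "phagetax_out",
                       species_threshold = 95, genus_threshold = 65,
                       cluster_threshold = 30, min_identity = 0.35,
                       min_coverage = 0.50, min_orf_nt = 120,
                       backend = "internal", call_orfs = TRUE,
                       partial_genomes = character(), seed = 1L) {
  stopifnot(
    species_threshold > 0, species_threshold <= 100,
    genus_threshold > 0, genus_threshold <= 100,
    cluster_threshold > 0, cluster_threshold <= 100,
    min_identity > 0, min_identity <= 1,
    min_coverage >= 0, min_coverage <= 1,
    min_orf_nt > 0
  )
  structure(
    list(version = 1L, input = input, format = format, outdir = outdir,
         species_threshold = species_threshold,
         genus_threshold = genus_threshold,
         cluster_threshold = cluster_threshold,
         min_identity = min_identity, min_coverage = min_coverage,
         min_orf_nt = min_orf_nt, backend = backend, call_orfs = call_orfs,
         partial_genomes = partial_genomes, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y <- y[names(y) %in% names(formals(run_config))]
  do.call(run_config, y)
}

#' Run the full classification pipeline
#'
#' Executes all stages in order -- ingest (and ORF calling where needed),
#' all-versus-all nucleotide similarity, protein grouping, shared-content
#' matrix, two-tier taxonomy, pangenome partition, and network export --
#' writing every intermediate table plus a JSON manifest with the config,
#' input checksums and per-stage wall-clock times. Identical config and
#' inputs give identical (non-log) outputs.
#'
#' @param config A [run_config()] object or path to a YAML config.
#' @param genomes Optional pre-loaded genome tibble (overrides
#'   `config$input`).
#' @return List: `results` (as [classify_genomes()] plus `distance`),
#'   `manifest` (list also written to `manifest.json`), `outdir`.
#' @export
run_pipeline <- function(config = run_config(), genomes = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  failed_marker <- file.path(outdir, ".failed")
  if (file.exists(failed_marker)) unlink(failed_marker)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage: ", name), failed_marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  input_checksums <- NULL
  genomes <- run_stage("ingest", function() {
    if (is.null(genomes)) {
      if (is.null(config$input)) stop("no input configured")
      missing <- config$input[!file.exists(config$input)]
      if (length(missing) > 0) stop("missing input file: ", missing[1])
      input_checksums <<- as.list(tools::md5sum(config$input))
      g <- read_genomes(config$input, config$format)
    } else {
      g <- genomes
    }
    needs_orfs <- purrr::map_int(g$cds, nrow) == 0
    if (config$call_orfs && any(needs_orfs)) {
      g[needs_orfs, ] <- call_orfs(g[needs_orfs, ],
                                   min_len_nt = config$min_orf_nt)
    }
    g
  })

  params <- align_params()
  sim <- run_stage("nt_similarity", function() {
    similarity_matrix(genomes, params, config$backend)
  })
  groups <- run_stage("protein_groups", function() {
    build_groups(cds_table(genomes), config$min_identity, config$min_coverage)
  })
  shared <- run_stage("shared_content", function() {
    shared_content(cds_table(genomes), groups)
  })
  taxres <- run_stage("taxonomy", function() {
    subclusters <- assign_subclusters(sim, config$genus_threshold,
                                      config$species_threshold)
    assign_clusters(shared, subclusters, config$cluster_threshold)
  })
  pangenome <- run_stage("pangenome", function() {
    pangenome_partition(taxres, groups, config$partial_genomes)
  })
  outputs <- run_stage("export", function() {
    pa <- presence_absence(groups)
    d <- content_distance(pa)
    paths <- c(
      manifest_tsv = file.path(outdir, "genomes.tsv"),
      sim = file.path(outdir, "similarity.tsv"),
      groups = file.path(outdir, "groups.tsv"),
      shared = file.path(outdir, "shared_content.tsv"),
      heatmap = file.path(outdir, "shared_heatmap.tsv"),
      nexus = file.path(outdir, "content_distance.nex")
    )
    readr::write_tsv(genome_manifest(genomes), paths["manifest_tsv"])
    write_similarity_tsv(sim, paths["sim"])
    write_groups_tsv(groups, paths["groups"])
    write_similarity_tsv(shared$matrix, paths["shared"])
    leaf_order <- taxres$dendrogram$labels[taxres$dendrogram$order]
    write_heatmap_table(shared, leaf_order, paths["heatmap"], taxres)
    write_nexus_distances(d, paths["nexus"])
    tax_paths <- write_taxonomy_report(taxres, pangenome, outdir)
    list(paths = c(paths, taxonomy = tax_paths[1], pangenome = tax_paths[2]),
         distance = d)
  })

  all_paths <- unlist(outputs$paths)
  manifest <- list(
    config = unclass(config),
    input_checksums = input_checksums,
    n_genomes = nrow(genomes),
    stages = stages,
    outputs = lapply(stats::setNames(as.list(all_paths), names(all_paths)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(
    results = list(similarity = sim, groups = groups, shared = shared,
                   taxonomy = taxres, pangenome = pangenome,
                   distance = outputs$distance, genomes = genomes),
    manifest = manifest,
    outdir = outdir
  )
}
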