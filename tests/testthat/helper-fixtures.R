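# Shared helpers: small random-sequence generators and a lazily computed
# demo classification reused across test files.

DNA <- c("A", "C", "G", "T")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_dna <- function(seq, d) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < d)
  for (i in hit) b[i] <- sample(setdiff(DNA, b[i]), 1)
  paste(b, collapse = "")
}

mutate_protein <- function(seq, d) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < d)
  b[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(b, collapse = "")
}

genome_tbl <- function(...) {
  seqs <- c(...)
  ids <- names(seqs)
  tibble::tibble(
    genome_id = ids, name = ids, sequence = unname(seqs),
    length_bp = nchar(unname(seqs)),
    gc_percent = NA_real_,
    cds = replicate(length(seqs), phagetax:::empty_cds_table(),
                    simplify = FALSE)
  )
}

# independent nucleotide oracle: optimal local alignment by full DP
nt_oracle_identities <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = TRUE
  )
  ali <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2
  )
  Biostrings::nmatch(ali)
}

# independent protein oracle
protein_oracle <- function(p, q) {
  ali <- Biostrings::pairwiseAlignment(
    p, q, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  list(
    score = Biostrings::score(ali),
    identities = Biostrings::nmatch(ali),
    columns = Biostrings::nchar(ali),
    span_p = IRanges::width(Biostrings::pattern(ali)),
    span_q = IRanges::width(Biostrings::subject(ali))
  )
}

# cluster-level partition with singletons as their own taxa
cluster_partition <- function(assignments) {
  ifelse(assignments$singleton, assignments$genome_id,
         assignments$cluster_id)
}

# demo population and its full classification, computed once per session
.demo_cache <- new.env(parent = emptyenv())

demo_population <- function() {
  if (is.null(.demo_cache$pop)) {
    .demo_cache$pop <- simulate_population(population_config())
  }
  .demo_cache$pop
}

demo_classification <- function() {
  if (is.null(.demo_cache$res)) {
    .demo_cache$res <- classify_genomes(demo_population()$genomes)
  }
  .demo_cache$res
}

# a small, fast population for pipeline-level tests
small_population <- function(seed = 5) {
  simulate_population(population_config(
    n_clusters = 2, genera_per_cluster = 2, genomes_per_genus = 2,
    gene_pool_size = 150, genes_per_genome = 10, mean_gene_len_nt = 600,
    n_singletons = 1, rng_seed = seed
  ))
}
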