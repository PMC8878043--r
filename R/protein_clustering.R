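#' Pairwise protein match decision
#'
#' Best local alignment under BLOSUM62 with gap open 11 / extend 1;
#' identity is identical residues over alignment columns, and coverage is
#' the aligned span divided by sequence length, evaluated on both sequences
#' and taken as the minimum. The pair matches when identity and coverage
#' both reach their thresholds; the decision is symmetric in its arguments.
#'
#' @param p,q Amino-acid strings.
#' @param min_identity Identity threshold (default 0.35).
#' @param min_coverage Coverage threshold on both sequences (default 0.50).
#' @return One-row tibble: `match`, `identity`, `coverage`.
#' @export
protein_pair_match <- function(p, q, min_identity = 0.35,
                               min_coverage = 0.50) {
  if (!nzchar(p) || !nzchar(q)) stop("empty sequence")
  a <- protein_align_batch(p, q)
  tibble(match = a$identity >= min_identity & a$coverage >= min_coverage,
         identity = a$identity, coverage = a$coverage)
}

blosum62_env <- new.env(parent = emptyenv())

blosum62_tables <- function() {
  if (is.null(blosum62_env$submat)) {
    data("BLOSUM62", package = "Biostrings", envir = blosum62_env)
    m <- blosum62_env$BLOSUM62
    alpha <- rownames(m)
    lookup <- rep(match("X", alpha) - 1L, 128) # unknown residues score as X
    lookup[utf8ToInt(paste(alpha, collapse = "")) + 1L] <-
      seq_along(alpha) - 1L
    blosum62_env$submat <- matrix(as.integer(m), nrow(m), ncol(m))
    blosum62_env$lookup <- lookup
  }
  list(submat = blosum62_env$submat, lookup = blosum62_env$lookup)
}

# Local alignment of one pattern against many subjects (Smith-Waterman,
# BLOSUM62, affine gaps). Returns identity (identical residues / alignment
# columns) and coverage (aligned span / length, min over both sequences).
protein_align_batch <- function(p, subjects) {
  tabs <- blosum62_tables()
  a <- .cpp_protein_batch(p, subjects, tabs$submat, tabs$lookup, 11L, 1L)
  cov <- pmin(a$span_p / nchar(p), a$span_q / nchar(subjects))
  list(identity = ifelse(a$columns > 0, a$identities / a$columns, 0),
       coverage = cov, score = a$score)
}

#' Group proteins into orthologous families (phams)
#'
#' Builds a graph whose nodes are proteins and whose edges join pairs that
#' satisfy [protein_pair_match()]; groups are the connected components
#' (single linkage). Groups with a single member are orphams. Group ids are
#' assigned deterministically by the lexicographically smallest member
#' protein_id.
#'
#' @param cds CDS tibble (see [cds_table()]).
#' @param min_identity,min_coverage Thresholds, see [protein_pair_match()].
#' @param length_filter Skip pairs whose lengths differ by more than 4x
#'   (such pairs cannot reach 50% coverage of the longer sequence). Set to
#'   `FALSE` to force all-pairs alignment.
#' @return Tibble of class `phage_groups`: `group_id`, `protein_id`,
#'   `genome_id`, with one row per protein (groups partition the proteome).
#' @export
build_groups <- function(cds, min_identity = 0.35, min_coverage = 0.50,
                         length_filter = TRUE) {
  stopifnot(nrow(cds) >= 1)
  if (anyDuplicated(cds$protein_id) > 0) stop("protein_ids must be unique")
  n <- nrow(cds)
  lens <- nchar(cds$aa_sequence)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      if (length_filter && min_coverage > 0) {
        ratio <- pmax(lens[i], lens[j]) / pmin(lens[i], lens[j])
        j <- j[ratio <= 4]
      }
      if (length(j) == 0) next
      a <- protein_align_batch(cds$aa_sequence[i], cds$aa_sequence[j])
      hit <- a$identity >= min_identity & a$coverage >= min_coverage
      if (any(hit)) {
        edges[[length(edges) + 1L]] <- cbind(i, j[hit])
      }
    }
  }
  comp <- if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership
  } else {
    seq_len(n)
  }
  # deterministic ids from the smallest member protein_id
  smallest <- tapply(cds$protein_id, comp, function(x) sort(x)[1])
  ord <- order(smallest)
  rank <- match(as.character(comp), names(smallest)[ord])
  out <- tibble(
    group_id = sprintf("G%05d", rank),
    protein_id = cds$protein_id,
    genome_id = cds$genome_id
  )
  out <- dplyr::arrange(out, .data$group_id, .data$protein_id)
  class(out) <- c("phage_groups", class(out))
  out
}

#' Summarise protein groups
#'
#' @param groups Output of [build_groups()].
#' @return Tibble per group: `group_id`, `n_members`, `n_genomes`, `orpham`.
#' @export
group_summary <- function(groups) {
  groups %>%
    dplyr::group_by(.data$group_id) %>%
    dplyr::summarise(n_members = dplyr::n(),
                     n_genomes = dplyr::n_distinct(.data$genome_id),
                     .groups = "drop") %>%
    dplyr::mutate(orpham = .data$n_members == 1)
}

#' Shared protein content between genome pairs
#'
#' For genomes a, b let `s_a` be the number of a's proteins whose group also
#' contains at least one protein of b, and symmetrically `s_b`. The shared
#' percentage is `100 * (s_a + s_b) / (n_a + n_b)` with proteome sizes in
#' the denominator; the diagonal is 100 by definition.
#'
#' @param cds CDS tibble; every genome must have at least one protein.
#' @param groups Output of [build_groups()] over the same proteome.
#' @return Object of class `phage_shared`: list with `matrix` (symmetric,
#'   percent) and `genome_ids`.
#' @export
shared_content <- function(cds, groups) {
  ids <- unique(cds$genome_id)
  sizes <- table(factor(cds$genome_id, levels = ids))
  if (any(sizes == 0)) {
    stop("genome with zero proteins: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  gg <- dplyr::distinct(groups, .data$group_id, .data$genome_id)
  # per genome: named count of proteins per group
  prot_by_genome <- split(groups$group_id, groups$genome_id)
  groups_of <- lapply(prot_by_genome, unique)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      gi <- prot_by_genome[[ids[i]]]
      for (j in (i + 1):n) {
        gj <- prot_by_genome[[ids[j]]]
        s_i <- sum(gi %in% groups_of[[ids[j]]])
        s_j <- sum(gj %in% groups_of[[ids[i]]])
        v <- 100 * (s_i + s_j) / (length(gi) + length(gj))
        m[i, j] <- v; m[j, i] <- v
      }
    }
  }
  structure(list(matrix = m, genome_ids = ids), class = "phage_shared")
}

#' @export
print.phage_shared <- function(x, ...) {
  cat("Shared protein content over", length(x$genome_ids), "genomes\n")
  invisible(x)
}

#' Write group membership as TSV
#'
#' @param groups Output of [build_groups()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(as_tibble(groups), path)
  invisible(path)
}
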