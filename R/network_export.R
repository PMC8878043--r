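#' Binary gene presence/absence matrix
#'
#' @param groups Output of [build_groups()].
#' @return Integer matrix, genomes x groups, 1 when the genome has at least
#'   one protein in the group. No all-zero rows can occur (every genome in
#'   `groups` has at least one protein).
#' @export
presence_absence <- function(groups) {
  ids <- sort(unique(groups$genome_id))
  gids <- sort(unique(groups$group_id))
  m <- matrix(0L, length(ids), length(gids), dimnames = list(ids, gids))
  occ <- dplyr::distinct(as_tibble(groups), .data$genome_id, .data$group_id)
  m[cbind(match(occ$genome_id, ids), match(occ$group_id, gids))] <- 1L
  m
}

#' Genome-content distance from gene presence/absence
#'
#' With the default union denominator,
#' `d(a, b) = |symmetric difference| / |union|` over gene families (Jaccard
#' distance): the number of presence/absence differences per family present
#' in at least one of the two genomes. The alternative `"total"`
#' denominator divides by the total number of families instead.
#'
#' @param pa Presence/absence matrix from [presence_absence()].
#' @param denominator `"union"` (default) or `"total"`.
#' @return Symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
content_distance <- function(pa, denominator = c("union", "total")) {
  denominator <- match.arg(denominator)
  if (nrow(pa) < 2) stop("need at least 2 genomes")
  empty <- rowSums(pa) == 0
  if (any(empty)) {
    stop("genome with empty profile: ",
         paste(rownames(pa)[empty], collapse = ", "))
  }
  x <- pa %*% t(pa) # intersections
  sz <- rowSums(pa)
  un <- outer(sz, sz, "+") - x
  diffs <- un - x # symmetric difference
  denom <- if (denominator == "union") un else matrix(ncol(pa), nrow(pa), nrow(pa))
  d <- diffs / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  d
}

nexus_quote <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.]|'", x)
  x2 <- gsub("'", "''", x)
  ifelse(needs, paste0("'", x2, "'"), x2)
}

#' Write a distance matrix as a NEXUS DISTANCES block
#'
#' Emits TAXA and DISTANCES blocks (lower triangle with diagonal) readable
#' by splits-network software. Output is byte-deterministic for a fixed
#' input. Labels containing reserved characters are quoted.
#'
#' @param dist Symmetric distance matrix with genome_id dimnames.
#' @param path Output file.
#' @param digits Decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_nexus_distances <- function(dist, path, digits = 6) {
  ids <- rownames(dist)
  if (anyDuplicated(ids) > 0) stop("duplicate taxa labels")
  n <- length(ids)
  q <- nexus_quote(ids)
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  TAXLABELS",
    paste0("    ", q),
    "  ;",
    "END;", "",
    "BEGIN DISTANCES;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;",
    "  MATRIX"
  )
  for (i in seq_len(n)) {
    row <- formatC(dist[i, 1:i], format = "f", digits = digits)
    lines <- c(lines, paste0("    ", q[i], " ", paste(row, collapse = " ")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a NEXUS DISTANCES block
#'
#' Companion reader for [write_nexus_distances()] (lower-triangular with
#' diagonal), used for round-trip verification.
#'
#' @param path NEXUS file written by [write_nexus_distances()].
#' @return Symmetric distance matrix.
#' @export
read_nexus_distances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mi <- grep("^\\s*MATRIX\\s*$", lines)
  if (length(mi) == 0) stop("no MATRIX block found")
  mi <- mi[length(mi)]
  rows <- list()
  for (ln in lines[(mi + 1):length(lines)]) {
    if (grepl("^\\s*;", ln)) break
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "'")) {
      m <- regmatches(ln, regexec("^'((?:[^']|'')*)'\\s*(.*)$", ln))[[1]]
      if (length(m) == 0) stop("malformed quoted label: ", ln)
      label <- gsub("''", "'", m[2])
      rest <- trimws(m[3])
    } else {
      sp <- regexpr("\\s", ln)
      label <- substr(ln, 1, sp - 1)
      rest <- trimws(substring(ln, sp + 1))
    }
    vals <- if (nzchar(rest)) as.numeric(strsplit(rest, "\\s+")[[1]]) else numeric(0)
    rows[[label]] <- vals
  }
  n <- length(rows)
  ids <- names(rows)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, seq_len(i)] <- rows[[i]]
    m[seq_len(i), i] <- rows[[i]]
  }
  m
}

#' Write a shared-content heatmap table in dendrogram leaf order
#'
#' Permutes the shared-content matrix to the given leaf order and writes a
#' TSV with the cluster label of each genome as a colour-key column.
#'
#' @param shared `phage_shared` object or shared-percent matrix.
#' @param order Character vector: permutation of the genome ids (e.g.
#'   `hc$labels[hc$order]` from the taxonomy dendrogram).
#' @param path Output file.
#' @param taxonomy Optional `phage_taxonomy` for the cluster key column.
#' @return `path`, invisibly.
#' @export
write_heatmap_table <- function(shared, order, path, taxonomy = NULL) {
  m <- if (inherits(shared, "phage_shared")) shared$matrix else shared
  if (!setequal(order, rownames(m)) || length(order) != nrow(m)) {
    stop("order is not a permutation of the genome ids")
  }
  m <- m[order, order]
  key <- if (!is.null(taxonomy)) {
    a <- taxonomy$assignments
    a$cluster_id[match(order, a$genome_id)]
  } else {
    rep(NA_character_, length(order))
  }
  df <- tibble(genome_id = order, cluster = key) %>%
    dplyr::bind_cols(as_tibble(round(m, 1), .name_repair = "minimal"))
  readr::write_tsv(df, path)
  invisible(path)
}
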