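#' Alignment scoring parameters
#'
#' Defaults follow the blastn-style parameterisation used for intergenomic
#' similarity screens of phage genomes: short seeds (word size 7), match +2,
#' mismatch -3, gap open 5, gap extend 2. A gap of length k costs
#' `gap_open + k * gap_extend`. HSPs scoring below `min_score` (default 50,
#' i.e. a 25 bp exact match) are discarded.
#'
#' @param reward Match reward (> 0).
#' @param penalty Mismatch penalty (< 0).
#' @param gap_open Gap opening cost (> 0).
#' @param gap_extend Gap extension cost per position (> 0).
#' @param word_size Exact-match seed length (4..15).
#' @param min_score Minimum HSP score kept.
#' @param gap_trigger Ungapped score needed before gapped extension.
#' @param xdrop_ungapped,xdrop_gapped X-drop termination thresholds.
#' @return A list of class `align_params`.
#' @export
align_params <- function(reward = 2L, penalty = -3L, gap_open = 5L,
                         gap_extend = 2L, word_size = 7L, min_score = 50L,
                         gap_trigger = 40L, xdrop_ungapped = 30L,
                         xdrop_gapped = 100L) {
  stopifnot(reward > 0, penalty < 0, word_size >= 4, word_size <= 15)
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive costs")
  }
  structure(
    list(reward = as.integer(reward), penalty = as.integer(penalty),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size), min_score = as.integer(min_score),
         gap_trigger = as.integer(gap_trigger),
         xdrop_ungapped = as.integer(xdrop_ungapped),
         xdrop_gapped = as.integer(xdrop_gapped)),
    class = "align_params"
  )
}

encode_dna <- function(seq) {
  x <- utf8ToInt(seq)
  out <- rep(4L, length(x))
  out[x == 65L] <- 0L # A
  out[x == 67L] <- 1L # C
  out[x == 71L] <- 2L # G
  out[x == 84L] <- 3L # T
  out
}

#' Local alignment of two nucleotide sequences
#'
#' Seed-and-extend local alignment searching both subject strands. Returns
#' all high-scoring pairs (HSPs) above the score floor. Coordinates are
#' 0-based half-open on the forward strand of each sequence; for minus-strand
#' HSPs `s_start`/`s_end` still refer to the forward subject strand.
#'
#' @param query,subject DNA strings (uppercase A/C/G/T/N).
#' @param params An [align_params()] object.
#' @param backend `"internal"` (seed-and-extend, default) or `"blastn"`
#'   (external blastn binary, if on the PATH).
#' @return Tibble of HSPs: `q_start`, `q_end`, `s_start`, `s_end`,
#'   `s_strand`, `score`, `identities`, `aln_len`.
#' @export
align_pair <- function(query, subject, params = align_params(),
                       backend = c("internal", "blastn")) {
  backend <- match.arg(backend)
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  if (backend == "blastn") {
    return(align_pair_blastn(query, subject, params))
  }
  q <- encode_dna(query)
  run1 <- function(subj_seq, strand) {
    s <- encode_dna(subj_seq)
    h <- .cpp_seed_extend(q, s, params$reward, params$penalty,
                          params$gap_open, params$gap_extend,
                          params$word_size, params$min_score,
                          params$gap_trigger, params$xdrop_ungapped,
                          params$xdrop_gapped)
    h <- as_tibble(h)
    h$s_strand <- rep(strand, nrow(h))
    h
  }
  fwd <- run1(subject, "+")
  rev <- run1(revcomp(subject), "-")
  if (nrow(rev) > 0) {
    slen <- nchar(subject)
    new_start <- slen - rev$s_end
    rev$s_end <- slen - rev$s_start
    rev$s_start <- new_start
  }
  out <- dplyr::bind_rows(fwd, rev)
  out <- dplyr::arrange(out, .data$q_start, .data$s_start, .data$s_strand)
  dplyr::select(out, "q_start", "q_end", "s_start", "s_end", "s_strand",
                "score", "identities", "aln_len")
}

align_pair_blastn <- function(query, subject, params) {
  exe <- Sys.which("blastn")
  if (!nzchar(exe)) stop("blastn binary not found on PATH")
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  writeLines(c(">query", query), qf)
  writeLines(c(">subject", subject), sf)
  out <- system2(exe, c(
    "-query", qf, "-subject", sf, "-task", "blastn",
    "-word_size", params$word_size, "-reward", params$reward,
    "-penalty", params$penalty, "-gapopen", params$gap_open,
    "-gapextend", params$gap_extend, "-dust", "no", "-evalue", "10",
    "-outfmt", shQuote(paste("6 qstart qend sstart send nident length",
                             "score sstrand"))
  ), stdout = TRUE)
  if (length(out) == 0) {
    return(tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  s_strand = character(), score = integer(),
                  identities = integer(), aln_len = integer()))
  }
  f <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE)
  names(f) <- c("qstart", "qend", "sstart", "send", "nident", "length",
                "score", "sstrand")
  minus <- f$sstrand == "minus"
  s_lo <- ifelse(minus, f$send, f$sstart)
  s_hi <- ifelse(minus, f$sstart, f$send)
  res <- tibble(
    q_start = f$qstart - 1L, q_end = f$qend,
    s_start = s_lo - 1L, s_end = s_hi,
    s_strand = ifelse(minus, "-", "+"),
    score = as.integer(f$score), identities = as.integer(f$nident),
    aln_len = as.integer(f$length)
  )
  res <- dplyr::filter(res, .data$score >= params$min_score)
  dplyr::arrange(res, .data$q_start, .data$s_start, .data$s_strand)
}

#' Merge overlapping HSPs along one axis
#'
#' Projects HSPs onto the query or subject axis and resolves overlaps so no
#' base is counted twice in a similarity numerator: HSPs are taken in
#' decreasing score order (ties: smaller start, then input order) and kept
#' intact; lower-scoring HSPs overlapping an already-kept span are trimmed,
#' with their identity count reduced proportionally to the trimmed length
#' (rounded down).
#'
#' @param hsps HSP tibble from [align_pair()].
#' @param axis `"query"` or `"subject"`.
#' @param seq_length Length of the sequence on the chosen axis.
#' @return List with `aligned_length`, `identities`, and the kept
#'   `intervals` tibble (`start`, `end`, columns 0-based half-open).
#' @export
merge_hsps <- function(hsps, axis = c("query", "subject"), seq_length) {
  axis <- match.arg(axis)
  if (nrow(hsps) == 0) {
    return(list(aligned_length = 0L, identities = 0L,
                intervals = tibble(start = integer(), end = integer())))
  }
  if (axis == "query") {
    start <- hsps$q_start; end <- hsps$q_end
  } else {
    start <- hsps$s_start; end <- hsps$s_end
  }
  if (any(start < 0) || any(end > seq_length)) {
    stop("HSP coordinates exceed sequence length")
  }
  ord <- order(-hsps$score, start, seq_along(start))
  covered <- logical(seq_length)
  total_ident <- 0
  kept <- list()
  for (i in ord) {
    span <- seq.int(start[i] + 1L, end[i])
    free <- !covered[span]
    n_free <- sum(free)
    if (n_free == 0) next
    len <- end[i] - start[i]
    ident_kept <- if (n_free == len) {
      hsps$identities[i]
    } else {
      floor(hsps$identities[i] * n_free / len)
    }
    total_ident <- total_ident + min(ident_kept, n_free)
    covered[span] <- TRUE
    kept[[length(kept) + 1L]] <- c(start[i], end[i])
  }
  aligned <- sum(covered)
  ivs <- if (length(kept) > 0) {
    m <- do.call(rbind, kept)
    tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  } else {
    tibble(start = integer(), end = integer())
  }
  list(aligned_length = as.integer(aligned),
       identities = as.integer(min(total_ident, aligned)),
       intervals = ivs)
}

# Reciprocal similarity between two sequences; shared by the pair and
# matrix entry points. Alignments run in both directions and identities are
# merged on each genome's own axis.
pair_similarity_seqs <- function(seq_a, seq_b, params, backend) {
  len_a <- nchar(seq_a); len_b <- nchar(seq_b)
  h_ab <- align_pair(seq_a, seq_b, params, backend)
  h_ba <- align_pair(seq_b, seq_a, params, backend)
  m_a <- merge_hsps(h_ab, "query", len_a)
  m_b <- merge_hsps(h_ba, "query", len_b)
  list(
    sim_percent = 100 * (m_a$identities + m_b$identities) / (len_a + len_b),
    aligned_frac_a = m_a$aligned_length / len_a,
    aligned_frac_b = m_b$aligned_length / len_b,
    id_ab = m_a$identities, id_ba = m_b$identities
  )
}

#' Reciprocal intergenomic nucleotide similarity of one genome pair
#'
#' Aligns the pair in both directions, merges HSPs on each genome's own
#' axis, and reports `sim_percent = 100 * (id_ab + id_ba) / (len_a + len_b)`
#' together with aligned-fraction diagnostics. The value is symmetric in its
#' arguments and equals 100 for identical genomes.
#'
#' @param genomes Genome tibble.
#' @param genome_a,genome_b Genome identifiers present in `genomes`.
#' @param params [align_params()].
#' @param backend Alignment backend, see [align_pair()].
#' @return One-row tibble: `genome_a`, `genome_b`, `sim_percent`,
#'   `aligned_frac_a`, `aligned_frac_b`, `id_ab`, `id_ba`.
#' @export
intergenomic_similarity <- function(genomes, genome_a, genome_b,
                                    params = align_params(),
                                    backend = c("internal", "blastn")) {
  backend <- match.arg(backend)
  seq_a <- genomes$sequence[match(genome_a, genomes$genome_id)]
  seq_b <- genomes$sequence[match(genome_b, genomes$genome_id)]
  if (is.na(seq_a)) stop("unknown genome: ", genome_a)
  if (is.na(seq_b)) stop("unknown genome: ", genome_b)
  r <- pair_similarity_seqs(seq_a, seq_b, params, backend)
  tibble(genome_a = genome_a, genome_b = genome_b,
         sim_percent = r$sim_percent,
         aligned_frac_a = r$aligned_frac_a, aligned_frac_b = r$aligned_frac_b,
         id_ab = r$id_ab, id_ba = r$id_ba)
}

#' All-versus-all intergenomic similarity matrix
#'
#' Computes the upper triangle of reciprocal similarities and mirrors it;
#' the diagonal is 100 by definition.
#'
#' @inheritParams intergenomic_similarity
#' @param verbose Print one line per pair.
#' @return Object of class `phage_similarity`: list with `matrix` (dense
#'   symmetric, genome_id dimnames) and `pairs` (long tibble as returned by
#'   [intergenomic_similarity()] for each unordered pair).
#' @export
similarity_matrix <- function(genomes, params = align_params(),
                              backend = c("internal", "blastn"),
                              verbose = FALSE) {
  backend <- match.arg(backend)
  n <- nrow(genomes)
  if (n < 2) stop("need at least 2 genomes")
  ids <- genomes$genome_id
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- intergenomic_similarity(genomes, ids[i], ids[j], params, backend)
      m[i, j] <- r$sim_percent
      m[j, i] <- r$sim_percent
      pairs[[length(pairs) + 1L]] <- r
      if (verbose) {
        message(sprintf("%s vs %s: %.1f", ids[i], ids[j], r$sim_percent))
      }
    }
  }
  structure(list(matrix = m, pairs = dplyr::bind_rows(pairs)),
            class = "phage_similarity")
}

#' @export
print.phage_similarity <- function(x, ...) {
  cat("Intergenomic nucleotide similarity over", nrow(x$matrix),
      "genomes\n")
  rng <- range(x$pairs$sim_percent)
  cat(sprintf("off-diagonal range: %.1f .. %.1f %%\n", rng[1], rng[2]))
  invisible(x)
}

#' Write a similarity matrix as TSV
#'
#' @param sim `phage_similarity` object or a plain matrix.
#' @param path Output file.
#' @param digits Decimal places (default 1, matrix report convention).
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path, digits = 1) {
  m <- if (inherits(sim, "phage_similarity")) sim$matrix else sim
  df <- data.frame(genome_id = rownames(m), round(m, digits),
                   check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
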