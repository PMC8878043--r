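#' Read phage genomes from FASTA or GenBank flat files
#'
#' Parses one or more sequence files into a tidy genome table. FASTA input
#' yields genomes without CDS annotations; GenBank flat files additionally
#' yield one CDS record per `CDS` feature that carries a `/translation`
#' qualifier. Sequences are uppercased, `U` is normalised to `T`, and IUPAC
#' ambiguity codes other than `N` are mapped to `N` with a warning.
#'
#' @param paths Character vector of file paths.
#' @param format `"fasta"` or `"genbank"`.
#' @return A tibble with one row per genome: `genome_id`, `name`, `sequence`,
#'   `length_bp`, `gc_percent`, and a list-column `cds` of CDS tibbles
#'   (`genome_id`, `cds_index`, `start`, `end`, `strand`, `protein_id`,
#'   `aa_sequence`; coordinates 0-based half-open).
#' @export
read_genomes <- function(paths, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file not found: ", paste(missing, collapse = ", "))
  }
  recs <- purrr::map(paths, function(p) {
    if (format == "fasta") read_fasta_genomes(p) else read_genbank_genomes(p)
  })
  genomes <- dplyr::bind_rows(recs)
  if (nrow(genomes) == 0) stop("no records in input")
  dup <- genomes$genome_id[duplicated(genomes$genome_id)]
  if (length(dup) > 0) {
    stop("duplicate genome identifier: ", paste(unique(dup), collapse = ", "))
  }
  genomes
}

normalise_sequence <- function(seq, id) {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nchar(bad) > 0) {
    stop("non-nucleotide characters in record '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  n_amb <- nchar(seq) - nchar(gsub("[RYSWKMBDHV]", "", seq))
  if (n_amb > 0) {
    warning("record '", id, "': ", n_amb,
            " ambiguity code(s) other than N mapped to N")
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  }
  seq
}

gc_percent_of <- function(seq) {
  counts <- table(factor(strsplit(seq, "")[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) return(NA_real_)
  100 * sum(counts[c("G", "C")]) / denom
}

genome_row <- function(genome_id, name, seq, cds) {
  tibble(
    genome_id = genome_id, name = name, sequence = seq,
    length_bp = nchar(seq), gc_percent = gc_percent_of(seq),
    cds = list(cds)
  )
}

empty_cds_table <- function() {
  tibble(
    genome_id = character(), cds_index = integer(),
    start = integer(), end = integer(), strand = character(),
    protein_id = character(), aa_sequence = character()
  )
}

read_fasta_genomes <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  purrr::map2_dfr(as.character(set), seq_along(set), function(seq, i) {
    id <- ids[i]
    genome_row(id, names(set)[i], normalise_sequence(seq, id),
               empty_cds_table())
  })
}

# Minimal GenBank flat-file parser: LOCUS/DEFINITION headers, CDS features
# with /translation qualifiers, ORIGIN sequence block. Joined/complement
# locations keep the outer span; exact exon structure is not needed
# downstream because proteins come from the /translation qualifier.
read_genbank_genomes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("no records in ", path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("no records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2_dfr(starts, ends, function(s, e) {
    parse_genbank_record(lines[s:e])
  })
}

parse_genbank_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  genome_id <- locus[2]
  acc_line <- grep("^VERSION", lines, value = TRUE)
  if (length(acc_line) > 0) {
    v <- strsplit(trimws(acc_line[1]), "\\s+")[[1]]
    if (length(v) >= 2) genome_id <- v[2]
  }
  def_i <- grep("^DEFINITION", lines)
  name <- if (length(def_i) > 0) {
    sub("^DEFINITION\\s+", "", lines[def_i[1]])
  } else genome_id

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("record '", genome_id, "' has no ORIGIN block")
  seq_lines <- lines[(ori[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))
  seq <- normalise_sequence(seq, genome_id)

  feat_i <- grep("^FEATURES", lines)
  cds <- empty_cds_table()
  if (length(feat_i) > 0) {
    feat_lines <- lines[(feat_i[1] + 1):(ori[1] - 1)]
    cds <- parse_genbank_cds(feat_lines, genome_id, nchar(seq))
  }
  genome_row(genome_id, name, seq, cds)
}

parse_genbank_cds <- function(feat_lines, genome_id, glen) {
  key_i <- grep("^ {5}\\S", feat_lines)
  if (length(key_i) == 0) return(empty_cds_table())
  key_end <- c(key_i[-1] - 1L, length(feat_lines))
  out <- list()
  idx <- 0L
  for (k in seq_along(key_i)) {
    block <- feat_lines[key_i[k]:key_end[k]]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (key != "CDS") next
    txt <- paste(trimws(block), collapse = "\n")
    qual_start <- regexpr("\n\\s*/", txt)
    loc_txt <- if (qual_start > 0) substr(txt, 1, qual_start) else txt
    loc_txt <- gsub("\\s", "", sub("^CDS", "", loc_txt))
    strand <- if (grepl("complement", loc_txt)) "-" else "+"
    nums <- as.integer(unlist(regmatches(loc_txt, gregexpr("[0-9]+", loc_txt))))
    if (length(nums) < 2) next
    start1 <- min(nums); end1 <- max(nums)
    translation <- extract_qualifier(txt, "translation")
    if (is.null(translation)) next
    idx <- idx + 1L
    pid <- extract_qualifier(txt, "protein_id") %||%
      paste0(genome_id, "_CDS_", sprintf("%04d", idx))
    aa <- gsub("[\\s\n]", "", translation, perl = TRUE)
    out[[length(out) + 1L]] <- tibble(
      genome_id = genome_id, cds_index = idx,
      start = start1 - 1L, end = end1,
      strand = strand, protein_id = pid, aa_sequence = aa
    )
  }
  if (length(out) == 0) return(empty_cds_table())
  res <- dplyr::bind_rows(out)
  stopifnot(all(res$start >= 0), all(res$end <= glen))
  res
}

extract_qualifier <- function(txt, name) {
  pat <- paste0("/", name, "=\"")
  pos <- regexpr(pat, txt, fixed = TRUE)
  if (pos < 0) return(NULL)
  rest <- substr(txt, pos + attr(pos, "match.length"), nchar(txt))
  endq <- regexpr("\"", rest, fixed = TRUE)
  if (endq < 0) return(NULL)
  gsub("\n\\s*", "", substr(rest, 1, endq - 1))
}

#' Flatten the CDS list-column of a genome table
#'
#' @param genomes Genome tibble from [read_genomes()] or [call_orfs()].
#' @return One tibble of all CDS records across genomes.
#' @export
cds_table <- function(genomes) {
  cds <- dplyr::bind_rows(genomes$cds)
  if (nrow(cds) == 0) return(empty_cds_table())
  dup <- cds$protein_id[duplicated(cds$protein_id)]
  if (length(dup) > 0) {
    stop("duplicate protein_id across collection: ",
         paste(unique(dup), collapse = ", "))
  }
  cds
}

GENETIC_CODE_11 <- NULL

translate_table11 <- function(dna) {
  aa <- Biostrings::translate(
    Biostrings::DNAStringSet(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"
  )
  as.character(aa)
}

#' Call open reading frames on unannotated genomes
#'
#' Deterministic six-frame ORF scan used for synthetic genomes: an ORF runs
#' from a start codon (ATG/GTG/TTG) to the next in-frame stop (TAA/TAG/TGA),
#' translated with genetic code 11 and the initial residue written as M.
#' Within a frame, candidate ORFs sharing a stop keep only the longest (the
#' most upstream start). ORFs shorter than `min_len_nt` (stop included) are
#' dropped.
#'
#' Candidate ORFs overlapping a longer ORF by more than `max_overlap` of the
#' shorter one's length are discarded (greedy, longest first), the usual
#' heuristic for suppressing spurious nested antisense calls; set
#' `max_overlap = 1` to keep every candidate.
#'
#' @param genomes Genome tibble.
#' @param min_len_nt Minimum ORF length in nucleotides, stop codon included.
#' @param overwrite Replace existing CDS annotations? Default `FALSE`; an
#'   error is raised if annotations exist and `overwrite` is not set.
#' @param max_overlap Maximum tolerated overlap with a longer kept ORF, as
#'   a fraction of the shorter ORF (default 0.5).
#' @return The genome tibble with the `cds` list-column populated.
#' @export
call_orfs <- function(genomes, min_len_nt = 120, overwrite = FALSE,
                      max_overlap = 0.5) {
  has_cds <- purrr::map_int(genomes$cds, nrow) > 0
  if (any(has_cds) && !overwrite) {
    stop("genomes already annotated: ",
         paste(genomes$genome_id[has_cds], collapse = ", "),
         " (use overwrite = TRUE)")
  }
  genomes$cds <- purrr::map2(
    genomes$sequence, genomes$genome_id,
    function(seq, id) {
      cds <- call_orfs_one(seq, id, min_len_nt)
      filter_orf_overlaps(cds, nchar(seq), max_overlap)
    }
  )
  genomes$cds <- purrr::map(genomes$cds, function(cds) {
    if (nrow(cds) == 0) return(cds)
    cds <- dplyr::arrange(cds, .data$start, .data$strand)
    cds$cds_index <- seq_len(nrow(cds))
    cds$protein_id <- paste0(cds$genome_id, "_", sprintf("%04d", cds$cds_index))
    cds
  })
  genomes
}

call_orfs_one <- function(seq, genome_id, min_len_nt) {
  glen <- nchar(seq)
  if (glen < min_len_nt) return(empty_cds_table())
  starts_c <- c("ATG", "GTG", "TTG")
  stops_c <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    codons_at <- function(frame) {
      n <- (nchar(s) - frame) %/% 3
      if (n <= 0) return(character(0))
      substring(s, frame + 1 + 3 * (0:(n - 1)), frame + 3 + 3 * (0:(n - 1)))
    }
    for (frame in 0:2) {
      cods <- codons_at(frame)
      if (length(cods) == 0) next
      is_stop <- cods %in% stops_c
      is_start <- cods %in% starts_c
      seg_start <- 1L
      stop_idx <- which(is_stop)
      for (si in stop_idx) {
        cand <- which(is_start[seg_start:si]) + seg_start - 1L
        seg_start <- si + 1L
        if (length(cand) == 0) next
        first <- cand[1] # most upstream start sharing this stop
        len_nt <- (si - first + 1L) * 3L
        if (len_nt < min_len_nt) next
        # coordinates on the scanned strand, 0-based half-open, stop included
        s0 <- frame + (first - 1L) * 3L
        e0 <- frame + si * 3L
        if (strand == "+") {
          start0 <- s0; end0 <- e0
        } else {
          start0 <- glen - e0; end0 <- glen - s0
        }
        orf_nt <- substr(s, s0 + 1, e0 - 3) # exclude the stop codon
        aa <- translate_table11(orf_nt)
        substr(aa, 1, 1) <- "M"
        out[[length(out) + 1L]] <- tibble(
          genome_id = genome_id, cds_index = NA_integer_,
          start = start0, end = end0, strand = strand,
          protein_id = NA_character_, aa_sequence = aa
        )
      }
    }
  }
  if (length(out) == 0) return(empty_cds_table())
  dplyr::bind_rows(out)
}

# Greedy overlap filter, longest ORF first. Tie-break keys (length, then
# distance to the nearer genome end, then translated sequence) are invariant
# under reverse complement, preserving strand symmetry of the caller.
filter_orf_overlaps <- function(cds, glen, max_overlap) {
  if (max_overlap >= 1 || nrow(cds) <= 1) return(cds)
  len <- cds$end - cds$start
  mirror_key <- pmin(cds$start, glen - cds$end)
  ord <- order(-len, mirror_key, cds$aa_sequence)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      ov <- min(cds$end[i], cds$end[j]) - max(cds$start[i], cds$start[j])
      if (ov > max_overlap * min(len[i], len[j])) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  cds[sort(kept), ]
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Write genome sequences to FASTA
#'
#' @param genomes Genome tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(genomes$sequence)
  names(set) <- genomes$genome_id
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Write all translated CDSs to a protein FASTA
#'
#' @param genomes Genome tibble with CDS annotations.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genomes, path) {
  cds <- cds_table(genomes)
  set <- Biostrings::AAStringSet(cds$aa_sequence)
  names(set) <- cds$protein_id
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Genome manifest table
#'
#' @param genomes Genome tibble.
#' @return Tibble with `genome_id`, `length_bp`, `gc_percent`, `n_cds`.
#' @export
genome_manifest <- function(genomes) {
  tibble(
    genome_id = genomes$genome_id,
    length_bp = genomes$length_bp,
    gc_percent = round(genomes$gc_percent, 2),
    n_cds = purrr::map_int(genomes$cds, nrow)
  )
}
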