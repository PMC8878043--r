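test_that("FASTA genomes parse with length, GC and empty CDS", {
  set.seed(101)
  seq <- rand_dna(1000)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">synA some description", seq), fa)
  g <- read_genomes(fa, "fasta")
  expect_equal(nrow(g), 1)
  expect_equal(g$genome_id, "synA")
  expect_equal(g$length_bp, 1000)
  expect_equal(g$sequence, seq)
  expect_equal(nrow(g$cds[[1]]), 0)
  counts <- table(strsplit(seq, "")[[1]])
  expect_equal(g$gc_percent,
               100 * sum(counts[c("G", "C")]) / sum(counts))
})

test_that("FASTA round-trip reproduces sequences exactly", {
  set.seed(102)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", rand_dna(500), ">g2", rand_dna(750)), fa)
  g <- read_genomes(fa, "fasta")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(g, out)
  g2 <- read_genomes(out, "fasta")
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$genome_id, g$genome_id)
})

test_that("input normalisation: case, U, ambiguity codes, bad characters", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acguACGU"), fa)
  expect_equal(read_genomes(fa, "fasta")$sequence, "ACGTACGT")
  writeLines(c(">a", "ACGTRYACGT"), fa)
  expect_warning(g <- read_genomes(fa, "fasta"), "ambiguity")
  expect_equal(g$sequence, "ACGTNNACGT")
  # N excluded from the GC denominator
  expect_equal(g$gc_percent, 100 * 4 / 8)
})

test_that("duplicate and empty inputs raise contract errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACGTACGT", ">dup", "TTTTACGT"), fa)
  expect_error(read_genomes(fa, "fasta"), "dup")
  writeLines(character(0), fa)
  expect_error(read_genomes(fa, "fasta"), "no records")
  expect_error(read_genomes("/nonexistent/x.fa", "fasta"), "not found")
})

make_genbank <- function(genome_id, seq, cds) {
  # cds: list of list(start1, end1, strand, protein_id, aa)
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     linear   PHG",
            genome_id, nchar(seq)),
    sprintf("DEFINITION  synthetic phage %s.", genome_id),
    sprintf("VERSION     %s", genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq))
  )
  for (c0 in cds) {
    loc <- sprintf("%d..%d", c0$start1, c0$end1)
    if (c0$strand == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(
      lines,
      sprintf("     CDS             %s", loc),
      sprintf("                     /protein_id=\"%s\"", c0$protein_id),
      sprintf("                     /translation=\"%s\"", c0$aa)
    )
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, nchar(seq), by = 60)) {
    lines <- c(lines, sprintf("%9d %s", i,
                              substr(seq, i, min(i + 59, nchar(seq)))))
  }
  c(lines, "//")
}

test_that("GenBank flat files yield CDS records matching the qualifiers", {
  set.seed(103)
  seq <- rand_dna(600)
  cds <- list(
    list(start1 = 10, end1 = 108, strand = "+", protein_id = "p1",
         aa = "MKLVITTTSSDDEEFFGGHHIKLVITTTSSDDE"),
    list(start1 = 150, end1 = 300, strand = "-", protein_id = "p2",
         aa = "MAAAACCDDEEFFGGHHIIKKLLMMNNPPQQRRSSTTVVWWYY"),
    list(start1 = 350, end1 = 580, strand = "+", protein_id = "p3",
         aa = "MVVVVLLLLKKKKRRRRDDDDEEEEFFFFYYYYWWWWSSSS")
  )
  gb <- withr::local_tempfile(fileext = ".gbk")
  writeLines(make_genbank("TEST01", seq, cds), gb)
  g <- read_genomes(gb, "genbank")
  expect_equal(g$genome_id, "TEST01")
  expect_equal(g$sequence, seq)
  tab <- g$cds[[1]]
  expect_equal(nrow(tab), 3)
  expect_equal(tab$aa_sequence, vapply(cds, `[[`, "", "aa"))
  expect_equal(tab$protein_id, c("p1", "p2", "p3"))
  expect_equal(tab$strand, c("+", "-", "+"))
  # 1-based inclusive in the file, 0-based half-open in the table
  expect_equal(tab$start, c(9L, 149L, 349L))
  expect_equal(tab$end, c(108L, 300L, 580L))
})

test_that("ORF calling finds a constructed ORF and matches a brute-force scan", {
  set.seed(104)
  sense <- setdiff(
    as.vector(outer(outer(DNA, DNA, paste0), DNA, paste0)),
    c("TAA", "TAG", "TGA")
  )
  orf <- paste0("ATG", paste(sample(sense, 60, replace = TRUE), collapse = ""),
                "TAA")
  # pad with stop-rich flanks so no other long ORF appears
  seq <- paste0("TTAATAATAA", orf, "TTAATAATAA")
  g <- genome_tbl(syn = seq)
  # max_overlap = 1 keeps every candidate, matching the exhaustive oracle
  g <- call_orfs(g, min_len_nt = 120, max_overlap = 1)
  tab <- g$cds[[1]]
  fwd <- tab[tab$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(nchar(fwd$aa_sequence), 61)
  expect_equal(fwd$end - fwd$start, 186)

  # brute-force six-frame oracle: every (start codon, next in-frame stop)
  brute_orfs <- function(s, min_len) {
    found <- 0
    for (str in c("+", "-")) {
      sc <- if (str == "+") s else phagetax:::revcomp(s)
      for (f in 0:2) {
        n <- (nchar(sc) - f) %/% 3
        if (n <= 0) next
        cods <- substring(sc, f + 1 + 3 * (0:(n - 1)), f + 3 + 3 * (0:(n - 1)))
        seg <- 1
        for (si in which(cods %in% c("TAA", "TAG", "TGA"))) {
          cand <- which(cods[seg:si] %in% c("ATG", "GTG", "TTG")) + seg - 1
          seg <- si + 1
          if (length(cand) > 0 && (si - cand[1] + 1) * 3 >= min_len) {
            found <- found + 1
          }
        }
      }
    }
    found
  }
  expect_equal(nrow(tab), brute_orfs(seq, 120))
})

test_that("ORF calling is strand-symmetric and handles degenerate input", {
  set.seed(105)
  seq <- rand_dna(3000)
  g1 <- call_orfs(genome_tbl(a = seq), min_len_nt = 120)
  g2 <- call_orfs(genome_tbl(a = phagetax:::revcomp(seq)), min_len_nt = 120)
  aa1 <- sort(g1$cds[[1]]$aa_sequence)
  aa2 <- sort(g2$cds[[1]]$aa_sequence)
  expect_equal(aa1, aa2)
  t1 <- table(factor(g1$cds[[1]]$strand, levels = c("+", "-")))
  t2 <- table(factor(g2$cds[[1]]$strand, levels = c("+", "-")))
  expect_equal(as.integer(t1), rev(as.integer(t2)))
  # all-N genome: no start codons, no ORFs
  gN <- call_orfs(genome_tbl(n = strrep("N", 5000)))
  expect_equal(nrow(gN$cds[[1]]), 0)
  # genome shorter than min_len: empty, not an error
  gs <- call_orfs(genome_tbl(s = "ATGAAATAA"), min_len_nt = 120)
  expect_equal(nrow(gs$cds[[1]]), 0)
  # annotated genomes refuse silent overwrite
  expect_error(call_orfs(g1), "overwrite")
})

test_that("genome manifest and CDS table aggregate the collection", {
  pop <- small_population()
  man <- genome_manifest(pop$genomes)
  expect_equal(man$genome_id, pop$genomes$genome_id)
  expect_equal(man$n_cds, purrr::map_int(pop$genomes$cds, nrow))
  cds <- cds_table(pop$genomes)
  expect_equal(nrow(cds), sum(man$n_cds))
  expect_false(anyDuplicated(cds$protein_id) > 0)
})
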