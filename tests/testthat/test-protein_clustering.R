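test_that("identical proteins match with full identity and coverage", {
  set.seed(501)
  p <- rand_protein(200)
  r <- protein_pair_match(p, p)
  expect_true(r$match)
  expect_equal(r$identity, 1)
  expect_equal(r$coverage, 1)
  expect_error(protein_pair_match("", p), "empty")
})

test_that("half-length fragment sits exactly on the coverage boundary", {
  set.seed(502)
  p <- rand_protein(200)
  q <- substr(p, 1, 100)
  r <- protein_pair_match(p, q)
  expect_equal(r$identity, 1)
  expect_equal(r$coverage, 0.5)
  expect_true(r$match) # >= threshold passes
  # alignment span cross-checked against the DP oracle
  orc <- protein_oracle(p, q)
  expect_equal(orc$span_p, 100)
  expect_equal(orc$span_q, 100)
  # decision is symmetric
  r2 <- protein_pair_match(q, p)
  expect_equal(r2$match, r$match)
  expect_equal(r2$coverage, r$coverage)
})

test_that("unrelated random proteins almost never match", {
  matches <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    if (protein_pair_match(rand_protein(100), rand_protein(100))$match) {
      matches <- matches + 1
    }
  }
  expect_lte(matches, 5)
})

test_that("alignment kernel agrees with the DP oracle on score", {
  for (s in 1:25) {
    set.seed(700 + s)
    p <- rand_protein(sample(80:250, 1))
    q <- if (s %% 2 == 0) mutate_protein(p, stats::runif(1, 0.1, 0.6)) else
      rand_protein(sample(80:250, 1))
    mine <- phagetax:::protein_align_batch(p, q)
    orc <- protein_oracle(p, q)
    expect_equal(mine$score, orc$score)
  }
})

proteome_tbl <- function(aa, genome_id = NULL) {
  n <- length(aa)
  tibble::tibble(
    genome_id = genome_id %||% paste0("g", seq_len(n)),
    cds_index = seq_len(n), start = 0L, end = 3L * (nchar(aa) + 1L),
    strand = "+", protein_id = sprintf("p%03d", seq_len(n)),
    aa_sequence = aa
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical proteins form one group; unrelated form orphams", {
  set.seed(503)
  p <- rand_protein(150)
  g <- build_groups(proteome_tbl(c(p, p, p)))
  expect_equal(length(unique(g$group_id)), 1)
  set.seed(504)
  aa <- vapply(1:10, function(i) rand_protein(120), character(1))
  g2 <- build_groups(proteome_tbl(aa))
  expect_equal(length(unique(g2$group_id)), 10)
  expect_true(all(group_summary(g2)$orpham))
})

test_that("single-linkage transitivity chains A-B-C into one group", {
  set.seed(505)
  b <- rand_protein(200)
  a <- paste0(substr(b, 1, 120), rand_protein(80))
  c0 <- paste0(rand_protein(80), substr(b, 81, 200))
  # a~b and b~c pass (120/200 coverage); a and c share only b[81..120],
  # far below the coverage threshold
  expect_true(protein_pair_match(a, b)$match)
  expect_true(protein_pair_match(b, c0)$match)
  expect_false(protein_pair_match(a, c0)$match)
  g <- build_groups(proteome_tbl(c(a, b, c0)))
  expect_equal(length(unique(g$group_id)), 1)
})

test_that("grouping equals the brute-force all-pairs oracle on small sets", {
  set.seed(506)
  # 3 families of related proteins plus singles, mixed lengths
  fam <- function(base, k, d) {
    vapply(seq_len(k), function(i) mutate_protein(base, d), character(1))
  }
  aa <- c(
    fam(rand_protein(180), 4, 0.3),
    fam(rand_protein(240), 3, 0.25),
    fam(rand_protein(90), 3, 0.2),
    vapply(1:5, function(i) rand_protein(sample(60:300, 1)), character(1))
  )
  cds <- proteome_tbl(aa)
  g_fast <- build_groups(cds) # with the 4x length pre-filter
  # oracle: all pairs through the independent DP, no pre-filter
  n <- length(aa)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      orc <- protein_oracle(aa[i], aa[j])
      ident <- ifelse(orc$columns > 0, orc$identities / orc$columns, 0)
      cov <- min(orc$span_p / nchar(aa[i]), orc$span_q / nchar(aa[j]))
      adj[i, j] <- ident >= 0.35 && cov >= 0.5
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  oracle_comp <- igraph::components(gr)$membership
  mine_comp <- as.integer(factor(g_fast$group_id[match(cds$protein_id,
                                                       g_fast$protein_id)]))
  # identical partitions (labels may differ)
  expect_equal(
    mclust::adjustedRandIndex(mine_comp, oracle_comp), 1
  )
})

test_that("groups partition the proteome and ignore input order", {
  pop <- small_population(seed = 12)
  cds <- cds_table(pop$genomes)
  g <- build_groups(cds)
  expect_equal(nrow(g), nrow(cds))
  expect_setequal(g$protein_id, cds$protein_id)
  expect_equal(sum(group_summary(g)$n_members), nrow(cds))
  # permuted input gives the same partition
  set.seed(507)
  cds2 <- cds[sample(nrow(cds)), ]
  g2 <- build_groups(cds2)
  m1 <- g$group_id[match(cds$protein_id, g$protein_id)]
  m2 <- g2$group_id[match(cds$protein_id, g2$protein_id)]
  expect_equal(mclust::adjustedRandIndex(m1, m2), 1)
  # deterministic ids mean the tables are in fact identical
  expect_equal(dplyr::arrange(tibble::as_tibble(g), protein_id),
               dplyr::arrange(tibble::as_tibble(g2), protein_id))
})

test_that("shared content follows the pooled-proteome formula", {
  set.seed(508)
  p1 <- rand_protein(150); p2 <- rand_protein(150)
  # a: 4 proteins, 2 in shared groups; b: 6 proteins, 3 in shared groups
  aa_a <- c(p1, p2, rand_protein(140), rand_protein(130))
  aa_b <- c(p1, mutate_protein(p1, 0.1), p2,
            rand_protein(120), rand_protein(110), rand_protein(100))
  cds <- dplyr::bind_rows(
    proteome_tbl(aa_a, genome_id = rep("a", 4)),
    proteome_tbl(aa_b, genome_id = rep("b", 6))
  )
  cds$protein_id <- sprintf("p%03d", seq_len(nrow(cds)))
  g <- build_groups(cds)
  sc <- shared_content(cds, g)
  expect_equal(sc$matrix["a", "b"], 100 * (2 + 3) / (4 + 6))
  expect_equal(sc$matrix["a", "a"], 100)
  expect_identical(sc$matrix, t(sc$matrix))
  # identical and disjoint proteomes hit the bounds
  cds_same <- dplyr::bind_rows(
    proteome_tbl(c(p1, p2), genome_id = rep("x", 2)),
    proteome_tbl(c(p1, p2), genome_id = rep("y", 2))
  )
  cds_same$protein_id <- sprintf("q%03d", seq_len(nrow(cds_same)))
  gs <- build_groups(cds_same)
  expect_equal(shared_content(cds_same, gs)$matrix["x", "y"], 100)
  set.seed(509)
  cds_disj <- dplyr::bind_rows(
    proteome_tbl(c(rand_protein(100), rand_protein(110)),
                 genome_id = rep("x", 2)),
    proteome_tbl(c(rand_protein(120), rand_protein(130)),
                 genome_id = rep("y", 2))
  )
  cds_disj$protein_id <- sprintf("r%03d", seq_len(nrow(cds_disj)))
  gd <- build_groups(cds_disj)
  expect_equal(shared_content(cds_disj, gd)$matrix["x", "y"], 0)
})
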