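sim_mat <- function(ids, fill = 10) {
  n <- length(ids)
  m <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

test_that("sub-cluster assignment follows the thresholded components rule", {
  m <- sim_mat(c("a", "b", "c"))
  m["a", "b"] <- m["b", "a"] <- 96
  m["b", "c"] <- m["c", "b"] <- 96
  m["a", "c"] <- m["c", "a"] <- 97
  r <- assign_subclusters(m)
  expect_equal(length(unique(r$subcluster_id)), 1)
  expect_equal(length(unique(r$species_id)), 1)

  # single-linkage chain: a-b 70, b-c 70, a-c 40 -> one sub-cluster
  m2 <- sim_mat(c("a", "b", "c"))
  m2["a", "b"] <- m2["b", "a"] <- 70
  m2["b", "c"] <- m2["c", "b"] <- 70
  m2["a", "c"] <- m2["c", "a"] <- 40
  r2 <- assign_subclusters(m2)
  expect_equal(length(unique(r2$subcluster_id)), 1)
  # but three species at the 95% level
  expect_equal(length(unique(r2$species_id)), 3)

  # all below threshold: every genome its own sub-cluster
  r3 <- assign_subclusters(sim_mat(c("a", "b", "c"), fill = 40))
  expect_equal(length(unique(r3$subcluster_id)), 3)

  m_bad <- sim_mat(c("a", "b"))
  m_bad["a", "b"] <- 50
  expect_error(assign_subclusters(m_bad), "symmetric")
})

test_that("species refine sub-clusters and thresholds act monotonically", {
  set.seed(801)
  for (rep in 1:10) {
    n <- 8
    ids <- paste0("g", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0, 100)
    m <- m + t(m); diag(m) <- 100
    lo <- assign_subclusters(m, genus_threshold = 50)
    hi <- assign_subclusters(m, genus_threshold = 80)
    # raising the threshold never merges: hi partition refines lo partition
    for (sc in unique(hi$subcluster_id)) {
      members <- hi$genome_id[hi$subcluster_id == sc]
      expect_equal(
        length(unique(lo$subcluster_id[lo$genome_id %in% members])), 1
      )
    }
    # species nest within sub-clusters by construction
    r <- assign_subclusters(m)
    tab <- table(r$species_id, r$subcluster_id)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

shared_mat <- function(ids, fill = 5) {
  n <- length(ids)
  m <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

test_that("clusters form above the shared-content threshold", {
  ids <- c("a1", "a2", "b1", "b2")
  sub <- tibble::tibble(genome_id = ids, subcluster_id = c(1, 1, 2, 2),
                        species_id = c("1.1", "1.1", "2.1", "2.1"))
  m <- shared_mat(ids, fill = 40) # everything shares 40% -> one cluster
  m["a1", "a2"] <- m["a2", "a1"] <- 90
  m["b1", "b2"] <- m["b2", "b1"] <- 90
  tax <- assign_clusters(m, sub)
  expect_equal(length(unique(tax$assignments$cluster_id)), 1)

  m2 <- shared_mat(ids, fill = 10) # 10% between sub-clusters -> two clusters
  m2["a1", "a2"] <- m2["a2", "a1"] <- 90
  m2["b1", "b2"] <- m2["b2", "b1"] <- 90
  tax2 <- assign_clusters(m2, sub)
  a <- tax2$assignments
  expect_equal(length(unique(a$cluster_id)), 2)
  expect_equal(a$cluster_id[a$genome_id == "a1"],
               a$cluster_id[a$genome_id == "a2"])
  expect_error(assign_clusters(m2[1:3, 1:3], sub), "different genome sets")
})

test_that("sub-clusters stay atomic even when the cut would split them", {
  ids <- c("x1", "x2", "y1")
  # x1-x2 share little protein content but are one sub-cluster by
  # nucleotide similarity; the dendrogram cut alone would separate them
  sub <- tibble::tibble(genome_id = ids, subcluster_id = c(1, 1, 2),
                        species_id = c("1.1", "1.2", "2.1"))
  m <- shared_mat(ids, fill = 5)
  m["x1", "y1"] <- m["y1", "x1"] <- 50
  expect_warning(tax <- assign_clusters(m, sub), "atomic")
  a <- tax$assignments
  expect_equal(a$cluster_id[a$genome_id == "x1"],
               a$cluster_id[a$genome_id == "x2"])
})

test_that("labels combine cluster letter and sub-cluster number", {
  ids <- c("a1", "a2", "a3", "b1", "s1")
  sub <- tibble::tibble(
    genome_id = ids, subcluster_id = c(1, 1, 2, 3, 4),
    species_id = c("1.1", "1.2", "2.1", "3.1", "4.1")
  )
  m <- shared_mat(ids, fill = 2)
  for (p in list(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"))) {
    m[p[1], p[2]] <- m[p[2], p[1]] <- 60
  }
  tax <- assign_clusters(m, sub)
  a <- tax$assignments
  # largest cluster gets letter A; its larger sub-cluster number 1
  expect_equal(a$label[a$genome_id == "a1"], "A1")
  expect_equal(a$label[a$genome_id == "a2"], "A1")
  expect_equal(a$label[a$genome_id == "a3"], "A2")
  expect_true(all(a$singleton[a$genome_id %in% c("b1", "s1")]))
  expect_true(all(a$cluster_id[a$singleton] == "SINGLETON"))
  g <- glance(tax)
  expect_equal(g$n_singletons, 2)
  expect_equal(g$n_clusters, 1)
  expect_equal(tidy(tax), a)
})

test_that("pangenome partition classifies each in-cluster group once", {
  # cluster of 3 genomes; groups: universal, partial, private
  groups <- tibble::tibble(
    group_id = c("G1", "G1", "G1", "G2", "G2", "G3", "G4"),
    protein_id = paste0("p", 1:7),
    genome_id = c("a", "b", "c", "a", "b", "c", "a")
  )
  tax <- tibble::tibble(
    genome_id = c("a", "b", "c"), species_id = "1.1",
    subcluster_id = 1, cluster_id = "A", label = "A1", singleton = FALSE
  )
  s <- pangenome_partition(tax, groups)
  expect_equal(s$n_core, 1) # G1 in all three
  expect_equal(s$n_accessory, 1) # G2 in two
  expect_equal(s$n_unique, 2) # G3, G4 single-genome proteins
  expect_equal(s$n_core_exclusive, 1)
  # conservation: every in-cluster group counted exactly once
  expect_equal(s$n_core + s$n_accessory +
                 dplyr::n_distinct(groups$group_id[groups$group_id %in%
                                                     c("G3", "G4")]),
               dplyr::n_distinct(groups$group_id))
})

test_that("single-genome clusters report N/A core and accessory", {
  groups <- tibble::tibble(
    group_id = c("G1", "G2", "G2"),
    protein_id = c("p1", "p2", "p3"),
    genome_id = c("s", "s", "t")
  )
  tax <- tibble::tibble(
    genome_id = c("s", "t"), species_id = c("1.1", "2.1"),
    subcluster_id = c(1, 2), cluster_id = "SINGLETON",
    label = c("S1", "S2"), singleton = TRUE
  )
  s <- pangenome_partition(tax, groups)
  expect_true(all(is.na(s$n_core)))
  expect_true(all(is.na(s$n_accessory)))
  # G1 is unique to s; G2 is shared with t so not unique
  expect_equal(s$n_unique[s$cluster_id == "s"], 1)
})

test_that("partial genomes are excluded from the core requirement", {
  groups <- tibble::tibble(
    group_id = c("G1", "G1", "G2", "G2", "G2"),
    protein_id = paste0("p", 1:5),
    genome_id = c("a", "b", "a", "b", "c")
  )
  tax <- tibble::tibble(
    genome_id = c("a", "b", "c"), species_id = "1.1",
    subcluster_id = 1, cluster_id = "A", label = "A1", singleton = FALSE
  )
  s_all <- pangenome_partition(tax, groups)
  expect_equal(s_all$n_core, 1) # only G2 spans all three
  s_part <- pangenome_partition(tax, groups, partial_genomes = "c")
  expect_equal(s_part$n_core, 2) # G1 now core among the full genomes
})

test_that("planted population recovers its taxonomy exactly", {
  pop <- small_population(seed = 21)
  res <- classify_genomes(pop$genomes)
  a <- tidy(res$taxonomy)
  tr <- pop$truth[match(a$genome_id, pop$truth$genome_id), ]
  expect_equal(mclust::adjustedRandIndex(a$subcluster_id, tr$genus), 1)
  expect_equal(mclust::adjustedRandIndex(cluster_partition(a), tr$cluster), 1)
  # planted singleton flagged as such
  expect_true(all(a$singleton[grepl("^SNG", a$genome_id)]))
  # pangenome accounting covers every in-cluster group exactly once
  for (k in unique(a$cluster_id[!a$singleton])) {
    members <- a$genome_id[a$cluster_id == k & !a$singleton]
    gk <- res$groups[res$groups$genome_id %in% members, ]
    occ <- dplyr::distinct(tibble::as_tibble(gk), group_id, genome_id) %>%
      dplyr::count(group_id)
    srow <- res$pangenome[res$pangenome$cluster_id == k, ]
    expect_equal(srow$n_core + srow$n_accessory + sum(occ$n == 1),
                 dplyr::n_distinct(gk$group_id))
  }
})

test_that("taxonomy reports are deterministic", {
  pop <- small_population(seed = 22)
  res <- classify_genomes(pop$genomes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_taxonomy_report(res$taxonomy, res$pangenome, d1)
  write_taxonomy_report(res$taxonomy, res$pangenome, d2)
  for (f in c("taxonomy.tsv", "pangenome_summary.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  tax_tab <- readr::read_tsv(file.path(d1, "taxonomy.tsv"),
                             show_col_types = FALSE)
  expect_equal(nrow(tax_tab), nrow(pop$genomes))
  pan_tab <- readLines(file.path(d1, "pangenome_summary.tsv"))
  expect_true(any(grepl("N/A", pan_tab))) # singleton rows use N/A
})
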