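two_cluster_set <- function() {
  record_set(list(
    make_record(c("asp", "ser"), organism = "org one", index = 1),
    make_record(c("asp", "ser", "orn"), organism = "org one", index = 2)
  ))
}

test_that("binary matrices are built at cluster and organism granularity", {
  rs <- two_cluster_set()
  m <- build_binary_matrix(rs, granularity = "cluster")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), c("asp.ser", "orn.ser"))
  expect_equal(unname(m["org one-C1", ]), c(1L, 0L))
  expect_equal(unname(m["org one-C2", ]), c(1L, 1L))

  mo <- build_binary_matrix(rs, granularity = "organism")
  expect_equal(dim(mo), c(1L, 2L))
  expect_equal(unname(mo[1, ]), c(1L, 1L))

  # organism support equals the union of its cluster supports
  expect_setequal(colnames(mo)[mo[1, ] == 1L],
                  unique(colnames(m)[colSums(m) > 0]))

  expect_equal(dim(build_binary_matrix(record_set(list()))), c(0L, 0L))
})

test_that("prediction-less records give all-zero flagged rows", {
  rs <- record_set(list(
    make_record(c("asp", "ser"), organism = "a"),
    cluster_record("b", 1, "NRPS", list())
  ))
  m <- build_binary_matrix(rs)
  expect_equal(sum(m["b-C1", ]), 0L)
  expect_equal(attr(m, "empty_instances"), "b-C1")
})

test_that("identical POP sets give JI one, disjoint sets zero", {
  shared <- c("asp.nrp", "asp.ser", "orn.ser")
  expect_equal(jaccard_index(shared, shared), 1.0)
  expect_equal(jaccard_index(c("a.b"), c("c.d")), 0.0)
  expect_equal(jaccard_index(c("a.b", "b.c"), c("b.c", "c.d")), 1 / 3)
  both_empty <- jaccard_index(character(0), character(0))
  expect_equal(as.numeric(both_empty), 0)
  expect_true(isTRUE(attr(both_empty, "both_empty")))
})

test_that("JI satisfies its axioms over random seeded sets", {
  set.seed(21)
  vocab <- outer(letters[1:6], letters[1:6], canonical_pair)
  for (i in 1:40) {
    a <- sample(vocab, sample(0:10, 1))
    b <- sample(vocab, sample(1:10, 1))
    ji <- as.numeric(jaccard_index(a, b))
    expect_gte(ji, 0); expect_lte(ji, 1)
    expect_equal(ji, as.numeric(jaccard_index(b, a)))
    expect_equal(ji, oracle_jaccard(a, b))
    expect_equal(as.numeric(jaccard_index(a, a)), as.numeric(length(a) > 0))
    if (ji == 1) expect_setequal(a, b)
    if (length(a) && length(b) && ji == 0) {
      expect_length(intersect(a, b), 0L)
    }
  }
})

test_that("the JI matrix matches brute-force pairwise computation", {
  rs <- two_cluster_set()
  jm <- jaccard_matrix(build_binary_matrix(rs))
  expect_equal(unname(diag(jm)), c(1, 1))
  expect_equal(jm["org one-C1", "org one-C2"], 0.5)
  expect_equal(jm, t(jm))

  set.seed(33)
  m <- matrix(rbinom(3 * 6, 1, 0.5), nrow = 3,
              dimnames = list(paste0("r", 1:3), paste0("p", 1:6)))
  jm <- jaccard_matrix(m)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(jm[i, j],
                 oracle_jaccard(colnames(m)[m[i, ] == 1],
                                colnames(m)[m[j, ] == 1]))
  }

  one <- build_binary_matrix(record_set(list(make_record(c("a", "b")))))
  expect_equal(unname(jaccard_matrix(one)), matrix(1))
})

test_that("average-linkage clustering reproduces closed forms and an independent reference", {
  m <- matrix(c(1, 0, 0,
                1, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$hclust$height, 0)

  m <- matrix(c(1, 0, 0,
                0, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(hierarchical_cluster(m)$hclust$height, sqrt(2))

  set.seed(17)
  for (k in c(4, 8, 12)) {
    # jitter breaks distance ties, under which merge order (and hence
    # later average-linkage heights) is legitimately implementation-defined
    m <- matrix(rbinom(5 * k, 1, 0.4) + runif(5 * k, 0, 1e-3), nrow = 5,
                dimnames = list(paste0("r", 1:5), paste0("c", 1:k)))
    hc <- hierarchical_cluster(m)
    expect_equal(sort(hc$hclust$height),
                 sort(oracle_average_linkage_heights(m)),
                 tolerance = 1e-10)
    # heights are non-decreasing along the merge sequence
    expect_true(all(diff(hc$hclust$height) >= -1e-12))
    expect_setequal(hc$leaf_order, rownames(m))
  }
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), "at least 2")
})

test_that("dendrograms serialize to Newick readable by tree tools", {
  set.seed(2)
  m <- matrix(rbinom(4 * 6, 1, 0.5), nrow = 4,
              dimnames = list(paste0("inst", 1:4), paste0("p", 1:6)))
  path <- withr::local_tempfile(fileext = ".newick")
  write_dendrogram_newick(hierarchical_cluster(m), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("distribution tables report multiplicity-weighted percentages", {
  d <- pop_distribution(pecs_for(delftibactin()))
  expect_equal(d$percent[d$pair == "gly.thr"], 25)          # 2 of 8
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)

  du <- pop_distribution(pecs_for(delftibactin()), with_multiplicity = FALSE)
  expect_equal(du$percent[du$pair == "gly.thr"], 100 / 7, tolerance = 1e-9)

  single <- pop_distribution(pair_multiset("orn.ser", origin = "x"))
  expect_equal(single$pair, "orn.ser")
  expect_equal(single$percent, 100)

  expect_error(pop_distribution(list()), "empty")
})

test_that("PEC and POP distributions align over a shared vocabulary", {
  # perfect predictions: the two columns are identical
  rs <- record_set(lapply(1:3, function(i) {
    make_record(delftibactin()$backbone$tokens, organism = paste0("o", i),
                compound = "Delftibactin", identity = 100)
  }))
  tab <- pec_vs_pop_distribution(rs, default_compound_library())
  expect_equal(tab$percent_pec, tab$percent_pop, tolerance = 1e-12)
  expect_equal(sum(tab$percent_pec), 100, tolerance = 1e-9)

  # orn replaced by nrp: orn.ser present among PECs, absent among POPs
  toks <- delftibactin()$backbone$tokens
  toks[toks == "orn"] <- "nrp"
  rs <- record_set(list(make_record(toks, organism = "corrupted",
                                    compound = "Delftibactin", identity = 50)))
  tab <- pec_vs_pop_distribution(rs, default_compound_library())
  expect_gt(tab$percent_pec[tab$pair == "orn.ser"], 0)
  expect_equal(tab$percent_pop[tab$pair == "orn.ser"], 0)

  # unresolvable compounds are flagged and excluded
  rs <- record_set(list(
    make_record(c("ala", "val"), organism = "known",
                compound = "Delftibactin", identity = 10),
    make_record(c("ala", "val"), organism = "unknown compound org",
                compound = "Mysteriobactin", identity = 80)
  ))
  tab <- pec_vs_pop_distribution(rs, default_compound_library())
  expect_equal(attr(tab, "excluded"), "unknown compound org-C1")
})

test_that("branch distributions include the global Branch_0 view", {
  rs <- record_set(list(
    make_record(c("asp", "ser", "orn"), organism = "o1"),
    make_record(c("asp", "ser"), organism = "o2"),
    make_record(c("nrp", "nrp"), organism = "o3")
  ))
  ba <- c("o1-C1" = "Branch_1", "o2-C1" = "Branch_1", "o3-C1" = "Branch_2")
  out <- branch_distribution(rs, ba)
  expect_equal(names(out)[1], "Branch_0")
  expect_setequal(names(out), c("Branch_0", "Branch_1", "Branch_2"))

  # a branch resolving only nrp.nrp sits at 100%
  b2 <- out[["Branch_2"]]
  expect_equal(b2$pair, "nrp.nrp")
  expect_equal(b2$percent, 100)

  # all records in one branch: branch table equals the global table
  ba_all <- setNames(rep("Branch_1", 3),
                     vapply(rs$records, cluster_key, character(1)))
  out <- branch_distribution(rs, ba_all)
  expect_equal(out[["Branch_1"]], out[["Branch_0"]])

  expect_error(branch_distribution(rs, c("ghost-C1" = "Branch_9")), "unknown")
})
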