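delft_pecs <- function() unique_pairs(pecs_for(delftibactin()))

test_that("the documented six-POP example scores 0.5/0.5/0/1/1/1", {
  pecs <- delft_pecs()
  pops <- c("nrp.pk", "ohmal.nrp", "ohmal.ser", "orn.ser", "orn.thr", "asp.thr")
  pts <- vapply(pops, function(p) match_pop(p, pecs)$points, numeric(1))
  expect_equal(unname(pts), c(0.5, 0.5, 0, 1, 1, 1))

  kinds <- vapply(pops, function(p) match_pop(p, pecs)$match_kind, character(1))
  expect_equal(unname(kinds),
               c("partial_nrp", "partial_nrp", "none", "exact", "exact", "exact"))
})

test_that("nrp.nrp and token-disjoint pairs are incorrect matches", {
  pecs <- delft_pecs()
  expect_equal(match_pop("nrp.nrp", pecs)$points, 0)
  expect_equal(match_pop("leu.val", pecs)$points, 0)
  # tokens present in the compound but never adjacent
  expect_equal(match_pop("gly.ser", pecs)$points, 0)
})

test_that("scoring a full cluster aggregates points and fraction", {
  r <- make_record(c("pk", "nrp", "ohmal", "ser", "orn", "thr", "asp"),
                   organism = "Variovorax paradoxus", index = 3,
                   compound = "Delftibactin", identity = 91)
  s <- score_cluster(r, delftibactin())
  expect_equal(s$total_points, 4.0)
  expect_equal(s$n_pops, 6L)
  expect_equal(s$fraction_correct, 2 / 3)
  expect_equal(s$identity_percent, 91)
  expect_false(s$no_pops)
})

test_that("every compound scores perfectly against itself", {
  lib <- default_compound_library()
  set.seed(5)
  vocab <- c("ala", "val", "ser", "gly", "thr", "orn", "asp", "pk", "ohmal")
  backbones <- c(list(delftibactin()$backbone$tokens),
                 replicate(10, sample(vocab, sample(2:9, 1), replace = TRUE),
                           simplify = FALSE))
  for (toks in backbones) {
    pecs <- unique_pairs(fragment_backbone(backbone(toks, normalize = FALSE)))
    res <- score_pairs(pecs, pecs)
    expect_true(all(res$points == 1))
    expect_true(all(res$match_kind == "exact"))
  }
})

test_that("match_pop agrees with a brute-force oracle on small vocabularies", {
  pk_table <- default_pk_class()
  set.seed(9)
  vocabs <- list(c("a", "b", "c", "pk", "ohmal"),
                 c("ser", "orn", "thr", "gly", "mal"),
                 c("x1", "x2", "x3", "x4", "x5"))
  for (vocab in vocabs) {
    for (rep in 1:8) {
      bb <- sample(vocab, sample(2:5, 1), replace = TRUE)
      pecs <- unique_pairs(fragment_backbone(backbone(bb, normalize = FALSE)))
      cand <- unique(c(vocab, "nrp"))
      for (t1 in cand) for (t2 in cand) {
        got <- match_pop(canonical_pair(t1, t2), pecs, pk_table)
        want <- oracle_match(t1, t2, bb, pk_table)
        expect_equal(got$match_kind, want,
                     info = sprintf("pair %s.%s vs backbone %s", t1, t2,
                                    paste(bb, collapse = "+")))
      }
    }
  }
})

test_that("only symmetric polyketide-class mapping reproduces the documented points", {
  # candidate rules: no mapping, map POP side only, map PEC side only,
  # symmetric mapping. The documented values (ohmal.nrp -> 0.5,
  # ohmal.ser -> 0, nrp.pk -> 0.5) pin down the symmetric rule.
  pecs <- delft_pecs()
  members <- default_pk_class()
  map_side <- function(keys, on) {
    if (!on) return(keys)
    vapply(strsplit(keys, ".", fixed = TRUE), function(t) {
      canonical_pair(ifelse(t %in% members, "pk", t)[1],
                     ifelse(t %in% members, "pk", t)[2])
    }, character(1))
  }
  naive_points <- function(pop, map_pop, map_pec) {
    p <- map_side(pop, map_pop)
    q <- map_side(pecs, map_pec)
    toks <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (p %in% q) 1
    else if (sum(toks == "nrp") == 1 &&
             toks[toks != "nrp"] %in% unlist(strsplit(q, ".", fixed = TRUE))) 0.5
    else 0
  }
  pops <- c("nrp.pk", "ohmal.nrp", "ohmal.ser", "orn.ser", "orn.thr", "asp.thr")
  want <- c(0.5, 0.5, 0, 1, 1, 1)
  rules <- list(none = c(FALSE, FALSE), pop_only = c(TRUE, FALSE),
                pec_only = c(FALSE, TRUE), symmetric = c(TRUE, TRUE))
  ok <- vapply(rules, function(r) {
    all(vapply(pops, naive_points, numeric(1), map_pop = r[1],
               map_pec = r[2]) == want)
  }, logical(1))
  expect_true(ok[["symmetric"]])
  expect_false(any(ok[c("none", "pec_only")]))
  # with a library backbone drawn with the generic class token, POP-side
  # mapping coincides with the symmetric rule; symmetric additionally
  # covers libraries transcribed with specific acyl tokens (e.g. ohmal)
  expect_true(ok[["pop_only"]])
  ohmal_pecs <- unique_pairs(fragment_backbone(backbone(c("ohmal", "asp"),
                                                        normalize = FALSE)))
  expect_equal(match_pop("asp.pk", ohmal_pecs)$points, 1)
  # and the implementation matches the symmetric rule
  impl <- vapply(pops, function(p) match_pop(p, pecs)$points, numeric(1))
  expect_equal(unname(impl), want)
})

test_that("points stay within bounds for arbitrary POP sets", {
  set.seed(13)
  vocab <- c("ala", "ser", "gly", "thr", "orn", "pk", "ohmal", "nrp")
  pecs <- delft_pecs()
  for (i in 1:30) {
    pops <- unique(canonical_pair(sample(vocab, 6, replace = TRUE),
                                  sample(vocab, 6, replace = TRUE)))
    res <- score_pairs(pops, pecs)
    expect_true(all(res$points %in% c(0, 0.5, 1)))
    expect_lte(sum(res$points), nrow(res))
  }
})

test_that("identity-correctness pairing flags degenerate correlations", {
  r1 <- make_record(c("orn", "ser"), organism = "o1",
                    compound = "Delftibactin", identity = 100)
  s1 <- score_cluster(r1, delftibactin())
  tab <- identity_vs_correctness(list(s1))
  expect_equal(nrow(tab), 1L)
  expect_false(attr(tab, "correlation_defined"))
  expect_true(is.na(attr(tab, "spearman_rho")))

  # zero variance in identity: correlation undefined
  r2 <- make_record(c("asp", "thr"), organism = "o2",
                    compound = "Delftibactin", identity = 100)
  tab <- identity_vs_correctness(list(s1, score_cluster(r2, delftibactin())))
  expect_false(attr(tab, "correlation_defined"))

  # a record without identity annotation is flagged and excluded
  r3 <- make_record(c("gly", "thr"), organism = "o3")
  tab <- identity_vs_correctness(list(s1, score_cluster(r3, delftibactin())))
  expect_true(tab$excluded[tab$cluster_key == "o3-C1"])
})
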