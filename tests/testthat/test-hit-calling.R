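test_that("consensus requires pan-activity and the IC50 gate in every sample", {
  m <- toy_matrix()
  hits <- consensus_hits(m, c("CLL01", "CLL02"))
  expect_equal(hits$compound_id, c("A", "C"))   # sorted by GM IC50
  expect_equal(hits$ic50_gm[1], sqrt(0.5 * 1))
  # active in one CLL sample but inconclusive in the other: excluded
  expect_false("B" %in% hits$compound_id)
  # one IC50 over the gate excludes the compound even if all-active
  m2 <- m
  m2$ic50[m2$compound_id == "C" & m2$sample_id == "CLL02"] <- 35
  expect_false("C" %in% consensus_hits(m2, c("CLL01", "CLL02"))$compound_id)
  expect_error(consensus_hits(m, c("CLL01", "NOPE")), "not in activity")
})

test_that("adding a CLL sample can only shrink the consensus list", {
  ms <- mini_screen()
  cll <- sprintf("CLL%02d", 1:6)
  hits_all <- consensus_hits(ms$matrix, cll)$compound_id
  for (k in 2:5) {
    subset_hits <- consensus_hits(ms$matrix, cll[1:k])$compound_id
    expect_true(all(hits_all %in% subset_hits))
  }
})

test_that("fold shift reproduces the worked potency ratios", {
  expect_equal(fold_shift(0.1, 3.2), 32)
  expect_equal(fold_shift(2.5, 2.5), 1)
  expect_equal(round(fold_shift(4.5, 14.4)), 3)
  expect_error(fold_shift(0, 1), "positive")
})

test_that("efficacy difference averages the two top concentrations", {
  d <- tidyr::expand_grid(
    compound_id = "X",
    sample_id = c("CLL01", "CLL02", "NRM01", "NRM02"),
    conc_uM = c(57, 11.4, 2.28)
  )
  resp <- c("CLL01" = -90, "CLL02" = -95, "NRM01" = -20, "NRM02" = -25)
  d$value_norm <- resp[d$sample_id]
  expect_equal(
    efficacy_difference(d, "X", c("CLL01", "CLL02"), c("NRM01", "NRM02")),
    70
  )
  # identical groups: no differential efficacy
  d0 <- d
  d0$value_norm <- -50
  expect_equal(
    efficacy_difference(d0, "X", c("CLL01", "CLL02"), c("NRM01", "NRM02")),
    0
  )
  # boundary: 42-point gap exceeds the 40-point gate
  d2 <- d
  d2$value_norm <- ifelse(d2$sample_id %in% c("CLL01", "CLL02"), -80, -38)
  expect_gt(
    efficacy_difference(d2, "X", c("CLL01", "CLL02"), c("NRM01", "NRM02")),
    40
  )
  expect_error(efficacy_difference(d, "absent", "CLL01", "NRM01"), "no response")
})

test_that("the three selectivity clauses are evaluated as alternatives", {
  mk_matrix <- function(normal_ic50, normal_cat = "active") {
    tibble::tibble(
      compound_id = "S",
      sample_id = c("CLL01", "CLL02", sprintf("NRM%02d", 1:5)),
      category = c("active", "active", rep(normal_cat, 5)),
      curve_class = "1.1",
      ic50 = c(0.1, 0.1, rep(normal_ic50, 5)),
      efficacy = 95
    )
  }
  consensus <- tibble::tibble(compound_id = "S", ic50_gm = 0.1,
                              ic50_min = 0.1, ic50_max = 0.1, n_samples = 2)
  cll <- c("CLL01", "CLL02")
  nrm <- sprintf("NRM%02d", 1:5)
  # clause 1: 30-fold potency shift
  sel <- call_selectivity(mk_matrix(3), consensus, cll, nrm)
  expect_true(sel$selective)
  expect_equal(sel$fold_shift, 30)
  # no clause: comparable potency
  sel2 <- call_selectivity(mk_matrix(0.11), consensus, cll, nrm)
  expect_false(sel2$selective)
  # clause 3: inactive in a majority of normal donors, IC50s undefined there
  m3 <- mk_matrix(NA_real_, normal_cat = "inactive")
  m3$category[m3$sample_id %in% c("NRM04", "NRM05")] <- "active"
  m3$ic50[m3$sample_id %in% c("NRM04", "NRM05")] <- 0.2
  sel3 <- call_selectivity(m3, consensus, cll, nrm)
  expect_true(sel3$selective)
  expect_equal(sel3$n_normal_inactive, 3L)
})

test_that("screen summaries report one-decimal percentages that add up", {
  ms <- mini_screen()
  s <- ms$summary
  expect_equal(
    s$per_sample$n_active + s$per_sample$n_inconclusive +
      s$per_sample$n_inactive,
    s$per_sample$n_tested
  )
  expect_equal(s$per_sample$pct_active,
               round(100 * s$per_sample$n_active / s$per_sample$n_tested, 1))
  # worked percentage arithmetic at the screen scale
  expect_equal(round(100 * 356 / 2816, 1), 12.6)
  expect_equal(round(100 * 2385 / 2816, 1), 84.7)
  expect_equal(round(100 * 102 / 2816, 1), 3.6)
  # degenerate: no actives
  m0 <- toy_matrix()
  m0$category <- "inactive"
  m0$curve_class <- "4"
  s0 <- summarize_screen(m0, consensus_hits(m0, c("CLL01", "CLL02")),
                         cll_samples = c("CLL01", "CLL02"))
  expect_equal(s0$per_sample$pct_active, rep(0, 3))
})

test_that("activity outcomes encode as 1/2/3/4 integers", {
  m <- toy_matrix()
  m <- m[!(m$compound_id == "D" & m$sample_id == "NRM01"), ]  # untested cell
  enc <- encode_outcomes(m)
  expect_equal(enc["A", ], c(CLL01 = 1L, CLL02 = 1L, NRM01 = 3L))
  expect_equal(unname(enc["B", "CLL02"]), 2L)
  expect_equal(unname(enc["D", ]), c(3L, 3L, 4L))
})

test_that("profile clustering groups identical outcomes together", {
  enc <- rbind(
    a1 = c(1L, 1L, 1L), a2 = c(1L, 1L, 1L),
    b1 = c(3L, 3L, 3L), b2 = c(3L, 3L, 3L),
    c1 = c(1L, 3L, 1L), c2 = c(1L, 3L, 1L),
    d1 = c(2L, 2L, 3L), d2 = c(2L, 2L, 3L)
  )
  colnames(enc) <- c("s1", "s2", "s3")
  cl <- cluster_profiles(enc, k = 4)
  expect_equal(cl$dist["a1", "a2"], 0)
  expect_equal(cl$dist["a1", "b1"], 1)   # maximal disagreement
  # identical profiles sit in the same flat cluster, distinct ones apart
  expect_equal(length(unique(cl$clusters)), 4)
  expect_equal(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_equal(cl$clusters[["d1"]], cl$clusters[["d2"]])
  expect_false(cl$clusters[["a1"]] == cl$clusters[["b1"]])
  # identical profiles are adjacent leaves
  ord <- cl$order
  expect_equal(abs(which(ord == "a1") - which(ord == "a2")), 1)
})

test_that("untested cells are excluded from the distance", {
  enc <- rbind(x = c(1L, 4L, 1L), y = c(1L, 3L, 4L))
  colnames(enc) <- c("s1", "s2", "s3")
  cl <- cluster_profiles(enc)
  # only s1 is tested in both; codes agree there
  expect_equal(cl$dist["x", "y"], 0)
  # single compound: trivial ordering, no tree
  single <- cluster_profiles(enc[1, , drop = FALSE])
  expect_null(single$hclust)
  expect_equal(single$order, "x")
})

test_that("dendrograms export as newick", {
  enc <- rbind(a = c(1L, 1L), b = c(3L, 3L), c = c(1L, 3L))
  colnames(enc) <- c("s1", "s2")
  path <- tempfile(fileext = ".nwk")
  write_dendrogram(cluster_profiles(enc), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
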