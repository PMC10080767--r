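test_that("path enumeration yields the canonical relationship family", {
  p3 <- enumerate_relation_paths(3)
  expect_equal(vapply(p3, `[[`, "", "name"),
               c("PDP", "PTP", "PMP", "PDTP", "PDMP", "PTMP", "PDTMP"))
  expect_equal(vapply(p3, `[[`, 0L, "level"), c(1L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_equal(vapply(enumerate_relation_paths(1), `[[`, "", "name"),
               c("PDP", "PTP", "PMP"))
  p2 <- enumerate_relation_paths(2)
  expect_length(p2, 6L)
  expect_false("PDTMP" %in% vapply(p2, `[[`, "", "name"))
  expect_error(enumerate_relation_paths(4), "max_level")
  expect_error(enumerate_relation_paths(0), "max_level")
})

test_that("conjunction semantics on a 3-patient fixture match the hand count", {
  cl <- make_claims(c("p1", "p2", "p3"),
                    c("2018-01-01", "2018-01-01", "2018-01-02"),
                    c("d1", "d1", "d1"),
                    list("m1", "m1", "m2"))
  g <- build_hetero_graph(cl)
  adjs <- build_all_relation_graphs(g)
  expect_equal(adjs$PDP$neighbors$p1, c("p2", "p3"))
  expect_equal(adjs$PDTP$neighbors$p1, "p2")
  expect_equal(adjs$PDTMP$neighbors$p1, "p2")
  # sharing a department in one visit and a date in another must NOT link
  expect_equal(adjs$PDTP$neighbors$p3, character())
})

test_that("only full co-visit partners survive at the triple level", {
  # p2 shares department+date+medicine with p1; p4 and p5 only share the
  # department (different days / medicines)
  cl <- make_claims(c("p1", "p2", "p4", "p5"),
                    c("2018-02-01", "2018-02-01", "2018-02-02", "2018-02-03"),
                    rep("d9", 4),
                    list(c("m1", "m2"), "m1", "m3", "m4"))
  g <- build_hetero_graph(cl)
  pdp <- build_relation_adjacency(g, enumerate_relation_paths(1)[[1]])
  pdtmp <- build_relation_adjacency(g, enumerate_relation_paths(3)[[7]])
  expect_setequal(pdp$neighbors$p1, c("p2", "p4", "p5"))
  expect_equal(pdtmp$neighbors$p1, "p2")
})

test_that("adjacencies equal the brute-force pairwise-visit oracle", {
  paths <- enumerate_relation_paths(3)
  for (rep_i in 1:5) {
    set.seed(100 + rep_i)
    cl <- random_claims(n_patients = sample(5:15, 1))
    g <- build_hetero_graph(cl)
    adjs <- build_all_relation_graphs(g)
    for (p in paths) {
      got <- adjacency_matrix(adjs[[p$name]])
      want <- oracle_adjacency(cl, p$shared_types)[g$patients, g$patients]
      expect_identical(got, want)
    }
  }
})

test_that("higher levels are nested within compatible lower levels", {
  set.seed(31)
  cl <- random_claims(n_patients = 20)
  g <- build_hetero_graph(cl)
  adjs <- build_all_relation_graphs(g)
  subset_of <- function(a, b) !any(adjacency_matrix(a) & !adjacency_matrix(b))
  paths <- lapply(adjs, `[[`, "path")
  for (hi in names(adjs)) for (lo in names(adjs)) {
    if (all(paths[[lo]]$shared_types %in% paths[[hi]]$shared_types) && hi != lo)
      expect_true(subset_of(adjs[[hi]], adjs[[lo]]),
                  label = paste(hi, "subset of", lo))
  }
})

test_that("adjacencies are symmetric and irreflexive", {
  set.seed(17)
  cl <- random_claims(n_patients = 12)
  g <- build_hetero_graph(cl)
  for (adj in build_all_relation_graphs(g)) {
    A <- adjacency_matrix(adj)
    expect_identical(A, t(A))
    expect_false(any(diag(A)))
  }
})

test_that("relabelling patients permutes neighbour sets identically", {
  set.seed(23)
  cl <- random_claims(n_patients = 8)
  g <- build_hetero_graph(cl)
  ren <- setNames(sprintf("q%02d", seq_along(g$patients)), g$patients)
  cl2 <- cl
  cl2$patient_id <- unname(ren[cl$patient_id])
  g2 <- build_hetero_graph(cl2)
  a1 <- build_all_relation_graphs(g)
  a2 <- build_all_relation_graphs(g2)
  for (nm in names(a1)) {
    exp_nb <- lapply(a1[[nm]]$neighbors, function(x) sort(unname(ren[x])))
    names(exp_nb) <- unname(ren[names(a1[[nm]]$neighbors)])
    expect_equal(a2[[nm]]$neighbors[names(exp_nb)], exp_nb)
  }
})

test_that("medicine-free paths ignore medicine edits", {
  set.seed(41)
  cl <- random_claims(n_patients = 10)
  g1 <- build_hetero_graph(cl)
  cl2 <- cl
  cl2$medicine_ids <- lapply(cl$medicine_ids, function(x) character())
  g2 <- build_hetero_graph(cl2)
  for (nm in c("PDP", "PTP", "PDTP")) {
    p <- enumerate_relation_paths(3)
    p <- p[[which(vapply(p, `[[`, "", "name") == nm)]]
    expect_equal(build_relation_adjacency(g1, p)$neighbors,
                 build_relation_adjacency(g2, p)$neighbors)
  }
})

test_that("a single patient yields empty neighbour sets everywhere", {
  cl <- make_claims("p1", "2018-01-01", "d1", list("m1"))
  g <- build_hetero_graph(cl)
  adjs <- build_all_relation_graphs(g)
  expect_length(adjs, 7L)
  for (adj in adjs) expect_equal(adj$neighbors$p1, character())
})

test_that("multiplicity counts witnessing visit pairs once each", {
  # p1 and p2 co-visit twice; one co-visit shares two medicines but still
  # counts as a single witness
  cl <- make_claims(c("p1", "p2", "p1", "p2"),
                    c("2018-01-01", "2018-01-01", "2018-01-08", "2018-01-08"),
                    rep("d1", 4),
                    list(c("m1", "m2"), c("m1", "m2"), "m3", "m3"))
  g <- build_hetero_graph(cl)
  pdtmp <- build_relation_adjacency(g, enumerate_relation_paths(3)[[7]])
  row <- pdtmp$pairs[pdtmp$pairs$patient_i == "p1", ]
  expect_equal(row$multiplicity, 2L)
})

test_that("neighbour capping keeps symmetry and respects the cap direction", {
  sim <- simulate_claims(n_fraud = 10, n_normal = 20, ring_size = 5,
                         n_departments = 3, n_dates = 10, n_medicines = 10,
                         seed = 9)
  g <- build_hetero_graph(sim$claims)
  adj <- build_relation_adjacency(g, enumerate_relation_paths(1)[[1]])
  capped <- cap_neighbors(adj, max_neighbors = 3, seed = 1)
  A <- adjacency_matrix(capped)
  expect_identical(A, t(A))
  expect_true(all(rowSums(adjacency_matrix(capped)) <=
                  rowSums(adjacency_matrix(adj))))
})
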