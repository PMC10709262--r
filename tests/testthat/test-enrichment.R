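test_that("enrichment score equals brute-force enumeration", {
  # the 6-gene example, oracle = direct walk
  scores <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  gs <- c("g1", "g6")
  expect_equal(enrichment_score(scores, gs)$es, es_oracle(scores, gs))

  # exhaustive over random instances with N <= 50
  set.seed(13)
  for (i in 1:60) {
    N <- sample(3:50, 1)
    sc <- setNames(sort(rnorm(N), decreasing = TRUE), paste0("x", 1:N))
    m <- sample(1:(N - 1), 1)
    gset <- sample(names(sc), m)
    we <- sample(c(0, 1, 1.5), 1)
    expect_equal(enrichment_score(sc, gset, we)$es, es_oracle(sc, gset, we))
  }
})

test_that("ES boundary cases and invariances", {
  scores <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.2, -1, -2, -4),
                     paste0("g", 1:10))
  # geneset = contiguous top block -> ES hits +1 when the block ends
  expect_equal(enrichment_score(scores, paste0("g", 1:3))$es, 1)
  # geneset = every gene -> no misses, ES = 1
  expect_equal(enrichment_score(scores, names(scores))$es, 1)
  # no overlap is an error
  expect_error(enrichment_score(scores, c("zz1", "zz2")), "no genes")
  # weight_exp = 0: invariant under strictly monotone rescaling of scores
  gs <- c("g2", "g7", "g9")
  a <- enrichment_score(scores, gs, weight_exp = 0)$es
  b <- enrichment_score(setNames(scores * 7 + 100, names(scores)), gs,
                        weight_exp = 0)$es
  expect_equal(a, b)
  # unsorted or duplicated inputs are rejected
  expect_error(enrichment_score(rev(scores), gs), "descending")
  bad <- scores; names(bad)[2] <- "g1"
  expect_error(enrichment_score(bad, gs), "duplicate")
})

test_that("fast null-ES path agrees with the full running sum", {
  set.seed(14)
  N <- 80
  sc <- setNames(sort(rnorm(N), decreasing = TRUE), paste0("g", 1:N))
  w <- abs(sc)
  for (i in 1:40) {
    m <- sample(1:(N - 1), 1)
    pos <- sort(sample.int(N, m))
    full <- enrichment_score(sc, names(sc)[pos])$es
    expect_equal(scstate:::es_from_positions(pos, w, N), full)
  }
})

test_that("NES and permutation p behave at the extremes and are seeded", {
  set.seed(15)
  sc <- setNames(sort(rnorm(200), decreasing = TRUE), paste0("g", 1:200))
  top <- names(sc)[1:20]
  r <- nes_and_p(sc, top, n_perm = 500, seed = 3)
  expect_equal(r$n_more_extreme, 0L)           # extreme case bound attained
  expect_lt(r$p, 0.01)                         # p = 1 / (1 + #matching nulls)
  expect_gt(r$nes, 1)
  expect_identical(r[c("es", "nes", "p")],
                   nes_and_p(sc, top, n_perm = 500, seed = 3)[c("es", "nes", "p")])

  # a random geneset on a random ranking is unremarkable
  rnd <- sample(names(sc), 20)
  r0 <- nes_and_p(sc, rnd, n_perm = 500, seed = 4)
  expect_gt(r0$p, 0.05)
  expect_lt(abs(r0$nes), 2)
  # NES carries the sign of ES
  expect_equal(sign(r0$nes), sign(r0$es))
})

test_that("permutation p matches the analytic KS tail on an exchangeable null", {
  kolm_q <- function(l) { k <- 1:100; 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2)) }
  set.seed(33)
  N <- 500; m <- 50
  sc <- setNames(sort(rnorm(N), decreasing = TRUE), paste0("g", 1:N))
  ne <- m * (N - m) / N
  for (i in 1:5) {
    gs <- sample(names(sc), m)
    r <- nes_and_p(sc, gs, n_perm = 2000, seed = i, weight_exp = 0)
    # Stephens-corrected asymptotic two-sample KS tail
    lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * abs(r$es)
    pa <- kolm_q(lam)
    n_same <- (1 + r$n_more_extreme) / r$p - 1   # matching-sign null count
    se <- sqrt(max(pa * (1 - pa), 1e-6) / n_same)
    expect_lt(abs(r$p - pa), 3 * se)
  }
})

test_that("top geneset selection ranks by max |NES| with documented ties", {
  res <- data.frame(
    cluster = rep(c("0", "1"), each = 3),
    geneset = rep(c("B_SET", "A_SET", "C_SET"), 2),
    es = 0.5, nes = c(2, -2, 1.5, 1, 1, -0.5), p = 0.01)
  expect_identical(top_genesets(res, 1), "A_SET")   # tie 2 vs 2: lexicographic
  expect_identical(top_genesets(res, 2), c("A_SET", "B_SET"))
  expect_warning(all3 <- top_genesets(res, 10), "available")
  expect_length(all3, 3)
})

test_that("supercluster assignment groups NES profiles and is order-stable", {
  mk_res <- function(clusters, nes_rows, sets = paste0("S", 1:3)) {
    do.call(rbind, lapply(seq_along(clusters), function(i) {
      data.frame(cluster = clusters[i], geneset = sets,
                 es = 0.1, nes = nes_rows[[i]], p = 0.5)
    }))
  }
  res <- mk_res(c("0", "1", "2"),
                list(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)))
  sc <- assign_superclusters(res, n_super = 3)
  expect_length(unique(sc$assignment), 3)

  # duplicate NES rows co-assigned at any cut
  res2 <- mk_res(c("0", "1", "2", "3"),
                 list(c(5, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)))
  sc2 <- assign_superclusters(res2, n_super = 3)
  expect_identical(sc2$assignment[["0"]], sc2$assignment[["1"]])

  # invariance to input row order (as a partition)
  perm <- res2[sample(nrow(res2)), ]
  sc3 <- assign_superclusters(perm, n_super = 3)
  expect_equal(adjusted_rand_index(sc2$assignment[c("0", "1", "2", "3")],
                                   sc3$assignment[c("0", "1", "2", "3")]), 1)

  # proliferation-set ordering pins the letters
  sc4 <- assign_superclusters(res2, n_super = 3, proliferation_sets = "S1")
  # the S1-high duplicate pair has the highest mean NES on S1 -> letter C
  expect_identical(unname(sc4$assignment[c("0", "1")]), c("C", "C"))

  expect_error(assign_superclusters(res, n_super = 4), "n_super")
})

test_that("signatures are own-contrast intersections minus others' unions", {
  up <- list(
    A = list(B = c("g1", "g2", "g3"), C = c("g1", "g2", "g9")),
    B = list(A = c("g4"), C = c("g4", "g2")),
    C = list(A = c("g5"), B = c("g5", "g6")))
  sig <- suppressWarnings(supercluster_signatures(up))
  # g1 up in both A contrasts and nowhere else -> in A's signature
  expect_true("g1" %in% sig$A)
  # g2 up in both A contrasts but also in B's up-lists -> excluded
  expect_false("g2" %in% sig$A)
  # g9 only up in one A contrast -> excluded
  expect_false("g9" %in% sig$A)
  expect_identical(sig$B, "g4")
  expect_identical(sig$C, "g5")
  # pairwise disjoint
  expect_length(intersect(sig$A, sig$B), 0)
  expect_length(intersect(sig$A, sig$C), 0)
  w <- testthat::capture_warnings(
    supercluster_signatures(list(A = list(B = "x"), B = list(A = "x"))))
  expect_length(w, 2)
  expect_match(w, "empty signature", all = TRUE)
})
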