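stage_sets_toy <- function() {
  # two genes per stage: G1.S -> a1,a2; S -> b1,b2; ...
  sets <- split(paste0(rep(letters[1:5], each = 2), 1:2),
                rep(CC_STAGES, each = 2))
  sets[CC_STAGES]
}

toy_expr <- function(vals) {
  # vals: 5-vector of per-stage expression for a single cell, recycled
  genes <- unlist(stage_sets_toy(), use.names = FALSE)
  m <- matrix(rep(rep(vals, each = 2), length.out = 10), ncol = 1,
              dimnames = list(genes, "cell1"))
  m
}

test_that("stage scores are stage means, z-normalized within cell", {
  expr <- toy_expr(c(0, 0, 3, 0, 0))   # expresses only G2 genes
  sc <- score_stages(expr, stage_sets_toy())
  expect_equal(unname(which.max(sc[1, ])), 3)
  expect_equal(mean(sc[1, ]), 0)
  expect_equal(sd(sc[1, ]), 1)

  # all-equal raw scores -> degenerate, all-zero vector
  sc0 <- score_stages(toy_expr(rep(2, 5)), stage_sets_toy())
  expect_true(attr(sc0, "degenerate")[1])
  expect_true(all(sc0 == 0))

  # absent genes dropped with warning; fully absent stage is an error
  sets <- stage_sets_toy()
  sets$G2 <- c(sets$G2, "missing_gene")
  expect_warning(score_stages(expr, sets), "absent")
  sets$G2 <- c("nope1", "nope2")
  expect_error(suppressWarnings(score_stages(expr, sets)), "G2")
  expect_error(score_stages(expr, stage_sets_toy()[-1]), "G1.S")
})

test_that("assignment follows profile correlation with threshold", {
  profiles <- default_stage_profiles()
  # score vector equal to a profile -> that stage with correlation 1
  sc <- rbind(profiles["G2.M", ], profiles["S", ])
  rownames(sc) <- c("x", "y")
  a <- assign_stages(sc, profiles, cor_thr = 0.2)
  expect_identical(a$stage, c("G2.M", "S"))
  expect_equal(a$correlation, c(1, 1))

  # threshold dominance
  a2 <- assign_stages(sc, profiles, cor_thr = 1.01)
  expect_true(all(a2$stage == "unassigned"))

  # derived example: (2, -.5, -.5, -.5, -.5) -> G1.S, checked against a
  # direct correlation computation
  v <- matrix(c(2, -0.5, -0.5, -0.5, -0.5), nrow = 1,
              dimnames = list("z", CC_STAGES))
  oracle <- apply(profiles, 1, function(p) cor(v[1, ], p))
  expect_identical(names(which.max(oracle)), "G1.S")
  a3 <- assign_stages(v, profiles)
  expect_identical(a3$stage, "G1.S")
  expect_equal(a3$correlation, max(oracle))

  # zero-variance score vector -> unassigned
  flat <- matrix(0, 1, 5, dimnames = list("f", CC_STAGES))
  expect_identical(assign_stages(flat, profiles)$stage, "unassigned")
})

test_that("refinement converges to blob structure and respects bounds", {
  set.seed(3)
  profiles <- default_stage_profiles()
  blobs <- do.call(rbind, lapply(1:5, function(s) {
    sweep(matrix(rnorm(30 * 5, sd = 0.1), 30, 5), 2, profiles[s, ], `+`)
  }))
  rownames(blobs) <- paste0("c", seq_len(nrow(blobs)))
  truth <- rep(CC_STAGES, each = 30)
  # initial profiles deliberately perturbed
  init <- profiles + matrix(rnorm(25, sd = 0.3), 5, 5)
  ref <- refine_assignments(blobs, init, cor_thr = 0.2, refine_iter = 200,
                            tol = 0)
  expect_true(ref$converged)
  expect_lte(ref$n_iter, 5)
  expect_identical(ref$assignment$stage, truth)
  # a fixed point is stable: restarting from the final profiles changes nothing
  again <- refine_assignments(blobs, ref$profiles, cor_thr = 0.2,
                              refine_iter = 1, tol = 0)
  expect_identical(again$assignment$stage, ref$assignment$stage)

  # refine_iter = 0 reproduces plain assignment
  r0 <- refine_assignments(blobs, init, refine_iter = 0)
  expect_identical(r0$assignment, assign_stages(blobs, init))
  expect_equal(r0$n_iter, 0L)
})

test_that("circular phase recovers an exact ring in order", {
  t_true <- seq(0, 2 * pi, length.out = 41)[-41]
  centers <- (seq_len(5) - 1) * 2 * pi / 5 + pi / 5
  sc <- outer(t_true, centers, function(t, c) cos(t - c))
  colnames(sc) <- CC_STAGES
  rownames(sc) <- paste0("c", seq_along(t_true))
  labels <- CC_STAGES[floor(t_true / (2 * pi / 5)) + 1]
  theta <- fit_circular_phase(sc, labels = labels)
  expect_true(all(theta >= 0 & theta < 2 * pi))
  # order-preserving: unwrapped phases are monotone in t_true
  d <- diff(theta) %% (2 * pi)
  expect_true(all(d > 0))
  # uniform spacing preserved
  expect_lt(max(d) - min(d), 1e-6)
  # stage circular means advance in cycle order
  mu <- vapply(CC_STAGES, function(s) circular_mean(theta[labels == s]),
               numeric(1))
  expect_equal(round(sum(diff(c(mu, mu[1])) %% (2 * pi)) / (2 * pi)), 1)
  expect_error(fit_circular_phase(sc[1:2, ]), "3 non-degenerate")
})

test_that("cell order does not affect the caller, and cor_thr is monotone", {
  sim <- standard_sim()
  cells <- colnames(sim$counts)[1:120]
  expr <- normalize_log(sim$counts, cells)
  sc <- score_stages(expr, sim$stage_sets)
  perm <- sample(seq_len(nrow(sc)))
  sc_p <- sc[perm, ]
  attr(sc_p, "degenerate") <- attr(sc, "degenerate")[perm]
  a <- assign_stages(sc)
  a_p <- assign_stages(sc_p)
  expect_identical(a$stage[perm], a_p$stage)

  n_assigned <- vapply(c(0, 0.3, 0.7, 0.95), function(thr) {
    sum(assign_stages(sc, cor_thr = thr)$stage != "unassigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("the four-label reporting map is fixed", {
  expect_identical(stage_to_four(c("M.G1", "G1.S", "S", "G2", "G2.M")),
                   c("G1", "G1/S", "S/G2", "S/G2", "G2/M"))
})
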