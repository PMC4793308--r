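planted_block <- function(nr_core = 3, nc_core = 3, nr = 6, nc = 6,
                          flip = 0, seed = NULL) {
  m <- matrix(0, nr, nc)
  m[seq_len(nr_core), seq_len(nc_core)] <- 1
  if (flip > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample(length(m), round(flip * length(m)))
    m[idx] <- 1 - m[idx]
  }
  m
}

test_that("fitness matches its definition and handles degeneracies", {
  m <- planted_block()
  rc <- rep(c(TRUE, FALSE), each = 3); cc <- rc
  expect_equal(cp_fitness(m, rc, cc), 1)
  expect_true(is.na(cp_fitness(matrix(1, 4, 4), rc[1:4], cc[1:4])))
  # against the naive stats::cor oracle on random partitions
  set.seed(19)
  for (i in 1:30) {
    w <- random_binary_matrix(5, 6, 0.5)
    rcore <- runif(5) < 0.5; ccore <- runif(6) < 0.5
    expect_equal(cp_fitness(w, rcore, ccore),
                 cp_fitness_oracle(w, rcore, ccore))
  }
})

test_that("annealing recovers an exact planted block with fitness 1", {
  m <- planted_block()
  fit <- fit_core_periphery(m, seed = 4)
  expect_equal(fit$fitness, 1)
  expect_equal(unname(fit$row_core), rep(c(TRUE, FALSE), each = 3))
  expect_equal(unname(fit$col_core), rep(c(TRUE, FALSE), each = 3))
  expect_error(fit_core_periphery(matrix(1, 1, 5)), "at least 2 x 2")
  expect_error(fit_core_periphery(matrix(1, 3, 3)), "uniform")
})

test_that("reported cores sit on the high-degree side", {
  set.seed(41)
  for (i in 1:10) {
    m <- planted_block(flip = 0.1, seed = 100 + i)
    fit <- fit_core_periphery(m, seed = i)
    if (is.na(fit$fitness) || all(fit$row_core) || !any(fit$row_core)) next
    core_deg <- mean(rowSums(m)[fit$row_core])
    peri_deg <- mean(rowSums(m)[!fit$row_core])
    expect_gte(core_deg, peri_deg)
  }
})

test_that("occurrence percentages are reproducible and block-exact", {
  m <- planted_block()
  rownames(m) <- paste0("m", 1:6); colnames(m) <- paste0("p", 1:6)
  occ <- core_periphery_occurrence(m, n_runs = 10, seed = 9)
  expect_identical(occ, core_periphery_occurrence(m, n_runs = 10, seed = 9))
  tab <- occ$occurrence
  expect_equal(tab$percent_core[tab$node %in% c("m1", "m2", "m3", "p1", "p2", "p3")],
               rep(100, 6))
  expect_equal(tab$percent_periphery[tab$node %in% c("m4", "m5", "m6")],
               rep(100, 3))
  expect_true(all(tab$percent_core + tab$percent_periphery <= 100))
})

test_that("annealing reaches the brute-force optimum on small instances", {
  set.seed(55)
  hits <- 0
  for (s in 1:20) {
    m <- planted_block(nr_core = 2, nc_core = 2, nr = 5, nc = 5,
                       flip = 0.12, seed = 200 + s)
    if (all(m == 1) || all(m == 0)) next
    best <- cp_bruteforce_optimum(m)
    fit <- fit_core_periphery(m, seed = s)
    hits <- hits + (!is.na(fit$fitness) && fit$fitness >= best - 1e-9)
  }
  expect_gte(hits, 19)
})
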