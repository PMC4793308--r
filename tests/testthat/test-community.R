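toy_transects <- function() {
  # 2 transects; species A: 2 stems in T1, dbh 20 & 20; B: 1 stem each, dbh 20/40
  data.frame(
    site_id = "CF1", habitat = "continuous",
    transect_id = c("T1", "T1", "T1", "T2"),
    x = 0, y = 0,
    species = c("A", "A", "B", "B"),
    dbh = c(20, 20, 20, 40),
    stringsAsFactors = FALSE
  )
}

test_that("IVI components and totals follow the share definitions", {
  one <- toy_transects()[1, ]
  expect_equal(compute_ivi(one, "continuous")$ivi, 1)

  sym <- toy_transects()
  sym$dbh <- 20
  sym$transect_id <- c("T1", "T1", "T2", "T2")
  sym$species <- c("A", "B", "A", "B")
  ivi <- compute_ivi(sym, "continuous")
  expect_equal(ivi$ivi, c(0.5, 0.5))

  ivi <- compute_ivi(toy_transects(), "continuous")
  # hand-computed: density 2/4 vs 2/4; frequency A 1/3, B 2/3;
  # basal area shares via pi(dbh/2)^2: A 800pi/2800pi, B 2000pi/2800pi
  a <- ivi[ivi$species == "A", ]
  expect_equal(a$relative_density, 0.5)
  expect_equal(a$relative_frequency, 1 / 3)
  expect_equal(a$relative_dominance, 800 / 2800)
  expect_equal(a$ivi, (0.5 + 1 / 3 + 2 / 7) / 3)
  expect_equal(sum(ivi$ivi), 1)
  expect_error(compute_ivi(toy_transects(), "fragment"), "no trees")
})

test_that("Jaccard similarity covers the published diet overlap", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  counts <- count_species_by_habitat()
  j <- jaccard(counts$continuous_species, counts$fragment_species)
  expect_equal(j, 20 / 37)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("Mantel statistic and permutation p behave as specified", {
  set.seed(61)
  pts <- matrix(runif(14), 7, 2)
  d1 <- as.matrix(dist(pts))
  r <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1 / 100)   # identity included in the count
  # positive affine transform leaves r at 1
  expect_equal(mantel_test(d1, 2 * d1 + 0.3 * (1 - diag(7)), n_perm = 19,
                           seed = 1)$statistic, 1)
  # statistic agrees with the reference implementation
  skip_if_not_installed("vegan")
  d2 <- as.matrix(dist(matrix(runif(14), 7, 2)))
  expect_equal(mantel_test(d1, d2, n_perm = 19, seed = 2)$statistic,
               unname(vegan::mantel(d1, d2, permutations = 19)$statistic))
})

test_that("Mantel p is invariant under consistent relabelling", {
  set.seed(67)
  d1 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  d2 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  p0 <- mantel_test(d1, d2, n_perm = 999, seed = 3)$p_value
  ord <- sample(6)
  p1 <- mantel_test(d1[ord, ord], d2[ord, ord], n_perm = 999, seed = 3)$p_value
  expect_lt(abs(p0 - p1), 0.08)   # same null distribution; MC noise only
  expect_error(mantel_test(matrix(0, 4, 4), d2[1:4, 1:4], n_perm = 9),
               "zero variance")
})

test_that("transformed t-tests match the textbook formula", {
  expect_equal(transformed_t_test(c(1, 2, 3), c(1, 2, 3), "log1p")$statistic, 0)
  r <- transformed_t_test(c(0.1, 0.2, 0.4), c(0.3, 0.5, 0.6, 0.2), "arcsine_sqrt")
  expect_equal(r$df, 5)
  expect_equal(r$statistic,
               student_t_oracle(asin(sqrt(c(0.1, 0.2, 0.4))),
                                asin(sqrt(c(0.3, 0.5, 0.6, 0.2)))),
               tolerance = 1e-12)
  x <- c(3, 8, 1, 9, 4); y <- c(2, 7, 7, 3)
  expect_equal(transformed_t_test(x, y, "log1p")$statistic,
               student_t_oracle(log1p(x), log1p(y)), tolerance = 1e-12)
  expect_error(transformed_t_test(c(0.2, 1.4), c(0.1, 0.5), "arcsine_sqrt"),
               "\\[0, 1\\]")
  expect_error(transformed_t_test(1, c(1, 2), "log1p"), "at least two")
})

test_that("item-time fractions sum to one within habitat", {
  obs <- make_obs(c("m1", "m1"), c("A", "B"))
  obs$item <- c("MF", "IL"); obs$duration <- c(3, 1)
  f <- item_time_fractions(obs)
  expect_equal(sort(f$fraction), c(0.25, 0.75))
  one <- obs[1, ]
  expect_equal(item_time_fractions(one)$fraction, 1)
  zero <- obs; zero$duration <- 0
  expect_error(item_time_fractions(zero), "no feeding time")
})

test_that("nested ANOVA reproduces first-principles sums of squares", {
  # balanced toy: 2 habitats x 3 items x 4 replicates
  set.seed(71)
  d <- expand.grid(habitat = c("cf", "fr"), item = c("MF", "IL", "P"),
                   rep = 1:4)
  d$y <- plogis(rnorm(nrow(d), sd = 1) +
                  ifelse(d$habitat == "cf", 0.4, 0) +
                  as.numeric(d$item) * 0.3)
  r <- nested_anova(d$y, d$habitat, d$item)
  o <- nested_anova_oracle(asin(sqrt(d$y)), d$habitat, d$item)
  expect_equal(r$habitat$statistic, o$F_habitat, tolerance = 1e-10)
  expect_equal(r$item_within_habitat$statistic, o$F_item, tolerance = 1e-10)
  expect_equal(r$habitat$df, c(o$df[1], o$df[3]))
  expect_equal(r$item_within_habitat$df, c(o$df[2], o$df[3]))

  same <- nested_anova(rep(0.4, 12), rep(c("cf", "fr"), 6),
                       rep(c("MF", "IL"), each = 6))
  expect_equal(same$habitat$statistic, 0)
  expect_equal(same$habitat$p_value, 1)
})

test_that("habitat F grows with the habitat effect", {
  set.seed(73)
  d <- expand.grid(habitat = c("cf", "fr"), item = c("MF", "IL"), rep = 1:5)
  noise <- rnorm(nrow(d), sd = 0.05)
  fs <- vapply(c(0, 0.1, 0.25), function(eff) {
    y <- plogis(noise + ifelse(d$habitat == "cf", eff, 0))
    nested_anova(y, d$habitat, d$item)$habitat$statistic
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("the angular transform is monotone with fixed endpoints", {
  expect_equal(arcsine_sqrt(c(0, 1)), c(0, pi / 2))
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_sqrt(p)) > 0))
  expect_error(arcsine_sqrt(1.2), "\\[0, 1\\]")
})
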