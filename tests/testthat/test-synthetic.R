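test_that("the paper-like preset reproduces the study census and flora", {
  sc <- generate_scenario(synthetic_config("paper_like", seed = 3))
  ind <- sc$individuals
  expect_equal(sum(ind$habitat == "continuous"), 15)
  expect_equal(sum(ind$habitat == "fragment"), 18)
  cls <- table(paste(ind$age_class, ind$sex, sep = "-"),
               ind$habitat)
  expect_equal(unname(cls[, "continuous"][c("adult-F", "adult-M", "infant-F")]),
               c(6, 4, 2))
  expect_equal(unname(cls[, "fragment"][c("adult-F", "juvenile-F", "juvenile-M")]),
               c(5, 4, 3))
  expect_equal(sum(sc$flora$continuous), 27)
  expect_equal(sum(sc$flora$fragment), 30)
  expect_equal(nrow(sc$flora), 37)
})

test_that("scenarios are deterministic with stream separation by stage", {
  a <- generate_scenario(synthetic_config("paper_like", seed = 12))
  b <- generate_scenario(synthetic_config("paper_like", seed = 12))
  expect_identical(a, b)
  c0 <- generate_scenario(synthetic_config("paper_like", seed = 12, nu = 0))
  expect_identical(a$individuals, c0$individuals)
  expect_identical(a$flora, c0$flora)
  expect_identical(a$transects, c0$transects)
  expect_false(identical(a$observations, c0$observations))
})

test_that("paper-like records build a census-shaped interaction matrix", {
  sc <- generate_scenario(synthetic_config("paper_like", seed = 3))
  web <- build_interaction_matrix(sc$observations, "continuous",
                                  individuals = sc$individuals)
  expect_equal(dim(web), c(15, 27))
})

test_that("nu = 1 nests narrow diets inside broader-class diets", {
  cfg <- synthetic_config("paper_like", seed = 5, nu = 1)
  sc <- generate_scenario(cfg)
  for (h in habitats()) {
    web <- build_interaction_matrix(sc$observations, h,
                                    individuals = sc$individuals)
    ind <- sc$individuals[match(rownames(web), sc$individuals$individual_id), ]
    adults <- ind$age_class == "adult"
    infants <- ind$age_class == "infant"
    adult_union <- colSums(web[adults, , drop = FALSE] > 0) > 0
    for (i in which(infants)) {
      expect_true(all(adult_union[web[i, ] > 0]))
    }
  }
})

test_that("nestedness and degree orderings respond to the generator knobs", {
  nodf_at <- function(nu, s) {
    cfg <- synthetic_config("paper_like", seed = s, nu = nu)
    ind <- roster <- generate_scenario(cfg)$individuals
    ih <- ind[ind$habitat == "continuous", ]
    fl <- cfg$flora$species[cfg$flora$continuous]
    nodf(generate_diets(ih, fl, nu, cfg$class_breadths, seed = s * 7 + 1))
  }
  seeds <- 1:15
  n1 <- vapply(seeds, function(s) nodf_at(1, s), numeric(1))
  n0 <- vapply(seeds, function(s) nodf_at(0, s), numeric(1))
  expect_gt(mean(n1), mean(n0))

  ord_ok <- 0
  for (s in seeds) {
    cfg <- synthetic_config("paper_like", seed = s)
    sc <- generate_scenario(cfg)
    web <- build_interaction_matrix(sc$observations, "fragment",
                                    individuals = sc$individuals)
    cs <- class_diet_summary(web, sc$individuals)
    ad <- mean(cs$mean_degree[cs$class %in% c("adult-F", "adult-M")])
    ju <- mean(cs$mean_degree[grepl("juvenile", cs$class)])
    inf <- mean(cs$mean_degree[grepl("infant", cs$class)])
    ord_ok <- ord_ok + (ad > ju && ju > inf)
  }
  expect_gte(ord_ok / length(seeds), 0.85)
})

test_that("item-time fractions track the configured targets", {
  sc <- generate_scenario(synthetic_config("paper_like", seed = 9))
  f <- item_time_fractions(sc$observations)
  mf <- f$fraction[f$habitat == "continuous" & f$item == "MF"]
  expect_lt(abs(mf - 0.545), 0.1)
  il <- f$fraction[f$habitat == "fragment" & f$item == "IL"]
  expect_lt(abs(il - 0.562), 0.1)
  for (h in habitats()) {
    expect_equal(sum(f$fraction[f$habitat == h]), 1)
  }
})

test_that("transect layout and dbh rule match the sampling design", {
  cfg <- synthetic_config("paper_like", seed = 21)
  tr <- generate_transects(cfg)
  expect_true(all(tr$dbh >= 10))
  layout <- unique(tr[, c("site_id", "transect_id")])
  expect_equal(nrow(layout), 60)   # 10 transects x 3 sites x 2 habitats
  expect_equal(length(unique(tr$site_id)), 6)
  # transects are valid input downstream
  ivi <- compute_ivi(tr, "continuous")
  expect_equal(sum(ivi$ivi), 1)
})

test_that("single-species floras give that species the whole IVI", {
  cfg <- synthetic_config(
    "generic", seed = 2,
    flora = data.frame(species = "only", continuous = TRUE, fragment = TRUE,
                       continuous_items = "MF", fragment_items = "MF",
                       stringsAsFactors = FALSE),
    community = list(pool_extra = 0, stems_per_transect = 10,
                     abundance_sdlog = 1, n_sites = 3, n_transects = 10,
                     dbh_shape = 1.5, dbh_scale = 12)
  )
  tr <- generate_transects(cfg)
  expect_equal(compute_ivi(tr, "continuous")$ivi, 1)
})

test_that("stronger abundance skew concentrates the top IVI", {
  top_ivi <- function(sdlog, s) {
    cfg <- synthetic_config("paper_like", seed = s)
    cfg$community$abundance_sdlog <- sdlog
    max(compute_ivi(generate_transects(cfg), "continuous")$ivi)
  }
  seeds <- 1:8
  lo <- mean(vapply(seeds, function(s) top_ivi(0.2, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) top_ivi(2.5, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("inconsistent configurations are rejected", {
  expect_error(synthetic_config("paper_like", nu = 1.5), "nu")
  expect_error(synthetic_config("paper_like",
                                class_breadths = c("adult-F" = 0.5)),
               "six age/sex classes")
  bad <- c("adult-F" = 1.2, "adult-M" = 0.4, "juvenile-F" = 0.3,
           "juvenile-M" = 0.3, "infant-F" = 0.2, "infant-M" = 0.2)
  expect_error(synthetic_config("paper_like", class_breadths = bad), "\\(0, 1\\]")
  expect_error(generate_diets(data.frame(individual_id = "a", sex = "F",
                                         age_class = "adult"),
                              character(0), 0.5,
                              c("adult-F" = 0.5)), "empty flora")
})
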