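# Synthetic study generator: age/sex-structured monkey censuses, floras with
# per-habitat occupancy and item sets, class-graded nested diets, feeding
# records with durations, and vegetation transects. Every stage draws from
# its own sub-stream of the master seed, so e.g. changing the nestedness
# knob nu alters diets but not the flora or the transects.

#' Synthetic scenario configuration
#'
#' Builds the configuration driving [generate_scenario()]. The
#' `"paper_like"` preset encodes the study conditions of the source system:
#' 15 continuous-forest individuals (6 adult F, 4 adult M, 1 juvenile F,
#' 1 juvenile M, 2 infant F, 1 infant M) and 18 fragment individuals
#' (5, 4, 4, 3, 1, 1), a 37-species flora of which 27 occur in continuous
#' forest and 30 in fragments (with the published per-habitat item sets), and
#' feeding-time item weights matching the published percentages.
#'
#' Class diet breadths (fraction of the habitat's flora an individual of the
#' class consumes, on average) default to adult F 0.58, adult M 0.42,
#' juveniles 0.35, infants 0.20: ordered adult > juvenile > infant as the
#' system requires, with an overall mean fill near the published connectance.
#'
#' @param preset `"paper_like"` or `"generic"` (a small neutral scenario).
#' @param nu Nestedness knob in [0, 1]: probability that a diet item is drawn
#'   preferentially from plants already used by broader-diet individuals
#'   (weight proportional to current plant degree) rather than uniformly.
#' @param seed Master integer seed.
#' @param class_breadths Named numeric over [age_sex_classes()], each in (0, 1].
#' @param records_per_link_lambda Feeding records per realized link are
#'   `1 + Poisson(lambda)`.
#' @param ... Overrides for other components (census, flora, item_weights,
#'   time_targets_minutes, community settings); see the returned object.
#' @return Object of class `synthetic_config` (a list).
#' @export
synthetic_config <- function(preset = c("paper_like", "generic"), nu = 0.8,
                             seed = 1L, class_breadths = NULL,
                             records_per_link_lambda = 2, ...) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, nu = nu, seed = as.integer(seed),
              records_per_link_lambda = records_per_link_lambda,
              duration_shape = 2)
  if (preset == "paper_like") {
    cfg$census <- list(
      continuous = c("adult-F" = 6, "adult-M" = 4, "juvenile-F" = 1,
                     "juvenile-M" = 1, "infant-F" = 2, "infant-M" = 1),
      fragment = c("adult-F" = 5, "adult-M" = 4, "juvenile-F" = 4,
                   "juvenile-M" = 3, "infant-F" = 1, "infant-M" = 1)
    )
    t3 <- load_fixture("table3_items")
    cfg$flora <- data.frame(
      species = t3$species,
      continuous = !is_absent(t3$continuous_items),
      fragment = !is_absent(t3$fragment_items),
      continuous_items = ifelse(is_absent(t3$continuous_items), "",
                                trimws(t3$continuous_items)),
      fragment_items = ifelse(is_absent(t3$fragment_items), "",
                              trimws(t3$fragment_items)),
      stringsAsFactors = FALSE
    )
    # Published feeding-time percentages per item and habitat.
    cfg$item_weights <- list(
      continuous = c(MF = 54.5, IL = 31.0, P = 6.2, ML = 3.8, B = 2.3,
                     IF = 1.2, FL = 0.73),
      fragment = c(IL = 56.2, MF = 37.6, IF = 5.0, ML = 0.8, P = 0.5,
                   B = 0, FL = 0)
    )
    # Published per-class foraging totals (hours -> minutes).
    cfg$time_targets_minutes <- list(
      continuous = c(adult = 31.30, juvenile = 5.56, infant = 2.80) * 60,
      fragment = c(adult = 46.14, juvenile = 14.96, infant = 0.12) * 60
    )
  } else {
    cfg$census <- list(
      continuous = c("adult-F" = 3, "adult-M" = 2, "juvenile-F" = 1,
                     "juvenile-M" = 1, "infant-F" = 1, "infant-M" = 1),
      fragment = c("adult-F" = 3, "adult-M" = 2, "juvenile-F" = 1,
                   "juvenile-M" = 1, "infant-F" = 1, "infant-M" = 1)
    )
    sp <- sprintf("sp%02d", 1:20)
    cfg$flora <- data.frame(
      species = sp, continuous = TRUE, fragment = TRUE,
      continuous_items = "MF IL", fragment_items = "MF IL",
      stringsAsFactors = FALSE
    )
    cfg$item_weights <- list(continuous = c(MF = 1, IL = 1),
                             fragment = c(MF = 1, IL = 1))
    cfg$time_targets_minutes <- list(
      continuous = c(adult = 600, juvenile = 200, infant = 60),
      fragment = c(adult = 600, juvenile = 200, infant = 60)
    )
  }
  cfg$class_breadths <- if (is.null(class_breadths)) {
    c("adult-F" = 0.58, "adult-M" = 0.42, "juvenile-F" = 0.35,
      "juvenile-M" = 0.35, "infant-F" = 0.20, "infant-M" = 0.20)
  } else class_breadths
  # Vegetation community around the diet flora: extra non-food species, stem
  # density per 100 m2 transect, abundance skew, transect layout.
  cfg$community <- list(pool_extra = 25, stems_per_transect = 14,
                        abundance_sdlog = 1, n_sites = 3, n_transects = 10,
                        dbh_shape = 1.5, dbh_scale = 12)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  if (cfg$nu < 0 || cfg$nu > 1) stop("nu must lie in [0, 1]", call. = FALSE)
  if (any(unlist(cfg$census) < 0)) stop("census counts must be >= 0", call. = FALSE)
  b <- cfg$class_breadths
  if (!all(age_sex_classes() %in% names(b))) {
    stop("class_breadths must name all six age/sex classes", call. = FALSE)
  }
  if (any(b <= 0 | b > 1)) stop("class breadths must lie in (0, 1]", call. = FALSE)
  for (h in habitats()) {
    if (sum(cfg$flora[[h]]) < 1 && sum(cfg$census[[h]]) > 0) {
      stop("no flora available in habitat ", h, call. = FALSE)
    }
  }
  invisible(cfg)
}

# Deterministic individual roster from the census.
roster_individuals <- function(census) {
  do.call(rbind, lapply(habitats(), function(h) {
    cls <- rep(names(census[[h]]), census[[h]])
    if (length(cls) == 0) return(NULL)
    parts <- strsplit(cls, "-", fixed = TRUE)
    age <- vapply(parts, `[`, "", 1)
    sex <- vapply(parts, `[`, "", 2)
    n <- length(cls)
    data.frame(
      individual_id = sprintf("%s-%s%s-%02d", ifelse(h == "continuous", "CF", "FR"),
                              toupper(substr(age, 1, 1)), sex,
                              stats::ave(seq_len(n), cls, FUN = seq_along)),
      sex = sex, age_class = age, habitat = h,
      group_id = paste0(ifelse(h == "continuous", "CF", "FR"),
                        1 + (seq_len(n) - 1) %% 3),
      stringsAsFactors = FALSE
    )
  }))
}

#' Generate class-graded, optionally nested diets
#'
#' Individuals are processed from broadest class to narrowest (adults first).
#' Each diet size is drawn binomially from the habitat flora with the class's
#' breadth fraction (at least 1). Each partner is then taken, with
#' probability `nu`, as the most popular not-yet-chosen plant of the union of
#' plants used by strictly broader-diet classes (popularity = plant degree
#' among those classes, ties broken at random), producing decreasing-fill
#' nested structure; otherwise it is drawn uniformly from the unchosen
#' flora. Individuals of the broadest class have no broader pool and always
#' sample uniformly. At `nu = 1` every diet is (up to pool exhaustion) a
#' prefix of the popularity ranking, so narrower diets are subsets of
#' broader ones.
#'
#' @param individuals Roster rows for one habitat (`individual_id`, `sex`,
#'   `age_class`).
#' @param flora_species Character vector of available plant species.
#' @param nu Nestedness knob in [0, 1].
#' @param class_breadths Named breadth fractions per class.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Binary interaction matrix, rows in roster order.
#' @export
generate_diets <- function(individuals, flora_species, nu, class_breadths,
                           seed = NULL) {
  if (length(flora_species) == 0) stop("empty flora", call. = FALSE)
  cls <- class_label(individuals$sex, individuals$age_class)
  if (any(!cls %in% names(class_breadths))) stop("unknown class in roster", call. = FALSE)
  ord <- order(-class_breadths[cls], individuals$individual_id)
  P <- length(flora_species)
  web <- matrix(0L, nrow(individuals), P,
                dimnames = list(individuals$individual_id, flora_species))
  draw <- function() {
    deg <- stats::setNames(numeric(P), flora_species)  # running plant degrees
    deg_broader <- deg   # snapshot: degrees contributed by broader classes only
    level <- Inf
    for (i in ord) {
      b <- class_breadths[[cls[i]]]
      if (b < level) { deg_broader <- deg; level <- b }
      size <- max(1L, stats::rbinom(1, P, b))
      chosen <- character(0)
      for (s in seq_len(size)) {
        pool_used <- setdiff(flora_species[deg_broader > 0], chosen)
        pool_any <- setdiff(flora_species, chosen)
        pick <- if (length(pool_used) > 0 && stats::runif(1) < nu) {
          top <- pool_used[deg_broader[pool_used] == max(deg_broader[pool_used])]
          if (length(top) == 1) top else sample(top, 1)
        } else {
          if (length(pool_any) == 1) pool_any else sample(pool_any, 1)
        }
        chosen <- c(chosen, pick)
        deg[pick] <- deg[pick] + 1
      }
      web[i, chosen] <- 1L
    }
    web
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Expand a binary diet matrix into feeding records with items and durations.
# Raw durations are gamma(shape) draws, then rescaled by iterative
# proportional fitting so that both margins approximate their configured
# targets: total time per age group, and the habitat-level share of feeding
# time per plant item (renormalized over the items actually realized).
diets_to_records <- function(web, individuals, habitat, cfg, seed) {
  with_seed(seed, {
    item_sets <- stats::setNames(
      strsplit(cfg$flora[[paste0(habitat, "_items")]], "\\s+"), cfg$flora$species
    )
    w_items <- cfg$item_weights[[habitat]]
    links <- which(web > 0, arr.ind = TRUE)
    if (nrow(links) == 0) stop("no links to expand", call. = FALSE)
    rows <- lapply(seq_len(nrow(links)), function(k) {
      id <- rownames(web)[links[k, 1]]
      sp <- colnames(web)[links[k, 2]]
      ind <- individuals[individuals$individual_id == id, ]
      n_rec <- 1L + stats::rpois(1, cfg$records_per_link_lambda)
      set <- item_sets[[sp]]
      wt <- w_items[set]
      wt[is.na(wt)] <- 0
      if (sum(wt) <= 0) wt <- rep(1, length(set))
      data.frame(
        habitat = habitat, site_id = ind$group_id, individual_id = id,
        sex = ind$sex, age_class = ind$age_class, plant_species = sp,
        item = sample(set, n_rec, replace = TRUE, prob = wt),
        duration = stats::rgamma(n_rec, shape = cfg$duration_shape),
        stringsAsFactors = FALSE
      )
    })
    rec <- do.call(rbind, rows)
    class_t <- cfg$time_targets_minutes[[habitat]]
    class_t <- class_t[class_t > 0 & names(class_t) %in% rec$age_class]
    total <- sum(class_t)
    iw <- w_items[unique(rec$item)]
    iw[is.na(iw) | iw <= 0] <- min(iw[iw > 0], na.rm = TRUE) / 10
    item_t <- total * iw / sum(iw)
    rec <- rec[rec$age_class %in% names(class_t), , drop = FALSE]
    for (iter in 1:50) {
      for (age in names(class_t)) {
        sel <- rec$age_class == age
        rec$duration[sel] <- rec$duration[sel] * class_t[age] / sum(rec$duration[sel])
      }
      for (it in names(item_t)) {
        sel <- rec$item == it
        rec$duration[sel] <- rec$duration[sel] * item_t[it] / sum(rec$duration[sel])
      }
    }
    # final pass so class totals hit their targets exactly
    for (age in names(class_t)) {
      sel <- rec$age_class == age
      rec$duration[sel] <- rec$duration[sel] * class_t[age] / sum(rec$duration[sel])
    }
    rec
  })
}

#' Generate vegetation transects
#'
#' Lays out `n_transects` 50 x 2 m transects in each of `n_sites` sites per
#' habitat. Stem counts per transect are Poisson, species are drawn from a
#' lognormal-abundance community containing the habitat's food flora plus
#' extra non-food species, and dbh is `10 + gamma` cm (the >= 10 cm sampling
#' rule).
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed; default derived from the config seed.
#' @return Data.frame of transect records (see [read_transects()]).
#' @export
generate_transects <- function(config, seed = sub_seed(config$seed, 6)) {
  cm <- config$community
  with_seed(seed, {
    out <- list()
    for (h in habitats()) {
      food <- config$flora$species[config$flora[[h]]]
      pool <- c(food, sprintf("nonfood%02d", seq_len(cm$pool_extra)))
      abun <- stats::rlnorm(length(pool), meanlog = 0, sdlog = cm$abundance_sdlog)
      for (s in seq_len(cm$n_sites)) {
        site <- paste0(ifelse(h == "continuous", "CF", "FR"), s)
        cx <- s * 2000 + ifelse(h == "continuous", 0, 50000)
        for (tr in seq_len(cm$n_transects)) {
          n <- stats::rpois(1, cm$stems_per_transect)
          if (n == 0) next
          out[[length(out) + 1]] <- data.frame(
            site_id = site, habitat = h, transect_id = paste0("T", tr),
            x = cx + stats::runif(1, -300, 300),
            y = stats::runif(1, -300, 300),
            species = sample(pool, n, replace = TRUE, prob = abun),
            dbh = 10 + stats::rgamma(n, shape = cm$dbh_shape, scale = cm$dbh_scale),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a full synthetic study
#'
#' Produces the roster of individuals (deterministic from the census), the
#' flora, per-habitat feeding observation records (diets expanded into
#' records with items and durations), and vegetation transects. Each stage
#' consumes an independent sub-stream of the master seed: the roster and
#' flora never depend on `nu`, and transects never depend on the diets.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `individuals`, `flora`, `observations`, `transects`,
#'   `config`.
#' @examples
#' sc <- generate_scenario(synthetic_config("generic", seed = 7))
#' table(sc$individuals$habitat)
#' @export
generate_scenario <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  master <- config$seed
  individuals <- roster_individuals(config$census)
  obs <- list()
  for (h in habitats()) {
    ind_h <- individuals[individuals$habitat == h, , drop = FALSE]
    if (nrow(ind_h) == 0) next
    flora_h <- config$flora$species[config$flora[[h]]]
    k_diet <- if (h == "continuous") 3L else 4L
    web <- generate_diets(ind_h, flora_h, config$nu, config$class_breadths,
                          seed = sub_seed(master, k_diet))
    obs[[h]] <- diets_to_records(web, ind_h, h, config,
                                 seed = sub_seed(master, k_diet + 7L))
  }
  observations <- do.call(rbind, obs)
  observations$record_id <- seq_len(nrow(observations))
  observations <- observations[, obs_columns]
  rownames(observations) <- NULL
  list(individuals = individuals, flora = config$flora,
       observations = observations,
       transects = generate_transects(config, seed = sub_seed(master, 6L)),
       config = config)
}
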