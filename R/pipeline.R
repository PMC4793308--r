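# End-to-end orchestration: from observations + transects (real or synthetic)
# to the four published table shapes, the null-model tests, the bipartite
# plots, and a run manifest.

#' Pipeline configuration
#'
#' @param preset Synthetic preset passed to [synthetic_config()] when no
#'   input files are given; ignored otherwise.
#' @param observations,transects Optional paths to input CSVs; when both are
#'   `NULL` a synthetic scenario is generated.
#' @param weighting Cell weighting for the interaction matrices
#'   (`"count"`, `"minutes"`).
#' @param n_randomizations Null Model II randomizations (default 1000).
#' @param n_cp_runs Core-periphery fits per network (default 20).
#' @param alpha Significance level for flagging nestedness (default 0.05).
#' @param nu Nestedness knob for the synthetic preset.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "paper_like", observations = NULL,
                            transects = NULL, weighting = "count",
                            n_randomizations = 1000, n_cp_runs = 20,
                            alpha = 0.05, nu = 0.8, seed = 1L,
                            out_dir = tempfile("howlernet_run_")) {
  structure(list(preset = preset, observations = observations,
                 transects = transects, weighting = weighting,
                 n_randomizations = n_randomizations, n_cp_runs = n_cp_runs,
                 alpha = alpha, nu = nu, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequence: load or simulate observations and transects; per habitat build
#' the interaction matrix; compute the community table (transect attributes),
#' the top-10 IVI ranking, the species x item x core/periphery table, and the
#' network-attribute table with the Null Model II nestedness test; export a
#' bipartite plot per habitat and a JSON manifest of settings. Every
#' randomized stage receives its own sub-stream of the master seed, so the
#' whole bundle is a pure function of (inputs, config).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-habitat results (`matrices`,
#'   `attributes`, `null_tests`, `core_periphery`, `ivi`, `community`,
#'   `items`) plus `individuals`, `out_dir`, and the paths written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[howlernet] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  individuals <- NULL
  if (is.null(config$observations)) {
    scen <- stage("simulate", {
      sc <- synthetic_config(config$preset, nu = config$nu, seed = config$seed)
      generate_scenario(sc)
    })
    observations <- scen$observations
    transects <- scen$transects
    individuals <- scen$individuals
    log_stage("simulated %d observation records, %d stems",
              nrow(observations), nrow(transects))
  } else {
    observations <- stage("read_observations", read_observations(config$observations))
    transects <- if (is.null(config$transects)) NULL else
      stage("read_transects", read_transects(config$transects))
    log_stage("read %d observation records", nrow(observations))
  }

  res <- list(matrices = list(), attributes = list(), null_tests = list(),
              core_periphery = list(), ivi = list(), community = list(),
              items = NULL, individuals = individuals,
              out_dir = config$out_dir)
  hs <- intersect(habitats(), unique(observations$habitat))

  for (h in hs) {
    web <- stage("matrix", build_interaction_matrix(
      observations, h, weighting = config$weighting, individuals = individuals))
    res$matrices[[h]] <- web
    write_matrix_csv(web, file.path(config$out_dir, paste0("matrix_", h, ".csv")))
    log_stage("%s: %d monkeys x %d plants, %d links", h, nrow(web), ncol(web),
              sum(web > 0))

    attrs <- stage("attributes", network_attributes(web))
    res$attributes[[h]] <- attrs
    nt <- stage("nullmodel", nestedness_test(
      as_binary(web), n = config$n_randomizations,
      seed = sub_seed(config$seed, 20 + match(h, habitats()))))
    res$null_tests[[h]] <- nt
    cp <- stage("coreperiphery", core_periphery_occurrence(
      as_binary(web), n_runs = config$n_cp_runs,
      seed = sub_seed(config$seed, 30 + match(h, habitats()))))
    res$core_periphery[[h]] <- cp

    if (!is.null(transects)) {
      ivi <- stage("ivi", compute_ivi(transects, h))
      res$ivi[[h]] <- ivi
      write_tsv(utils::head(ivi, 10),
                file.path(config$out_dir, paste0("table2_ivi_top10_", h, ".tsv")))
      tr <- transects[transects$habitat == h, ]
      per_site <- split(tr, tr$site_id)
      res$community[[h]] <- data.frame(
        habitat = h,
        mean_species_richness = mean(vapply(per_site, function(d)
          length(unique(d$species)), numeric(1))),
        mean_tree_density = mean(vapply(per_site, nrow, numeric(1))),
        ivi_food_species = sum(ivi$ivi[ivi$species %in% observations$plant_species]),
        stringsAsFactors = FALSE
      )
    }

    plot_bipartite(web, individuals,
                   file = file.path(config$out_dir, paste0("network_", h, ".png")))
  }

  # Table-4 shaped attribute summary across habitats.
  attr_tab <- data.frame(metric = c(
    "No. of monkeys", "No. of plant species", "Nestedness (NODF-metric)",
    "Links per species", "Connectance (C)", "Interaction diversity",
    "Resource selectivity (H2')"
  ))
  for (h in hs) {
    a <- res$attributes[[h]]
    attr_tab[[h]] <- c(a$n_rows, a$n_cols, round(a$nodf, 2),
                       round(a$links_per_species, 2), round(a$connectance, 2),
                       round(a$interaction_diversity, 2),
                       round(a$h2_selectivity, 2))
  }
  res$attribute_table <- attr_tab
  write_tsv(attr_tab, file.path(config$out_dir, "table4_attributes.tsv"))

  # Table-3 shaped: per plant, items consumed and core/periphery occurrence.
  items_tab <- NULL
  for (h in hs) {
    occ <- res$core_periphery[[h]]$occurrence
    occ <- occ[occ$side == "plant", ]
    it <- stats::aggregate(
      item ~ plant_species,
      data = observations[observations$habitat == h, ],
      FUN = function(x) paste(names(sort(table(x), decreasing = TRUE)),
                              collapse = " "))
    tab <- merge(data.frame(species = occ$node,
                            percent_core = occ$percent_core,
                            percent_periphery = occ$percent_periphery,
                            stringsAsFactors = FALSE),
                 stats::setNames(it, c("species", "items")), all.x = TRUE)
    tab$habitat <- h
    items_tab <- rbind(items_tab, tab[, c("habitat", "species", "items",
                                          "percent_core", "percent_periphery")])
  }
  res$items <- items_tab
  write_tsv(items_tab, file.path(config$out_dir, "table3_core_periphery.tsv"))

  if (length(res$community) > 0) {
    write_tsv(do.call(rbind, res$community),
              file.path(config$out_dir, "table1_community.tsv"))
  }

  # Null-test summaries as JSON alongside the manifest.
  nulls <- lapply(res$null_tests, function(x)
    list(observed_nodf = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, p_value = x$p_value,
         significant = x$p_value < config$alpha,
         n_randomizations = x$n_randomizations))
  jsonlite::write_json(nulls, file.path(config$out_dir, "nestedness_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "howlernet",
    version = as.character(utils::packageVersion("howlernet")),
    r_version = R.version.string,
    seed = config$seed,
    settings = config[c("preset", "weighting", "n_randomizations",
                        "n_cp_runs", "alpha", "nu")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Two-column bipartite network plot
#'
#' Monkeys on the left (glyph encodes the six age/sex classes: squares =
#' adults, triangles = juveniles, diamonds = infants; filled = male, open =
#' female), plant species on the right, one line segment per link.
#'
#' @param web Non-empty interaction matrix.
#' @param individuals Optional roster giving `sex` and `age_class` per row
#'   label; without it all monkeys share one glyph.
#' @param file Optional PNG path; `NULL` draws on the active device.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_bipartite <- function(web, individuals = NULL, file = NULL) {
  check_web(web)
  if (sum(web) == 0) stop("empty network: nothing to plot", call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = max(600, 22 * ncol(web)))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  R <- nrow(web); C <- ncol(web)
  ry <- seq(0, 1, length.out = R + 2)[2:(R + 1)]
  cy <- seq(0, 1, length.out = C + 2)[2:(C + 1)]
  glyphs <- c("adult-F" = 22, "adult-M" = 15, "juvenile-F" = 24,
              "juvenile-M" = 17, "infant-F" = 23, "infant-M" = 18)
  pch <- rep(21, R)
  if (!is.null(individuals)) {
    idx <- match(rownames(web), individuals$individual_id)
    cls <- class_label(individuals$sex[idx], individuals$age_class[idx])
    pch <- unname(glyphs[cls])
    pch[is.na(pch)] <- 21
  }
  oldpar <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(oldpar), add = TRUE)
  graphics::plot(NULL, xlim = c(-0.35, 1.45), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "", main = "Monkey-plant network")
  links <- which(web > 0, arr.ind = TRUE)
  graphics::segments(0.02, ry[links[, 1]], 0.98, cy[links[, 2]],
                     col = grDevices::grey(0.6))
  graphics::points(rep(0, R), ry, pch = pch, bg = "white", cex = 1.4)
  graphics::points(rep(1, C), cy, pch = 21, bg = "forestgreen", cex = 1.1)
  if (!is.null(rownames(web))) {
    graphics::text(-0.03, ry, rownames(web), adj = 1, cex = 0.6)
  }
  if (!is.null(colnames(web))) {
    graphics::text(1.03, cy, colnames(web), adj = 0, cex = 0.6)
  }
  graphics::legend("topleft", legend = names(glyphs), pch = unname(glyphs),
                   pt.bg = "white", bty = "n", cex = 0.7)
  invisible(file)
}
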