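# Vegetation-side and behavioural statistics: importance value index from
# transects, Jaccard similarity, permutation Mantel test, transformed t-tests,
# item-time fractions, and the nested ANOVA of angular-transformed fractions.

#' Angular (arcsine square root) transform
#'
#' \eqn{\arcsin\sqrt{p}} in radians; monotone on [0, 1], mapping 0 to 0 and
#' 1 to \eqn{\pi/2}. The standard variance-stabilizing transform for
#' proportions before ANOVA / t-tests.
#'
#' @param p Values in [0, 1].
#' @return Transformed values in [0, pi/2].
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("arcsine transform requires values in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Importance value index (IVI) per species
#'
#' For each tree species in a habitat's transects, computes relative density
#' (share of stems), relative frequency (share of species-in-transect
#' occurrences), and relative dominance (share of basal area,
#' \eqn{\pi (dbh/2)^2}), and averages the three, so the IVI sums to 1 over
#' species within a habitat.
#'
#' @param transects Data.frame of transect records (see [read_transects()]).
#' @param habitat `"continuous"` or `"fragment"`.
#' @return Data.frame sorted by decreasing `ivi` with columns `species`,
#'   `relative_density`, `relative_frequency`, `relative_dominance`, `ivi`.
#' @export
compute_ivi <- function(transects, habitat) {
  habitat <- match.arg(habitat, habitats())
  transects <- validate_transects(transects)
  tr <- transects[transects$habitat == habitat, , drop = FALSE]
  if (nrow(tr) == 0) stop(sprintf("no trees recorded in habitat '%s'", habitat),
                          call. = FALSE)
  sp <- sort(unique(tr$species))
  stems <- table(factor(tr$species, levels = sp))
  tkey <- paste(tr$site_id, tr$transect_id)
  occ <- table(factor(unique(data.frame(s = tr$species, t = tkey))$s, levels = sp))
  basal <- tapply(pi * (tr$dbh / 2)^2, factor(tr$species, levels = sp), sum)
  basal[is.na(basal)] <- 0
  out <- data.frame(
    species = sp,
    relative_density = as.numeric(stems / sum(stems)),
    relative_frequency = as.numeric(occ / sum(occ)),
    relative_dominance = as.numeric(basal / sum(basal)),
    stringsAsFactors = FALSE
  )
  out$ivi <- (out$relative_density + out$relative_frequency +
                out$relative_dominance) / 3
  out[order(-out$ivi, out$species), , drop = FALSE]
}

#' Jaccard similarity of two species sets
#'
#' @param a,b Character vectors of species names (duplicates ignored).
#' @return \eqn{|A \cap B| / |A \cup B|} in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) stop("Jaccard undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / length(u)
}

check_dist <- function(d, what) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) ||
      any(d < 0)) {
    stop(what, " must be a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  }
  d
}

#' Permutation Mantel test
#'
#' Pearson correlation between the upper triangles of two distance matrices,
#' with significance from joint row/column permutations of the second matrix.
#' The p-value is two-tailed on |r| and includes the identity permutation in
#' the count: `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @param d1,d2 Distance matrices (`dist` objects or symmetric matrices) over
#'   the same labels in the same order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Object of class `stat_test_result` with `statistic` (r), `df`
#'   (number of distance pairs minus 2), `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- check_dist(d1, "d1"); d2 <- check_dist(d2, "d2")
  if (nrow(d1) != nrow(d2)) stop("distance matrices must match in size", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrices must share labels in the same order", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  ut <- upper.tri(d1)
  x <- d1[ut]
  if (stats::sd(x) == 0 || stats::sd(d2[ut]) == 0) {
    stop("zero variance among distances: Mantel statistic undefined", call. = FALSE)
  }
  r_obs <- stats::cor(x, d2[ut])
  perm_r <- function() {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(nrow(d2))
      stats::cor(x, d2[ord, ord][ut])
    }, numeric(1))
  }
  r_perm <- if (is.null(seed)) perm_r() else with_seed(seed, perm_r())
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  structure(list(statistic = r_obs, df = sum(ut) - 2, p_value = p,
                 n_perm = n_perm, transform_applied = "none",
                 method = "Mantel (permutation, two-tailed)"),
            class = "stat_test_result")
}

#' Two-sample t-test on transformed data
#'
#' Student's two-sample t-test (pooled variance, `df = n1 + n2 - 2`) after a
#' `log(x + 1)` or angular (arcsine square root) transform, the conventions
#' for count-like and proportion data respectively.
#'
#' @param x,y Numeric samples (at least two values each); for
#'   `"arcsine_sqrt"` all values must lie in [0, 1].
#' @param transform `"log1p"`, `"arcsine_sqrt"`, or `"none"`.
#' @return Object of class `stat_test_result` with `statistic` (t), `df`,
#'   `p_value`, `transform_applied`.
#' @export
transformed_t_test <- function(x, y, transform = c("log1p", "arcsine_sqrt", "none")) {
  transform <- match.arg(transform)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least two values", call. = FALSE)
  }
  f <- switch(transform, log1p = log1p, arcsine_sqrt = arcsine_sqrt, none = identity)
  tt <- stats::t.test(f(x), f(y), var.equal = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, transform_applied = transform,
                 method = "two-sample t (pooled variance)"),
            class = "stat_test_result")
}

#' Fraction of feeding time per plant item
#'
#' @param records Observation records with positive total duration.
#' @return Data.frame with `habitat`, `item`, `minutes`, `fraction`; fractions
#'   sum to 1 within each habitat.
#' @export
item_time_fractions <- function(records) {
  records <- validate_observations(records)
  if (nrow(records) == 0 || sum(records$duration) <= 0) {
    stop("no feeding time recorded", call. = FALSE)
  }
  agg <- stats::aggregate(duration ~ habitat + item, data = records, FUN = sum)
  names(agg)[names(agg) == "duration"] <- "minutes"
  tot <- tapply(agg$minutes, agg$habitat, sum)
  agg$fraction <- agg$minutes / as.numeric(tot[agg$habitat])
  agg[order(agg$habitat, -agg$fraction), , drop = FALSE]
}

#' Nested ANOVA of angular-transformed fractions
#'
#' Fits the nested design `value ~ habitat + item-within-habitat` on
#' arcsine-square-root transformed proportions via [stats::aov()] and reports
#' the F tests for the habitat effect and for items nested within habitats,
#' both against the residual mean square. Degenerate data with zero total
#' variation report `F = 0`, `p = 1` by convention.
#'
#' @param values Proportions in [0, 1].
#' @param habitat Factor (or coercible) of habitat per value.
#' @param item Factor of plant item per value (nested within habitat).
#' @return List with `habitat` and `item_within_habitat`, each a
#'   `stat_test_result` (`statistic` = F, `df` = c(num, den)), plus `table`
#'   (the full ANOVA table).
#' @export
nested_anova <- function(values, habitat, item) {
  y <- arcsine_sqrt(values)
  habitat <- factor(habitat)
  item <- factor(item)
  dat <- data.frame(y = y, habitat = habitat, item = item)
  fit <- stats::aov(y ~ habitat + habitat:item, data = dat)
  tab <- summary(fit)[[1]]
  res_row <- nrow(tab)
  degenerate <- sum(tab[, "Sum Sq"]) < 1e-12
  mk <- function(row) {
    if (degenerate) {
      f <- 0; p <- 1
    } else {
      f <- tab[row, "F value"]; p <- tab[row, "Pr(>F)"]
    }
    structure(list(statistic = f,
                   df = c(tab[row, "Df"], tab[res_row, "Df"]),
                   p_value = p, transform_applied = "arcsine_sqrt",
                   method = "nested ANOVA"),
              class = "stat_test_result")
  }
  list(habitat = mk(1), item_within_habitat = mk(2), table = tab)
}

#' @export
print.stat_test_result <- function(x, ...) {
  df <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, P = %.4g (transform: %s)\n",
              x$method, x$statistic, df, x$p_value, x$transform_applied))
  invisible(x)
}
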