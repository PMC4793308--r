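# Network-level attributes: connectance, mean links per species, Shannon
# interaction diversity, and the standardized two-dimensional specialization
# index H2'.

#' Connectance
#'
#' The proportion of realized links among all possible ones: the number of
#' non-zero cells divided by the number of cells in the matrix.
#'
#' @param web Interaction matrix.
#' @return Fraction in [0, 1] (full precision; round for reporting).
#' @export
connectance <- function(web) {
  check_web(web)
  sum(web > 0) / length(web)
}

#' Mean number of links per species
#'
#' Realized links divided by the total number of nodes (rows + columns).
#'
#' @param web Interaction matrix.
#' @return Non-negative number.
#' @export
links_per_species <- function(web) {
  check_web(web)
  sum(web > 0) / (nrow(web) + ncol(web))
}

#' Shannon interaction diversity
#'
#' Shannon entropy (natural log) of the interaction weights,
#' \eqn{H = -\sum_{ij} p_{ij} \ln p_{ij}} with \eqn{p_{ij} = w_{ij}/\sum w}.
#' For a binary matrix this equals \eqn{\ln L} with L the number of links.
#'
#' @param web Interaction matrix with positive total weight.
#' @param weighted If `FALSE` (default) the matrix is binarized first, so the
#'   result is \eqn{\ln L}; if `TRUE` the weights are used as given.
#' @return Entropy in nats.
#' @export
interaction_diversity <- function(web, weighted = FALSE) {
  check_web(web)
  if (!weighted) web <- as_binary(web)
  tot <- sum(web)
  if (tot <= 0) stop("all-zero matrix: interaction diversity undefined", call. = FALSE)
  p <- web[web > 0] / tot
  -sum(p * log(p))
}

shannon <- function(w) {
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

#' Entropy extremes compatible with marginal totals
#'
#' Computes the minimum and maximum two-dimensional Shannon entropy over
#' matrices whose row and column sums equal the given marginals; these bound
#' the observed interaction entropy and normalize [h2_selectivity()].
#'
#' With `method = "exhaustive"` all non-negative integer matrices with the
#' given marginals are enumerated (exact; feasible only for small problems).
#' With `method = "heuristic"`:
#' \itemize{
#'   \item the maximum comes from the maximally even table: expected values
#'     \eqn{r_i c_j / m}, and when `integer = TRUE` the closest integer
#'     allocation (floors of the expected values, remaining units assigned
#'     greedily by largest fractional remainder subject to the marginals);
#'   \item the minimum comes from greedy packing: repeatedly place
#'     \eqn{\min(r_i, c_j)} in the cell of the currently largest remaining
#'     row and column totals.
#' }
#' `method = "auto"` (default) uses the exhaustive computation when the table
#' has at most 16 cells and total weight at most 12, the heuristics otherwise.
#'
#' @param row_totals,col_totals Non-negative marginal totals with equal sums.
#' @param method `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param integer Constrain the evenness maximizer to integer tables
#'   (default `TRUE`, the published convention for count data). With `FALSE`
#'   the continuous extremes are used, which are invariant to rescaling all
#'   weights.
#' @return List with `h2_min` and `h2_max` (nats), `h2_min <= h2_max`.
#' @export
h2_bounds <- function(row_totals, col_totals,
                      method = c("auto", "exhaustive", "heuristic"),
                      integer = TRUE) {
  method <- match.arg(method)
  m <- sum(row_totals)
  if (abs(m - sum(col_totals)) > 1e-9) {
    stop("row and column totals must have equal sums", call. = FALSE)
  }
  if (m <= 0) stop("total weight must be positive", call. = FALSE)
  if (method == "auto") {
    small <- length(row_totals) * length(col_totals) <= 16 && m <= 12 &&
      integer && all(abs(row_totals - round(row_totals)) < 1e-9) &&
      all(abs(col_totals - round(col_totals)) < 1e-9)
    method <- if (small) "exhaustive" else "heuristic"
  }
  if (method == "exhaustive") {
    ext <- entropy_extremes_exhaustive(round(row_totals), round(col_totals))
    return(list(h2_min = ext[1], h2_max = ext[2]))
  }
  list(h2_min = shannon(pack_min_entropy(row_totals, col_totals)),
       h2_max = if (integer) {
         shannon(even_integer_allocation(row_totals, col_totals))
       } else {
         shannon(outer(row_totals, col_totals) / m)
       })
}

# Greedy minimum-entropy packing: place min(remaining row, remaining col) in
# the cell of the largest remaining marginals until all mass is allocated.
pack_min_entropy <- function(r, cmarg) {
  out <- matrix(0, length(r), length(cmarg))
  repeat {
    i <- which.max(r); j <- which.max(cmarg)
    v <- min(r[i], cmarg[j])
    if (v <= 0) break
    out[i, j] <- out[i, j] + v
    r[i] <- r[i] - v
    cmarg[j] <- cmarg[j] - v
  }
  out
}

# Integer allocation closest to the independence table r_i c_j / m: floors
# first, then distribute the remaining units one at a time to the feasible
# cell (row and column still short) with the largest fractional remainder.
even_integer_allocation <- function(r, cmarg) {
  m <- sum(r)
  e <- outer(r, cmarg) / m
  a <- floor(e)
  frac <- e - a
  rdef <- r - rowSums(a)
  cdef <- cmarg - colSums(a)
  while (sum(rdef) > 1e-9) {
    feas <- outer(rdef > 1e-9, cdef > 1e-9, "&")
    if (!any(feas)) break   # non-integer marginals can leave slack; stop even
    cand <- which(feas, arr.ind = TRUE)
    pick <- cand[which.max(frac[cand]), , drop = FALSE]
    a[pick] <- a[pick] + 1
    frac[pick] <- frac[pick] - 1
    rdef[pick[1]] <- rdef[pick[1]] - 1
    cdef[pick[2]] <- cdef[pick[2]] - 1
  }
  a
}

# Exact entropy extremes by depth-first enumeration of all non-negative
# integer matrices with the given marginals. Exponential; guarded by callers.
entropy_extremes_exhaustive <- function(r, cmarg) {
  n <- length(r); k <- length(cmarg)
  best <- c(Inf, -Inf)
  cells <- matrix(0, n, k)
  recurse <- function(i, ctot) {
    if (i > n) {
      h <- shannon(cells)
      if (h < best[1]) best[1] <<- h
      if (h > best[2]) best[2] <<- h
      return(invisible())
    }
    # enumerate compositions of r[i] over k columns bounded by ctot
    comp <- function(j, left) {
      if (j == k) {
        if (left <= ctot[k]) {
          cells[i, k] <<- left
          recurse(i + 1, ctot - cells[i, ])
          cells[i, k] <<- 0
        }
        return(invisible())
      }
      for (v in 0:min(left, ctot[j])) {
        cells[i, j] <<- v
        comp(j + 1, left - v)
      }
      cells[i, j] <<- 0
    }
    comp(1, r[i])
  }
  recurse(1, cmarg)
  best
}

#' Network-level specialization H2'
#'
#' The standardized two-dimensional Shannon index
#' \eqn{H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})}, where \eqn{H_2} is the
#' entropy of the interaction weights and the extremes are the entropy bounds
#' compatible with the observed marginal totals (see [h2_bounds()]). Ranges
#' from 0 (extreme generalization: partners used in proportion to
#' availability) to 1 (extreme specialization). Returns 0 when the bounds
#' coincide (degenerate marginals leave nothing to standardize).
#'
#' @param web Weighted interaction matrix with positive total.
#' @inheritParams h2_bounds
#' @return Value in [0, 1] (clamped).
#' @references Bluthgen N, Menzel F, Bluthgen N (2006) Measuring
#'   specialization in species interaction networks. BMC Ecology 6:9.
#' @export
h2_selectivity <- function(web, method = c("auto", "exhaustive", "heuristic"),
                           integer = TRUE) {
  check_web(web)
  if (sum(web) <= 0) stop("all-zero matrix: H2' undefined", call. = FALSE)
  b <- h2_bounds(rowSums(web), colSums(web), method = match.arg(method),
                 integer = integer)
  denom <- b$h2_max - b$h2_min
  if (denom <= 1e-12) return(0)
  min(1, max(0, (b$h2_max - shannon(web)) / denom))
}

#' Per-class diet summary
#'
#' Summarizes partner use per age/sex class: number of individuals, species
#' richness of the class's pooled diet, degree statistics, and (when records
#' are supplied) the number of distinct plant items consumed.
#'
#' @param web Interaction matrix (rows = individuals).
#' @param individuals Data.frame with columns `individual_id`, `sex`,
#'   `age_class` covering every row label of `web`.
#' @param records Optional observation records for item counts.
#' @return Data.frame with one row per class present: `class`,
#'   `n_individuals`, `n_species` (pooled partner richness), `mean_degree`,
#'   `min_degree`, `max_degree`, `n_items` (NA without records).
#' @export
class_diet_summary <- function(web, individuals, records = NULL) {
  check_web(web)
  idx <- match(rownames(web), individuals$individual_id)
  if (anyNA(idx)) {
    stop("individual(s) without class information: ",
         paste(rownames(web)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cls <- class_label(individuals$sex[idx], individuals$age_class[idx])
  deg <- rowSums(web > 0)
  out <- do.call(rbind, lapply(split(seq_len(nrow(web)), cls), function(rows) {
    sub <- web[rows, , drop = FALSE]
    data.frame(
      class = cls[rows[1]],
      n_individuals = length(rows),
      n_species = sum(colSums(sub > 0) > 0),
      mean_degree = mean(deg[rows]),
      min_degree = min(deg[rows]),
      max_degree = max(deg[rows]),
      stringsAsFactors = FALSE
    )
  }))
  out$n_items <- NA_integer_
  if (!is.null(records)) {
    rcls <- class_label(records$sex, records$age_class)
    items <- vapply(out$class, function(cl) {
      length(unique(records$item[rcls == cl &
                                   records$individual_id %in% rownames(web)]))
    }, integer(1))
    out$n_items <- items
  }
  rownames(out) <- NULL
  out[order(match(out$class, age_sex_classes())), , drop = FALSE]
}

#' Table of network attributes
#'
#' Bundles the five network attributes plus node and link counts for one
#' interaction matrix, in the shape of the published attribute table.
#' Nestedness and interaction diversity are computed on the binary view
#' (the qualitative approach); H2' on the weights as given.
#'
#' @param web Weighted interaction matrix.
#' @return An object of class `network_attributes`: a list with `n_rows`,
#'   `n_cols`, `n_links`, `nodf`, `links_per_species`, `connectance`,
#'   `interaction_diversity`, `h2_selectivity`.
#' @export
network_attributes <- function(web) {
  check_web(web, min_dim = 2L)
  bin <- as_binary(web)
  structure(list(
    n_rows = nrow(web),
    n_cols = ncol(web),
    n_links = sum(bin),
    nodf = nodf(bin),
    links_per_species = links_per_species(web),
    connectance = connectance(web),
    interaction_diversity = interaction_diversity(web, weighted = FALSE),
    h2_selectivity = h2_selectivity(web)
  ), class = "network_attributes")
}

#' @export
print.network_attributes <- function(x, ...) {
  cat("Network attributes\n")
  cat(sprintf("  No. of monkeys           %d\n", x$n_rows))
  cat(sprintf("  No. of plant species     %d\n", x$n_cols))
  cat(sprintf("  Nestedness (NODF-metric) %.2f\n", x$nodf))
  cat(sprintf("  Links per species        %.2f\n", x$links_per_species))
  cat(sprintf("  Connectance (C)          %.2f\n", x$connectance))
  cat(sprintf("  Interaction diversity    %.2f\n", x$interaction_diversity))
  cat(sprintf("  Resource selectivity (H2') %.2f\n", x$h2_selectivity))
  invisible(x)
}
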