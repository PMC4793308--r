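# Independent oracles and small builders used across the suite. Everything
# here is deliberately naive (double loops, full enumeration, textbook
# formulas) and separate from the package's implementations.

# NODF by literal double loops over ordered pairs.
nodf_bruteforce <- function(m) {
  pair_sum <- function(m) {
    s <- 0
    f <- rowSums(m)
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(nrow(m))) {
        if (i < j) {
          hi <- if (f[i] >= f[j]) i else j
          lo <- if (f[i] >= f[j]) j else i
          if (f[hi] > f[lo] && f[lo] > 0) {
            shared <- sum(m[hi, ] == 1 & m[lo, ] == 1)
            s <- s + 100 * shared / f[lo]
          }
        }
      }
    }
    s
  }
  (pair_sum(m) + pair_sum(t(m))) /
    (nrow(m) * (nrow(m) - 1) / 2 + ncol(m) * (ncol(m) - 1) / 2)
}

# All non-negative integer matrices with the given marginals, as a list.
enumerate_margin_matrices <- function(rt, ct) {
  n <- length(rt); k <- length(ct)
  out <- list()
  fill_row <- function(mat, i, colleft) {
    if (i > n) {
      out[[length(out) + 1]] <<- mat
      return(invisible())
    }
    rowfill <- function(j, left, row) {
      if (j == k) {
        if (left <= colleft[k]) {
          row[k] <- left
          mat[i, ] <- row
          fill_row(mat, i + 1, colleft - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, colleft[j])) {
        row[j] <- v
        rowfill(j + 1, left - v, row)
      }
    }
    rowfill(1, rt[i], numeric(k))
  }
  fill_row(matrix(0, n, k), 1, ct)
  out
}

entropy_oracle <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# Exact entropy extremes over all matrices with the observed marginals.
h2_bounds_oracle <- function(rt, ct) {
  hs <- vapply(enumerate_margin_matrices(rt, ct), entropy_oracle, numeric(1))
  c(min = min(hs), max = max(hs))
}

# Core-periphery fitness straight from the definition via stats::cor.
cp_fitness_oracle <- function(web, row_core, col_core) {
  x <- c(); y <- c()
  for (i in seq_len(nrow(web))) {
    for (j in seq_len(ncol(web))) {
      if (row_core[i] && col_core[j]) { x <- c(x, web[i, j]); y <- c(y, 1) }
      if (!row_core[i] && !col_core[j]) { x <- c(x, web[i, j]); y <- c(y, 0) }
    }
  }
  if (length(x) == 0 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Best achievable fitness over every core/periphery labelling.
cp_bruteforce_optimum <- function(web) {
  R <- nrow(web); C <- ncol(web)
  best <- -Inf
  for (code in 0:(2^(R + C) - 1)) {
    lab <- as.logical(bitwAnd(bitwShiftR(code, 0:(R + C - 1)), 1L))
    f <- cp_fitness_oracle(web, lab[seq_len(R)], lab[R + seq_len(C)])
    if (!is.na(f) && f > best) best <- f
  }
  best
}

# Pooled-variance two-sample t from the textbook formula.
student_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Nested ANOVA sums of squares from first principles (possibly unbalanced).
nested_anova_oracle <- function(y, habitat, item) {
  habitat <- as.character(habitat); item <- as.character(item)
  grand <- mean(y)
  ss_hab <- 0; ss_item <- 0; ss_res <- 0
  df_hab <- length(unique(habitat)) - 1
  df_item <- 0; n_cells <- 0
  for (h in unique(habitat)) {
    yh <- y[habitat == h]
    ss_hab <- ss_hab + length(yh) * (mean(yh) - grand)^2
    its <- unique(item[habitat == h])
    df_item <- df_item + length(its) - 1
    for (it in its) {
      yc <- y[habitat == h & item == it]
      ss_item <- ss_item + length(yc) * (mean(yc) - mean(yh))^2
      ss_res <- ss_res + sum((yc - mean(yc))^2)
      n_cells <- n_cells + 1
    }
  }
  df_res <- length(y) - n_cells
  list(F_habitat = (ss_hab / df_hab) / (ss_res / df_res),
       F_item = (ss_item / df_item) / (ss_res / df_res),
       df = c(df_hab, df_item, df_res))
}

# Minimal valid observation table builder.
make_obs <- function(individual_id, plant_species, habitat = "continuous",
                     item = "MF", duration = 5, sex = "F", age_class = "adult") {
  n <- max(length(individual_id), length(plant_species))
  data.frame(
    record_id = seq_len(n), habitat = habitat, site_id = "s1",
    individual_id = individual_id, sex = sex, age_class = age_class,
    plant_species = plant_species, item = item, duration = duration,
    stringsAsFactors = FALSE
  )
}

random_binary_matrix <- function(nr, nc, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}
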