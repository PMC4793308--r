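# NODF: nestedness metric based on overlap and decreasing fill.

#' NODF nestedness of a binary interaction matrix
#'
#' For every unordered pair of rows with unequal marginal totals (fills), the
#' pair contributes the percentage of the sparser row's presences that are
#' shared with the denser row; pairs with equal fills, or where the sparser
#' fill is zero, contribute 0 (the "decreasing fill" condition). The same is
#' computed over column pairs, and NODF is the grand sum divided by the number
#' of row pairs plus column pairs, giving a value in [0, 100].
#'
#' Degree-0 rows and columns participate as pair members contributing 0; they
#' are not dropped, so node counts stay faithful to the census.
#'
#' @param web Binary interaction matrix with at least 2 rows and 2 columns.
#' @return NODF as a percentage in [0, 100].
#' @examples
#' nodf(diag(3))                       # no overlap: 0
#' m <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
#' nodf(m)                             # perfectly nested: 100
#' @references Almeida-Neto M, Guimaraes P, Guimaraes PR, Loyola RD, Ulrich W
#'   (2008) A consistent metric for nestedness analysis in ecological systems.
#'   Oikos 117:1227-1239.
#' @export
nodf <- function(web) {
  check_web(web, binary = TRUE, min_dim = 2L)
  (nodf_pair_sum(web) + nodf_pair_sum(t(web))) /
    (choose(nrow(web), 2) + choose(ncol(web), 2))
}

# Sum of paired overlap terms over all unordered row pairs of m.
nodf_pair_sum <- function(m) {
  f <- rowSums(m)
  ov <- tcrossprod(m)              # shared presences per row pair
  fi <- matrix(f, nrow(m), nrow(m))
  fj <- t(fi)
  lo <- pmin(fi, fj)
  term <- matrix(0, nrow(m), nrow(m))
  valid <- (fi != fj) & (lo > 0)
  term[valid] <- 100 * ov[valid] / lo[valid]
  sum(term[upper.tri(term)])
}
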