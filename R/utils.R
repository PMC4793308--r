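# Internal helpers shared across modules.

#' Plant item codes
#'
#' The seven plant-item codes used throughout: B (bark), IF (immature fruit),
#' FL (flower), MF (mature fruit), IL (immature leaf), ML (mature leaf),
#' P (petiole).
#'
#' @return Character vector of the seven item codes.
#' @export
plant_items <- function() c("B", "IF", "FL", "MF", "IL", "ML", "P")

#' Habitat levels
#'
#' @return Character vector `c("continuous", "fragment")`.
#' @export
habitats <- function() c("continuous", "fragment")

#' Age/sex classes
#'
#' The six age/sex classes as "sex-age" labels, broadest diets first.
#'
#' @return Character vector of six class labels.
#' @export
age_sex_classes <- function() {
  c("adult-F", "adult-M", "juvenile-F", "juvenile-M", "infant-F", "infant-M")
}

class_label <- function(sex, age_class) paste(age_class, sex, sep = "-")

# Deterministic sub-seed derivation (Lehmer step), so independent stages of a
# computation consume independent, reproducible streams and changing one
# stage's draws never reshuffles another's. Kept < 2^31 - 1.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL leaves the global stream in use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Validate an interaction matrix ("web"): numeric matrix, dimnames unique,
# all entries finite and >= 0. binary = TRUE additionally requires 0/1.
check_web <- function(web, binary = FALSE, min_dim = 1L) {
  if (!is.matrix(web) || !is.numeric(web)) {
    stop("interaction matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(web) < min_dim || ncol(web) < min_dim) {
    stop(sprintf("interaction matrix must be at least %d x %d", min_dim, min_dim),
         call. = FALSE)
  }
  if (any(!is.finite(web)) || any(web < 0)) {
    stop("interaction matrix entries must be finite and non-negative", call. = FALSE)
  }
  rl <- rownames(web); cl <- colnames(web)
  if (!is.null(rl) && anyDuplicated(rl)) stop("duplicate row labels", call. = FALSE)
  if (!is.null(cl) && anyDuplicated(cl)) stop("duplicate column labels", call. = FALSE)
  if (binary && !all(web %in% c(0, 1))) {
    stop("matrix must be binary (0/1); binarize with as_binary() first", call. = FALSE)
  }
  invisible(web)
}

#' Binarize an interaction matrix
#'
#' @param web Numeric interaction matrix (individuals x plant species).
#' @return Matrix of 0/1 with the same dimnames; cells > 0 become 1.
#' @export
as_binary <- function(web) {
  check_web(web)
  out <- (web > 0) * 1
  dimnames(out) <- dimnames(web)
  out
}

# round() in R is already half-even; alias kept for intent at reporting sites.
round2 <- function(x) round(x, 2)
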