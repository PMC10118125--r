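#' @importFrom stats median sd cor dist hclust cutree prcomp phyper p.adjust
#'   nls coef resid fitted rnorm runif rpois rlnorm setNames approx predict
#' @importFrom utils head tail
#' @importFrom data.table := .N .SD data.table as.data.table
NULL

.datatable.aware <- TRUE

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# All generators route through this so they are pure functions of config+seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "solubilome_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "solubilome_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the pair-counting contingency-table formula. Used to score
#' recovery of planted trajectory classes by the clustering layer.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number, 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(sum(tab))
  expected <- sum_i * sum_j / n_pairs
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
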