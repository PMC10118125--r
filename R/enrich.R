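# Hypergeometric over-representation of annotation terms in trajectory
# clusters, tested against the detected-protein background (all proteins
# that passed the detection filters), with Benjamini-Hochberg q-values per
# cluster.

#' Upper-tail hypergeometric p-value
#'
#' Exact probability of drawing at least `k` annotated proteins when `n` are
#' drawn without replacement from a background of `N` proteins of which `K`
#' carry the annotation: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Vectorized over all four arguments.
#'
#' @param k observed members of the term in the cluster.
#' @param n cluster size.
#' @param K members of the term in the background.
#' @param N background size.
#' @return p-values in (0, 1\]; `k = 0` gives exactly 1.
#' @examples
#' hypergeometric_pvalue(4, 4, 5, 10)  # 5/210
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(as.numeric(k), len); n <- rep_len(as.numeric(n), len)
  K <- rep_len(as.numeric(K), len); N <- rep_len(as.numeric(N), len)
  bad <- k < 0 | k > n | n > N | K > N | k > K | (n - k) > (N - K)
  if (any(bad))
    stopf("impossible hypergeometric configuration (k=%g, n=%g, K=%g, N=%g)",
          k[bad][1], n[bad][1], K[bad][1], N[bad][1],
          class = "solubilome_domain_error")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Term over-representation per trajectory cluster
#'
#' One upper-tail hypergeometric test per (term, cluster) pair. The
#' background is the set of proteins considered in the analysis (those
#' passing the detection filters); annotations are restricted to the
#' background before counting, terms whose background membership falls below
#' `min_term_size` are skipped, and q-values are Benjamini-Hochberg within
#' each cluster. Results are sorted by p-value.
#'
#' @param assignments data.frame with `protein_id` and a grouping column
#'   (`class_label` if present, else `cluster_id`).
#' @param annotations an `annotation_map` (see [read_annotations()]).
#' @param background character vector of protein ids; must contain every
#'   clustered protein.
#' @param min_term_size minimum background membership for a term to be
#'   tested (default 2; avoids degenerate single-protein enrichments).
#' @return `data.table` with columns `term_id`, `term_name`,
#'   `cluster_label`, `k`, `n`, `K`, `N`, `fraction` (= k/n), `p_value`,
#'   `q_value`.
#' @export
enrich_clusters <- function(assignments, annotations, background,
                            min_term_size = 2L) {
  asg <- data.table::as.data.table(assignments)
  group_col <- if ("class_label" %in% names(asg)) "class_label" else "cluster_id"
  outside <- setdiff(asg$protein_id, background)
  if (length(outside) > 0)
    stopf("background must contain every clustered protein (%d missing, e.g. %s)",
          length(outside), outside[1], class = "solubilome_validation_error")
  ann <- data.table::as.data.table(annotations)[protein_id %in% background]
  term_k <- ann[, .(K = data.table::uniqueN(protein_id),
                    term_name = term_name[1]), by = term_id]
  skipped <- term_k[K < min_term_size]
  if (nrow(skipped) > 0)
    message(sprintf("skipping %d term(s) with background membership < %d",
                    nrow(skipped), min_term_size))
  term_k <- term_k[K >= min_term_size]
  N <- length(unique(background))

  clusters <- split(asg$protein_id, asg[[group_col]])
  res <- data.table::rbindlist(lapply(names(clusters), function(cl) {
    members <- unique(clusters[[cl]])
    n <- length(members)
    kk <- ann[term_id %in% term_k$term_id & protein_id %in% members,
              .(k = data.table::uniqueN(protein_id)), by = term_id]
    tab <- kk[term_k, on = "term_id"]
    tab[is.na(k), k := 0L]
    tab[, `:=`(cluster_label = cl, n = n, N = N)]
    tab[, fraction := k / n]
    tab[, p_value := hypergeometric_pvalue(k, n, K, N)]
    tab[, q_value := p.adjust(p_value, method = "BH")]
    tab[order(p_value)]
  }))
  if (nrow(res) == 0)
    return(data.table::data.table(term_id = character(0), term_name = character(0),
                                  cluster_label = character(0), k = integer(0),
                                  n = integer(0), K = integer(0), N = integer(0),
                                  fraction = numeric(0), p_value = numeric(0),
                                  q_value = numeric(0)))
  res[, .(term_id, term_name, cluster_label, k, n, K, N, fraction,
          p_value, q_value)]
}
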