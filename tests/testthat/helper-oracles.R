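# Independent oracles used to freeze expected values. These deliberately do
# not share code with the implementation paths they check.

# upper-tail hypergeometric mass by direct enumeration of the pmf
oracle_hyper_upper <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# interacting pairs inside a set by brute-force double loop
oracle_pairs <- function(protein_set, edges_a, edges_b) {
  hits <- list()
  for (i in seq_along(edges_a)) {
    a <- edges_a[i]; b <- edges_b[i]
    if (a == b) next
    if (a %in% protein_set && b %in% protein_set) {
      key <- paste(sort(c(a, b)), collapse = "|")
      hits[[key]] <- sort(c(a, b))
    }
  }
  unname(hits[order(names(hits))])
}

# exhaustive minimal-cost frame-to-frame matching: every injective map of
# detections onto tracks (0 = start new track, penalty max_disp^2)
oracle_match_frame <- function(cost, max_disp) {
  nd <- nrow(cost); nt <- ncol(cost)
  grids <- expand.grid(rep(list(0:nt), nd))
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(grids))) {
    a <- as.integer(grids[r, ])
    nz <- a[a > 0]
    if (anyDuplicated(nz)) next
    cst <- sum(a == 0) * max_disp^2
    ok <- TRUE
    for (i in seq_len(nd)) {
      if (a[i] > 0) {
        if (cost[i, a[i]] > max_disp^2) { ok <- FALSE; break }
        cst <- cst + cost[i, a[i]]
      }
    }
    if (ok && cst < best_cost) { best_cost <- cst; best <- a }
  }
  list(assignment = best, cost = best_cost)
}

# independent frame-by-frame linker built on the oracle matcher (no memory)
oracle_link <- function(det, max_disp) {
  det <- det[order(det$frame), ]
  det$particle <- NA_integer_
  frames <- sort(unique(det$frame))
  ends <- list()  # per track: c(x, y, frame)
  for (f in frames) {
    rows <- which(det$frame == f)
    active <- which(vapply(ends, function(e) e[3] == f - 1, logical(1)))
    if (length(active) > 0) {
      cost <- matrix(Inf, length(rows), length(active))
      for (i in seq_along(rows)) for (j in seq_along(active)) {
        e <- ends[[active[j]]]
        cost[i, j] <- (det$x[rows[i]] - e[1])^2 + (det$y[rows[i]] - e[2])^2
      }
      a <- oracle_match_frame(cost, max_disp)$assignment
    } else {
      a <- rep(0L, length(rows))
    }
    for (i in seq_along(rows)) {
      trk <- if (a[i] > 0) active[a[i]] else length(ends) + 1L
      det$particle[rows[i]] <- trk
      ends[[trk]] <- c(det$x[rows[i]], det$y[rows[i]], f)
    }
  }
  det
}

# partition of detections into tracks as a canonical set of sets, keyed by
# (frame, x, y) so row order is irrelevant
track_partition <- function(linked) {
  keys <- sprintf("%g|%g|%g", linked$frame, linked$x, linked$y)
  parts <- lapply(split(keys, linked$particle), sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

# build a fraction quant table in code (one row per protein x time x rep x
# fraction); pellet_share gives P_index truth per protein x time
make_fq_table <- function(proteins, time_points, replicates, pellet_share,
                          total = 100, coverage = 0.5, n_peptides = 5L) {
  rows <- list()
  for (pi in seq_along(proteins)) for (tp in seq_along(time_points))
    for (r in replicates) {
      p <- pellet_share[pi, tp]
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = proteins[pi], time_point = time_points[tp],
        replicate = r,
        fraction = c("pellet", "supernatant"),
        abundance = c(total * p, total * (1 - p)),
        n_peptides = n_peptides, coverage = coverage,
        stringsAsFactors = FALSE)
    }
  out <- data.table::rbindlist(rows)
  out[, time_point := factor(time_point, levels = time_points, ordered = TRUE)]
  data.table::setattr(out, "class", c("fraction_quant_table", class(out)))
  out[]
}

# render a Gaussian spot image in code (independent of gen_cell_image)
render_spots <- function(shape, centers, amplitude, sigma = 1.5, noise_sd = 0,
                         seed = NULL) {
  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-(((yy - centers[i, 2])^2 + (xx - centers[i, 1])^2) / (2 * sigma^2)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmax(img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx), 0)
  }
  img
}

# analytic integral of logistic growth od(t) = K / (1 + C exp(-r t))
# from 0 to T, minus baseline od(0) * T (the AUC definition under test)
oracle_logistic_auc <- function(K, r, n0, T) {
  C <- (K - n0) / n0
  integral <- (K / r) * (log(exp(r * T) + C) - log(1 + C))
  integral - (K / (1 + C)) * T
}
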