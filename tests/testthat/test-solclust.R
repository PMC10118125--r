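arch <- solubility_archetypes()

# noisy matrix with planted classes, built directly (bypasses the abundance
# layer; class per row in rownames prefix)
planted_matrix <- function(counts, sd, seed) {
  set.seed(seed)
  rows <- lapply(names(counts), function(cl) {
    t(replicate(counts[[cl]],
                pmin(pmax(arch[cl, ] + rnorm(5, 0, sd), 0.01), 0.99)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("%s|%03d", rep(names(counts), unlist(counts)),
                         seq_len(nrow(m)))
  colnames(m) <- colnames(arch)
  m
}

test_that("distance-criterion cut recovers planted partitions", {
  counts <- list(mostly_pellet = 20, mostly_supernatant = 20,
                 transient_solubilization = 10,
                 gradual_desolubilization = 10, gradual_solubilization = 10)
  m <- planted_matrix(counts, sd = 0.03, seed = 21)
  res <- classify_trajectories(m)
  truth <- sub("\\|.*", "", rownames(m))
  expect_equal(adjusted_rand_index(res$assignments$class_label, truth), 1)
  expect_equal(sum(attr(res$profiles, "size")), nrow(m))
  expect_true(is.finite(res$threshold))

  # order invariance: permuting rows gives the same partition
  set.seed(22); perm <- sample(nrow(m))
  res2 <- classify_trajectories(m[perm, ])
  lab1 <- res$assignments$class_label[match(rownames(m), res$assignments$protein_id)]
  lab2 <- res2$assignments$class_label[match(rownames(m), res2$assignments$protein_id)]
  expect_equal(lab1, lab2)
})

test_that("degenerate geometry: identical trajectories cannot split by distance", {
  m <- matrix(0.5, 10, 5,
              dimnames = list(paste0("P", 1:10), colnames(arch)))
  expect_error(cluster_trajectories(m, 5), class = "solubilome_cut_error")
  forced <- cluster_trajectories(m, 5, force_split = TRUE)
  expect_equal(length(unique(forced$assignments$cluster_id)), 5L)
  # a single cluster is always attainable
  one <- cluster_trajectories(m, 1)
  expect_equal(unique(one$assignments$cluster_id), 1L)
  expect_error(cluster_trajectories(m, 11), class = "solubilome_domain_error")
})

test_that("class-label rules match the canonical shapes", {
  prof <- function(v) matrix(v, 1, 5, dimnames = list("1", colnames(arch)))
  expect_equal(unname(assign_class_labels(prof(c(0.85, 0.85, 0.85, 0.85, 0.85)))),
               "mostly_pellet")
  expect_equal(unname(assign_class_labels(prof(c(0.80, 0.20, 0.70, 0.80, 0.80)))),
               "transient_solubilization")
  expect_equal(unname(assign_class_labels(prof(c(0.80, 0.65, 0.50, 0.35, 0.20)))),
               "gradual_solubilization")
  expect_equal(unname(assign_class_labels(prof(c(0.20, 0.35, 0.50, 0.65, 0.80)))),
               "gradual_desolubilization")
  expect_equal(unname(assign_class_labels(prof(c(0.15, 0.15, 0.15, 0.15, 0.15)))),
               "mostly_supernatant")

  # two clusters claiming one label is an ambiguity error with both medians
  two <- rbind(`1` = rep(0.85, 5), `2` = rep(0.80, 5))
  colnames(two) <- colnames(arch)
  expect_error(assign_class_labels(two), "0.85",
               class = "solubilome_label_error")

  # property: archetypes plus per-point noise (sd <= 0.03) keep their label.
  # At sd 0.05 a single 5-point trajectory occasionally exceeds the static
  # range by chance; cluster *medians*, the rules' actual input, carry
  # noise ~ sd / sqrt(cluster size), far below this.
  set.seed(33)
  for (sd_noise in c(0.01, 0.03)) for (i in 1:100) for (cl in rownames(arch)) {
    noisy <- prof(pmin(pmax(arch[cl, ] + rnorm(5, 0, sd_noise), 0.01), 0.99))
    expect_equal(unname(assign_class_labels(noisy)), cl)
  }
})

test_that("changing set is the union of the three dynamic classes, in order", {
  asg <- data.frame(
    protein_id = paste0("P", 1:10),
    class_label = c("mostly_pellet", "mostly_pellet", "mostly_pellet",
                    "mostly_supernatant", "mostly_supernatant",
                    "mostly_supernatant", "mostly_supernatant",
                    "transient_solubilization", "gradual_desolubilization",
                    "gradual_solubilization"))
  expect_equal(extract_changing_set(asg), c("P8", "P9", "P10"))
  asg$class_label <- "mostly_pellet"
  expect_equal(extract_changing_set(asg), character(0))
})

test_that("property PCA standardizes, orients and ranks variance", {
  # two perfectly correlated features -> PC1 explains everything
  set.seed(44)
  x <- rnorm(50)
  p2 <- data.frame(protein_id = paste0("P", 1:50), f1 = x, f2 = 2 * x + 3)
  pc2 <- pca_protein_properties(p2)
  expect_equal(pc2$explained_variance[1], 1, tolerance = 1e-12)

  # independent standard normals, large n -> roughly equal variances
  set.seed(3)
  X <- matrix(rnorm(10000 * 4), ncol = 4)
  big <- data.frame(protein_id = paste0("P", 1:10000), X)
  pcb <- pca_protein_properties(big)
  expect_lt(max(abs(pcb$explained_variance - 0.25)) / 0.25, 0.05)
  # invariants: fractions sum to 1, non-increasing, loadings orthonormal
  expect_equal(sum(pcb$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(pcb$explained_variance) <= 1e-12))
  expect_equal(crossprod(pcb$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest-|loading| entry positive in each component
  for (j in 1:4) {
    v <- pcb$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }

  # duplicated protein rows get identical scores
  dup <- rbind(p2, p2[1, ])
  pcd <- pca_protein_properties(dup)
  expect_equal(unname(pcd$scores[51, ]), unname(pcd$scores[1, ]))

  # zero-variance feature dropped with warning
  p3 <- data.frame(protein_id = paste0("P", 1:50), f1 = x, f2 = 2 * x,
                   f3 = 1)
  expect_warning(pc3 <- pca_protein_properties(p3), "f3")
  expect_equal(nrow(pc3$loadings), 2L)
})

test_that("interaction pairs agree with the brute-force oracle", {
  edges <- data.frame(a = c("A", "A"), b = c("B", "D"))
  got <- interaction_pairs(c("A", "B", "C"), edges)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$a, got$b), c("A", "B"))
  expect_equal(nrow(interaction_pairs(c("A", "B"), edges[0, ])), 0L)

  set.seed(11)
  pool <- sprintf("Y%03d", 1:200)
  ea <- sample(pool, 500, replace = TRUE)
  eb <- sample(pool, 500, replace = TRUE)
  set_100 <- sample(pool, 100)
  got <- interaction_pairs(set_100, data.frame(a = ea, b = eb))
  want <- oracle_pairs(set_100, ea, eb)
  expect_equal(nrow(got), length(want))
  got_keys <- sort(paste(got$a, got$b, sep = "|"))
  want_keys <- sort(vapply(want, paste, "", collapse = "|"))
  expect_equal(got_keys, want_keys)
})
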