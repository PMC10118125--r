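# P_index: per-protein pellet-partition index from sedimentation
# fractionation. P_index = pellet / (supernatant + pellet); 0 means the
# protein was detected only in the supernatant, 1 only in the pellet.

#' Pellet-partition index (P_index)
#'
#' The proportion of a protein's abundance recovered in the pellet fraction
#' after ultracentrifugation: `pellet / (supernatant + pellet)`. Used as a
#' proxy for (in)solubility. Vectorized; both inputs must be non-negative and
#' each pair must have a positive total (callers filter non-detected
#' proteins first).
#'
#' @param supernatant,pellet non-negative abundances (iBAQ-style arbitrary
#'   units), recycled to common length.
#' @return numeric vector of values in \[0, 1\].
#' @examples
#' compute_pindex(5, 0)   # 0: supernatant only
#' compute_pindex(0, 7)   # 1: pellet only
#' compute_pindex(3, 1)   # 0.25
#' @export
compute_pindex <- function(supernatant, pellet) {
  n <- max(length(supernatant), length(pellet))
  supernatant <- rep_len(supernatant, n)
  pellet <- rep_len(pellet, n)
  if (any(supernatant < 0 | pellet < 0, na.rm = TRUE))
    stopf("abundances must be non-negative", class = "solubilome_domain_error")
  total <- supernatant + pellet
  if (any(!is.na(total) & total == 0))
    stopf("P_index undefined where supernatant + pellet = 0; filter non-detected proteins first",
          class = "solubilome_domain_error")
  pellet / total
}

#' Apply the detection filters for solubility profiling
#'
#' Retains proteins that satisfy all three criteria used to define the
#' analyzable set: sequence coverage >= `min_coverage`, at least
#' `min_peptides` peptides, and positive total abundance
#' (supernatant + pellet > 0) in every replicate at every time point.
#' Coverage and peptide count are evaluated on per-protein maxima across all
#' rows (protein-level quantities in MaxQuant-style tables); the
#' completeness criterion is evaluated over the full time x replicate grid
#' observed in the table, so an absent row fails it. Missing (`NA`)
#' abundance is treated as not detected, like 0.
#'
#' Each excluded protein is reported with a single reason, assigned in
#' priority order `low_coverage` > `few_peptides` > `incomplete_series`.
#' Filtering is idempotent.
#'
#' @param table a `fraction_quant_table` (see [read_fraction_quant()]).
#' @param min_coverage minimum sequence coverage fraction (default 0.10).
#' @param min_peptides minimum peptide count (default 2).
#' @return list with `table` (filtered records) and `report`, a
#'   `filter_report` list carrying `n_input_proteins`, `n_pass` and an
#'   `exclusions` data.table (`protein_id`, `reason`).
#' @export
apply_detection_filters <- function(table, min_coverage = 0.10, min_peptides = 2L) {
  dt <- data.table::as.data.table(table)
  if (nrow(dt) == 0) {
    report <- structure(list(n_input_proteins = 0L, n_pass = 0L,
                             exclusions = data.table::data.table(
                               protein_id = character(0), reason = character(0))),
                        class = "filter_report")
    return(list(table = table, report = report))
  }
  prot <- dt[, .(max_coverage = max(coverage, na.rm = TRUE),
                 max_peptides = max(n_peptides, na.rm = TRUE)),
             by = protein_id]

  # totals per protein x time x replicate over the full observed grid;
  # dcast fills absent combinations with NA (treated as not detected)
  tot <- dt[, .(total = sum(abundance, na.rm = FALSE)),
            by = .(protein_id, time_point, replicate)]
  grid <- data.table::CJ(protein_id = unique(dt$protein_id),
                         time_point = unique(dt$time_point),
                         replicate = unique(dt$replicate))
  tot <- tot[grid, on = c("protein_id", "time_point", "replicate")]
  complete <- tot[, .(complete = all(!is.na(total) & total > 0)), by = protein_id]

  prot <- prot[complete, on = "protein_id"]
  prot[, reason := data.table::fcase(
    max_coverage < min_coverage, "low_coverage",
    max_peptides < min_peptides, "few_peptides",
    !complete, "incomplete_series",
    default = NA_character_
  )]
  keep <- prot$protein_id[is.na(prot$reason)]
  excl <- prot[!is.na(reason), .(protein_id, reason)]
  out <- dt[protein_id %in% keep]
  data.table::setattr(out, "class", class(table))
  report <- structure(list(
    n_input_proteins = nrow(prot),
    n_pass = length(keep),
    exclusions = excl
  ), class = "filter_report")
  list(table = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Detection filter report: %d / %d proteins pass\n",
              x$n_pass, x$n_input_proteins))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Per-replicate P_index records from a fractionation table
#'
#' Pivots supernatant/pellet rows and applies [compute_pindex()] per
#' protein x time x replicate. Cells whose total abundance is zero or
#' missing yield `NA` (they should have been removed by
#' [apply_detection_filters()]).
#'
#' @param table a `fraction_quant_table`.
#' @return `data.table` with columns `protein_id`, `time_point`,
#'   `replicate`, `pindex`.
#' @export
pindex_records <- function(table) {
  dt <- data.table::as.data.table(table)
  wide <- data.table::dcast(dt, protein_id + time_point + replicate ~ fraction,
                            value.var = "abundance",
                            fun.aggregate = sum, fill = NA_real_)
  for (col in .fraction_levels)
    if (!(col %in% names(wide))) wide[, (col) := NA_real_]
  total <- wide$supernatant + wide$pellet
  p <- rep(NA_real_, nrow(wide))
  ok <- !is.na(total) & total > 0
  p[ok] <- wide$pellet[ok] / total[ok]
  out <- wide[, .(protein_id, time_point, replicate)]
  out[, pindex := p]
  out[]
}

#' Replicate mean matrix and replicate agreement
#'
#' Averages per-replicate P_index into the mean trajectory matrix used for
#' clustering, and quantifies replicate agreement as pairwise Pearson
#' correlations over all protein x time cells shared by each replicate pair
#' (pairwise deletion of missing cells).
#'
#' @param records long P_index records from [pindex_records()].
#' @return list with `mean` (proteins x time `pindex_matrix`, row order =
#'   first appearance in `records`) and `correlations`
#'   (data.table `rep_a`, `rep_b`, `pearson_r`, `n_cells`; empty with a
#'   warning when only one replicate is present).
#' @export
summarize_replicates <- function(records) {
  dt <- data.table::as.data.table(records)
  reps <- sort(unique(dt$replicate))
  tp <- if (is.factor(dt$time_point)) levels(dt$time_point) else unique(as.character(dt$time_point))
  prot <- unique(dt$protein_id)

  mean_dt <- dt[, .(pindex = mean(pindex)), by = .(protein_id, time_point)]
  m <- matrix(NA_real_, nrow = length(prot), ncol = length(tp),
              dimnames = list(prot, tp))
  m[cbind(match(mean_dt$protein_id, prot),
          match(as.character(mean_dt$time_point), tp))] <- mean_dt$pindex
  attr(m, "missing") <- is.na(m)
  class(m) <- c("pindex_matrix", class(m))

  if (length(reps) < 2) {
    warnf("single replicate: replicate correlations are empty")
    corr <- data.table::data.table(rep_a = integer(0), rep_b = integer(0),
                                   pearson_r = numeric(0), n_cells = integer(0))
  } else {
    cell <- data.table::dcast(dt, protein_id + time_point ~ replicate,
                              value.var = "pindex")
    pairs <- utils::combn(as.character(reps), 2)
    corr <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
      x <- cell[[pairs[1, i]]]; y <- cell[[pairs[2, i]]]
      ok <- !is.na(x) & !is.na(y)
      data.table::data.table(rep_a = as.integer(pairs[1, i]),
                             rep_b = as.integer(pairs[2, i]),
                             pearson_r = if (sum(ok) >= 3) cor(x[ok], y[ok]) else NA_real_,
                             n_cells = sum(ok))
    }))
  }
  list(mean = m, correlations = corr)
}

#' Phosphopeptide relative-abundance trajectories
#'
#' Relative abundance of a phosphosite is its mean-over-replicates intensity
#' divided by the protein's mean total abundance (supernatant + pellet, the
#' same denominator as P_index) at that time point. Cells where the total is
#' zero or missing are flagged undefined (`NA`), not imputed; an intensity of
#' 0 with a detected protein is a genuine 0 (site undetected).
#' Phosphopeptides whose protein is absent from `totals` are recorded as
#' orphans and excluded with a warning.
#'
#' @param phospho data.frame with columns `protein_id`, `site_label`,
#'   `time_point`, `replicate`, `intensity` (non-negative).
#' @param totals data.frame with columns `protein_id`, `time_point`,
#'   `total_abundance` (mean over replicates).
#' @return `data.table` with columns `protein_id`, `site_label`,
#'   `time_point`, `rel_abundance`, `undefined`; attribute `orphans` lists
#'   excluded protein ids.
#' @export
phospho_relative_abundance <- function(phospho, totals) {
  ph <- data.table::as.data.table(phospho)
  tt <- data.table::as.data.table(totals)
  if (any(ph$intensity < 0, na.rm = TRUE))
    stopf("phosphopeptide intensities must be non-negative",
          class = "solubilome_validation_error")
  orphans <- setdiff(unique(ph$protein_id), unique(tt$protein_id))
  if (length(orphans) > 0) {
    warnf("excluding %d orphan phosphoprotein(s) absent from totals: %s",
          length(orphans), paste(orphans, collapse = ", "))
    ph <- ph[!(protein_id %in% orphans)]
  }
  agg <- ph[, .(intensity = mean(intensity)),
            by = .(protein_id, site_label, time_point)]
  agg[, time_point := as.character(time_point)]
  tt[, time_point := as.character(time_point)]
  out <- tt[agg, on = c("protein_id", "time_point")]
  out[, undefined := is.na(total_abundance) | total_abundance <= 0]
  out[, rel_abundance := ifelse(undefined, NA_real_, intensity / total_abundance)]
  res <- out[, .(protein_id, site_label, time_point, rel_abundance, undefined)]
  data.table::setattr(res, "orphans", orphans)
  res[]
}
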