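# Tabular IO with strict schema validation. All pipeline tables are plain
# delimited text (MaxQuant-style exports); delimiter is auto-detected among
# tab and comma unless given.

.fraction_levels <- c("supernatant", "pellet")

.default_columns <- c(
  protein_id = "protein_id", time_point = "time_point",
  replicate = "replicate", fraction = "fraction",
  abundance = "abundance", n_peptides = "n_peptides",
  coverage = "coverage"
)

.read_delim <- function(path, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "solubilome_io_error")
  sep <- delim %||% "auto"
  data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                    na.strings = c("", "NA", "NaN"), colClasses = NULL,
                    showProgress = FALSE)
}

.coerce_numeric <- function(x, what, keep_na = TRUE) {
  if (is.numeric(x)) return(list(values = as.numeric(x), bad = integer(0)))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "")
  list(values = v, bad = bad)
}

#' Read a supernatant/pellet fractionation quant table
#'
#' Reads long-form per-protein abundance records split by sedimentation
#' fraction across time points and replicates (one row per protein x time x
#' replicate x fraction), the shape produced by exporting iBAQ columns from a
#' MaxQuant proteinGroups search. Validates the schema strictly: mapped
#' columns must exist, numeric fields must parse (offending rows are dropped
#' with a warning naming their indices), fraction labels are normalized
#' (case/whitespace) to `supernatant`/`pellet`, and the
#' (protein, time, replicate, fraction) key must be unique.
#'
#' Missing abundance cells are kept as `NA`, distinct from 0: both fail the
#' detection filter downstream, but the distinction is preserved for
#' diagnostics.
#'
#' @param path delimited text file with a header row.
#' @param columns named character vector mapping canonical field names
#'   (`protein_id`, `time_point`, `replicate`, `fraction`, `abundance`,
#'   `n_peptides`, `coverage`) to the file's column names. Defaults to the
#'   identity mapping.
#' @param time_levels character vector giving the time axis order. Defaults
#'   to order of first appearance in the file (the time axis is configuration,
#'   not data; pass it explicitly in pipelines).
#' @param delim field delimiter; `NULL` auto-detects among tab and comma.
#' @return A `data.table` of class `fraction_quant_table` with canonical
#'   column names; `time_point` is an ordered factor.
#' @export
read_fraction_quant <- function(path, columns = NULL, time_levels = NULL,
                                delim = NULL) {
  map <- .default_columns
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), names(map))
    if (length(unknown) > 0)
      stopf("unknown schema field(s): %s", paste(unknown, collapse = ", "),
            class = "solubilome_schema_error")
    map[names(columns)] <- columns
  }
  dt <- .read_delim(path, delim)
  missing_cols <- map[!(map %in% names(dt))]
  if (length(missing_cols) > 0)
    stopf("schema error: mapped column(s) absent from file: %s",
          paste(sprintf("%s (-> %s)", missing_cols, names(missing_cols)),
                collapse = ", "),
          class = "solubilome_schema_error")
  out <- dt[, map, with = FALSE]
  data.table::setnames(out, names(map))

  bad_rows <- integer(0)
  for (col in c("abundance", "n_peptides", "coverage", "replicate")) {
    cc <- .coerce_numeric(out[[col]], col)
    data.table::set(out, j = col, value = cc$values)
    bad_rows <- union(bad_rows, cc$bad)
  }
  if (length(bad_rows) > 0) {
    warnf("rejected %d row(s) with unparseable numerics (row index: %s)",
          length(bad_rows), paste(sort(bad_rows), collapse = ", "))
    out <- out[-sort(bad_rows)]
  }

  out[, `:=`(
    protein_id = as.character(protein_id),
    replicate = as.integer(replicate),
    n_peptides = as.integer(n_peptides),
    fraction = normalize_fraction(fraction)
  )]
  validate_fraction_quant(out)
  lev <- time_levels %||% unique(as.character(out$time_point))
  extra <- setdiff(unique(as.character(out$time_point)), lev)
  if (length(extra) > 0)
    stopf("time point(s) %s absent from time_levels",
          paste(extra, collapse = ", "), class = "solubilome_schema_error")
  out[, time_point := factor(as.character(time_point), levels = lev, ordered = TRUE)]
  data.table::setattr(out, "class",
                      c("fraction_quant_table", class(out)))
  out[]
}

#' Normalize sedimentation fraction labels
#'
#' Trims whitespace and lowercases, then maps to the canonical
#' `supernatant`/`pellet` pair (accepting the common `sup`/`s`/`p`/`pel`
#' shorthands). Unrecognized labels are an error.
#'
#' @param x character vector of fraction labels.
#' @return character vector of canonical labels.
#' @export
normalize_fraction <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- ifelse(raw %in% c("supernatant", "sup", "s", "soluble"), "supernatant",
         ifelse(raw %in% c("pellet", "pel", "p", "insoluble"), "pellet", NA_character_))
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stopf("unrecognized fraction label(s): %s", paste(bad, collapse = ", "),
          class = "solubilome_schema_error")
  }
  out
}

validate_fraction_quant <- function(dt) {
  if (any(dt$abundance < 0, na.rm = TRUE))
    stopf("negative abundance values present", class = "solubilome_validation_error")
  if (any(dt$coverage < 0 | dt$coverage > 1, na.rm = TRUE))
    stopf("coverage outside [0, 1]", class = "solubilome_validation_error")
  if (any(dt$n_peptides < 0, na.rm = TRUE))
    stopf("negative peptide counts present", class = "solubilome_validation_error")
  key <- paste(dt$protein_id, dt$time_point, dt$replicate, dt$fraction, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- dt[duplicated(key), ]
    stopf("integrity error: duplicate (protein, time, replicate, fraction) key, e.g. %s/%s/rep%s/%s",
          dup$protein_id[1], dup$time_point[1], dup$replicate[1], dup$fraction[1],
          class = "solubilome_integrity_error")
  }
  invisible(dt)
}

#' Read a wide P_index trajectory matrix
#'
#' One row per protein, one column per time point, values in \[0, 1\] or
#' missing. This is the layout of a deposited per-protein solubility table
#' (protein id in the first column unless `id_col` says otherwise). Missing
#' cells are kept as `NA` and flagged, never imputed.
#'
#' @param path delimited text file.
#' @param time_levels optional time axis order; defaults to the file's column
#'   order for the value columns.
#' @param id_col name of the protein id column; defaults to the first column.
#' @param delim field delimiter, `NULL` to auto-detect.
#' @return numeric matrix (proteins x time points) of class `pindex_matrix`,
#'   with a logical attribute `missing` marking NA cells.
#' @export
read_trajectory_matrix <- function(path, time_levels = NULL, id_col = NULL,
                                   delim = NULL) {
  dt <- .read_delim(path, delim)
  id_col <- id_col %||% names(dt)[1]
  if (!(id_col %in% names(dt)))
    stopf("schema error: id column '%s' absent", id_col,
          class = "solubilome_schema_error")
  value_cols <- setdiff(names(dt), id_col)
  lev <- time_levels %||% value_cols
  miss <- setdiff(lev, value_cols)
  if (length(miss) > 0)
    stopf("schema error: time point column(s) absent: %s",
          paste(miss, collapse = ", "), class = "solubilome_schema_error")
  ids <- as.character(dt[[id_col]])
  m <- as.matrix(dt[, lev, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("validation error: P_index outside [0, 1] for protein %s at %s (value %g)",
          ids[bad[1, 1]], lev[bad[1, 2]], m[bad[1, , drop = FALSE]],
          class = "solubilome_validation_error")
  attr(m, "missing") <- is.na(m)
  class(m) <- c("pindex_matrix", class(m))
  m
}

#' Read an annotation map (term -> proteins)
#'
#' Accepts either a two-column delimited file (`term_id`, `protein_id`, with
#' an optional third `term_name` column) or GMT (term, description, then
#' members, tab-separated). Empty member sets are dropped.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gmt"`.
#' @return a `data.table` of class `annotation_map` with columns `term_id`,
#'   `term_name`, `protein_id`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    recs <- lapply(parts, function(p) {
      if (length(p) < 3) return(NULL)
      members <- unique(p[-(1:2)])
      members <- members[members != ""]
      if (length(members) == 0) return(NULL)
      data.table::data.table(term_id = p[1], term_name = p[2], protein_id = members)
    })
    out <- data.table::rbindlist(recs)
  } else {
    dt <- .read_delim(path)
    if (ncol(dt) < 2)
      stopf("annotation TSV needs >= 2 columns (term, protein)",
            class = "solubilome_schema_error")
    out <- data.table::data.table(
      term_id = as.character(dt[[1]]),
      term_name = if (ncol(dt) >= 3) as.character(dt[[3]]) else as.character(dt[[1]]),
      protein_id = as.character(dt[[2]])
    )
    out <- out[!is.na(protein_id) & protein_id != ""]
  }
  if (nrow(out) == 0)
    stopf("annotation map is empty", class = "solubilome_validation_error")
  out <- unique(out)
  data.table::setattr(out, "class", c("annotation_map", class(out)))
  out[]
}

#' Read and normalize an undirected interaction edge list
#'
#' Two protein-id columns (plus an optional source tag). Self-edges are
#' dropped and each pair is stored order-independently (lexicographically
#' sorted endpoints) with duplicates removed.
#'
#' @param path delimited text file with >= 2 columns.
#' @return `data.table` of class `edge_list` with columns `a`, `b` (sorted so
#'   `a < b`) and `source` if present in the file.
#' @export
read_edge_list <- function(path) {
  dt <- .read_delim(path)
  if (ncol(dt) < 2)
    stopf("edge list needs >= 2 columns", class = "solubilome_schema_error")
  normalize_edges(data.table::data.table(
    a = as.character(dt[[1]]), b = as.character(dt[[2]]),
    source = if (ncol(dt) >= 3) as.character(dt[[3]]) else NA_character_
  ))
}

#' Normalize an edge table (drop self-edges, deduplicate unordered pairs)
#' @param edges data.frame with columns `a`, `b` (and optionally `source`).
#' @return normalized `edge_list` data.table.
#' @export
normalize_edges <- function(edges) {
  dt <- data.table::as.data.table(edges)
  if (!all(c("a", "b") %in% names(dt)))
    stopf("edge table needs columns 'a' and 'b'", class = "solubilome_schema_error")
  dt <- dt[!is.na(a) & !is.na(b) & a != b]
  swap <- dt$a > dt$b
  tmp <- dt$a[swap]; dt$a[swap] <- dt$b[swap]; dt$b[swap] <- tmp
  dt <- unique(dt, by = c("a", "b"))
  data.table::setattr(dt, "class",
                      unique(c("edge_list", class(dt))))
  dt[]
}

#' Write result tables and a JSON manifest
#'
#' Writes one delimited file per named table into `out_dir` and a
#' `manifest.json` listing file name, row count and MD5 checksum. Numeric
#' columns are written at full round-trip precision so write-then-read is an
#' identity.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory, created if needed.
#' @param sep field separator for the table files.
#' @return the manifest as a data.frame (invisibly also written as JSON).
#' @export
write_results <- function(tables, out_dir, sep = ",") {
  if (length(tables) > 0 && (is.null(names(tables)) || any(names(tables) == "")))
    stopf("tables must be a named list", class = "solubilome_validation_error")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stopf("cannot create output directory %s", out_dir, class = "solubilome_io_error")
  entries <- lapply(names(tables), function(nm) {
    ext <- if (sep == "\t") "tsv" else "csv"
    file <- file.path(out_dir, paste0(nm, ".", ext))
    df <- as.data.frame(tables[[nm]])
    data.table::fwrite(df, file, sep = sep)
    data.frame(name = nm, file = basename(file), n_rows = nrow(df),
               md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  })
  manifest <- if (length(entries) > 0) do.call(rbind, entries) else
    data.frame(name = character(0), file = character(0),
               n_rows = integer(0), md5 = character(0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
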