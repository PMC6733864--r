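#' Construct and validate an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix of counts with samples as
#' rows and OTUs as columns. Row names are sample identifiers and column
#' names are OTU identifiers; both must be unique.
#'
#' @param counts Numeric matrix of counts, samples in rows, OTUs in columns.
#'   Must carry unique, non-empty dimnames.
#' @return The validated matrix with class `"otu_table"`.
#' @examples
#' m <- matrix(c(4L, 8L, 2L, 8L, 16L, 4L), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), c("OTU1", "OTU2")))
#' tab <- otu_table(m)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers")
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite and numeric")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, total count %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Sample and OTU identifiers of an OTU table
#' @param table An `otu_table`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(table) rownames(table)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table)

#' Read an OTU count table from a tab-separated file
#'
#' The file stores one row per sample and one column per OTU by default
#' (the first column holds sample identifiers and the header row holds OTU
#' identifiers). Files laid out the other way around -- the BIOM text
#' convention with OTUs as rows -- are handled by `orientation =
#' "otus_in_rows"`, which transposes on read.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"otus_in_columns"` (default) or
#'   `"otus_in_rows"`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("otus_in_columns", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate identifiers in first column of ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell in ", path)
  rownames(m) <- as.character(df[[1L]])
  if (orientation == "otus_in_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU count table to a tab-separated file
#'
#' Inverse of [read_otu_table]; a write/read round trip reproduces the
#' table exactly.
#'
#' @param table An [otu_table].
#' @param path Output path.
#' @param orientation Layout to write; see [read_otu_table].
#' @export
write_otu_table <- function(table, path,
                            orientation = c("otus_in_columns", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  id_col <- "sample_id"
  if (orientation == "otus_in_rows") {
    m <- t(m)
    id_col <- "otu_id"
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Greengenes-style taxonomy map
#'
#' Expects a two-column TSV mapping OTU identifier to a ranked lineage
#' string such as `"k__Bacteria; p__Bacteroidetes; ...; g__Bacteroides;
#' s__"`. Rank prefixes (`k__`, `p__`, ...) are stripped; a rank whose
#' token is empty, missing, or a bare prefix is recorded as `NA`
#' (unclassified at that rank), all three forms occurring in Greengenes
#' output.
#'
#' @param path Path to a two-column TSV (`otu_id`, `lineage`).
#' @return A `taxonomy_map`: data frame with columns `otu_id`, `kingdom`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxonomy_map(stats::setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Build a taxonomy map from named lineage strings
#'
#' @param lineages Character vector of lineage strings named by OTU id.
#' @return A `taxonomy_map` data frame; see [read_taxonomy].
#' @export
taxonomy_map <- function(lineages) {
  if (is.null(names(lineages)) || anyDuplicated(names(lineages)))
    stop("lineages must be uniquely named by OTU id")
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(tax_ranks)  # pad truncated lineages with NA
    p
  }, character(length(tax_ranks))))
  out <- data.frame(otu_id = names(lineages), mat,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("otu_id", tax_ranks)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Write a taxonomy map back to Greengenes lineage form
#'
#' @param taxonomy A `taxonomy_map`.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  lin <- apply(as.matrix(taxonomy[, tax_ranks]), 1L, function(r) {
    keep <- seq_len(max(c(0L, which(!is.na(r)))))
    if (length(keep) == 0L) return("k__")
    r[is.na(r)] <- ""
    paste0(prefixes[keep], r[keep], collapse = "; ")
  })
  utils::write.table(
    data.frame(otu_id = taxonomy$otu_id, lineage = lin),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genus of each OTU
#'
#' @param taxonomy A `taxonomy_map`.
#' @param ids OTU identifiers to query.
#' @return Character vector of genera, `NA` where the OTU is unclassified
#'   at genus level or absent from the map (a lookup never raises).
#' @export
genus_of <- function(taxonomy, ids) {
  g <- taxonomy$genus[match(ids, taxonomy$otu_id)]
  g[!is.na(g) & g == ""] <- NA_character_
  g
}

#' Drop OTUs with low total counts
#'
#' Retains exactly the OTUs whose count summed across all loaded samples is
#' at least `min_total`; the sample set is unchanged. The default of 10
#' removes OTUs with fewer than 10 representations across the dataset.
#' Idempotent.
#'
#' @param table An [otu_table].
#' @param min_total Minimum column sum to retain an OTU (>= 0).
#' @return Filtered [otu_table] (possibly with zero OTUs).
#' @export
filter_low_count <- function(table, min_total = 10) {
  stopifnot(min_total >= 0)
  keep <- colSums(table) >= min_total
  otu_table(unclass(table)[, keep, drop = FALSE])
}

#' Group OTUs by genus
#'
#' OTUs not classified at least to the genus level are removed; every
#' retained OTU maps to exactly one genus, so the value sets partition the
#' classified input.
#'
#' @param ids Character vector of OTU identifiers.
#' @param taxonomy A `taxonomy_map`.
#' @return Named list: genus -> character vector of OTU ids.
#' @export
reduce_to_genus <- function(ids, taxonomy) {
  g <- genus_of(taxonomy, ids)
  keep <- !is.na(g)
  split(ids[keep], g[keep])
}

#' Read and validate a sample metadata table
#'
#' Required columns: `sample_id`, `cohort_id`, `health_status`,
#' `antibiotic_last_year` (logical or NA for missing/"not sure" answers).
#' An optional `random_number` column carries the uniform draws used for
#' population subdivision.
#'
#' @param path Path to a TSV file.
#' @return A `sample_frame` data frame.
#' @export
read_sample_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_frame(df)
}

#' @rdname read_sample_frame
#' @param df Data frame with the required columns.
#' @export
sample_frame <- function(df) {
  req <- c("sample_id", "cohort_id", "health_status", "antibiotic_last_year")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("sample frame is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  df$antibiotic_last_year <- as.logical(df$antibiotic_last_year)
  if (!is.null(df$random_number)) df$random_number <- as.numeric(df$random_number)
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Write a sample metadata table
#' @param samples A `sample_frame`.
#' @param path Output path.
#' @export
write_sample_frame <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
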