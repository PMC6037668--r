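# Plain-TSV readers/writers for the package's table formats. All tables use
# a header row and a sample-ID first column; statuses are 1/0/NA.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_miwas("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a wide phenotype status table
#'
#' TSV with `sample_id` first column and one 1/0/NA status column per
#' phenotype.
#'
#' @param path File path.
#' @return Phenotype data frame.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample_id") names(df)[1] <- "sample_id"
  for (nm in setdiff(names(df), "sample_id")) {
    v <- df[[nm]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop_miwas("phenotype column '", nm, "' not coded 1/0/NA")
    }
    df[[nm]] <- as.integer(v)
  }
  df
}

#' Read a samples-by-traits numeric matrix
#'
#' @param path TSV with `sample_id` first column.
#' @return Numeric matrix with sample row names.
#' @export
read_trait_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a sample covariate table
#'
#' Expects `sample_id` plus the confounder columns used by [residualize]
#' (family_id, sex, dna_extractor, collection_method, sequencing_run,
#' sequencing_depth, age, bmi); extra columns are kept.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_covariate_table <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample_id") names(df)[1] <- "sample_id"
  df
}

#' Read a square labelled distance matrix
#'
#' @param path TSV whose first column and header hold matching sample IDs.
#' @return Numeric square matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m))) {
    stop_miwas("distance matrix labels mismatch between rows and header")
  }
  m
}

#' Read a taxon count table with lineages
#'
#' TSV holding integer counts plus a `lineage` column of semicolon-delimited
#' ranks. Orientation (taxa in rows with a lineage column, or samples in
#' rows) is auto-detected from the header: a `lineage` column implies taxa
#' in rows.
#'
#' @param path File path.
#' @return A [taxon_counts] object (samples in rows).
#' @export
read_taxon_count_table <- function(path) {
  df <- read_tsv(path)
  if (!"lineage" %in% names(df)) {
    stop_miwas("count table needs a 'lineage' column (taxa in rows)")
  }
  lineage <- df$lineage
  taxa <- as.character(df[[1]])
  m <- as.matrix(df[, setdiff(names(df), c(names(df)[1], "lineage")),
                    drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- taxa
  tc <- taxon_counts(t(m), lineage)
  tc
}
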