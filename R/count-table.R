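#' Validate an ASV count table
#'
#' A count table is an integer matrix with one row per amplicon sequence
#' variant (ASV) and one column per sample; `dimnames` carry the ASV and
#' sample identifiers.  All entries must be non-negative integers and both
#' identifier sets must be unique.
#'
#' @param counts matrix to validate.
#' @return the validated matrix (storage mode integer), invisibly usable.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts))
    stop("count table must be a matrix (ASVs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (!is.numeric(counts)) stop("count table must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at ASV '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file with a header row of sample ids, a first
#' column of ASV ids (first header cell ignored) and non-negative integer
#' cells.
#'
#' @param path path to the TSV file.
#' @return validated integer matrix, ASVs in rows, samples in columns.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("count table contains non-numeric cells: ", path)
  validate_count_table(m)
}

#' Write an ASV count table to TSV
#'
#' @param counts validated count table matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(asv = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with header `sample  species  sex  population`.  Each analysed sample
#' must appear exactly once and `sex` must take exactly two levels across the
#' file (conventionally `male`/`female`).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with columns sample, species, sex, population.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta data.frame to validate.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample", "species", "sex", "population")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop("duplicate sample ids in metadata: ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  lv <- unique(meta$sex)
  if (length(lv) > 2)
    stop("sex must take exactly two levels, found: ",
         paste(lv, collapse = ", "))
  meta[need]
}

#' Read an ASV taxonomy table
#'
#' TSV with header `asv  domain  phylum  class  order  family  genus`.
#' Missing ranks are stored as the explicit string "unclassified".
#'
#' @param path path to the taxonomy TSV.
#' @return data.frame with the asv column plus the six ranked lineages.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param tax data.frame to validate.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("asv", taxonomic_ranks())
  miss <- setdiff(need, names(tax))
  if (length(miss) > 0)
    stop("taxonomy lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$asv))
    stop("duplicate ASV ids in taxonomy: ",
         paste(unique(tax$asv[duplicated(tax$asv)]), collapse = ", "))
  tax <- tax[need]
  for (r in taxonomic_ranks()) {
    v <- tax[[r]]
    v[is.na(v) | v == ""] <- "unclassified"
    tax[[r]] <- v
  }
  tax
}

#' Ordered taxonomic ranks stored in a taxonomy table
#' @return character vector domain..genus.
#' @export
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Per-sample sequencing depths
#'
#' @param counts count table matrix.
#' @return named integer vector of column sums.
#' @export
sample_depths <- function(counts) {
  d <- colSums(counts)
  if (all(d < .Machine$integer.max)) storage.mode(d) <- "integer"
  d
}
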