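#' Validate a feature-by-sample count matrix
#'
#' Checks that a matrix of sequencing counts is non-negative, integer-valued
#' and carries unique feature (row) and sample (column) identifiers. Samples
#' with an all-zero column are dropped with a warning rather than an error:
#' bowel-cleansed mice can yield near-empty communities and such samples are
#' uninformative but not a reason to abort a run.
#'
#' @param mat numeric matrix, features in rows, samples in columns, with
#'   rownames and colnames set.
#' @param what label used in error messages (e.g. "ASV counts").
#' @return the validated matrix (possibly with all-zero samples dropped), of
#'   class `count_table`.
#' @export
validate_count_table <- function(mat, what = "counts") {
  if (!is.matrix(mat)) fmt_stop(sprintf("%s: expected a matrix", what))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    fmt_stop(sprintf("%s: feature and sample identifiers are required", what))
  dup_f <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_f))
    fmt_stop(sprintf("%s: duplicate feature id '%s'", what, dup_f[1]))
  dup_s <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_s))
    fmt_stop(sprintf("%s: duplicate sample id '%s'", what, dup_s[1]))
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    fmt_stop(sprintf(
      "%s: cell (%s, %s) is not a non-negative integer", what,
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  zero <- colSums(mat) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero sample(s): %s", sum(zero),
                    paste(colnames(mat)[zero], collapse = ", ")))
    mat <- mat[, !zero, drop = FALSE]
  }
  storage.mode(mat) <- "double"
  class(mat) <- c("count_table", class(mat))
  mat
}

#' Read a feature-by-sample count table
#'
#' TSV dialect: UTF-8, tab separated, lines starting with `#` ignored, first
#' column holds the feature identifier, remaining columns one sample each.
#' BIOM 2.1 files are accepted read-only through the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` (canonical) or `"biom"`.
#' @return validated `count_table` matrix.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) fmt_stop(sprintf("file not found: %s", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      fmt_stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    return(validate_count_table(mat, what = basename(path)))
  }
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) fmt_stop(sprintf("parse error in %s: %s",
                                         path, conditionMessage(e))))
  if (ncol(df) < 2)
    fmt_stop(sprintf("parse error in %s: header line must name a feature-id column and at least one sample", path))
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    fmt_stop(sprintf("%s: non-numeric count cells", path))
  rownames(mat) <- ids
  validate_count_table(mat, what = basename(path))
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x, f))`
#' reproduces `x` exactly.
#'
#' @param mat count matrix.
#' @param path destination file.
#' @param id_name header label for the feature-id column.
#' @export
write_count_table <- function(mat, path, id_name = "ID") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Expects columns `sample`, `genotype` (WT/KO), `treatment` (control/FMT) and
#' optionally `pair_id` linking pre/post-FMT samples from the same animal.
#'
#' @param path TSV file.
#' @return data.frame with factor-checked columns.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df data.frame to validate in place of a file.
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample", "genotype", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fmt_stop(sprintf("metadata: missing column(s) %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample))
    fmt_stop(sprintf("metadata: duplicate sample id '%s'",
                     df$sample[duplicated(df$sample)][1]))
  bad_g <- setdiff(unique(df$genotype), c("WT", "KO"))
  if (length(bad_g))
    fmt_stop(sprintf("metadata: genotype level '%s' not in {WT, KO}", bad_g[1]))
  bad_t <- setdiff(unique(df$treatment), c("control", "FMT"))
  if (length(bad_t))
    fmt_stop(sprintf("metadata: treatment level '%s' not in {control, FMT}", bad_t[1]))
  df$group <- paste0(df$genotype, ifelse(df$treatment == "FMT", "FMT", ""))
  df
}

#' Read an ASV taxonomy table
#'
#' First column is the ASV/feature id, remaining columns the ranks Kingdom
#' through Genus (Species optional). Unassigned ranks may be empty strings.
#'
#' @param path TSV file.
#' @return data.frame with a `feature_id` column plus rank columns.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1] <- "feature_id"
  ranks <- intersect(c("Kingdom", "Phylum", "Class", "Order", "Family",
                       "Genus", "Species"), names(df))
  if (length(ranks) < 6)
    fmt_stop("taxonomy: expected rank columns Kingdom..Genus")
  if (anyDuplicated(df$feature_id))
    fmt_stop("taxonomy: duplicate feature ids")
  df
}

#' Read a scored protein-protein interaction edge list
#'
#' STRING-export-like TSV with columns `gene_a`, `gene_b`, `score`; scores are
#' combined confidence values in \[0, 1\].
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(df)))
    fmt_stop("edge table: expected columns gene_a, gene_b, score")
  if (any(df$score < 0 | df$score > 1))
    fmt_stop("edge table: scores must lie in [0, 1]")
  df[, need]
}

#' Align a count table with its sample metadata
#'
#' Restricts both objects to the samples they share, in the same order. Sample
#' ids present in only one of the two are dropped with a message.
#'
#' @param counts `count_table` matrix.
#' @param meta metadata data.frame with a `sample` column.
#' @return list with elements `counts` and `meta`.
#' @export
align_tables <- function(counts, meta) {
  shared <- intersect(colnames(counts), meta$sample)
  if (!length(shared))
    fmt_stop("no samples shared between counts and metadata")
  dropped <- c(setdiff(colnames(counts), shared), setdiff(meta$sample, shared))
  if (length(dropped))
    message("align_tables: dropping unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  counts <- counts[, shared, drop = FALSE]
  meta <- meta[match(shared, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, meta = meta)
}
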