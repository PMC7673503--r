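# Reading/writing expression matrices and metadata tables, and encoding a
# categorical variable as a +1/-1 label vector.

#' Read a gene-expression matrix from tab-separated text
#'
#' The file must have one header row and one id column.  With
#' `orientation = "genes"` rows are genes and columns are samples (the
#' series-matrix convention); with `orientation = "samples"` the file is
#' transposed on read.  Internally matrices are always stored genes x
#' samples.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes"` if rows are genes, `"samples"` if rows are
#'   samples.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' M <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' write_expression(M, tf)
#' all.equal(read_expression(tf), M + 0)
read_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate id(s): ", paste(dup, collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))
      stop(sprintf("non-numeric value in column '%s' (e.g. row %d: '%s')",
                   colnames(vals)[j], bad[1], vals[[j]][bad[1]]))
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (orientation == "samples") M <- t(M)
  validate_expression(M)
  M
}

#' Write a gene-expression matrix as tab-separated text
#'
#' @param M numeric matrix, genes x samples.
#' @param path output path.
#' @param id_column header for the gene-id column.
#' @export
write_expression <- function(M, path, id_column = "gene_id") {
  validate_expression(M)
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default set of strings parsed as missing metadata values
#'
#' Public repository dumps are inconsistent about how absent annotations are
#' written, so empty cells, `NA`, `NaN` and `unknown` (case-insensitive) are
#' all treated as missing by default.
#'
#' @export
missing_value_strings <- function() c("", "na", "nan", "unknown")

#' Read a sample-metadata table
#'
#' First column is the sample id; every other column is one categorical
#' variable.  Cells matching `missing_values` (case-insensitively) become
#' `NA`.
#'
#' @param path path to a TSV file.
#' @param missing_values character vector of strings treated as missing.
#' @return data.frame with column `sample_id` and one character column per
#'   variable.
#' @export
read_metadata <- function(path, missing_values = missing_value_strings()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  colnames(df)[1] <- "sample_id"
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  for (j in seq(2, length.out = ncol(df) - 1)) {
    miss <- is.na(df[[j]]) | tolower(trimws(df[[j]])) %in% tolower(missing_values)
    df[[j]][miss] <- NA_character_
  }
  df
}

#' Write a sample-metadata table
#'
#' @param meta data.frame with a `sample_id` column; `NA` cells are written
#'   as empty strings.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Encode a categorical metadata variable as a binary +1/-1 labeling
#'
#' The minority class (fewer samples after filtering) is coded +1 and the
#' majority class -1, so that "positive" always refers to the rarer value.
#' Samples whose value is missing, outside `allowed_values`, or outside the
#' two most frequent classes (when `allowed_values` is not given) are
#' excluded.  An exact tie in class sizes is broken lexicographically: the
#' smaller class label becomes +1.
#'
#' @param meta metadata data.frame as returned by [read_metadata()].
#' @param variable name of the column to encode.
#' @param allowed_values optional character vector of exactly two values to
#'   keep; all other values are excluded.
#' @return object of class `pcap_labels` with elements `variable`,
#'   `positive_class`, `negative_class`, `sample_ids`, `labels` (named
#'   +1/-1 vector) and `excluded`.
#' @export
encode_binary_labels <- function(meta, variable, allowed_values = NULL) {
  if (!variable %in% colnames(meta)) {
    stop("variable '", variable, "' not found in metadata")
  }
  ids <- as.character(meta$sample_id)
  vals <- as.character(meta[[variable]])
  keep <- !is.na(vals)
  if (!is.null(allowed_values)) {
    if (length(allowed_values) != 2) {
      stop("allowed_values must contain exactly two values")
    }
    keep <- keep & vals %in% allowed_values
  } else {
    counts <- sort(table(vals[keep]), decreasing = TRUE)
    if (length(counts) < 2) {
      stop("fewer than 2 classes remain for variable '", variable, "'")
    }
    # top two classes by count; count ties resolved alphabetically so the
    # retained pair is deterministic
    ord <- order(-as.vector(counts), names(counts))
    top2 <- names(counts)[ord][1:2]
    keep <- keep & vals %in% top2
  }
  counts <- table(vals[keep])
  if (length(counts) < 2) {
    stop("fewer than 2 classes remain for variable '", variable, "'")
  }
  cls <- names(counts)
  # minority -> +1; ties broken lexicographically
  ord <- order(as.vector(counts), cls)
  positive <- cls[ord[1]]
  negative <- cls[ord[2]]
  labels <- ifelse(vals[keep] == positive, 1, -1)
  names(labels) <- ids[keep]
  structure(
    list(
      variable = variable,
      positive_class = positive,
      negative_class = negative,
      sample_ids = ids[keep],
      labels = labels,
      excluded = ids[!keep]
    ),
    class = "pcap_labels"
  )
}

#' @export
print.pcap_labels <- function(x, ...) {
  cat(sprintf(
    "Binary labeling of '%s': +1 = %s (%d), -1 = %s (%d); %d excluded\n",
    x$variable, x$positive_class, sum(x$labels == 1),
    x$negative_class, sum(x$labels == -1), length(x$excluded)
  ))
  invisible(x)
}
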