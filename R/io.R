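# Shared domain containers and readers/writers for the plain-text formats the
# pipeline touches: TSV expression matrices, GMT gene sets, FASTA sequences.
# All readers reject malformed input with a located error rather than
# silently dropping rows.

#' Construct an expression panel
#'
#' An expression panel holds a feature-by-tissue matrix of non-negative
#' normalized expression values for one feature class (circRNA, miRNA or
#' gene). circRNA panels are conventionally in SRPBM (spliced reads per
#' billion mapped reads), miRNA/gene panels in CPM (counts per million).
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   tissues in columns (colnames = tissue ids). All values must be >= 0.
#' @param feature_class One of `"circRNA"`, `"miRNA"`, `"gene"`.
#' @param unit_label Free-text unit of the values, e.g. `"SRPBM"` or `"CPM"`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, feature_class = c("circRNA", "miRNA", "gene"),
                             unit_label = "") {
  feature_class <- match.arg(feature_class)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression_panel: 'values' must have feature rownames and tissue colnames")
  if (anyDuplicated(rownames(values)))
    stop("expression_panel: duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("expression_panel: duplicate tissue ids")
  if (!is.numeric(values) || anyNA(values))
    stop("expression_panel: values must be numeric with no missing cells")
  if (any(values < 0))
    stop("expression_panel: negative expression value")
  structure(list(values = values, feature_class = feature_class,
                 unit_label = unit_label),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d %s features x %d tissues [%s]\n",
              nrow(x$values), x$feature_class, ncol(x$values), x$unit_label))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Construct a raw-count panel
#'
#' Like [expression_panel()] but holding raw non-negative integer counts,
#' plus (optionally) per-sample total mapped reads as needed for SRPBM.
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param feature_class Feature class of the counted features.
#' @param total_mapped Optional named numeric vector of total mapped reads
#'   per sample (names matching `colnames(counts)`); required by [srpbm()].
#' @return An object of class `count_panel`.
#' @export
count_panel <- function(counts, feature_class = c("circRNA", "miRNA", "gene"),
                        total_mapped = NULL) {
  feature_class <- match.arg(feature_class)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_panel: 'counts' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("count_panel: duplicate feature or sample ids")
  if (anyNA(counts) || any(counts < 0))
    stop("count_panel: counts must be non-negative with no missing cells")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("count_panel: counts must be integers")
  if (!is.null(total_mapped)) {
    if (is.null(names(total_mapped)) ||
        !all(colnames(counts) %in% names(total_mapped)))
      stop("count_panel: total_mapped must be named for every sample")
    if (any(total_mapped <= 0))
      stop("count_panel: total_mapped must be > 0")
    total_mapped <- total_mapped[colnames(counts)]
  }
  structure(list(counts = counts, feature_class = feature_class,
                 total_mapped = total_mapped),
            class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf("count_panel: %d %s features x %d samples\n",
              nrow(x$counts), x$feature_class, ncol(x$counts)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## TSV expression matrices

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose header row names the tissues, whose
#' first column holds feature ids, and whose body is numeric. Lines starting
#' with `#` are treated as comments and skipped. Missing or non-numeric
#' cells and duplicated feature ids are errors, not warnings.
#'
#' @param path Path to the TSV file.
#' @param feature_class Feature class to stamp on the panel.
#' @param unit_label Unit label to stamp on the panel.
#' @return An [expression_panel()].
#' @export
read_expression_tsv <- function(path, feature_class = c("circRNA", "miRNA", "gene"),
                                unit_label = "") {
  feature_class <- match.arg(feature_class)
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L)
    stop("read_expression_tsv: ", path, ": need a header line and at least one row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  tissue_ids <- header[-1L]
  if (length(tissue_ids) == 0L)
    stop("read_expression_tsv: ", path, ": header has no tissue columns")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n_col <- length(header)
  feature_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(tissue_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col)
      stop("read_expression_tsv: ", path, ": row ", i + 1L, " has ",
           length(row), " fields, expected ", n_col)
    feature_ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("read_expression_tsv: ", path, ": non-numeric cell at row ", i + 1L,
           " (", row[1L], "), column '", tissue_ids[bad], "'")
    }
    values[i, ] <- v
  }
  if (anyDuplicated(feature_ids))
    stop("read_expression_tsv: ", path, ": duplicated feature id: ",
         feature_ids[duplicated(feature_ids)][1L])
  dimnames(values) <- list(feature_ids, tissue_ids)
  expression_panel(values, feature_class, unit_label)
}

#' Write an expression panel to TSV
#'
#' Values are written in full double precision so that a write/read
#' round-trip reproduces the panel bit-exactly. An optional `#`-prefixed
#' metadata comment is placed above the header.
#'
#' @param panel An [expression_panel()].
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `# `).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(panel, path, comment = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(c("feature_id", colnames(panel$values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(panel$values)), function(i) {
    paste(c(rownames(panel$values)[i],
            formatC(panel$values[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# Read non-comment, non-blank lines of a TSV file.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

## ---------------------------------------------------------------------------
## GMT gene sets

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene1 ...`.
#' Empty gene lists, duplicate set names and lines with fewer than three
#' fields are rejected with the offending line number.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a named list of unique character vectors
#'   of gene ids, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("read_gmt: ", path, ": no gene sets")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descs <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("read_gmt: ", path, ": line ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("read_gmt: ", path, ": line ", i, " ('", f[1L], "') has no genes")
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("read_gmt: ", path, ": duplicate set name: ",
         nms[duplicated(nms)][1L])
  names(sets) <- nms
  names(descs) <- nms
  gene_set_collection(sets, descriptions = descs)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of member gene ids.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene_set_collection: sets must be a uniquely named, non-empty list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(!lengths(sets))) stop("gene_set_collection: empty gene set")
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## FASTA sequences

#' Read RNA/DNA sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are upper-cased and T is normalized to U, so one RNA alphabet
#' flows through seed matching regardless of whether sequences were supplied
#' as DNA or RNA. Empty records, characters outside `{A,C,G,U,T}` (case
#' insensitive) and duplicated ids are errors.
#'
#' @param path Path to the FASTA file (single- or multi-line records).
#' @return A named character vector of class `sequence_set`: RNA sequences
#'   keyed by record id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("read_fasta: ", path, ": no records")
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(raw))
  sequence_set(setNames(seqs, ids), source = path)
}

#' Construct a sequence set
#'
#' @param seqs Named character vector of sequences over `{A,C,G,U,T}`;
#'   T is normalized to U.
#' @param source Optional provenance label.
#' @return A named character vector of class `sequence_set`.
#' @export
sequence_set <- function(seqs, source = NULL) {
  if (!length(seqs) || is.null(names(seqs)))
    stop("sequence_set: sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("sequence_set: duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1L])
  nms <- names(seqs)
  seqs <- setNames(chartr("T", "U", toupper(as.character(seqs))), nms)
  if (any(!nzchar(seqs)))
    stop("sequence_set: empty sequence record: ",
         names(seqs)[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("sequence_set: illegal character in sequence '",
         names(seqs)[bad][1L], "'")
  structure(setNames(as.character(seqs), names(seqs)),
            source = source, class = "sequence_set")
}

#' Write a sequence set to FASTA
#'
#' @param seqs A `sequence_set`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(inherits(seqs, "sequence_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequences (lengths %d-%d nt)\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Interaction tables

#' Construct an interaction table
#'
#' Typed edge list for circRNA-miRNA or miRNA-gene interactions. Each row
#' carries one or more non-negative criterion scores; Pareto ranking adds
#' `front_index` and `pareto_score` columns.
#'
#' @param source_id,target_id Character vectors of edge endpoints.
#' @param criteria Named list or data.frame of non-negative numeric criterion
#'   scores, one element per criterion, each the length of `source_id`.
#' @param edge_type `"circ-mir"` or `"mir-gene"`.
#' @return A `data.frame` of class `interaction_table` with attribute
#'   `edge_type` and `criteria` (the criterion column names).
#' @export
interaction_table <- function(source_id, target_id, criteria,
                              edge_type = c("circ-mir", "mir-gene")) {
  edge_type <- match.arg(edge_type)
  criteria <- as.data.frame(criteria, optional = TRUE)
  if (!ncol(criteria) || is.null(names(criteria)))
    stop("interaction_table: at least one named criterion is required")
  df <- data.frame(source_id = as.character(source_id),
                   target_id = as.character(target_id),
                   criteria, stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("source_id", "target_id")]))
    stop("interaction_table: duplicate (source_id, target_id) pair")
  for (cn in names(criteria)) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("interaction_table: criterion '", cn, "' must be finite numeric")
    if (any(v < 0))
      stop("interaction_table: criterion '", cn, "' has negative values")
  }
  structure(df, edge_type = edge_type, criteria = names(criteria),
            class = c("interaction_table", "data.frame"))
}

#' Criterion column names of an interaction table
#' @param table An `interaction_table`.
#' @return Character vector of criterion names.
#' @export
interaction_criteria <- function(table) attr(table, "criteria")

#' Write a result table to TSV with a metadata comment header
#'
#' All tabular outputs of the pipeline are tab-delimited with `.` decimal
#' marks; a leading comment block records the tool version and the
#' parameters the table was produced under.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("cernaFrontier"))
  writeLines(paste0("# cernaFrontier ", version), con)
  if (length(params)) {
    kv <- vapply(names(params), function(k)
      paste0(k, "=", paste(format(params[[k]], digits = 15), collapse = ",")),
      character(1))
    writeLines(paste0("# ", kv), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#'
#' @param path Path to the TSV.
#' @return A data.frame (comment lines skipped).
#' @export
read_result_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
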