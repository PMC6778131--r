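#' Read a guide library CSV
#'
#' Expects the header `guide_id,gene,spacer,is_ntc`. `is_ntc` must agree with
#' the NTC sentinel in the `gene` column.
#'
#' @param path Path to a CSV file.
#' @param ntc_label Gene label used for non-targeting controls.
#' @return A `guide_library` data frame.
#' @export
read_guide_library <- function(path, ntc_label = "NTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("guide_id", "gene", "spacer", "is_ntc")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("guide library is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$is_ntc <- as.logical(df$is_ntc)
  validate_guide_library(df, ntc_label = ntc_label)
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Write a guide library CSV
#'
#' @param library A `guide_library` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(library, path) {
  utils::write.csv(
    library[, c("guide_id", "gene", "spacer", "is_ntc")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' The first column holds row identifiers (guides or clones); the remaining
#' columns are samples. Cells must be non-negative integers. Lines starting
#' with `#` are ignored. Malformed input is rejected with the offending line
#' number rather than coerced.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix with row and column names.
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) stop("counts file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  if (ncol_expect < 2) stop("counts file needs an id column plus >=1 sample column")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) stop("duplicated sample id in counts header")
  n <- length(fields) - 1L
  ids <- character(n)
  mat <- matrix(0L, nrow = n, ncol = ncol_expect - 1L)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expect) {
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   lineno[i + 1L], path, length(f), ncol_expect))
    }
    vals <- f[-1]
    if (!all(grepl("^[0-9]+$", vals))) {
      stop(sprintf("non-integer or negative count at line %d of %s",
                   lineno[i + 1L], path))
    }
    ids[i] <- f[1]
    mat[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated row id in counts file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dimnames(mat) <- list(ids, sample_ids)
  mat
}

#' Write a count matrix to TSV
#'
#' @param counts Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, id_column = "guide_id") {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Screen sample sheets carry `sample_id, timepoint, replicate, is_plasmid`;
#' barcode sheets omit `is_plasmid`.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "timepoint", "replicate") %in% names(df))) {
    stop("sample sheet must have sample_id, timepoint and replicate columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in sample sheet")
  if ("is_plasmid" %in% names(df)) df$is_plasmid <- as.logical(df$is_plasmid)
  df$timepoint <- as.character(df$timepoint)
  df
}

#' Write a sample sheet TSV
#'
#' @param samples Data frame of sample metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequence reads from FASTA
#'
#' Sequences are uppercased; anything outside `ACGTN` is rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in FASTA record(s): ",
         paste(utils::head(names(seqs)[bad], 5), collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an AIRR-style rearrangement TSV
#'
#' Required columns: `sequence_id, sequence, v_call, d_call, j_call, v_end,
#' junction, junction_length`. `v_end` is the 0-based half-open end of the V
#' region within `sequence` (use `from_one_based = TRUE` for 1-based inclusive
#' coordinates as emitted by IMGT-style annotators).
#'
#' @param path Path to a tab-separated file.
#' @param from_one_based Convert a 1-based inclusive `v_end` to 0-based
#'   half-open on read.
#' @return A data frame of annotated BCR records.
#' @export
read_airr_tsv <- function(path, from_one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sequence_id", "sequence", "v_call", "d_call", "j_call",
                "v_end", "junction", "junction_length")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("AIRR table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$sequence <- toupper(df$sequence)
  df$v_end <- as.integer(df$v_end)
  if (from_one_based) df$v_end <- df$v_end  # 1-based inclusive end == 0-based half-open end
  if (any(df$v_end <= 0L | df$v_end > nchar(df$sequence))) {
    stop("v_end out of range for some records (expected 0 < v_end <= sequence length)")
  }
  df
}

#' Write an AIRR-style rearrangement TSV
#'
#' @param airr Data frame of annotated BCR records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(airr, path) {
  utils::write.table(airr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a repertoire graph to GraphML
#'
#' @param graph A `repertoire_graph` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  ig <- as_igraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a clonal tree to newick
#'
#' Two-leaf trees use the `(A:d,B:0);` convention, with the full pairwise
#' distance on the first branch.
#'
#' @param tree A `clonal_tree` object (see [parsimony_tree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$tree, file = path)
  invisible(path)
}
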