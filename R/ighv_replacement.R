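#' Extract the stem region of an annotated BCR
#'
#' The stem is the N-IgHD-N-IgHJ region starting 3 bp downstream of the IgHV
#' gene boundary, i.e. the sequence suffix from 0-based position `v_end + 3`
#' through the end of the annotated span.
#'
#' @param sequence Nucleotide sequence (V through J).
#' @param v_end 0-based half-open end of the V region within `sequence`.
#' @param j_end 0-based half-open end of the annotated span; defaults to the
#'   sequence end.
#' @return The stem string; `""` when the sequence ends at or before
#'   `v_end + 3` (such records are excluded from pairing).
#' @export
extract_stem <- function(sequence, v_end, j_end = nchar(sequence)) {
  if (any(v_end <= 0 | v_end > nchar(sequence))) {
    stop("v_end must satisfy 0 < v_end <= sequence length")
  }
  substr(sequence, v_end + 4L, j_end)
}

#' Exclude BCRs with short joining regions
#'
#' Records whose N-IgHD-N-IgHJ span is shorter than `min_junction` nucleotides
#' are removed before replacement pairing, since very short joins can be
#' germline-encoded.
#'
#' @param bcrs AIRR-style data frame (see [read_airr_tsv()]); the span is
#'   `junction_length - 3` (the junction column carries the last 3 V
#'   nucleotides ahead of the N-D-N-J region).
#' @param min_junction Minimum span in nt (default 8).
#' @return List with `retained` (data frame) and `n_excluded`.
#' @export
filter_short_junctions <- function(bcrs, min_junction = 8L) {
  span <- bcrs$junction_length - 3L
  keep <- span >= min_junction
  list(retained = bcrs[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Pairwise V-region identity
#'
#' Percent identity of a global alignment with unit match/mismatch scores and
#' a linear unit gap cost: `matches / alignment columns * 100`. The argument
#' pair is canonicalised (lexicographic order) before aligning, so the value
#' is exactly symmetric.
#'
#' @param a,b Nucleotide sequences (non-empty).
#' @return Percent identity in \[0, 100\].
#' @export
v_region_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Detect IgHV gene replacement events
#'
#' Collapses reads to unique sequences, extracts stems, applies the
#' short-junction exclusion, groups unique BCRs by identical stem, and calls
#' a pair a replacement event when the two records (a) carry different V
#' calls with pairwise V-region identity below `identity_threshold`, and (b)
#' differ in their 5' junction string (last 3 nt of V + N-D-N-J). The
#' replacement percentage is the share of unique BCRs (post-exclusion)
#' participating in at least one pair.
#'
#' @param bcrs AIRR-style data frame with columns `sequence_id, sequence,
#'   v_call, v_end, junction, junction_length`.
#' @param identity_threshold V-region identity (%) below which V genes are
#'   considered different (default 95).
#' @param min_junction Minimum N-D-N-J span in nt (default 8).
#' @return A `replacement_report` list: `n_unique_bcrs` (post-exclusion),
#'   `n_excluded_short_junction`, `replacement_pairs` (data frame `id_a,
#'   id_b, stem, v_call_a, v_call_b, v_identity`), `n_participating`,
#'   `n_events` (stem groups containing at least one pair) and
#'   `pct_replacement` (`NA` when no records survive exclusion).
#' @export
detect_replacements <- function(bcrs, identity_threshold = 95,
                                min_junction = 8L) {
  required <- c("sequence_id", "sequence", "v_call", "v_end",
                "junction", "junction_length")
  missing <- setdiff(required, names(bcrs))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  # unique-sequence collapse: identical reads are one BCR
  uniq <- bcrs[!duplicated(bcrs$sequence), , drop = FALSE]

  flt <- filter_short_junctions(uniq, min_junction = min_junction)
  uniq <- flt$retained
  n_unique <- nrow(uniq)
  empty_pairs <- data.frame(
    id_a = character(0), id_b = character(0), stem = character(0),
    v_call_a = character(0), v_call_b = character(0),
    v_identity = numeric(0), stringsAsFactors = FALSE
  )
  if (n_unique == 0) {
    return(structure(list(
      n_unique_bcrs = 0L, n_excluded_short_junction = flt$n_excluded,
      replacement_pairs = empty_pairs, n_participating = 0L, n_events = 0L,
      pct_replacement = NA_real_
    ), class = "replacement_report"))
  }

  uniq$stem <- extract_stem(uniq$sequence, uniq$v_end)
  uniq$v_region <- substr(uniq$sequence, 1L, uniq$v_end)
  uniq$junction5 <- substr(uniq$sequence, uniq$v_end - 2L, nchar(uniq$sequence))
  skip <- !nzchar(uniq$v_region)
  if (any(skip)) {
    warning(sum(skip), " record(s) without a V-region sequence skipped")
    uniq <- uniq[!skip, , drop = FALSE]
  }

  pairs <- empty_pairs
  groups <- split(seq_len(nrow(uniq)), uniq$stem)
  groups <- groups[nzchar(names(groups)) & lengths(groups) > 1]
  for (g in groups) {
    for (ii in seq_len(length(g) - 1)) {
      for (jj in (ii + 1):length(g)) {
        a <- g[ii]; b <- g[jj]
        if (uniq$v_call[a] == uniq$v_call[b]) next
        if (uniq$junction5[a] == uniq$junction5[b]) next
        vid <- v_region_identity(uniq$v_region[a], uniq$v_region[b])
        if (vid >= identity_threshold) next
        pairs <- rbind(pairs, data.frame(
          id_a = uniq$sequence_id[a], id_b = uniq$sequence_id[b],
          stem = uniq$stem[a],
          v_call_a = uniq$v_call[a], v_call_b = uniq$v_call[b],
          v_identity = vid, stringsAsFactors = FALSE
        ))
      }
    }
  }
  participating <- unique(c(pairs$id_a, pairs$id_b))
  structure(list(
    n_unique_bcrs = n_unique,
    n_excluded_short_junction = flt$n_excluded,
    replacement_pairs = pairs,
    n_participating = length(participating),
    n_events = length(unique(pairs$stem)),
    pct_replacement = 100 * length(participating) / n_unique
  ), class = "replacement_report")
}
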