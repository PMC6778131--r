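#' Generate a labelled germline V-gene set
#'
#' Synthetic stand-ins for IgHV germline genes: random sequences that are
#' mutually dissimilar (pairwise global-alignment identity below
#' `max_pairwise_identity`), so discordant V calls always imply discordant V
#' sequence, as the replacement detector assumes.
#'
#' @param n Number of V genes.
#' @param length V-gene length in nt.
#' @param max_pairwise_identity Reject candidates more similar than this (%).
#' @param seed Integer seed.
#' @return Named character vector (`IGHVS1`, `IGHVS2`, ...).
#' @export
make_germline_v_set <- function(n = 8L, length = 60L,
                                max_pairwise_identity = 90, seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  vs <- character(0)
  while (length(vs) < n) {
    cand <- paste0(sample(bases, length, replace = TRUE), collapse = "")
    ok <- all(vapply(vs, function(v) {
      v_region_identity(cand, v) < max_pairwise_identity
    }, logical(1)))
    if (ok) vs <- c(vs, cand)
  }
  setNames(vs, sprintf("IGHVS%d", seq_len(n)))
}

#' Configuration for a synthetic BCR repertoire
#'
#' Each clone is a germline V gene joined to a random N-D-N-J region
#' ("stem" downstream of the first 3 nt), expanded to a power-law clone size
#' and diversified by uniform per-base somatic hypermutation (SHM). A clone
#' can carry a planted IgHV replacement: a second sequence family with the
#' identical stem, a different V gene and an altered 5' junction.
#'
#' @param n_clones Number of clones.
#' @param clone_size_exponent Power-law exponent of the clone-size
#'   distribution (P(size = s) proportional to s^-exponent); smaller values
#'   mean stronger clonal expansion.
#' @param max_clone_size Upper truncation of the clone-size law.
#' @param germline_v_set Named character vector of V genes; `NULL` generates
#'   one with [make_germline_v_set()] from the same seed.
#' @param shm_rate Substitution probability per base per read, in \[0, 0.1\].
#' @param replacement_rate Probability that a clone carries a planted IgHV
#'   replacement event, in \[0, 1\].
#' @param junction_length_range Two-element nt bounds of the N-D-N-J span.
#' @param seed Integer seed.
#' @return A `repertoire_sim_config` list.
#' @export
repertoire_sim_config <- function(n_clones = 50L,
                                  clone_size_exponent = 2,
                                  max_clone_size = 500L,
                                  germline_v_set = NULL,
                                  shm_rate = 1e-3,
                                  replacement_rate = 0,
                                  junction_length_range = c(8L, 32L),
                                  seed = 1L) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (shm_rate < 0 || shm_rate > 0.1) stop("shm_rate must be in [0, 0.1]")
  if (replacement_rate < 0 || replacement_rate > 1) {
    stop("replacement_rate must be in [0, 1]")
  }
  if (length(junction_length_range) != 2 ||
      junction_length_range[1] > junction_length_range[2] ||
      junction_length_range[1] < 3) {
    stop("junction_length_range must be increasing nt bounds >= 3")
  }
  cfg <- list(
    n_clones = as.integer(n_clones),
    clone_size_exponent = clone_size_exponent,
    max_clone_size = as.integer(max_clone_size),
    germline_v_set = germline_v_set,
    shm_rate = shm_rate,
    replacement_rate = replacement_rate,
    junction_length_range = as.integer(junction_length_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "repertoire_sim_config"
  cfg
}

#' Simulate a clonally expanded BCR heavy-chain repertoire
#'
#' @param config A [repertoire_sim_config()].
#' @return A list with elements:
#'   * `reads` — named character vector of read sequences (FASTA-ready);
#'   * `airr` — AIRR-style per-read annotation table (`sequence_id, sequence,
#'     v_call, d_call, j_call, v_end, junction, junction_length`); `v_end` is
#'     0-based half-open; `junction` is V(last 3 nt) + N-D-N-J, so
#'     `junction_length` is the N-D-N-J span plus 3;
#'   * `truth` — one row per planted sequence family (`family_id, clone_id,
#'     event_id, v_call, ancestor, stem, ndnj_span, n_reads`); rows sharing a
#'     non-`NA` `event_id` form a planted IgHV-replacement pair.
#' @export
simulate_repertoire <- function(config = repertoire_sim_config()) {
  stopifnot(inherits(config, "repertoire_sim_config"))
  set.seed(config$seed)
  vset <- config$germline_v_set
  if (is.null(vset)) {
    vset <- make_germline_v_set(seed = config$seed)
  }
  if (length(vset) == 0) stop("germline_v_set must be non-empty")
  if (is.null(names(vset))) names(vset) <- sprintf("IGHVS%d", seq_along(vset))
  if (config$replacement_rate > 0 && length(vset) < 2) {
    stop("planted replacements need at least two germline V genes")
  }
  bases <- c("A", "C", "G", "T")
  d_labels <- sprintf("IGHDS%d", 1:6)
  j_labels <- sprintf("IGHJS%d", 1:4)

  sizes <- sample_power_law(config$n_clones, config$clone_size_exponent,
                            config$max_clone_size)
  jlr <- config$junction_length_range

  families <- list()
  next_event <- 1L
  for (k in seq_len(config$n_clones)) {
    vi <- sample(length(vset), 1)
    span <- sample(seq(jlr[1], jlr[2]), 1)
    ndnj <- paste0(sample(bases, span, replace = TRUE), collapse = "")
    stem <- substring(ndnj, 4)
    d_call <- sample(d_labels, 1)
    j_call <- sample(j_labels, 1)
    families[[length(families) + 1L]] <- list(
      clone_id = k, event_id = NA_integer_, v_call = names(vset)[vi],
      ancestor = paste0(vset[[vi]], ndnj), v_end = nchar(vset[[vi]]),
      d_call = d_call, j_call = j_call, stem = stem, ndnj_span = span,
      n_reads = sizes[k]
    )
    if (runif(1) < config$replacement_rate) {
      # replacement partner: identical stem, different V, altered 5' junction
      vj <- sample(setdiff(seq_along(vset), vi), 1)
      repeat {
        gap2 <- paste0(sample(bases, 3, replace = TRUE), collapse = "")
        jx1 <- paste0(substr(vset[[vi]], nchar(vset[[vi]]) - 2, nchar(vset[[vi]])), ndnj)
        jx2 <- paste0(substr(vset[[vj]], nchar(vset[[vj]]) - 2, nchar(vset[[vj]])), gap2, stem)
        if (jx1 != jx2) break
      }
      families[[length(families) + 1L]] <- list(
        clone_id = k, event_id = next_event, v_call = names(vset)[vj],
        ancestor = paste0(vset[[vj]], gap2, stem), v_end = nchar(vset[[vj]]),
        d_call = d_call, j_call = j_call, stem = stem, ndnj_span = span,
        n_reads = sample_power_law(1, config$clone_size_exponent,
                                   config$max_clone_size)
      )
      families[[length(families) - 1L]]$event_id <- next_event
      next_event <- next_event + 1L
    }
  }

  truth <- do.call(rbind, lapply(seq_along(families), function(i) {
    f <- families[[i]]
    data.frame(family_id = i, clone_id = f$clone_id, event_id = f$event_id,
               v_call = f$v_call, ancestor = f$ancestor, stem = f$stem,
               ndnj_span = f$ndnj_span, n_reads = f$n_reads,
               stringsAsFactors = FALSE)
  }))

  total_reads <- sum(truth$n_reads)
  reads <- character(total_reads)
  airr_rows <- vector("list", total_reads)
  idx <- 0L
  for (i in seq_along(families)) {
    f <- families[[i]]
    for (r in seq_len(f$n_reads)) {
      idx <- idx + 1L
      seqr <- mutate_sequence(f$ancestor, config$shm_rate, bases)
      reads[idx] <- seqr
      jx <- substr(seqr, f$v_end - 2L, nchar(seqr))
      airr_rows[[idx]] <- data.frame(
        sequence_id = sprintf("read%06d", idx),
        sequence = seqr, v_call = f$v_call, d_call = f$d_call,
        j_call = f$j_call, v_end = f$v_end, junction = jx,
        junction_length = nchar(jx), stringsAsFactors = FALSE
      )
    }
  }
  airr <- do.call(rbind, airr_rows)
  names(reads) <- airr$sequence_id
  list(reads = reads, airr = airr, truth = truth)
}

# Truncated discrete power law: P(s) proportional to s^-exponent, s in 1..max.
sample_power_law <- function(n, exponent, max_size) {
  s <- seq_len(max_size)
  sample(s, n, replace = TRUE, prob = s^(-exponent))
}

mutate_sequence <- function(seq, rate, bases = c("A", "C", "G", "T")) {
  if (rate <= 0) return(seq)
  len <- nchar(seq)
  n_mut <- rbinom(1, len, rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(len, n_mut)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste0(chars, collapse = "")
}
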