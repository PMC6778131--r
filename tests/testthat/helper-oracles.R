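# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Screen scoring from raw integer counts, pseudofrequency 0. The frequency
# ratio (N_L * S_P) / (N_P * S_L) is an exact integer rational evaluated
# before the single log2, so the arithmetic is exact to double precision.
oracle_score_screen <- function(counts, samples, library, late_timepoint) {
  plasmid <- samples$sample_id[samples$is_plasmid]
  late <- samples[!samples$is_plasmid & samples$timepoint == late_timepoint, ]
  S <- colSums(counts)
  z <- matrix(NA_real_, nrow(counts), nrow(late))
  for (j in seq_len(nrow(late))) {
    sj <- late$sample_id[j]
    lfc <- log2((counts[, sj] * S[plasmid]) / (counts[, plasmid] * S[sj]))
    mu <- mean(lfc)
    sdev <- sqrt(sum((lfc - mu)^2) / length(lfc))
    z[, j] <- (lfc - mu) / sdev
  }
  gene <- library$gene[match(rownames(counts), library$guide_id)]
  sapply(split(seq_len(nrow(counts)), gene), function(idx) mean(z[idx, ]))
}

# All-pairs Hamming-1 edges (sequences containing N excluded), vectorised
# column-wise so instances up to ~500 vertices stay fast.
oracle_edges <- function(seqs) {
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  out <- list()
  for (len in unique(nchar(seqs))) {
    grp <- sort(seqs[nchar(seqs) == len])
    n <- length(grp)
    if (n < 2) next
    ch <- do.call(rbind, strsplit(grp, ""))
    diffs <- matrix(0L, n, n)
    for (p in seq_len(len)) {
      diffs <- diffs + outer(ch[, p], ch[, p], "!=")
    }
    hit <- which(diffs == 1 & upper.tri(diffs), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out[[length(out) + 1]] <- data.frame(
        from = grp[hit[, 1]], to = grp[hit[, 2]], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$from, df$to), , drop = FALSE]
}

edge_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(pmin(df$from, df$to), pmax(df$from, df$to)))
}

# Exhaustive parsimony by stepwise-addition enumeration of unrooted
# topologies (rooted at leaf 1) plus a per-site Fitch recursion.
oracle_parsimony_score <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 3)
  chars <- do.call(rbind, strsplit(unname(seqs), ""))

  insert_all <- function(tree, leaf) {
    res <- list(list(tree, leaf))
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in insert_all(tree[[side]], leaf)) {
          mod <- tree
          mod[[side]] <- sub
          res[[length(res) + 1]] <- mod
        }
      }
    }
    res
  }
  trees <- list(2L)
  for (leaf in seq_len(n)[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_all, leaf = leaf), recursive = FALSE)
  }

  fitch_site <- function(tree, site) {
    rec <- function(node) {
      if (!is.list(node)) return(list(set = chars[node, site], cost = 0L))
      l <- rec(node[[1]]); r <- rec(node[[2]])
      inter <- intersect(l$set, r$set)
      if (length(inter) > 0) {
        list(set = inter, cost = l$cost + r$cost)
      } else {
        list(set = union(l$set, r$set), cost = l$cost + r$cost + 1L)
      }
    }
    top <- rec(tree)
    # join the root edge leading to leaf 1
    if (chars[1, site] %in% top$set) top$cost else top$cost + 1L
  }

  score_tree <- function(tree) {
    sum(vapply(seq_len(ncol(chars)), function(s) fitch_site(tree, s), integer(1)))
  }
  min(vapply(trees, score_tree, integer(1)))
}

# Random SHM-style cluster: mutate a random ancestor along random parentage.
random_cluster <- function(k, len = 40, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- paste0(sample(bases, len, replace = TRUE), collapse = "")
  while (length(seqs) < k) {
    parent <- sample(seqs, 1)
    nm <- sample(1:3, 1)
    pos <- sample.int(len, nm)
    ch <- strsplit(parent, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    cand <- paste0(ch, collapse = "")
    if (!cand %in% seqs) seqs <- c(seqs, cand)
  }
  setNames(seqs, paste0("s", seq_len(k)))
}

# Minimal hand-built screen: counts matrix + sample sheet.
tiny_screen <- function(counts, timepoints, replicates) {
  samples <- data.frame(
    sample_id = colnames(counts),
    timepoint = timepoints,
    replicate = replicates,
    is_plasmid = timepoints == "plasmid",
    stringsAsFactors = FALSE
  )
  list(counts = counts, samples = samples)
}
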