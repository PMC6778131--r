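#' Maximum-parsimony clonal tree for a cluster's sequences
#'
#' Builds an unrooted tree over a cluster's unique sequences with integer
#' branch lengths (substitution counts, ACCTRAN assignment) summing to the
#' Fitch parsimony score. For small clusters (up to `max_exhaustive` leaves)
#' every unrooted topology is scored and a minimum-score tree returned; above
#' that, a heuristic search (neighbour-joining start on Hamming distances,
#' nearest-neighbour-interchange rearrangements) is used.
#'
#' @param sequences Named character vector of >= 2 equal-length sequences
#'   (unnamed input gets labels `s1, s2, ...`).
#' @param max_exhaustive Leaf count up to which the search is exhaustive.
#' @param method `"auto"` (exhaustive up to `max_exhaustive`, else
#'   heuristic), `"exhaustive"` or `"heuristic"`.
#' @param seed Integer seed (the heuristic path is deterministic given it).
#' @return A `clonal_tree` list: `tree` (an `ape::phylo` with integer branch
#'   lengths), `score` (total parsimony score) and `method` used.
#' @export
parsimony_tree <- function(sequences, max_exhaustive = 8L,
                           method = c("auto", "exhaustive", "heuristic"),
                           seed = 1L) {
  method <- match.arg(method)
  n <- length(sequences)
  if (n < 2) stop("need at least two sequences")
  if (length(unique(nchar(sequences))) != 1) {
    stop("sequences must have equal length")
  }
  if (is.null(names(sequences))) names(sequences) <- paste0("s", seq_len(n))
  if (anyDuplicated(names(sequences))) stop("sequence names must be unique")
  set.seed(as.integer(seed))

  if (n == 2) {
    d <- hamming(sequences[1], sequences[2])
    txt <- sprintf("(%s:%d,%s:0);", names(sequences)[1], d, names(sequences)[2])
    return(structure(list(tree = ape::read.tree(text = txt), score = d,
                          method = "pair"), class = "clonal_tree"))
  }

  pd <- phangorn::phyDat(
    do.call(rbind, strsplit(sequences, "")),
    type = "DNA"
  )

  if (n == 3) return(three_taxon_tree(sequences))

  if (method == "exhaustive" ||
      (method == "auto" && n <= max_exhaustive)) {
    trees <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = names(sequences))
    scores <- vapply(trees, function(tr) phangorn::fitch(tr, pd), numeric(1))
    return(finish_tree(trees[[which.min(scores)]], pd, "exhaustive"))
  }

  dm <- hamming_dist_matrix(sequences)
  start <- ape::unroot(ape::nj(stats::as.dist(dm)))
  start$edge.length <- NULL
  fit <- phangorn::optim.parsimony(start, pd, method = "fitch",
                                   rearrangements = "NNI", trace = 0)
  finish_tree(fit, pd, "heuristic")
}

# Single unrooted 3-taxon topology: per site, a column with two equal states
# puts one change on the odd leaf's branch; an all-distinct column puts one
# change on each of the second and third branches (the first leaf's state is
# taken as the central assignment). Total equals the Fitch score
# (#distinct states - 1 per column).
three_taxon_tree <- function(sequences) {
  ch <- do.call(rbind, strsplit(sequences, ""))
  b <- c(0L, 0L, 0L)
  for (s in seq_len(ncol(ch))) {
    col <- ch[, s]
    if (col[1] == col[2] && col[2] == col[3]) next
    if (col[1] == col[2]) { b[3] <- b[3] + 1L
    } else if (col[1] == col[3]) { b[2] <- b[2] + 1L
    } else if (col[2] == col[3]) { b[1] <- b[1] + 1L
    } else { b[2] <- b[2] + 1L; b[3] <- b[3] + 1L }
  }
  nm <- names(sequences)
  txt <- sprintf("(%s:%d,%s:%d,%s:%d);", nm[1], b[1], nm[2], b[2], nm[3], b[3])
  structure(list(tree = ape::read.tree(text = txt), score = sum(b),
                 method = "exhaustive"), class = "clonal_tree")
}

finish_tree <- function(tree, pd, method) {
  tree <- phangorn::acctran(tree, pd)
  score <- as.numeric(phangorn::fitch(tree, pd))
  stopifnot(isTRUE(all.equal(sum(tree$edge.length), score)))
  structure(list(tree = tree, score = score, method = method),
            class = "clonal_tree")
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Sequences of equal length.
#' @return Integer substitution count.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

hamming_dist_matrix <- function(sequences) {
  n <- length(sequences)
  chars <- do.call(rbind, strsplit(sequences, ""))
  dm <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(chars[i, ] != chars[j, ])
      dm[i, j] <- d
      dm[j, i] <- d
    }
  }
  dm
}

#' Parsimony trees for all clusters of a repertoire graph
#'
#' @param graph A `repertoire_graph`.
#' @param min_size Smallest cluster (in unique sequences) to build a tree for.
#' @param max_exhaustive Passed to [parsimony_tree()].
#' @param seed Integer seed.
#' @return Named list of `clonal_tree` objects, one per qualifying cluster
#'   (names are cluster ids).
#' @export
cluster_trees <- function(graph, min_size = 2L, max_exhaustive = 8L, seed = 1L) {
  stopifnot(inherits(graph, "repertoire_graph"))
  by_cluster <- split(graph$vertices$sequence, graph$vertices$cluster_id)
  by_cluster <- by_cluster[lengths(by_cluster) >= min_size]
  out <- lapply(by_cluster, function(seqs) {
    names(seqs) <- seqs
    parsimony_tree(seqs, max_exhaustive = max_exhaustive, seed = seed)
  })
  out
}
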