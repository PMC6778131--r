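#' Collapse reads to unique sequences
#'
#' @param reads Character vector of uppercase ACGT(N) sequences.
#' @return Named integer vector: unique sequence -> read multiplicity,
#'   sequences in lexicographic order.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0) stop("no reads supplied")
  if (any(grepl("[^ACGTN]", reads))) {
    stop("reads must be uppercase sequences over {A,C,G,T,N}")
  }
  tab <- table(reads)
  setNames(as.integer(tab), names(tab))
}

#' Single-substitution edges between unique sequences
#'
#' An edge joins two sequences iff they have equal length and Hamming
#' distance exactly 1 (single-nucleotide, non-indel difference). Sequences
#' containing N are excluded from edge building. The implementation buckets
#' sequences by their string with one position masked — two unique sequences
#' share a bucket iff they differ exactly at the masked position — which is
#' extensionally equal to the all-pairs Hamming check without being O(n^2).
#'
#' @param vertices Named vector as from [collapse_reads()] (names are the
#'   unique sequences), or a character vector of unique sequences.
#' @return Data frame with character columns `from`, `to` (`from < to`
#'   lexicographically), one row per edge.
#' @export
build_edges <- function(vertices) {
  seqs <- if (is.null(names(vertices))) as.character(vertices) else names(vertices)
  if (length(seqs) == 0) stop("no vertices supplied")
  if (anyDuplicated(seqs)) stop("vertex sequences must be unique")
  usable <- seqs[!grepl("N", seqs, fixed = TRUE)]
  from <- character(0); to <- character(0)
  for (len in unique(nchar(usable))) {
    grp <- usable[nchar(usable) == len]
    if (length(grp) < 2) next
    for (p in seq_len(len)) {
      key <- paste0(substr(grp, 1, p - 1), ".", substr(grp, p + 1, len))
      buckets <- split(grp, key)
      buckets <- buckets[lengths(buckets) > 1]
      for (b in buckets) {
        b <- sort(b)
        pr <- utils::combn(b, 2)
        from <- c(from, pr[1, ])
        to <- c(to, pr[2, ])
      }
    }
  }
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

#' Connected-component clusters of a sequence graph
#'
#' Cluster IDs are stable: clusters are numbered by decreasing vertex count,
#' ties broken by the lexicographically smallest member sequence.
#'
#' @param vertices Named multiplicity vector or character vector of unique
#'   sequences.
#' @param edges Edge data frame from [build_edges()].
#' @return Named integer vector: sequence -> cluster id.
#' @export
find_clusters <- function(vertices, edges) {
  seqs <- if (is.null(names(vertices))) as.character(vertices) else names(vertices)
  ig <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seqs, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(ig)
  membership <- comp$membership[seqs]
  # stable renumbering: size desc, then smallest member sequence
  groups <- split(seqs, membership)
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  relabel <- integer(length(groups))
  relabel[as.integer(names(groups)[ord])] <- seq_along(groups)
  setNames(relabel[membership], seqs)
}

#' Build a BCR repertoire graph from reads
#'
#' Vertices are unique sequences sized by read multiplicity; edges join
#' vertices differing by a single non-indel substitution; clusters are
#' connected components.
#'
#' @param reads Character vector of sequences (e.g. from [read_fasta()]).
#' @return A `repertoire_graph` list: `vertices` (data frame `sequence, size,
#'   cluster_id`), `edges` (data frame `from, to`), `n_reads`, and
#'   `n_with_ambiguity` (vertices containing N, kept as isolated vertices).
#' @export
build_repertoire_graph <- function(reads) {
  vmap <- collapse_reads(reads)
  edges <- build_edges(vmap)
  clusters <- find_clusters(vmap, edges)
  vertices <- data.frame(
    sequence = names(vmap),
    size = as.integer(vmap),
    cluster_id = as.integer(clusters[names(vmap)]),
    stringsAsFactors = FALSE
  )
  structure(
    list(vertices = vertices, edges = edges,
         n_reads = length(reads),
         n_with_ambiguity = sum(grepl("N", names(vmap), fixed = TRUE))),
    class = "repertoire_graph"
  )
}

#' Convert a repertoire graph to igraph
#'
#' @param graph A `repertoire_graph`.
#' @return An undirected `igraph` object with `size` and `cluster_id` vertex
#'   attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "repertoire_graph"))
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(
      name = graph$vertices$sequence,
      size = graph$vertices$size,
      cluster_id = graph$vertices$cluster_id,
      stringsAsFactors = FALSE
    )
  )
}

#' Clonality report for a repertoire
#'
#' Summarises clonal expansion: total and unique read counts, the percentage
#' of unique sequences (low values mean strong expansion), the largest
#' cluster, and the cluster-size distribution.
#'
#' @param reads Character vector of reads.
#' @param graph Optional pre-built `repertoire_graph` over the same reads.
#' @return A `clonality_report` list: `n_reads, n_unique, pct_unique,
#'   max_cluster_size, cluster_sizes` (integer vector by cluster id).
#' @export
clonality <- function(reads, graph = NULL) {
  if (is.null(graph)) graph <- build_repertoire_graph(reads)
  if (graph$n_reads != length(reads)) {
    stop("graph was not built from the supplied reads")
  }
  sizes <- tabulate(graph$vertices$cluster_id)
  structure(
    list(
      n_reads = length(reads),
      n_unique = nrow(graph$vertices),
      pct_unique = 100 * nrow(graph$vertices) / length(reads),
      max_cluster_size = max(sizes),
      cluster_sizes = sizes
    ),
    class = "clonality_report"
  )
}

#' Cluster-enforced linkage (CC) subsampling of a repertoire graph
#'
#' Downsamples the graph to `n_target` vertices while preserving clonal
#' structure, in three steps per attempt: (1) vertex selection — vertices are
#' drawn (by default with probability proportional to vertex size) and
#' redrawn until every original cluster is represented (when
#' `n_target` is below the cluster count, the largest clusters are
#' prioritised, one vertex each); (2) cluster-vertex migration — within each
#' cluster holding two or more selected vertices, the selection is moved
#' along cluster paths so it induces a connected subgraph (a deterministic
#' size-then-lexicographic breadth-first prefix from the largest selected
#' vertex, preserving the selected count); (3) induced graph formation —
#' total induction keeps every original edge with both endpoints selected.
#' The process is repeated `repeats` times and the attempt whose maximum
#' sampled cluster size is closest to the original maximum cluster size
#' scaled by the sampling fraction `n_target / |V|` is retained (ties: the
#' earliest attempt).
#'
#' @param graph A `repertoire_graph`.
#' @param n_target Number of vertices to retain, in `[1, |V|]`.
#' @param repeats Number of subsampling attempts.
#' @param seed Integer seed; the result is deterministic given it.
#' @param weight `"size"` (default) to select vertices proportionally to read
#'   multiplicity, `"uniform"` for unweighted selection.
#' @return A `repertoire_graph` over the sampled vertices (clusters
#'   renumbered by the stable rule), with attribute `cc_info` recording the
#'   retained attempt, the target maximum cluster size and the achieved one.
#' @export
cc_subsample <- function(graph, n_target, repeats = 20L, seed = 1L,
                         weight = c("size", "uniform")) {
  stopifnot(inherits(graph, "repertoire_graph"))
  weight <- match.arg(weight)
  n <- nrow(graph$vertices)
  if (n_target < 1 || n_target > n) {
    stop("n_target must be between 1 and the number of vertices (", n, ")")
  }
  set.seed(as.integer(seed))
  vs <- graph$vertices
  w <- if (weight == "size") vs$size else rep(1, n)
  idx_of <- setNames(seq_len(n), vs$sequence)

  # adjacency in deterministic order: neighbour size desc, then sequence
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    a <- idx_of[graph$edges$from]
    b <- idx_of[graph$edges$to]
    for (e in seq_along(a)) {
      adj[[a[e]]] <- c(adj[[a[e]]], b[e])
      adj[[b[e]]] <- c(adj[[b[e]]], a[e])
    }
    adj <- lapply(adj, function(nb) {
      if (is.null(nb)) return(integer(0))
      nb[order(-vs$size[nb], vs$sequence[nb])]
    })
  } else {
    adj <- rep(list(integer(0)), n)
  }

  clusters <- split(seq_len(n), vs$cluster_id)
  k <- length(clusters)
  mcs_orig <- max(lengths(clusters))
  target_mcs <- mcs_orig * n_target / n

  best <- NULL
  best_diff <- Inf
  for (attempt in seq_len(repeats)) {
    sel <- cc_select_vertices(n, n_target, w, vs, clusters)
    sel <- cc_migrate(sel, clusters, adj, vs)
    per_cluster <- tabulate(vs$cluster_id[sel], nbins = k)
    diff <- abs(max(per_cluster) - target_mcs)
    if (diff < best_diff) {
      best <- sel
      best_diff <- diff
      best_attempt <- attempt
    }
  }

  keep <- sort(best)
  kept_seq <- vs$sequence[keep]
  sub_edges <- graph$edges[graph$edges$from %in% kept_seq &
                             graph$edges$to %in% kept_seq, , drop = FALSE]
  rownames(sub_edges) <- NULL
  vmap <- setNames(vs$size[keep], kept_seq)
  new_clusters <- find_clusters(vmap, sub_edges)
  out <- structure(
    list(
      vertices = data.frame(sequence = kept_seq,
                            size = vs$size[keep],
                            cluster_id = as.integer(new_clusters[kept_seq]),
                            stringsAsFactors = FALSE),
      edges = sub_edges,
      n_reads = sum(vs$size[keep]),
      n_with_ambiguity = sum(grepl("N", kept_seq, fixed = TRUE))
    ),
    class = "repertoire_graph"
  )
  attr(out, "cc_info") <- list(
    attempt = best_attempt,
    target_max_cluster = target_mcs,
    achieved_max_cluster = max(tabulate(out$vertices$cluster_id))
  )
  out
}

# Step 1: vertex selection with cluster representation.
cc_select_vertices <- function(n, n_target, w, vs, clusters, max_tries = 100L) {
  k <- length(clusters)
  if (n_target < k) {
    # prioritise the largest clusters (ties: smallest member sequence),
    # one vertex from each
    ord <- order(-lengths(clusters),
                 vapply(clusters, function(i) min(vs$sequence[i]), character(1)))
    chosen <- clusters[ord][seq_len(n_target)]
    return(vapply(chosen, function(i) {
      if (length(i) == 1) i else sample(i, 1, prob = w[i])
    }, integer(1)))
  }
  for (try in seq_len(max_tries)) {
    sel <- sample.int(n, n_target, prob = w)
    if (length(unique(vs$cluster_id[sel])) == k) return(sel)
  }
  # constructive fallback: one weighted vertex per cluster, remainder weighted
  base <- vapply(clusters, function(i) {
    if (length(i) == 1) i else sample(i, 1, prob = w[i])
  }, integer(1))
  rest <- setdiff(seq_len(n), base)
  extra <- n_target - k
  if (extra > 0) {
    base <- c(base, if (length(rest) == 1) rest else
      sample(rest, extra, prob = w[rest]))
  }
  base
}

# Step 2: cluster-vertex migration. Within each multiply-selected cluster,
# reselect a connected set of the same cardinality: a deterministic BFS
# prefix (neighbour order: size desc, then sequence) from the largest
# selected vertex.
cc_migrate <- function(sel, clusters, adj, vs) {
  out <- integer(0)
  sel_by_cluster <- split(sel, vs$cluster_id[sel])
  for (cl in names(sel_by_cluster)) {
    s <- sel_by_cluster[[cl]]
    if (length(s) < 2 || cc_connected(s, adj)) {
      out <- c(out, s)
      next
    }
    root <- s[order(-vs$size[s], vs$sequence[s])][1]
    out <- c(out, bfs_prefix(root, length(s), adj))
  }
  out
}

# Is the induced subgraph over vertex set s connected?
cc_connected <- function(s, adj) {
  s_set <- s
  visited <- s[1]
  frontier <- s[1]
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(intersect(nxt, s_set), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  length(visited) == length(s_set)
}

# First m vertices of a deterministic BFS from root over the whole cluster.
bfs_prefix <- function(root, m, adj) {
  visited <- root
  queue <- root
  while (length(visited) < m && length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    new <- setdiff(adj[[v]], visited)
    visited <- c(visited, new)
    queue <- c(queue, new)
  }
  visited[seq_len(m)]
}
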