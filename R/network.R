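#' Minimum-spanning haplotype network
#'
#' Collapses identical sequences to unique haplotypes (alignment columns
#' with any ambiguous character are dropped globally first), computes
#' pairwise Hamming distances in mutational steps, and builds a minimum
#' spanning tree by Kruskal's algorithm with a deterministic tie-break:
#' candidate edges are sorted by (weight, first node id, second node id).
#' Non-tree edges whose weight equals the largest weight on the tree path
#' between their endpoints could replace that path edge at identical total
#' weight; they are returned flagged `is_alternative`.
#'
#' @param h A [haplotype_set()].
#' @param pops Optional named list of sample-id vectors; per-population
#'   haplotype composition is recorded on each node.
#' @return An object of class `haplotype_network`: list with `nodes`
#'   (tibble: `haplotype`, `count`, `samples` (list-col), plus one count
#'   column per population) and `edges` (tibble: `from`, `to`, `steps`,
#'   `is_alternative`).
#' @export
build_haplotype_network <- function(h, pops = NULL) {
  ids <- if (is.null(pops)) h$sample_ids else unlist(pops, use.names = FALSE)
  if (length(ids) == 0L) stop("no sequences", call. = FALSE)
  seqs <- h$sequences[ids]
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bad <- matrix(!(chars %in% c("A", "C", "G", "T")), nrow = nrow(chars))
  chars <- chars[, colSums(bad) == 0, drop = FALSE]
  key <- apply(chars, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  hap_of <- match(key, key[uniq])
  n_hap <- sum(uniq)
  hap_ids <- sprintf("H%02d", seq_len(n_hap))

  nodes <- tibble::tibble(
    haplotype = hap_ids,
    count = as.integer(tabulate(hap_of, n_hap)),
    samples = lapply(seq_len(n_hap), function(k) ids[hap_of == k])
  )
  if (!is.null(pops)) {
    for (p in names(pops)) {
      nodes[[p]] <- vapply(nodes$samples, function(s) {
        sum(s %in% pops[[p]])
      }, integer(1))
    }
  }

  um <- chars[uniq, , drop = FALSE]
  dmat <- matrix(0L, n_hap, n_hap)
  if (n_hap > 1L) {
    matches <- matrix(0, n_hap, n_hap)
    for (b in c("A", "C", "G", "T")) {
      ind <- (um == b) * 1
      matches <- matches + tcrossprod(ind)
    }
    dmat <- ncol(um) - matches
  }

  edges <- tibble::tibble(from = character(), to = character(),
                          steps = integer(), is_alternative = logical())
  if (n_hap > 1L) {
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    cand <- tibble::tibble(from = hap_ids[pr[, 1]], to = hap_ids[pr[, 2]],
                           steps = as.integer(dmat[pr]))
    cand <- cand[order(cand$steps, cand$from, cand$to), ]
    # Kruskal with union-find
    parent <- seq_len(n_hap)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    in_tree <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      ra <- find(match(cand$from[e], hap_ids))
      rb <- find(match(cand$to[e], hap_ids))
      if (ra != rb) {
        parent[ra] <- rb
        in_tree[e] <- TRUE
      }
    }
    tree <- cand[in_tree, ]
    gt <- igraph::graph_from_data_frame(
      tree[, c("from", "to")], directed = FALSE, vertices = hap_ids)
    igraph::E(gt)$steps <- tree$steps
    alt <- cand[!in_tree, ]
    is_alt <- logical(nrow(alt))
    for (e in seq_len(nrow(alt))) {
      path <- igraph::shortest_paths(gt, alt$from[e], alt$to[e],
                                     output = "epath")$epath[[1]]
      is_alt[e] <- length(path) > 0 &&
        max(igraph::E(gt)$steps[path]) == alt$steps[e]
    }
    tree$is_alternative <- FALSE
    alt$is_alternative <- is_alt
    edges <- dplyr::bind_rows(tree, alt[alt$is_alternative, ])
  }
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "<haplotype_network> %d haplotypes (%d sequences), %d tree edges",
    nrow(x$nodes), sum(x$nodes$count), sum(!x$edges$is_alternative)))
  n_alt <- sum(x$edges$is_alternative)
  if (n_alt) cat(sprintf(" + %d alternative", n_alt))
  cat(sprintf("; total steps %d\n",
              sum(x$edges$steps[!x$edges$is_alternative])))
  invisible(x)
}

#' Network tables as tibbles
#' @param x A `haplotype_network`.
#' @param ... Unused.
#' @return The edge tibble (`tidy`).
#' @export
tidy.haplotype_network <- function(x, ...) x$edges
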