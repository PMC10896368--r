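#' Construct a signed directed regulatory network
#'
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{sign}; signs may be \code{"activation"}/\code{"inhibition"} or
#'   \code{"+"}/\code{"-"}. Duplicate (source, target, sign) triples are
#'   collapsed.
#' @param nodes optional extra node IDs beyond the edge endpoints.
#' @return object of class \code{signed_digraph} with \code{nodes} and
#'   \code{edges}.
#' @export
signed_digraph <- function(edges, nodes = character(0)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  edges$sign <- c("+" = "activation", "-" = "inhibition",
                  activation = "activation", inhibition = "inhibition")[edges$sign]
  if (any(is.na(edges$sign))) stop("edge sign must be activation/inhibition (+/-)", call. = FALSE)
  edges <- unique(edges[, c("source", "target", "sign")])
  rownames(edges) <- NULL
  structure(list(
    nodes = sort(unique(c(nodes, edges$source, edges$target))),
    edges = edges
  ), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("signed_digraph: %d nodes, %d edges (%d inhibition)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "inhibition")))
  invisible(x)
}

#' Prune a signed network by Boolean-state compatibility
#'
#' Keeps an activation edge only when source and target share the same
#' Boolean state, and an inhibition edge only when their states differ; edges
#' with an endpoint lacking a state are dropped, and the node set is
#' restricted to the stated proteins.
#'
#' @param network a \code{signed_digraph}.
#' @param state named 0/1 vector (Booleanized abundance: 1 = up in the
#'   condition, 0 = down).
#' @return the pruned \code{signed_digraph}.
#' @export
prune_by_boolean_state <- function(network, state) {
  e <- network$edges
  e <- e[e$source %in% names(state) & e$target %in% names(state), , drop = FALSE]
  ss <- state[e$source]; st <- state[e$target]
  keep <- ifelse(e$sign == "activation", ss == st, ss != st)
  signed_digraph(e[keep, , drop = FALSE],
                 nodes = intersect(network$nodes, names(state)))
}

#' Derive the two condition-specific networks from endpoint DAA estimates
#'
#' Booleanizes the endpoint (A+T+ vs A-T-) differential-abundance estimates —
#' positive estimate = 1, negative = 0 — to obtain the case (A+T+) state,
#' complements it for the control (A-T-) state, and prunes the prior network
#' under each. Proteins with an estimate of exactly 0 are dropped with a
#' warning.
#'
#' @param network a \code{signed_digraph}.
#' @param daa \code{daa_result} table for the A+T+ vs A-T- comparison.
#' @return list with \code{case} and \code{control} pruned networks and the
#'   \code{case_state} used.
#' @export
condition_networks <- function(network, daa) {
  idx <- match(network$nodes, daa$aptamer_id)
  est <- daa$estimate[idx]
  known <- !is.na(est)
  if (any(known & est == 0)) {
    warning("nodes with estimate exactly 0 dropped: ",
            paste(network$nodes[known & est == 0], collapse = ", "), call. = FALSE)
    known <- known & est != 0
  }
  case_state <- stats::setNames(as.integer(est[known] > 0), network$nodes[known])
  list(
    case = prune_by_boolean_state(network, case_state),
    control = prune_by_boolean_state(network, 1L - case_state),
    case_state = case_state
  )
}

#' Enumerate elementary circuits of a signed digraph
#'
#' An elementary circuit is a directed cycle that begins and ends at the same
#' node and visits each intermediate node at most once. All circuits with at
#' most \code{max_len} edges are enumerated (self-loops count as length 1),
#' each reported once in its canonical rotation starting at its
#' lexicographically smallest node. The parity of a circuit is positive when
#' it contains an even number of inhibition edges and negative otherwise.
#' Parallel activation and inhibition edges between the same node pair yield
#' distinct circuits.
#'
#' @param network a \code{signed_digraph}.
#' @param max_len maximum circuit length in edges (default 8); longer cycles
#'   are not reported and a message notes when the cap was hit.
#' @return object of class \code{circuit_set}: a list of circuits, each with
#'   \code{nodes} (in traversal order, starting at the smallest), \code{signs}
#'   (edge signs along the cycle) and \code{parity}.
#' @export
enumerate_circuits <- function(network, max_len = 8L) {
  if (max_len < 1) stop("max_len must be >= 1", call. = FALSE)
  nodes <- sort(network$nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  e <- network$edges
  adj <- split(seq_len(nrow(e)), factor(e$source, levels = nodes))

  circuits <- list()
  cap_hit <- FALSE

  # DFS from each start node s, restricted to nodes with index >= idx(s): every
  # cycle is then discovered exactly once, from its smallest node.
  for (s in nodes) {
    s_i <- idx[[s]]
    path_nodes <- s
    path_signs <- character(0)
    visit <- function(v) {
      for (ei in adj[[v]]) {
        tgt <- e$target[ei]
        if (idx[[tgt]] < s_i) next
        if (tgt == s) {
          circuits[[length(circuits) + 1L]] <<- list(
            nodes = path_nodes,
            signs = c(path_signs, e$sign[ei]),
            parity = if (sum(c(path_signs, e$sign[ei]) == "inhibition") %% 2 == 0)
              "positive" else "negative"
          )
        } else if (!(tgt %in% path_nodes)) {
          if (length(path_signs) + 1L >= max_len) {
            cap_hit <<- TRUE
            next
          }
          path_nodes <<- c(path_nodes, tgt)
          path_signs <<- c(path_signs, e$sign[ei])
          visit(tgt)
          path_nodes <<- path_nodes[-length(path_nodes)]
          path_signs <<- path_signs[-length(path_signs)]
        }
      }
    }
    visit(s)
  }
  if (cap_hit) message("circuit enumeration truncated at max_len = ", max_len)
  structure(circuits, class = "circuit_set", max_len = max_len)
}

#' @export
print.circuit_set <- function(x, ...) {
  par <- vapply(x, `[[`, character(1), "parity")
  cat(sprintf("circuit_set: %d circuits (%d positive, %d negative)\n",
              length(x), sum(par == "positive"), sum(par == "negative")))
  invisible(x)
}

#' Proteins constituting a circuit set
#'
#' @param circuits a \code{circuit_set}.
#' @return character vector: the union of nodes over all circuits (empty,
#'   with a warning, for an empty circuit set — enrichment is then skipped).
#' @export
circuit_proteins <- function(circuits) {
  if (length(circuits) == 0) {
    warning("empty circuit set; enrichment will be skipped", call. = FALSE)
    return(character(0))
  }
  sort(unique(unlist(lapply(circuits, `[[`, "nodes"))))
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term, tests whether the query set over-represents the term's
#' members relative to the background (the full measured panel), using the
#' upper-tail hypergeometric probability P(X >= k) — equivalent to a
#' one-tailed Fisher's exact test — followed by Benjamini-Hochberg FDR across
#' the tested terms. Terms are intersected with the background before
#' testing; terms with no query overlap get p = 1.
#'
#' @param query protein IDs (must be a subset of \code{background}).
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}); names are term IDs, an optional
#'   \code{"description"} attribute per element is carried through.
#' @param background all measured protein IDs.
#' @return data frame of class \code{enrichment_result}: term_id, term_name,
#'   k (overlap), n (query size), K (term size in background), N (background
#'   size), p, fdr.
#' @export
hypergeom_enrich <- function(query, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("background must be non-empty", call. = FALSE)
  if (!all(query %in% background)) {
    stop("query must be a subset of the background", call. = FALSE)
  }
  query <- unique(query)
  N <- length(background); n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), background)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- attr(gene_sets[[term]], "description")
    data.frame(term_id = term,
               term_name = if (is.null(desc)) term else desc,
               k = k, n = n, K = K, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cell-type over-representation with exclusive marker sets
#'
#' Same statistic as \code{\link{hypergeom_enrich}}, one test per cell type.
#' Marker sets must be mutually disjoint (markers exclusively expressed in a
#' single cell type); overlaps are an error.
#'
#' @param query protein IDs (subset of background).
#' @param markers named list: cell type -> exclusive marker proteins.
#' @param background all measured protein IDs.
#' @return an \code{enrichment_result} data frame (one row per cell type).
#' @export
celltype_enrich <- function(query, markers, background) {
  all_markers <- unlist(markers, use.names = FALSE)
  dup <- unique(all_markers[duplicated(all_markers)])
  if (length(dup) > 0) {
    stop("marker sets overlap on: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  hypergeom_enrich(query, markers, background)
}
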