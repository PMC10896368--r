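# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the circuit oracle enumerates candidate node
# permutations outright, the AUC oracle counts case-control pairs, the KM
# oracle multiplies hand-computed factors.

# all permutations of a character vector (n <= 7 here)
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# brute-force elementary-circuit enumeration: try every node subset, every
# rotation-canonical ordering (starting at the subset's smallest node), every
# combination of parallel-edge signs
brute_force_circuits <- function(net, max_len = 8) {
  nodes <- sort(net$nodes)
  e <- net$edges
  out <- list()
  for (k in seq_len(min(max_len, length(nodes)))) {
    for (subset in utils::combn(nodes, k, simplify = FALSE)) {
      first <- sort(subset)[1]
      rest <- setdiff(subset, first)
      seqs <- if (k == 1) list(first) else lapply(.perms(rest), function(p) c(first, p))
      for (s in seqs) {
        nxt <- c(s[-1], s[1])
        sign_opts <- lapply(seq_len(k), function(i) {
          e$sign[e$source == s[i] & e$target == nxt[i]]
        })
        if (any(lengths(sign_opts) == 0)) next
        combos <- expand.grid(sign_opts, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(combos))) {
          signs <- unlist(combos[r, ], use.names = FALSE)
          out[[length(out) + 1L]] <- list(
            nodes = s, signs = signs,
            parity = if (sum(signs == "inhibition") %% 2 == 0) "positive" else "negative"
          )
        }
      }
    }
  }
  out
}

circuit_keys <- function(circuits) {
  sort(vapply(circuits, function(cc) {
    paste(paste(cc$nodes, collapse = ">"), paste(cc$signs, collapse = ","),
          cc$parity, sep = "|")
  }, character(1)))
}

random_signed_digraph <- function(n_nodes, edge_prob = 0.25) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
  if (nrow(pairs) == 0) return(signed_digraph(
    data.frame(source = character(0), target = character(0), sign = character(0)),
    nodes = nodes))
  pairs$sign <- sample(c("activation", "inhibition"), nrow(pairs), replace = TRUE)
  signed_digraph(pairs, nodes = nodes)
}

# pair-counting AUC (ties count one half)
auc_pair_oracle <- function(scores, labels) {
  case <- scores[labels == 1]; ctrl <- scores[labels == 0]
  tot <- 0
  for (a in case) for (b in ctrl) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(case) * length(ctrl))
}

# Stouffer oracle: invert the two-sided p numerically (no qnorm on the tested
# path's transform), combine, return the two-sided tail
stouffer_oracle <- function(p, signs) {
  z <- vapply(p, function(pi) {
    stats::uniroot(function(z) 2 * stats::pnorm(z, lower.tail = FALSE) - pi,
                   c(0, 50), tol = 1e-14)$root
  }, numeric(1)) * signs
  zc <- sum(z) / sqrt(length(z))
  list(z_combined = zc, p_combined = 2 * stats::pnorm(abs(zc), lower.tail = FALSE))
}

# exact hypergeometric upper tail by direct summation of the pmf
hyper_tail_oracle <- function(k, N, K, n) {
  js <- max(k, max(0, n + K - N)):min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# product-limit estimate by hand at each distinct event time
km_oracle <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (t in tt) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  data.frame(time = tt, surv = out)
}

# small default world used by several tests
small_config <- function(...) {
  simulation_config(n_samples_per_cohort = c(one = 150L, two = 120L),
                    n_aptamers = 120L, seed = 5L, ...)
}

# shortcut: take ground-truth AT labels as at_status (isolates downstream
# modules from mixture-classification noise)
records_with_true_at <- function(sim, cohort) {
  rec <- sim$records[[cohort]]
  tr <- sim$truth$samples
  rec$at_status <- tr$at_true[match(rec$sample_id, tr$sample_id)]
  rec
}
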