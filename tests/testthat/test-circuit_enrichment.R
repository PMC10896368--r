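toy_net <- function(...) {
  e <- do.call(rbind, lapply(list(...), function(x) {
    data.frame(source = x[1], target = x[2], sign = x[3], stringsAsFactors = FALSE)
  }))
  signed_digraph(e)
}

test_that("Boolean-state pruning keeps only compatible edges", {
  net <- toy_net(c("A", "B", "activation"), c("B", "C", "activation"),
                 c("C", "A", "inhibition"), c("A", "C", "inhibition"))
  state <- c(A = 1, B = 1, C = 0)
  pruned <- prune_by_boolean_state(net, state)
  # A->B act (1,1) kept; B->C act (1,0) dropped; C->A inh (0,1) kept;
  # A-|C inh (1,0) kept
  keys <- with(pruned$edges, paste(source, target, sign))
  expect_setequal(keys, c("A B activation", "C A inhibition", "A C inhibition"))

  # endpoint without a state drops the edge
  state2 <- c(A = 1, B = 1)
  pruned2 <- prune_by_boolean_state(net, state2)
  expect_equal(nrow(pruned2$edges), 1)
  expect_setequal(pruned2$nodes, c("A", "B"))
})

test_that("condition networks complement each other's states", {
  net <- toy_net(c("A", "B", "activation"), c("B", "C", "inhibition"),
                 c("C", "A", "activation"), c("B", "A", "activation"))
  daa <- data.frame(aptamer_id = c("A", "B", "C"),
                    estimate = c(0.4, -0.2, 0.3), stringsAsFactors = FALSE)
  got <- condition_networks(net, daa)
  expect_identical(got$case_state, c(A = 1L, B = 0L, C = 1L))
  # case: A->B act (1,0) out; B->C inh (0,1) kept; C->A act (1,1) kept; B->A act (0,1) out
  expect_setequal(with(got$case$edges, paste(source, target)), c("B C", "C A"))
  # control is the pruning under complemented states
  manual <- prune_by_boolean_state(net, 1L - got$case_state)
  expect_identical(got$control$edges, manual$edges)
  # zero estimate drops the node with a warning
  daa0 <- daa; daa0$estimate[1] <- 0
  expect_warning(got0 <- condition_networks(net, daa0), "A")
  expect_false("A" %in% names(got0$case_state))
})

test_that("elementary circuits: hand-checkable cases", {
  dag <- toy_net(c("A", "B", "activation"), c("B", "C", "activation"),
                 c("A", "C", "inhibition"))
  expect_length(enumerate_circuits(dag), 0)

  tri <- toy_net(c("A", "B", "activation"), c("B", "C", "activation"),
                 c("C", "A", "activation"))
  cs <- enumerate_circuits(tri)
  expect_length(cs, 1)
  expect_identical(cs[[1]]$nodes, c("A", "B", "C"))
  expect_identical(cs[[1]]$parity, "positive")

  # complete digraph on 3 nodes: three 2-cycles and two 3-cycles
  cmp <- toy_net(c("A", "B", "activation"), c("B", "A", "inhibition"),
                 c("A", "C", "activation"), c("C", "A", "activation"),
                 c("B", "C", "inhibition"), c("C", "B", "inhibition"))
  cs2 <- enumerate_circuits(cmp)
  expect_length(cs2, 5)
  lens <- vapply(cs2, function(x) length(x$nodes), integer(1))
  expect_equal(sort(lens), c(2, 2, 2, 3, 3))
  # parity equals inhibition-count parity along each cycle
  for (cc in cs2) {
    expect_identical(cc$parity,
                     if (sum(cc$signs == "inhibition") %% 2 == 0) "positive" else "negative")
  }

  # self-loop is a length-1 circuit; max_len = 1 keeps only self-loops
  loop <- toy_net(c("A", "A", "inhibition"), c("A", "B", "activation"),
                  c("B", "A", "activation"))
  expect_length(enumerate_circuits(loop), 2)
  cs1 <- enumerate_circuits(loop, max_len = 1)
  expect_length(cs1, 1)
  expect_identical(cs1[[1]]$parity, "negative")

  # parallel edges of opposite sign yield distinct circuits
  par <- toy_net(c("A", "B", "activation"), c("A", "B", "inhibition"),
                 c("B", "A", "activation"))
  csp <- enumerate_circuits(par)
  expect_length(csp, 2)
  expect_setequal(vapply(csp, `[[`, character(1), "parity"),
                  c("positive", "negative"))
})

test_that("circuit enumeration matches brute force on random signed digraphs", {
  set.seed(60)
  for (i in 1:40) {
    net <- random_signed_digraph(sample(2:7, 1), edge_prob = 0.3)
    got <- enumerate_circuits(net, max_len = 8)
    want <- brute_force_circuits(net, max_len = 8)
    expect_identical(circuit_keys(got), circuit_keys(want))
  }
})

test_that("circuit_proteins unions nodes and warns when empty", {
  tri <- toy_net(c("A", "B", "activation"), c("B", "C", "activation"),
                 c("C", "A", "activation"))
  expect_setequal(circuit_proteins(enumerate_circuits(tri)), c("A", "B", "C"))
  expect_warning(empty <- circuit_proteins(structure(list(), class = "circuit_set")),
                 "empty")
  expect_length(empty, 0)
})

test_that("hypergeometric enrichment matches exact combinatorics and Fisher", {
  bg <- sprintf("g%02d", 1:10)
  sets <- list(T1 = bg[1:4])
  res <- hypergeom_enrich(bg[1:5], sets, bg)  # k=4 of K=4 within n=5
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$k, 4)

  # query = background: every term fully covered, p = 1
  res_all <- hypergeom_enrich(bg, list(T1 = bg[1:4], T2 = bg[5:7]), bg)
  expect_true(all(res_all$p == 1))
  expect_true(all(res_all$k == res_all$K))
  # zero overlap -> p = 1
  expect_equal(hypergeom_enrich(bg[5:6], list(T1 = bg[1:4]), bg)$p, 1)
  expect_error(hypergeom_enrich(c("zz"), sets, bg), "subset")

  # agreement with one-sided Fisher on random 2x2 tables
  set.seed(61)
  for (i in 1:40) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    bgN <- sprintf("x%03d", 1:N)
    term <- list(TT = bgN[1:K])
    q <- sample(bgN, n)
    p_got <- hypergeom_enrich(q, term, bgN)$p
    k <- sum(q %in% term$TT)
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    expect_equal(p_got, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(p_got, hyper_tail_oracle(k, N, K, n), tolerance = 1e-12)
  }

  # p is monotone decreasing in the overlap k for fixed margins
  ps <- vapply(0:4, function(k) {
    q <- c(bg[seq_len(k)], bg[5:(9 - k)])  # size-5 queries with overlap k
    hypergeom_enrich(q, sets, bg)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("cell-type enrichment needs exclusive markers", {
  bg <- sprintf("m%03d", 1:100)
  markers <- list(neuron = bg[1:5], astro = bg[6:10])
  res <- celltype_enrich(bg[1:5], markers, bg)
  # query exactly one full marker set of 5 in background 100: p = 1/C(100,5)
  expect_equal(res$p[res$term_id == "neuron"], 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p[res$term_id == "astro"], 1)
  expect_error(celltype_enrich(bg[1:5], list(a = bg[1:3], b = bg[3:5]), bg), "m003")
  # disjoint query -> all p = 1
  expect_true(all(celltype_enrich(bg[20:30], markers, bg)$p == 1))
})
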