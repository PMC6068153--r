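# Edge lists, the consensus rule, neighborhoods and key-driver analysis.

edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge lists are read per study, dropping self-loops", {
  p <- edge_file(c("source\ttarget\tstudy", "A\tB\ts1", "B\tC\ts1", "A\tB\ts2"))
  nets <- read_edge_lists(p)
  expect_named(nets, c("s1", "s2"))
  expect_equal(nrow(nets$s1$edges), 2)
  expect_true(all(nets$s1$edges$support == 1))
  p2 <- edge_file(c("A\tA\tstudy1", "A\tB\tstudy1"))
  expect_warning(nets2 <- read_edge_lists(p2), "self-loop")
  expect_equal(nrow(nets2$study1$edges), 1)
  p3 <- edge_file(c("A\tB"))
  expect_error(read_edge_lists(p3), "line 1.*got 2")
})

test_that("consensus keeps exactly the edges and nodes with sufficient support", {
  nets <- list(
    gene_network(data.frame(source = c("A", "B"), target = c("B", "C"))),
    gene_network(data.frame(source = c("A", "D"), target = c("B", "E"))),
    gene_network(data.frame(source = "C", target = "B")))
  cons <- consensus_network(nets, min_support = 2)
  # A-B in studies 1+2 kept; B-C in studies 1+3 kept; D-E only once dropped
  key <- paste(cons$edges$source, cons$edges$target)
  expect_setequal(key, c("A B", "B C"))
  expect_setequal(cons$nodes, c("A", "B", "C"))
  # min_support = 1 is the union (B-C and C-B coincide undirected)
  uni <- consensus_network(nets, min_support = 1)
  expect_equal(nrow(uni$edges), 3)
  expect_error(consensus_network(nets[1]), ">= 2")
  # undirected matching: A->B and B->A are the same edge
  nets2 <- list(gene_network(data.frame(source = "A", target = "B")),
                gene_network(data.frame(source = "B", target = "A")))
  expect_equal(consensus_network(nets2, 2)$edges$support, 2L)
})

test_that("random multi-study consensus equals brute-force support counting", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:12)
  for (rep in 1:10) {
    studies <- lapply(1:3, function(s) {
      n <- sample(5:20, 1)
      data.frame(source = sample(genes, n, TRUE), target = sample(genes, n, TRUE),
                 stringsAsFactors = FALSE)
    })
    nets <- lapply(studies, function(df) gene_network(df[df$source != df$target, ]))
    cons <- consensus_network(nets, min_support = 2)
    # oracle: canonicalized edge keys counted across studies
    keys <- lapply(nets, function(nw) unique(paste(nw$edges$source, nw$edges$target)))
    support <- table(unlist(keys))
    node_support <- table(unlist(lapply(nets, `[[`, "nodes")))
    ok_nodes <- names(node_support)[node_support >= 2]
    expected <- names(support)[support >= 2]
    if (length(expected) > 0) {
      keep <- vapply(strsplit(expected, " "),
                     function(e) all(e %in% ok_nodes), logical(1))
      expected <- expected[keep]
    }
    expect_setequal(paste(cons$edges$source, cons$edges$target), expected)
  }
})

test_that("neighborhoods respect hop depth and exclude the seed gene", {
  net <- gene_network(data.frame(source = c("a", "b"), target = c("b", "c")))
  expect_equal(neighborhood(net, "b", 1), c("a", "c"))
  expect_equal(neighborhood(net, "a", 1), "b")
  expect_equal(neighborhood(net, "a", 2), c("b", "c"))
  iso <- gene_network(data.frame(source = "a", target = "b"), nodes = c("a", "b", "z"))
  expect_length(neighborhood(iso, "z"), 0)
  expect_error(neighborhood(net, "nope"), "not in the network")
})

test_that("enrichment test equals the hypergeometric tail", {
  # worked case: background 100, signature 10, neighborhood 8, overlap 5
  bg <- sprintf("g%03d", 1:100)
  sig <- bg[1:10]
  neigh <- c(bg[1:5], bg[11:13])
  res <- enrichment_test(neigh, sig, bg)
  expect_equal(res$overlap, 5)
  expect_equal(res$expected, 0.8)
  expect_equal(res$fold, 6.25)
  expect_equal(res$p_value, hyper_tail_oracle(5, 10, 100, 8), tolerance = 1e-12)
  expect_equal(res$p_value, 1.64e-4, tolerance = 0.005)
  # overlap 0 -> p = 1
  expect_equal(enrichment_test(bg[50:52], sig, bg)$p_value, 1)
  expect_error(enrichment_test(neigh, sig, character()), "empty")
  expect_error(enrichment_test(c("zzz"), sig, bg), "subset")
})

test_that("enrichment p matches enumeration and is monotone in overlap (small backgrounds)", {
  for (N in c(10, 20, 30)) {
    bg <- sprintf("b%02d", 1:N)
    for (K in c(2, floor(N / 3))) {
      for (n in c(2, floor(N / 2))) {
        sig <- bg[1:K]
        prev <- Inf
        for (ov in 0:min(K, n)) {
          neigh <- c(bg[seq_len(ov)], bg[K + seq_len(n - ov)])
          p <- enrichment_test(neigh, sig, bg)$p_value
          expect_equal(p, hyper_tail_oracle(ov, K, N, n), tolerance = 1e-12)
          expect_lte(p, prev + 1e-15)
          prev <- p
        }
      }
    }
  }
})

test_that("KDA returns sorted, thresholded, truncated results with an audit table", {
  sim <- simulate_network(300, n_planted_drivers = 4, enrichment = 5,
                          signature_fraction = 0.1, seed = 42)
  cons <- consensus_network(sim$networks)
  res <- key_driver_analysis(cons, sim$truth$signature_genes, q_cut = 0.01, top_k = 15)
  expect_s3_class(res, "kda_result")
  expect_lte(nrow(res), 15)
  expect_true(all(res$q_value < 0.01))
  expect_true(!is.unsorted(res$q_value))
  audit <- attr(res, "audit")
  expect_equal(nrow(audit), length(cons$nodes))
  expect_true(all(res$signature_overlap <=
                    pmin(res$neighborhood_size, length(sim$truth$signature_genes))))
  # planted drivers dominate the calls
  expect_gte(length(intersect(res$gene, sim$truth$planted_drivers)), 3)
  # empty mapped signature -> warning + empty result
  expect_warning(empty <- key_driver_analysis(cons, c("not_a_gene")), "no genes")
  expect_equal(nrow(empty), 0)
})

test_that("KDA is invariant under node relabeling", {
  sim <- simulate_network(120, n_planted_drivers = 3, enrichment = 4,
                          signature_fraction = 0.1, seed = 43)
  cons <- consensus_network(sim$networks)
  relabel <- setNames(sprintf("x%03d", seq_along(cons$nodes)), cons$nodes)
  edges2 <- data.frame(source = unname(relabel[cons$edges$source]),
                       target = unname(relabel[cons$edges$target]),
                       stringsAsFactors = FALSE)
  cons2 <- gene_network(edges2, nodes = unname(relabel))
  sig2 <- unname(relabel[intersect(sim$truth$signature_genes, cons$nodes)])
  r1 <- key_driver_analysis(cons, sim$truth$signature_genes)
  r2 <- key_driver_analysis(cons2, sig2)
  expect_equal(unname(relabel[r1$gene]), r2$gene)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})
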