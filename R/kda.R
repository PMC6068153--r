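# Key-driver analysis: scan every network gene and test whether its graph
# neighborhood is enriched for signature genes, relative to a random draw
# from the background, using the one-sided hypergeometric (Fisher) tail.

#' Neighborhood enrichment test (one-sided hypergeometric)
#'
#' With population `background`, `|signature|` successes and a neighborhood
#' of size `|neigh|` drawn from it, computes the upper-tail probability of
#' seeing at least the observed overlap, plus the expected overlap and the
#' fold enrichment.
#'
#' @param neigh Character vector: the candidate gene's neighbors.
#' @param signature Character vector of signature genes.
#' @param background Character vector: all genes the neighborhood could
#'   have drawn from (both `neigh` and `signature` must be subsets).
#' @return List with `overlap`, `expected`, `fold` and `p_value`.
#' @export
enrichment_test <- function(neigh, signature, background) {
  if (length(background) == 0) stopf("background gene set is empty")
  if (!all(neigh %in% background)) stopf("neighborhood must be a subset of the background")
  if (!all(signature %in% background)) stopf("signature must be a subset of the background")
  N <- length(unique(background))
  K <- length(unique(signature))
  n <- length(unique(neigh))
  overlap <- length(intersect(neigh, signature))
  expected <- n * K / N
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (expected > 0) overlap / expected else NA_real_
  list(overlap = overlap, expected = expected, fold = fold, p_value = p)
}

#' Key driver analysis over a gene network
#'
#' Every background gene is scored by the enrichment of its `hops`-step
#' neighborhood for signature genes (one-sided hypergeometric test), with
#' BH adjustment across all testable genes. Genes whose neighborhoods are
#' smaller than `min_neighborhood` are reported in the audit table but
#' flagged untestable and excluded from the FDR adjustment.
#'
#' @param network A `gene_network` (typically a consensus network).
#' @param signature A `tmt_signature` or character vector of gene ids;
#'   silently restricted to network background genes.
#' @param hops Neighborhood depth (default 1).
#' @param q_cut FDR threshold for calling key drivers (default 0.01).
#' @param top_k Maximum number of key drivers returned (default 15).
#' @param background Optional character vector (e.g. the measured
#'   proteome) intersected with the network nodes to define the
#'   enrichment universe; defaults to all network nodes.
#' @param min_neighborhood Smallest testable neighborhood (default 3).
#' @param mode Neighborhood direction, "all" or "out".
#' @return Data frame of class `kda_result` (gene, neighborhood_size,
#'   signature_overlap, expected_overlap, fold_enrichment, p_value,
#'   q_value), sorted by q then fold, truncated to `top_k`. The full audit
#'   table over all scanned genes is attached as attribute `"audit"`.
#' @export
key_driver_analysis <- function(network, signature, hops = 1L, q_cut = 0.01,
                                top_k = 15L, background = NULL,
                                min_neighborhood = 3L, mode = c("all", "out")) {
  stopifnot(inherits(network, "gene_network"))
  mode <- match.arg(mode)
  assert_scalar_number(q_cut, "q_cut", lower = .Machine$double.eps, upper = 1)
  sig <- .sig_members(signature)
  bg <- if (is.null(background)) network$nodes else intersect(network$nodes, background)
  sig <- intersect(sig, bg)
  empty <- data.frame(gene = character(), neighborhood_size = integer(),
                      signature_overlap = integer(), expected_overlap = numeric(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("kda_result", "data.frame")
  if (length(sig) == 0) {
    warnf("signature has no genes in the network background; returning empty result")
    attr(empty, "audit") <- empty
    return(empty)
  }
  g <- .as_igraph(network)
  nbs <- igraph::ego(g, order = hops, nodes = bg, mode = mode, mindist = 1)
  K <- length(sig)
  N <- length(bg)
  in_bg <- stats::setNames(rep(TRUE, N), bg)
  in_sig <- stats::setNames(rep(FALSE, N), bg)
  in_sig[sig] <- TRUE
  n_size <- integer(N); n_over <- integer(N)
  for (i in seq_len(N)) {
    nb <- names(nbs[[i]])
    nb <- nb[!is.na(in_bg[nb])]
    n_size[i] <- length(nb)
    n_over[i] <- sum(in_sig[nb])
  }
  expected <- n_size * K / N
  p <- stats::phyper(n_over - 1, K, N - K, n_size, lower.tail = FALSE)
  testable <- n_size >= min_neighborhood
  q <- rep(NA_real_, N)
  q[testable] <- bh_adjust(p[testable])
  audit <- data.frame(gene = bg, neighborhood_size = n_size,
                      signature_overlap = n_over, expected_overlap = expected,
                      fold_enrichment = ifelse(expected > 0, n_over / expected, NA_real_),
                      p_value = p, q_value = q, testable = testable,
                      stringsAsFactors = FALSE)
  res <- audit[testable & !is.na(q) & q < q_cut, , drop = FALSE]
  res <- res[order(res$q_value, -res$fold_enrichment, res$gene), , drop = FALSE]
  res <- utils::head(res, top_k)
  res$testable <- NULL
  rownames(res) <- NULL
  class(res) <- c("kda_result", "data.frame")
  attr(res, "audit") <- audit
  attr(res, "parameters") <- list(hops = hops, q_cut = q_cut, top_k = top_k,
                                  min_neighborhood = min_neighborhood,
                                  n_background = N, n_signature = K)
  res
}

#' @export
print.kda_result <- function(x, ...) {
  pars <- attr(x, "parameters")
  if (!is.null(pars)) {
    cat(sprintf("kda_result: %d key drivers (q < %g) from %d background genes, signature size %d\n",
                nrow(x), pars$q_cut, pars$n_background, pars$n_signature))
  }
  NextMethod()
}
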