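#' Simulate multi-study gene networks with planted key drivers
#'
#' Builds a set of per-"study" edge lists over a common node universe.
#' A background Erdos-Renyi-style graph connects non-driver nodes, whose
#' neighborhoods therefore contain signature genes at the background rate
#' `signature_fraction`. Each planted driver instead receives
#' `driver_degree` dedicated neighbors of which a fraction
#' `enrichment * signature_fraction` (in expectation) are signature genes.
#' Driver edges appear in every study; each background edge is shared by
#' all studies with probability `overlap`, otherwise it is private to one
#' random study — so a support >= 2 consensus retains all planted
#' structure and the shared part of the background.
#'
#' @param n_nodes Number of genes.
#' @param n_studies Number of study networks (default 3).
#' @param overlap Probability a background edge is shared by all studies.
#' @param n_planted_drivers Number of planted key drivers.
#' @param enrichment Signature-density multiplier in driver neighborhoods
#'   (requires `enrichment * signature_fraction <= 1`).
#' @param seed Integer seed.
#' @param signature_fraction Fraction of nodes in the planted signature.
#' @param driver_degree Neighbors attached to each planted driver.
#' @param avg_degree Expected background degree.
#' @param nodes Optional character vector of node ids (e.g. measured
#'   protein identifiers); length must be `n_nodes`.
#' @param signature_genes Optional preset signature gene ids (subset of
#'   `nodes`); overrides `signature_fraction` sampling.
#' @return List with `networks` (named list of `gene_network`s, one per
#'   study) and `truth` (list: `planted_drivers`, `signature_genes`).
#' @export
simulate_network <- function(n_nodes, n_studies = 3L, overlap = 0.5,
                             n_planted_drivers = 0L, enrichment = 5,
                             seed = 1L, signature_fraction = 0.1,
                             driver_degree = 20L, avg_degree = 6,
                             nodes = NULL, signature_genes = NULL) {
  assert_scalar_number(n_nodes, "n_nodes", lower = 1)
  assert_scalar_number(n_studies, "n_studies", lower = 1)
  assert_scalar_number(overlap, "overlap", lower = 0, upper = 1)
  assert_scalar_number(n_planted_drivers, "n_planted_drivers", lower = 0,
                       upper = n_nodes)
  assert_scalar_number(enrichment, "enrichment", lower = 0)
  if (is.null(nodes)) {
    nodes <- sprintf("g%05d", seq_len(n_nodes))
  } else {
    nodes <- as.character(nodes)
    if (length(nodes) != n_nodes) stopf("`nodes` must have length n_nodes")
    if (anyDuplicated(nodes)) stopf("`nodes` must be unique")
  }
  with_seed(seed, {
    drivers <- if (n_planted_drivers > 0) sample(nodes, n_planted_drivers) else character()
    non_driver <- setdiff(nodes, drivers)
    if (is.null(signature_genes)) {
      n_sig <- round(signature_fraction * n_nodes)
      if (n_sig > length(non_driver)) stopf("signature larger than available non-driver nodes")
      signature_genes <- if (n_sig > 0) sample(non_driver, n_sig) else character()
    } else {
      signature_genes <- intersect(as.character(signature_genes), non_driver)
    }
    sig_frac <- length(signature_genes) / max(1, n_nodes)
    p_sig_nbr <- enrichment * sig_frac
    if (n_planted_drivers > 0 && p_sig_nbr > 1) {
      stopf("enrichment %g incompatible with signature fraction %.3g (product > 1)",
            enrichment, sig_frac)
    }

    # background among non-driver nodes, expected degree avg_degree
    m <- round(avg_degree * length(non_driver) / 2)
    bg_edges <- NULL
    if (m > 0 && length(non_driver) >= 2) {
      src <- sample(non_driver, m, replace = TRUE)
      tgt <- sample(non_driver, m, replace = TRUE)
      ok <- src != tgt
      a <- pmin(src[ok], tgt[ok]); b <- pmax(src[ok], tgt[ok])
      key <- !duplicated(paste(a, b, sep = "\r"))
      bg_edges <- data.frame(source = a[key], target = b[key],
                             stringsAsFactors = FALSE)
    } else {
      bg_edges <- data.frame(source = character(), target = character(),
                             stringsAsFactors = FALSE)
    }

    # dedicated driver neighborhoods with elevated signature density
    drv_edges <- NULL
    if (length(drivers) > 0) {
      pieces <- lapply(drivers, function(dv) {
        k <- min(driver_degree, length(non_driver))
        n_s <- stats::rbinom(1, k, p_sig_nbr)
        n_s <- min(n_s, length(signature_genes))
        nbr_sig <- if (n_s > 0) sample(signature_genes, n_s) else character()
        pool <- setdiff(non_driver, signature_genes)
        n_o <- min(k - n_s, length(pool))
        nbr_other <- if (n_o > 0) sample(pool, n_o) else character()
        nbr <- c(nbr_sig, nbr_other)
        data.frame(source = rep(dv, length(nbr)), target = nbr,
                   stringsAsFactors = FALSE)
      })
      drv_edges <- do.call(rbind, pieces)
    } else {
      drv_edges <- data.frame(source = character(), target = character(),
                              stringsAsFactors = FALSE)
    }

    shared <- stats::runif(nrow(bg_edges)) < overlap
    private_study <- sample.int(n_studies, nrow(bg_edges), replace = TRUE)
    study_ids <- sprintf("study%d", seq_len(n_studies))
    networks <- lapply(seq_len(n_studies), function(s) {
      keep <- shared | private_study == s
      e <- rbind(drv_edges, bg_edges[keep, , drop = FALSE])
      gene_network(e, nodes = nodes, directed = FALSE)
    })
    names(networks) <- study_ids
    list(networks = networks,
         truth = list(planted_drivers = sort(drivers),
                      signature_genes = sort(signature_genes)))
  })
}
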