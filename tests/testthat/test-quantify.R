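# Reading, complete-case filtering, sample-loading normalization and IRS.

mk <- function(vals, nr, plex = "p1", ref = character()) {
  m <- matrix(vals, nrow = nr)
  rownames(m) <- sprintf("P%d", seq_len(nr))
  colnames(m) <- sprintf("C%d", seq_len(ncol(m)))
  make_plex(plex, m, ref = ref)
}

test_that("plex table reading validates shape, duplicates and negatives", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(protein = c("P1", "P2", "P3"),
                   matrix(1:30, nrow = 3, dimnames = list(NULL, sprintf("C%d", 1:10))),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- read_plex_table(path, reference_channels = c("C1", "C2"))
  expect_s3_class(tb, "plex_table")
  expect_equal(dim(tb$intensities), c(3, 10))
  expect_equal(tb$reference_channels, c("C1", "C2"))

  df2 <- df; df2$protein[2] <- "P1"
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plex_table(path), "duplicate protein id.*P1")

  df3 <- df; df3$C3[2] <- -5
  write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plex_table(path), "negative intensity.*P2.*C3")

  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plex_table(path, reference_channels = "C99"),
               "reference channel")
})

test_that("complete-case filter keeps proteins positive everywhere, in shared order", {
  t1 <- mk(c(1, 2, 3, 4, 5, 6), 3, "p1")
  m2 <- matrix(c(1, 0, 3, 4, 5, 6), nrow = 3,
               dimnames = list(c("P1", "P2", "P3"), c("C1", "C2")))
  t2 <- make_plex("p2", m2)
  out <- filter_complete_cases(list(t1, t2))
  expect_equal(rownames(out[[1]]$intensities), c("P1", "P3"))
  expect_equal(rownames(out[[2]]$intensities), c("P1", "P3"))
  # identity when everything is observed
  out2 <- filter_complete_cases(list(t1))
  expect_equal(out2[[1]]$intensities, t1$intensities)
  # a zero in a reference channel also removes the protein
  m3 <- matrix(c(1, 2, 0, 4, 5, 6), nrow = 3,
               dimnames = list(c("P1", "P2", "P3"), c("C1", "C2")))
  t3 <- make_plex("p3", m3, ref = "C1")
  out3 <- filter_complete_cases(list(t3))
  expect_equal(rownames(out3[[1]]$intensities), c("P1", "P2"))
  # empty intersection is a warning, not an error
  t4 <- mk(c(0, 0), 2, "p4")
  expect_warning(res <- filter_complete_cases(list(t4)), "no protein")
  expect_equal(nrow(res[[1]]$intensities), 0)
})

test_that("sample-loading normalization equalizes channel totals", {
  m <- matrix(c(40, 60, 80, 120), nrow = 2,
              dimnames = list(c("P1", "P2"), c("C1", "C2")))
  tb <- filter_complete_cases(list(make_plex("p1", m)))[[1]]
  res <- sample_loading_normalize(tb)
  expect_equal(unname(res$factors), c(1.5, 0.75))
  totals <- colSums(res$table$intensities)
  expect_equal(unname(totals), c(150, 150), tolerance = 1e-9)
  # identity when totals already equal
  m2 <- matrix(c(50, 50, 60, 40), nrow = 2,
               dimnames = list(c("P1", "P2"), c("C1", "C2")))
  tb2 <- filter_complete_cases(list(make_plex("p2", m2)))[[1]]
  expect_equal(unname(sample_loading_normalize(tb2)$factors), c(1, 1))
  # degenerate channel -> error (bypasses the complete-case guard)
  tb3 <- tb2; tb3$intensities[, 1] <- 0
  expect_error(sample_loading_normalize(tb3), "degenerate channel")
  # provenance ordering is enforced
  expect_error(sample_loading_normalize(make_plex("p4", m)), "contract")
})

test_that("IRS equalizes reference means across plexes and matches the brute-force factors", {
  set.seed(71)
  P <- 50
  ids <- sprintf("P%03d", 1:P)
  tabs <- lapply(1:3, function(p) {
    m <- matrix(rlnorm(P * 6, meanlog = 8, sdlog = 1) * exp(rnorm(1, 0, 0.5)),
                nrow = P, dimnames = list(ids, sprintf("C%d", 1:6)))
    make_plex(sprintf("p%d", p), m, ref = c("C1", "C2"))
  })
  meta <- auto_metadata(tabs)
  filtered <- filter_complete_cases(tabs)
  sl <- lapply(filtered, sample_loading_normalize)
  sl_tabs <- lapply(sl, `[[`, "table")
  norm <- irs_normalize(sl_tabs, meta)

  # brute-force recomputation of the two-line IRS formula
  ref <- sapply(sl_tabs, function(tb) rowMeans(tb$intensities[, c("C1", "C2")]))
  target <- apply(ref, 1, function(r) prod(r)^(1 / length(r)))
  expect_equal(unname(norm$irs_factors), unname(target / ref), tolerance = 1e-12)

  # post-IRS reference means agree across plexes to 1e-9 relative
  post_ref <- sapply(seq_along(sl_tabs), function(k) {
    rowMeans(sl_tabs[[k]]$intensities[, c("C1", "C2")]) * norm$irs_factors[, k]
  })
  rel_spread <- apply(post_ref, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(max(rel_spread), 1e-9)
})

test_that("IRS is a per-(protein, plex) scalar, idempotent, and identity for one plex", {
  set.seed(72)
  P <- 20
  ids <- sprintf("P%02d", 1:P)
  tabs <- lapply(1:2, function(p) {
    m <- matrix(rlnorm(P * 5, 8, 1), nrow = P,
                dimnames = list(ids, sprintf("C%d", 1:5)))
    make_plex(sprintf("p%d", p), m, ref = "C1")
  })
  meta <- auto_metadata(tabs)
  norm <- quantify_plexes(tabs, meta)
  # within-plex between-sample ratios unchanged by IRS
  raw <- filter_complete_cases(tabs)
  sl <- lapply(raw, function(tb) sample_loading_normalize(tb)$table)
  s_in_p1 <- meta$sample_id[meta$plex == "p1"]
  ch_in_p1 <- meta$channel[meta$plex == "p1"]
  expect_equal(norm$values[, s_in_p1[1]] / norm$values[, s_in_p1[2]],
               sl[[1]]$intensities[, ch_in_p1[1]] / sl[[1]]$intensities[, ch_in_p1[2]],
               tolerance = 1e-12)
  # a second IRS pass is the identity
  tabs2 <- lapply(seq_along(sl), function(k) {
    tb <- sl[[k]]
    tb$intensities <- tb$intensities * norm$irs_factors[, k]
    tb
  })
  norm2 <- irs_normalize(tabs2, meta)
  expect_equal(unname(norm2$irs_factors),
               matrix(1, nrow = P, ncol = 2), tolerance = 1e-12)
  # single plex: all factors 1
  one <- quantify_plexes(tabs[1], meta[meta$plex == "p1", ])
  expect_equal(unname(one$irs_factors), matrix(1, nrow = P, ncol = 1),
               tolerance = 1e-12)
  # two plexes with ref levels 100 and 400: target 200, factors 2 and 0.5
  ma <- matrix(100, 1, 3, dimnames = list("P1", c("C1", "C2", "C3")))
  mb <- matrix(400, 1, 3, dimnames = list("P1", c("C1", "C2", "C3")))
  two <- lapply(list(make_plex("pa", ma, "C1"), make_plex("pb", mb, "C1")),
                function(tb) sample_loading_normalize(filter_complete_cases(list(tb))[[1]])$table)
  meta2 <- auto_metadata(two)
  norm3 <- irs_normalize(two, meta2)
  expect_equal(unname(norm3$irs_factors[1, ]), c(2, 0.5))
  # IRS before sample loading violates the provenance contract
  expect_error(irs_normalize(filter_complete_cases(tabs), meta), "contract")
})

test_that("mock-reference mode uses the sample-channel mean when no reference exists", {
  P <- 10
  ids <- sprintf("P%02d", 1:P)
  set.seed(73)
  tabs <- lapply(1:2, function(p) {
    m <- matrix(rlnorm(P * 4, 8, 1), nrow = P,
                dimnames = list(ids, sprintf("C%d", 1:4)))
    make_plex(sprintf("p%d", p), m)   # no reference channels
  })
  meta <- auto_metadata(tabs)
  norm <- quantify_plexes(tabs, meta)
  sl <- lapply(filter_complete_cases(tabs), function(tb) sample_loading_normalize(tb)$table)
  ref <- sapply(sl, function(tb) rowMeans(tb$intensities))
  target <- exp(rowMeans(log(ref)))
  expect_equal(unname(norm$irs_factors), unname(target / ref), tolerance = 1e-12)
})

test_that("plex tables round-trip through TSV", {
  sim <- simulate_tmt_experiment(experiment_design(), sim_params(n_proteins = 30, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plex_table(sim$plexes[[1]], path)
  back <- read_plex_table(path, reference_channels = c("C1", "C2"), plex_id = "plex1")
  expect_equal(back$intensities, sim$plexes[[1]]$intensities)
})
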