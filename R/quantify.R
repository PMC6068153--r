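#' Construct a validated single-plex reporter-intensity table
#'
#' @param plex_id Label for the plex (batch).
#' @param intensities Numeric matrix, proteins x channels, with protein ids
#'   as rownames and channel labels as colnames. All values must be >= 0.
#' @param reference_channels Channel labels carrying the pooled internal
#'   reference (may be empty; see mock-reference mode in [irs_normalize()]).
#' @return An object of class `plex_table`.
#' @export
plex_table <- function(plex_id, intensities, reference_channels = character()) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stopf("intensities must be a numeric matrix")
  }
  pid <- rownames(intensities)
  cid <- colnames(intensities)
  if (nrow(intensities) > 0 && is.null(pid)) stopf("intensities must have protein rownames")
  if (is.null(cid)) stopf("intensities must have channel colnames")
  if (anyDuplicated(pid)) {
    stopf("duplicate protein id in plex '%s': %s", plex_id,
          pid[duplicated(pid)][1])
  }
  if (anyDuplicated(cid)) stopf("duplicate channel id in plex '%s'", plex_id)
  if (anyNA(intensities)) stopf("missing intensities in plex '%s'", plex_id)
  neg <- which(intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf("negative intensity in plex '%s' at protein '%s', channel '%s'",
          plex_id, pid[neg[1, 1]], cid[neg[1, 2]])
  }
  missing_ref <- setdiff(reference_channels, cid)
  if (length(missing_ref) > 0) {
    stopf("reference channel(s) not present in plex '%s': %s",
          plex_id, paste(missing_ref, collapse = ", "))
  }
  structure(list(plex_id = as.character(plex_id),
                 intensities = intensities,
                 reference_channels = as.character(reference_channels),
                 provenance = character()),
            class = "plex_table")
}

#' @export
print.plex_table <- function(x, ...) {
  cat(sprintf("plex_table '%s': %d proteins x %d channels (%d reference)\n",
              x$plex_id, nrow(x$intensities), ncol(x$intensities),
              length(x$reference_channels)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

sample_channels <- function(x) {
  setdiff(colnames(x$intensities), x$reference_channels)
}

#' Read a single-plex reporter-intensity TSV
#'
#' Expects a header row; the first column holds protein identifiers and the
#' remaining columns one reporter channel each.
#'
#' @param path Path to a tab-separated file.
#' @param reference_channels Channel labels to flag as internal reference.
#' @param plex_id Plex label; defaults to the file name without extension.
#' @return A [plex_table].
#' @export
read_plex_table <- function(path, reference_channels = character(),
                            plex_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stopf("plex table '%s' needs a protein column plus channels", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric intensity values in '%s'", path)
  rownames(m) <- ids
  plex_table(plex_id, m, reference_channels)
}

#' Write a plex_table to TSV (protein id first column, one column per channel)
#' @param x A [plex_table].
#' @param path Output path.
#' @export
write_plex_table <- function(x, path) {
  stopifnot(inherits(x, "plex_table"))
  df <- data.frame(protein = rownames(x$intensities), x$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Restrict plexes to proteins quantified in every channel of every plex
#'
#' Zero intensity is treated as "not observed"; a protein is kept only when
#' strictly positive in all channels (including reference channels) of all
#' plexes, mirroring the complete-case rule used before cross-plex
#' normalization. Returned tables share an identical protein order.
#'
#' @param tables List of [plex_table] objects.
#' @return List of filtered `plex_table`s (provenance records the step).
#' @export
filter_complete_cases <- function(tables) {
  if (length(tables) < 1) stopf("need at least one plex table")
  stopifnot(all(vapply(tables, inherits, logical(1), "plex_table")))
  keep <- rownames(tables[[1]]$intensities)
  for (tb in tables) {
    ok <- rownames(tb$intensities)[apply(tb$intensities > 0, 1, all)]
    keep <- intersect(keep, ok)
  }
  if (length(keep) == 0) {
    warnf("no protein is quantified across all plexes; returning empty tables")
  }
  lapply(tables, function(tb) {
    tb$intensities <- tb$intensities[keep, , drop = FALSE]
    tb$provenance <- c(tb$provenance, "complete_cases")
    tb
  })
}

#' Sample-loading normalization within one plex
#'
#' Scales every channel so that all channel totals equal the grand mean of
#' the channel totals, the in-silico equivalent of combining labeled
#' samples in 1:1:...:1 ratios by total reporter-ion intensity.
#'
#' @param table A complete-case [plex_table].
#' @return List with the scaled `table` and the named `factors` applied.
#' @export
sample_loading_normalize <- function(table) {
  stopifnot(inherits(table, "plex_table"))
  if (!"complete_cases" %in% table$provenance) {
    stopf("pipeline contract: filter_complete_cases must run before sample-loading normalization")
  }
  totals <- colSums(table$intensities)
  if (any(totals == 0)) {
    stopf("degenerate channel with zero total in plex '%s': %s",
          table$plex_id, names(totals)[totals == 0][1])
  }
  factors <- mean(totals) / totals
  table$intensities <- sweep(table$intensities, 2, factors, "*")
  table$provenance <- c(table$provenance, "sample_loading")
  list(table = table, factors = factors)
}

#' Internal reference scaling across plexes
#'
#' For each protein i and plex p the reference level ref(i,p) is the
#' arithmetic mean of the reference-channel intensities (or of all sample
#' channels in mock-reference mode, when a plex designates no reference
#' channels). The scaling target is the geometric mean of ref(i,.) across
#' plexes, and every intensity of protein i in plex p is multiplied by
#' target(i)/ref(i,p), after which reference levels agree across plexes.
#' Sample channels are then assembled into one proteins x samples matrix
#' using the metadata's (plex, channel) -> sample_id map.
#'
#' @param tables List of complete-case, sample-loading-normalized
#'   [plex_table]s sharing the same protein set and order.
#' @param metadata Data frame with columns sample_id, genotype, diet, plex,
#'   channel; every non-reference channel must map to exactly one sample.
#' @return An object of class `tmt_norm` with elements `values` (positive
#'   proteins x samples matrix), `metadata`, `sl_factors`, `irs_factors`
#'   (proteins x plexes) and `provenance`.
#' @export
irs_normalize <- function(tables, metadata) {
  if (length(tables) < 1) stopf("need at least one plex table")
  stopifnot(all(vapply(tables, inherits, logical(1), "plex_table")))
  for (tb in tables) {
    if (!"sample_loading" %in% tb$provenance) {
      stopf("pipeline contract: sample_loading_normalize must run before IRS (plex '%s')",
            tb$plex_id)
    }
  }
  prot <- rownames(tables[[1]]$intensities)
  for (tb in tables) {
    if (!identical(rownames(tb$intensities), prot)) {
      stopf("plex tables must share an identical protein set and order (run filter_complete_cases)")
    }
  }
  plex_ids <- vapply(tables, `[[`, character(1), "plex_id")
  if (anyDuplicated(plex_ids)) stopf("duplicate plex ids")
  .validate_metadata(metadata, tables)

  ref <- sapply(tables, function(tb) {
    cols <- if (length(tb$reference_channels) > 0) tb$reference_channels else sample_channels(tb)
    rowMeans(tb$intensities[, cols, drop = FALSE])
  })
  ref <- matrix(ref, nrow = length(prot), dimnames = list(prot, plex_ids))
  if (any(ref == 0)) {
    stopf("degenerate reference: zero reference mean for protein '%s'",
          prot[which(rowSums(ref == 0) > 0)[1]])
  }
  target <- exp(rowMeans(log(ref)))
  irs_factors <- target / ref   # proteins x plexes

  scaled <- lapply(seq_along(tables), function(k) {
    tb <- tables[[k]]
    tb$intensities <- tb$intensities * irs_factors[, k]
    tb
  })

  # assemble sample columns in metadata order
  values <- matrix(NA_real_, nrow = length(prot), ncol = nrow(metadata),
                   dimnames = list(prot, metadata$sample_id))
  for (k in seq_along(scaled)) {
    tb <- scaled[[k]]
    smeta <- metadata[metadata$plex == tb$plex_id, , drop = FALSE]
    values[, smeta$sample_id] <- tb$intensities[, smeta$channel, drop = FALSE]
  }
  structure(
    list(values = values,
         metadata = metadata,
         sl_factors = NULL,
         irs_factors = irs_factors,
         provenance = c(tables[[1]]$provenance, "irs")),
    class = "tmt_norm")
}

.validate_metadata <- function(metadata, tables) {
  need <- c("sample_id", "genotype", "diet", "plex", "channel")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stopf("duplicate sample_id in metadata")
  if (anyDuplicated(metadata[, c("plex", "channel")])) {
    stopf("duplicate (plex, channel) pair in metadata")
  }
  plex_ids <- vapply(tables, `[[`, character(1), "plex_id")
  for (tb in tables) {
    smeta <- metadata[metadata$plex == tb$plex_id, , drop = FALSE]
    sc <- sample_channels(tb)
    unmapped <- setdiff(sc, smeta$channel)
    if (length(unmapped) > 0) {
      stopf("plex '%s': sample channel(s) %s not mapped to any sample",
            tb$plex_id, paste(unmapped, collapse = ", "))
    }
    bad <- setdiff(smeta$channel, sc)
    if (length(bad) > 0) {
      stopf("plex '%s': metadata channel(s) %s are not sample channels",
            tb$plex_id, paste(bad, collapse = ", "))
    }
  }
  orphan <- setdiff(metadata$plex, plex_ids)
  if (length(orphan) > 0) stopf("metadata references unknown plex: %s", orphan[1])
  invisible(TRUE)
}

#' @export
print.tmt_norm <- function(x, ...) {
  cat(sprintf("tmt_norm: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Run the quantification pipeline: complete cases, sample loading, IRS
#'
#' Convenience wrapper enforcing the canonical order
#' `filter_complete_cases` -> `sample_loading_normalize` -> `irs_normalize`.
#'
#' @inheritParams irs_normalize
#' @return A `tmt_norm`, with the per-plex sample-loading factors attached
#'   as the `sl_factors` element.
#' @export
quantify_plexes <- function(tables, metadata) {
  filtered <- filter_complete_cases(tables)
  sl <- lapply(filtered, sample_loading_normalize)
  norm <- irs_normalize(lapply(sl, `[[`, "table"), metadata)
  norm$sl_factors <- lapply(sl, `[[`, "factors")
  names(norm$sl_factors) <- vapply(filtered, `[[`, character(1), "plex_id")
  norm
}

#' Write a normalized proteins-by-samples matrix to TSV
#' @param x A `tmt_norm`.
#' @param path Output path.
#' @export
write_normalized_matrix <- function(x, path) {
  stopifnot(inherits(x, "tmt_norm"))
  df <- data.frame(protein = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
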