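# Signature extraction and sample-structure checks downstream of the
# differential tests: FDR-thresholded protein sets, Venn partitions of the
# per-diet comparisons, the diet-independent core set, and hierarchical
# clustering of sample profiles.

#' Extract the FDR-thresholded signature from a contrast table
#'
#' @param table A `contrast_table` from [run_contrast()].
#' @param q_cut FDR cutoff (0 < q_cut <= 1); members are proteins with
#'   q-value strictly below it.
#' @return Object of class `tmt_signature`: label, threshold, `members`
#'   (character vector) and `direction` (named "up"/"down" by sign of the
#'   log2 fold change).
#' @export
threshold_signature <- function(table, q_cut = 0.05) {
  stopifnot(is.data.frame(table))
  if (!is.numeric(q_cut) || length(q_cut) != 1 || q_cut <= 0 || q_cut > 1) {
    stopf("q_cut must lie in (0, 1]")
  }
  sel <- table$q_value < q_cut
  members <- table$protein[sel]
  direction <- ifelse(table$log2_fold_change[sel] >= 0, "up", "down")
  names(direction) <- members
  structure(list(label = attr(table, "label") %||% "signature",
                 threshold = q_cut, members = members, direction = direction),
            class = "tmt_signature")
}

#' @export
print.tmt_signature <- function(x, ...) {
  cat(sprintf("tmt_signature '%s': %d proteins at q < %g (%d up, %d down)\n",
              x$label, length(x$members), x$threshold,
              sum(x$direction == "up"), sum(x$direction == "down")))
  invisible(x)
}

.sig_members <- function(x) {
  if (inherits(x, "tmt_signature")) x$members else as.character(x)
}

#' Disjoint Venn regions of two or three signatures
#'
#' @param signatures List of 2 or 3 `tmt_signature` objects (or character
#'   vectors).
#' @return Named integer vector of exclusive region counts; names combine
#'   signature labels with "&". Regions sum to the size of the union.
#' @export
venn_partition <- function(signatures) {
  k <- length(signatures)
  if (k < 2 || k > 3) stopf("venn_partition supports 2 or 3 sets, got %d", k)
  sets <- lapply(signatures, .sig_members)
  labels <- vapply(seq_len(k), function(i) {
    if (inherits(signatures[[i]], "tmt_signature")) signatures[[i]]$label
    else names(signatures)[i] %||% LETTERS[i]
  }, character(1))
  if (any(labels == "" | is.na(labels))) labels <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) <= 1) membership <- matrix(membership, nrow = length(universe))
  out <- integer()
  for (mask in seq_len(2^k - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    region <- paste(labels[bits], collapse = "&")
    inside <- apply(membership, 1, function(m) all(m == bits))
    out[region] <- as.integer(sum(inside))
  }
  out
}

#' Intersection core of several signatures, with direction-discordance flags
#'
#' The core is the plain intersection of member sets; a core protein whose
#' up/down direction differs between signatures is retained but flagged.
#'
#' @param signatures List of >= 2 `tmt_signature` objects.
#' @return A `tmt_signature` labeled "core" whose `direction` comes from
#'   the first signature, plus a named logical element `discordant`.
#' @export
core_signature <- function(signatures) {
  if (length(signatures) < 2) stopf("core_signature needs >= 2 signatures")
  stopifnot(all(vapply(signatures, inherits, logical(1), "tmt_signature")))
  members <- Reduce(intersect, lapply(signatures, `[[`, "members"))
  dirs <- sapply(signatures, function(s) s$direction[members])
  if (length(members) == 1) dirs <- matrix(dirs, nrow = 1)
  discordant <- if (length(members) > 0) {
    apply(dirs, 1, function(d) length(unique(d)) > 1)
  } else logical()
  names(discordant) <- members
  direction <- if (length(members) > 0) signatures[[1]]$direction[members] else
    stats::setNames(character(), character())
  structure(list(label = "core",
                 threshold = signatures[[1]]$threshold,
                 members = members, direction = direction,
                 discordant = discordant),
            class = "tmt_signature")
}

#' Hierarchical clustering of sample intensity profiles
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' log2-transformed sample profiles, the standard check that samples group
#' by biology (genotype/diet) rather than by plex.
#'
#' @param norm A `tmt_norm` (or positive proteins x samples matrix).
#' @return An [stats::hclust] object (merge matrix, heights, leaf order).
#' @export
cluster_samples <- function(norm) {
  values <- if (inherits(norm, "tmt_norm")) norm$values else norm
  if (!is.matrix(values)) stopf("need a matrix of intensities")
  if (ncol(values) < 2) stopf("clustering needs >= 2 samples")
  if (any(values <= 0)) stopf("intensities must be positive for the log2 transform")
  d <- stats::dist(t(log2(values)), method = "euclidean")
  stats::hclust(d, method = "average")
}

#' Write a dendrogram as Newick text
#' @param h An [stats::hclust] object.
#' @param path Output path.
#' @export
write_dendrogram <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Write a signature to TSV (protein, direction, discordant flag if any)
#' @param x A `tmt_signature`.
#' @param path Output path.
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "tmt_signature"))
  df <- data.frame(protein = x$members,
                   direction = unname(x$direction),
                   stringsAsFactors = FALSE)
  if (!is.null(x$discordant)) df$discordant <- unname(x$discordant)
  write_tsv(df, path)
}
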