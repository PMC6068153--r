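# Count-model differential abundance on IRS-normalized intensities.
#
# The test is the exact conditional negative-binomial split test: condition
# on a protein's total count across both groups and ask whether the observed
# split between group totals is surprising under a common mean. Dispersion
# is a single common value estimated by conditional maximum likelihood on
# library-size-equalized counts. This is the simplest member of the
# count-test family appropriate for n = 4 per group isobaric designs.

#' Convert a normalized intensity matrix to library-equalized pseudo-counts
#'
#' Each sample column is scaled to the geometric mean of the column totals
#' and rounded (half-to-even) to integers, so that the conditional split
#' test downstream can treat library sizes as equal.
#'
#' @param x A `tmt_norm` or a positive numeric matrix (proteins x samples).
#' @return List with integer `counts` and per-sample `size_factors`
#'   (observed total / target total).
#' @export
to_pseudocounts <- function(x) {
  values <- if (inherits(x, "tmt_norm")) x$values else x
  if (!is.matrix(values) || !is.numeric(values)) stopf("need a numeric matrix")
  if (any(values < 0)) stopf("intensities must be non-negative")
  lib <- colSums(values)
  if (any(lib == 0)) stopf("sample with zero total intensity")
  target <- exp(mean(log(lib)))
  sf <- lib / target
  counts <- round(sweep(values, 2, sf, "/"))
  storage.mode(counts) <- "integer"
  list(counts = counts, size_factors = sf)
}

# conditional log-likelihood of a common dispersion phi given equalized
# counts; summed over proteins, per replicate group (Robinson-Smyth qCML)
.cond_loglik <- function(counts, groups, phi) {
  ll <- 0
  for (g in unique(groups)) {
    Y <- counts[, groups == g, drop = FALSE]
    n <- ncol(Y)
    if (n < 2) next
    z <- rowSums(Y)
    if (phi > 0) {
      r <- 1 / phi
      ll <- ll + sum(lgamma(Y + r)) - length(Y) * lgamma(r) - sum(lgamma(Y + 1)) -
        sum(lgamma(z + n * r)) + length(z) * lgamma(n * r) + sum(lgamma(z + 1))
    } else {
      # Poisson limit: counts | total are multinomial with equal cell probs
      ll <- ll - sum(lgamma(Y + 1)) + sum(lgamma(z + 1)) - sum(z) * log(n)
    }
  }
  ll
}

#' Estimate a common negative-binomial dispersion by conditional ML
#'
#' Maximizes the summed conditional log-likelihood (conditioning each
#' protein's replicate counts on their group total) over a single
#' dispersion shared by all proteins, on library-equalized counts. The
#' estimate is clamped to \[0, 10\].
#'
#' @param counts Integer matrix of equalized counts (proteins x samples).
#' @param groups Vector of group labels, one per column.
#' @return Scalar dispersion phi (variance = mu + phi * mu^2).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (length(groups) != ncol(counts)) stopf("groups must match the columns of counts")
  if (any(counts < 0)) stopf("counts must be non-negative")
  reps <- table(groups)
  if (!any(reps >= 2)) stopf("dispersion estimation needs >= 2 replicates in at least one group")
  if (nrow(counts) == 0) stopf("no proteins to estimate dispersion from")
  f <- function(phi) .cond_loglik(counts, groups, phi)
  opt <- stats::optimize(f, interval = c(1e-6, 10), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 10)
  ll <- c(f(0), opt$objective, f(10))
  phi <- cand[which.max(ll)]
  max(0, min(10, phi))
}

# two-sided exact p-value for the split of total z into group totals
# (zA, z - zA), with nA and nB libraries per group and dispersion phi.
# Conditional on z, the group-A total follows a Polya/beta-binomial-type
# law proportional to dnbinom(a; nA/phi) * dnbinom(z - a; nB/phi); the
# two-sided p sums all splits no more probable than the observed one.
.split_pvalue <- function(zA, zB, nA, nB, phi) {
  z <- zA + zB
  if (z == 0) return(1)
  n <- nA + nB
  if (phi == 0) {
    pA <- nA / n
    if (z <= 5000) {
      a <- 0:z
      probs <- stats::dbinom(a, z, pA)
    } else {
      q <- stats::qbinom(c(1e-15, 1 - 1e-15), z, pA)
      a <- max(0, min(q[1], zA)):min(z, max(q[2], zA))
      probs <- stats::dbinom(a, z, pA)
      probs <- probs / sum(probs)
    }
  } else {
    r <- 1 / phi
    sA <- nA * r; sB <- nB * r
    muA <- z * nA / n; muB <- z * nB / n
    if (z <= 5000) {
      a <- 0:z
    } else {
      qa <- stats::qnbinom(c(1e-15, 1 - 1e-15), size = sA, mu = muA)
      qb <- stats::qnbinom(c(1e-15, 1 - 1e-15), size = sB, mu = muB)
      lo <- max(0, min(qa[1], z - qb[2], zA))
      hi <- min(z, max(qa[2], z - qb[1], zA))
      a <- lo:hi
    }
    lp <- stats::dnbinom(a, size = sA, mu = muA, log = TRUE) +
      stats::dnbinom(z - a, size = sB, mu = muB, log = TRUE)
    lp <- lp - logsumexp(lp)
    probs <- exp(lp)
  }
  pobs <- probs[a == zA]
  min(1, sum(probs[probs <= pobs * (1 + 1e-10)]))
}

#' Exact conditional test for a two-group count split
#'
#' Conditions on the protein's total count and computes the two-sided
#' probability of group splits no more probable than the observed one under
#' a common-mean negative-binomial model with dispersion `phi`
#' (`phi = 0` reduces to the exact binomial split test). Assumes library
#' sizes have been equalized (see [to_pseudocounts()]).
#'
#' @param counts_A,counts_B Non-negative integer count vectors (replicates).
#' @param phi Common dispersion, >= 0.
#' @return List with `p_value` and `log2_fold_change` (A over B, computed
#'   as log2((mean_A + 0.5) / (mean_B + 0.5))).
#' @export
exact_test <- function(counts_A, counts_B, phi = 0) {
  if (any(counts_A < 0) || any(counts_B < 0)) stopf("counts must be non-negative")
  assert_scalar_number(phi, "phi", lower = 0)
  p <- .split_pvalue(sum(counts_A), sum(counts_B),
                     length(counts_A), length(counts_B), phi)
  lfc <- log2((mean(counts_A) + 0.5) / (mean(counts_B) + 0.5))
  list(p_value = p, log2_fold_change = lfc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values (BH-adjusted p-values), order-matched.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' The nine genotype/diet comparisons of the study design
#'
#' Builds the standard contrast list for a two-genotype, three-diet design:
#' (a)-(c) genotype comparisons within each diet, (d)-(g) each genotype's
#' LF vs HF and LF vs HFC responses, (h)-(i) HF vs HFC within genotype.
#'
#' @param genotypes Two genotype labels (first = wild type).
#' @param diets Three diet labels, ordered (LF, HF, HFC).
#' @return Named list of contrast specs, labels "a".."i".
#' @export
contrast_specs <- function(genotypes = c("Csf2+/+", "Csf2-/-"),
                           diets = c("LF", "HF", "HFC")) {
  stopifnot(length(genotypes) == 2, length(diets) == 3)
  g1 <- genotypes[1]; g2 <- genotypes[2]
  sel <- function(genotype = NULL, diet = NULL) {
    Filter(Negate(is.null), list(genotype = genotype, diet = diet))
  }
  list(
    a = contrast_spec("a", sel(g1, diets[1]), sel(g2, diets[1])),
    b = contrast_spec("b", sel(g1, diets[2]), sel(g2, diets[2])),
    c = contrast_spec("c", sel(g1, diets[3]), sel(g2, diets[3])),
    d = contrast_spec("d", sel(g1, diets[1]), sel(g1, diets[2])),
    e = contrast_spec("e", sel(g2, diets[1]), sel(g2, diets[2])),
    f = contrast_spec("f", sel(g1, diets[1]), sel(g1, diets[3])),
    g = contrast_spec("g", sel(g2, diets[1]), sel(g2, diets[3])),
    h = contrast_spec("h", sel(g1, diets[2]), sel(g1, diets[3])),
    i = contrast_spec("i", sel(g2, diets[2]), sel(g2, diets[3])))
}

#' Define a two-group contrast by genotype/diet selectors
#' @param label Short contrast label.
#' @param group_A,group_B Named lists with any of `genotype`, `diet`.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(label, group_A, group_B) {
  structure(list(label = label, group_A = group_A, group_B = group_B),
            class = "contrast_spec")
}

.select_samples <- function(metadata, selector) {
  keep <- rep(TRUE, nrow(metadata))
  for (fld in names(selector)) {
    if (!fld %in% names(metadata)) stopf("unknown selector field '%s'", fld)
    if (!selector[[fld]] %in% metadata[[fld]]) {
      stopf("unknown group label '%s' for field '%s'", selector[[fld]], fld)
    }
    keep <- keep & metadata[[fld]] == selector[[fld]]
  }
  metadata$sample_id[keep]
}

#' Differential abundance for one contrast
#'
#' Subsets the normalized matrix to the two groups, equalizes library
#' sizes, estimates the common dispersion on the contrast's samples, runs
#' the exact conditional split test per protein, and applies BH adjustment
#' across all quantified proteins.
#'
#' @param norm A `tmt_norm` from [irs_normalize()]/[quantify_plexes()].
#' @param metadata Sample metadata (defaults to the one stored in `norm`).
#' @param spec A [contrast_spec()].
#' @return A data.frame of class `contrast_table` with columns `protein`,
#'   `log2_fold_change`, `p_value`, `q_value`; the contrast label,
#'   dispersion and group sizes are attached as attributes.
#' @export
run_contrast <- function(norm, spec, metadata = norm$metadata) {
  stopifnot(inherits(norm, "tmt_norm"), inherits(spec, "contrast_spec"))
  ids_A <- .select_samples(metadata, spec$group_A)
  ids_B <- .select_samples(metadata, spec$group_B)
  if (length(ids_A) == 0 || length(ids_B) == 0) {
    stopf("contrast '%s': empty group", spec$label)
  }
  if (length(intersect(ids_A, ids_B)) > 0) {
    stopf("contrast '%s': groups overlap", spec$label)
  }
  sub <- norm$values[, c(ids_A, ids_B), drop = FALSE]
  pc <- to_pseudocounts(sub)
  groups <- rep(c("A", "B"), c(length(ids_A), length(ids_B)))
  phi <- estimate_common_dispersion(pc$counts, groups)
  cA <- pc$counts[, groups == "A", drop = FALSE]
  cB <- pc$counts[, groups == "B", drop = FALSE]
  P <- nrow(sub)
  p <- numeric(P); lfc <- numeric(P)
  zA <- rowSums(cA); zB <- rowSums(cB)
  nA <- ncol(cA); nB <- ncol(cB)
  for (i in seq_len(P)) {
    p[i] <- .split_pvalue(zA[i], zB[i], nA, nB, phi)
  }
  lfc <- log2((zA / nA + 0.5) / (zB / nB + 0.5))
  out <- data.frame(protein = rownames(sub), log2_fold_change = lfc,
                    p_value = p, q_value = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "label") <- spec$label
  attr(out, "dispersion") <- phi
  attr(out, "n_A") <- nA
  attr(out, "n_B") <- nB
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, n = 6L, ...) {
  cat(sprintf("contrast_table '%s': %d proteins, dispersion %.4g, n = %d + %d, %d at q < 0.05\n",
              attr(x, "label") %||% "?", nrow(x), attr(x, "dispersion"),
              attr(x, "n_A"), attr(x, "n_B"), sum(x$q_value < 0.05)))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Write a contrast table to TSV
#' @param x A `contrast_table`.
#' @param path Output path.
#' @export
write_contrast_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}
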