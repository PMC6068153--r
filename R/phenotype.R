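# Phenotype and metabolite statistics: baseline-normalized AUC for
# glucose/insulin tolerance curves, one-way ANOVA with Tukey HSD, and
# Pearson correlation/linear association for metabolite-protein pairs.

#' Baseline-normalized area under a tolerance curve
#'
#' Subtracts the time-0 value from the whole curve and integrates the
#' excursion by the trapezoidal rule; negative areas (dips below baseline)
#' are retained, giving a net AUC in value-units x minutes.
#'
#' @param values Measurements (e.g. glucose in mg/dL), one per time point.
#' @param times Strictly increasing times in minutes, first must be 0.
#' @return Scalar net AUC.
#' @export
auc_baseline <- function(values, times = c(0, 15, 30, 60, 120)) {
  if (length(values) != length(times) || length(values) < 2) {
    stopf("values and times must have equal length >= 2")
  }
  if (anyNA(values) || anyNA(times)) stopf("missing values in curve")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (times[1] != 0) stopf("first time point must be 0 (baseline)")
  y <- values - values[1]
  sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   n >= 2; at least two groups).
#' @return List with `F`, `p_value`, `df` (between, within) and
#'   `pairwise`, a data.frame with one row per group pair (comparison,
#'   diff, lwr, upr, p_adj from the studentized-range distribution).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stopf("every group needs n >= 2 (group '%s' has %d)",
          names(groups)[sizes < 2][1] %||% "?", min(sizes))
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk), tk,
                         row.names = NULL, stringsAsFactors = FALSE)
  names(pairwise) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  list(F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df = c(between = tab$Df[1], within = tab$Df[2]),
       pairwise = pairwise)
}

#' Pearson correlation and least-squares association
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @param x_name,y_name Labels recorded in the result.
#' @return One-row data.frame (class `association_record`): x_name,
#'   y_name, n, slope, intercept, r, r_squared, p_value (two-sided t-test
#'   on r).
#' @export
correlate <- function(x, y, x_name = deparse(substitute(x)),
                      y_name = deparse(substitute(y))) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("degenerate input: constant x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  out <- data.frame(x_name = x_name, y_name = y_name, n = length(x),
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r = unname(ct$estimate),
                    r_squared = unname(ct$estimate)^2,
                    p_value = ct$p.value,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_record", "data.frame")
  out
}

#' Metabolite-protein associations across shared samples
#'
#' Joins a metabolite table and a protein table on sample identifiers and
#' computes one association record per requested (metabolite, protein)
#' pair on the sample intersection.
#'
#' @param metabolites Data frame with a `sample_id` column plus one column
#'   per metabolite.
#' @param proteins A `tmt_norm` (proteins x samples) or a data frame with
#'   `sample_id` plus one column per protein.
#' @param pairs Data frame with columns `metabolite` and `protein` naming
#'   the columns/rows to associate.
#' @return Data frame of association records (one row per pair).
#' @export
associate_metabolite_protein <- function(metabolites, proteins, pairs) {
  stopifnot(is.data.frame(metabolites), "sample_id" %in% names(metabolites))
  stopifnot(is.data.frame(pairs), all(c("metabolite", "protein") %in% names(pairs)))
  if (inherits(proteins, "tmt_norm")) {
    proteins <- data.frame(sample_id = colnames(proteins$values),
                           t(proteins$values),
                           check.names = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(proteins), "sample_id" %in% names(proteins))
  shared <- intersect(metabolites$sample_id, proteins$sample_id)
  if (length(shared) == 0) stopf("no shared sample identifiers between tables")
  mi <- match(shared, metabolites$sample_id)
  pi <- match(shared, proteins$sample_id)
  recs <- lapply(seq_len(nrow(pairs)), function(k) {
    mcol <- pairs$metabolite[k]; pcol <- pairs$protein[k]
    if (!mcol %in% names(metabolites)) stopf("unknown metabolite '%s'", mcol)
    if (!pcol %in% names(proteins)) stopf("unknown protein '%s'", pcol)
    correlate(metabolites[[mcol]][mi], proteins[[pcol]][pi],
              x_name = mcol, y_name = pcol)
  })
  do.call(rbind, recs)
}
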