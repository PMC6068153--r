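#' Default group-effect specification for phenotype simulation
#'
#' Encodes the qualitative phenotype pattern the generator emulates: both
#' genotypes respond to high-fat feeding with larger glucose excursions,
#' the knockout's baseline-normalized AUC is about half the wild type's
#' on every diet, plasma 2-aminoadipate is strongly reduced in the
#' knockout (slightly raised by the HFC diet in wild type), and the
#' adipose DHTKD1-like protein covariate is elevated in the knockout and
#' diet-independent, with a strong negative within-group correlation to
#' the metabolite.
#'
#' @param genotypes Two genotype labels (first = wild type).
#' @param diets Three diet labels, ordered (LF, HF, HFC).
#' @return List understood by [simulate_phenotypes()]: a `groups` data
#'   frame (genotype, diet, glucose_scale, metabolite_mean, protein_mean,
#'   fasting_shift),
#'   the glucose excursion `glucose_template` (mg/dL above baseline at
#'   `times` minutes), `glucose_baseline`, per-source noise SDs, and the
#'   within-group metabolite-protein correlation `met_prot_cor`.
#' @export
default_phenotype_effects <- function(genotypes = c("Csf2+/+", "Csf2-/-"),
                                      diets = c("LF", "HF", "HFC")) {
  stopifnot(length(genotypes) == 2, length(diets) == 3)
  groups <- expand.grid(genotype = genotypes, diet = diets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wt <- groups$genotype == genotypes[1]
  scale_by_diet <- stats::setNames(c(0.55, 1.0, 1.05), diets)
  groups$glucose_scale <- scale_by_diet[groups$diet] * ifelse(wt, 1, 0.5)
  groups$metabolite_mean <- ifelse(wt,
                                   ifelse(groups$diet == diets[3], 1.9, 1.5),
                                   0.6)
  groups$protein_mean <- ifelse(wt, 1.0, 1.6)
  # fasting (t = 0) glucose shift, mg/dL: raised by obesogenic diets,
  # lowered in the knockout; cancels out of the baseline-normalized AUC
  fasting_by_diet <- stats::setNames(c(0, 35, 40), diets)
  groups$fasting_shift <- fasting_by_diet[groups$diet] - ifelse(wt, 0, 25)
  list(groups = groups,
       times = c(0, 15, 30, 60, 120),
       glucose_template = c(0, 180, 150, 90, 25),
       glucose_baseline = 140,
       glucose_sd = 12,
       metabolite_sd = 0.18,
       protein_sd = 0.15,
       met_prot_cor = -0.93)
}

#' Simulate glucose-tolerance curves and metabolite/protein covariates
#'
#' For every animal in `metadata`, draws a glucose curve (baseline +
#' group-scaled excursion template + Gaussian noise at each time point), a
#' plasma metabolite value and a protein-abundance covariate. Within each
#' group the metabolite and protein share a latent Gaussian factor giving
#' correlation `met_prot_cor` (negative by default, emulating the
#' 2-aminoadipate / DHTKD1 axis).
#'
#' @param metadata Data frame with columns `sample_id`, `genotype`, `diet`
#'   (one row per animal).
#' @param effect_spec Effect specification as produced by
#'   [default_phenotype_effects()]; its `groups` rows must cover exactly
#'   the groups present in `metadata`.
#' @param seed Integer seed.
#' @return List of data frames: `glucose` (sample_id, genotype, diet,
#'   t0..t120 in mg/dL), `metabolites` (sample_id, aa2) and `proteins`
#'   (sample_id, dhtkd1).
#' @export
simulate_phenotypes <- function(metadata,
                                effect_spec = default_phenotype_effects(),
                                seed = 1L) {
  need <- c("sample_id", "genotype", "diet")
  if (!all(need %in% names(metadata))) {
    stopf("metadata needs columns: %s", paste(need, collapse = ", "))
  }
  groups <- effect_spec$groups
  gkey <- function(g, d) paste(g, d, sep = "\r")
  spec_key <- gkey(groups$genotype, groups$diet)
  meta_key <- gkey(metadata$genotype, metadata$diet)
  unknown <- setdiff(spec_key, unique(meta_key))
  if (length(unknown) > 0) {
    bad <- groups[spec_key %in% unknown, c("genotype", "diet")][1, ]
    stopf("effect_spec names a group absent from metadata: %s / %s",
          bad$genotype, bad$diet)
  }
  uncovered <- setdiff(unique(meta_key), spec_key)
  if (length(uncovered) > 0) {
    stopf("metadata group(s) missing from effect_spec: %s",
          gsub("\r", " / ", uncovered[1]))
  }
  idx <- match(meta_key, spec_key)
  times <- effect_spec$times
  template <- effect_spec$glucose_template
  stopifnot(length(times) == length(template))
  rho <- effect_spec$met_prot_cor
  assert_scalar_number(rho, "met_prot_cor", lower = -1, upper = 1)
  n <- nrow(metadata)

  with_seed(seed, {
    fasting <- if (is.null(groups$fasting_shift)) rep(0, nrow(groups)) else groups$fasting_shift
    curves <- matrix(NA_real_, nrow = n, ncol = length(times))
    for (j in seq_along(times)) {
      mu <- effect_spec$glucose_baseline + fasting[idx] +
        groups$glucose_scale[idx] * template[j]
      curves[, j] <- mu + stats::rnorm(n, 0, effect_spec$glucose_sd)
    }
    curves[curves < 0] <- 0
    colnames(curves) <- sprintf("t%d", times)
    u <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    met <- groups$metabolite_mean[idx] + effect_spec$metabolite_sd * u
    prot <- groups$protein_mean[idx] +
      effect_spec$protein_sd * (rho * u + sqrt(1 - rho^2) * eps)
    list(
      glucose = data.frame(sample_id = metadata$sample_id,
                           genotype = metadata$genotype,
                           diet = metadata$diet, curves,
                           stringsAsFactors = FALSE),
      metabolites = data.frame(sample_id = metadata$sample_id, aa2 = met,
                               stringsAsFactors = FALSE),
      proteins = data.frame(sample_id = metadata$sample_id, dhtkd1 = prot,
                            stringsAsFactors = FALSE))
  })
}
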