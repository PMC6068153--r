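#' Describe a multi-plex TMT experimental design
#'
#' Captures the factorial layout of an isobaric-labeling proteomics
#' experiment: a genotype-by-diet design quantified across several TMT
#' plexes, with some channels of each plex reserved for a pooled internal
#' reference. Defaults reproduce a 2-genotype x 3-diet mouse study with
#' n = 4 animals per group measured across three TMT 10-plexes.
#'
#' @param genotypes Character vector of genotype labels.
#' @param diets Character vector of diet labels.
#' @param replicates_per_group Animals per genotype-by-diet cell.
#' @param plexes Number of TMT plexes (batches).
#' @param channels_per_plex Reporter channels per plex (10 for TMT 10-plex).
#' @param reference_channels_per_plex Channels per plex carrying the pooled
#'   internal-reference standard rather than a sample.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(genotypes = c("Csf2+/+", "Csf2-/-"),
                              diets = c("LF", "HF", "HFC"),
                              replicates_per_group = 4L,
                              plexes = 3L,
                              channels_per_plex = 10L,
                              reference_channels_per_plex = 2L) {
  if (anyDuplicated(genotypes) || anyDuplicated(diets)) {
    stopf("genotype and diet labels must be unique")
  }
  assert_scalar_number(replicates_per_group, "replicates_per_group", lower = 1)
  assert_scalar_number(plexes, "plexes", lower = 1)
  assert_scalar_number(channels_per_plex, "channels_per_plex", lower = 1)
  assert_scalar_number(reference_channels_per_plex, "reference_channels_per_plex",
                       lower = 0, upper = channels_per_plex - 1)
  n_samples <- length(genotypes) * length(diets) * replicates_per_group
  capacity <- plexes * (channels_per_plex - reference_channels_per_plex)
  if (n_samples > capacity) {
    stopf("design infeasible: %d samples exceed %d available sample channels",
          n_samples, capacity)
  }
  structure(
    list(genotypes = genotypes, diets = diets,
         replicates_per_group = as.integer(replicates_per_group),
         plexes = as.integer(plexes),
         channels_per_plex = as.integer(channels_per_plex),
         reference_channels_per_plex = as.integer(reference_channels_per_plex),
         n_samples = as.integer(n_samples)),
    class = "experiment_design")
}

#' Simulation parameters for synthetic TMT reporter intensities
#'
#' Protein baselines are log-normal; reporter intensities are drawn as
#' negative-binomial counts around the group mean (variance mu + phi*mu^2;
#' `nb_dispersion = 0` gives Poisson noise). Each plex carries a
#' multiplicative batch factor, emulating between-plex labeling and
#' instrument drift that internal reference scaling must remove.
#'
#' @param n_proteins Number of proteins simulated.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of the
#'   per-protein baseline abundance.
#' @param nb_dispersion Negative-binomial dispersion phi (>= 0).
#' @param plex_effect_sd Log-scale sd of the per-plex multiplicative batch
#'   factor (0 disables batch effects).
#' @param frac_differential Fraction of proteins planted as differential
#'   between the two genotypes.
#' @param fold_change Fold change applied to planted proteins (half up,
#'   half down, in the first genotype relative to the second).
#' @param protein_specific_plex_effects If TRUE, each (protein, plex) pair
#'   gets its own batch factor, a stress mode for IRS.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 2000L,
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 1,
                       nb_dispersion = 0.1,
                       plex_effect_sd = 0.3,
                       frac_differential = 0.1,
                       fold_change = 4,
                       protein_specific_plex_effects = FALSE,
                       seed = 1L) {
  assert_scalar_number(n_proteins, "n_proteins", lower = 0)
  assert_scalar_number(baseline_log_sd, "baseline_log_sd", lower = 0)
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(plex_effect_sd, "plex_effect_sd", lower = 0)
  assert_scalar_number(frac_differential, "frac_differential", lower = 0, upper = 1)
  assert_scalar_number(fold_change, "fold_change", lower = .Machine$double.eps)
  structure(
    list(n_proteins = as.integer(n_proteins),
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         nb_dispersion = nb_dispersion,
         plex_effect_sd = plex_effect_sd,
         frac_differential = frac_differential,
         fold_change = fold_change,
         protein_specific_plex_effects = isTRUE(protein_specific_plex_effects),
         seed = as.integer(seed)),
    class = "sim_params")
}

# assign samples to plexes/channels round-robin so every plex carries a
# balanced mix of groups (standard practice for multi-plex TMT designs)
.layout_samples <- function(design) {
  g <- rep(design$genotypes, each = length(design$diets) * design$replicates_per_group)
  d <- rep(rep(design$diets, each = design$replicates_per_group),
           times = length(design$genotypes))
  n <- design$n_samples
  if (n == 0L) {
    return(data.frame(sample_id = character(), genotype = character(),
                      diet = character(), plex = character(),
                      channel = character(), stringsAsFactors = FALSE))
  }
  plex_idx <- ((seq_len(n) - 1L) %% design$plexes) + 1L
  n_ref <- design$reference_channels_per_plex
  chan_idx <- integer(n)
  for (p in seq_len(design$plexes)) {
    in_p <- which(plex_idx == p)
    chan_idx[in_p] <- n_ref + seq_along(in_p)
  }
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    genotype = g, diet = d,
    plex = sprintf("plex%d", plex_idx),
    channel = sprintf("C%d", chan_idx),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-plex TMT experiment with planted differential proteins
#'
#' Generates one reporter-ion intensity table per plex, the sample metadata
#' mapping channels to genotype/diet groups, and a ground-truth record of
#' the planted differential proteins and plex batch factors. Reference
#' channels are filled with the rounded per-protein mean of that plex's
#' sample channels, emulating a pooled internal standard.
#'
#' @param design An [experiment_design()].
#' @param params A [sim_params()].
#' @return A list with elements `plexes` (list of [plex_table] objects),
#'   `metadata` (data.frame: sample_id, genotype, diet, plex, channel) and
#'   `truth` (list with `differential` data.frame of protein, log2fc and
#'   `plex_factors`).
#' @export
simulate_tmt_experiment <- function(design = experiment_design(),
                                    params = sim_params()) {
  stopifnot(inherits(design, "experiment_design"), inherits(params, "sim_params"))
  meta <- .layout_samples(design)
  P <- params$n_proteins
  proteins <- if (P > 0) sprintf("P%05d", seq_len(P)) else character()

  with_seed(params$seed, {
    base <- exp(stats::rnorm(P, params$baseline_log_mean, params$baseline_log_sd))
    plex_ids <- sprintf("plex%d", seq_len(design$plexes))
    if (params$protein_specific_plex_effects) {
      plex_fac <- matrix(exp(stats::rnorm(P * design$plexes, 0, params$plex_effect_sd)),
                         nrow = P, dimnames = list(proteins, plex_ids))
    } else {
      pf <- exp(stats::rnorm(design$plexes, 0, params$plex_effect_sd))
      plex_fac <- matrix(rep(pf, each = max(P, 1L)), nrow = max(P, 1L),
                         dimnames = list(if (P > 0) proteins else NULL, plex_ids))
      names(pf) <- plex_ids
    }
    n_diff <- round(params$frac_differential * P)
    diff_idx <- if (n_diff > 0) sort(sample.int(P, n_diff)) else integer()
    l2fc <- rep(c(1, -1), length.out = n_diff) * log2(params$fold_change)

    # per-protein multiplier for samples of the first genotype
    eff <- rep(1, max(P, 1L))
    eff[diff_idx] <- 2^l2fc

    chan_ids <- sprintf("C%d", seq_len(design$channels_per_plex))
    ref_ids <- if (design$reference_channels_per_plex > 0) {
      chan_ids[seq_len(design$reference_channels_per_plex)]
    } else character()

    tabs <- lapply(plex_ids, function(pid) {
      m <- matrix(0, nrow = P, ncol = design$channels_per_plex,
                  dimnames = list(proteins, chan_ids))
      smeta <- meta[meta$plex == pid, , drop = FALSE]
      for (k in seq_len(nrow(smeta))) {
        mu <- base * plex_fac[, pid]
        if (smeta$genotype[k] == design$genotypes[1]) mu <- mu * eff
        y <- if (params$nb_dispersion > 0) {
          stats::rnbinom(P, mu = mu, size = 1 / params$nb_dispersion)
        } else {
          stats::rpois(P, mu)
        }
        m[, smeta$channel[k]] <- y
      }
      sample_cols <- smeta$channel
      if (length(ref_ids) > 0 && P > 0) {
        ref_val <- round(rowMeans(m[, sample_cols, drop = FALSE]))
        for (rc in ref_ids) m[, rc] <- ref_val
      }
      # unoccupied sample channels (partial plexes) are not exported
      m <- m[, c(ref_ids, sample_cols), drop = FALSE]
      plex_table(pid, m, reference_channels = ref_ids)
    })
    names(tabs) <- plex_ids

    truth <- list(
      differential = data.frame(protein = proteins[diff_idx],
                                log2fc = l2fc, stringsAsFactors = FALSE),
      plex_factors = if (params$protein_specific_plex_effects) plex_fac else pf)
    list(plexes = tabs, metadata = meta, truth = truth)
  })
}
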