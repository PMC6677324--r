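#' Configuration for the synthetic expression-matrix generator
#'
#' The defaults emulate a diurnal brain RNA-seq design: samples every 3 h
#' across one 24-h light:dark cycle (ZT1, 4, ..., 22), two replicates per
#' timepoint, RPKM-scale values with multiplicative lognormal noise.
#' Rhythmic genes follow a cosinor
#' `mesor * (1 + a * cos(2*pi*(t - phi)/period)) * eps`; clock-mutant
#' genotypes multiply the relative amplitude `a` by an attenuation factor
#' (1 = intact rhythm, 0 = flat).
#'
#' @param n_genes number of genes.
#' @param frac_rhythmic fraction of genes that are rhythmic, in \[0,1\].
#' @param timepoints_h ZT hours sampled, strictly increasing within \[0,24).
#' @param n_replicates replicates per timepoint.
#' @param period_h rhythm period in hours.
#' @param amplitude_range range of relative amplitudes `a` (must be < 1 so
#'   expectations stay positive).
#' @param mesor_range range of mesors (RPKM).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (0 = noise free).
#' @param genotype_effects named numeric map genotype -> amplitude
#'   attenuation in \[0,1\].
#' @param mesor_shift optional named numeric map genotype -> multiplicative
#'   mesor factor, to model constitutive-low expression in clock mutants
#'   (default none).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a `sim_expression_config` list.
#' @export
sim_expression_config <- function(n_genes = 1000,
                                  frac_rhythmic = 0.1,
                                  timepoints_h = seq(1, 22, by = 3),
                                  n_replicates = 2,
                                  period_h = 24,
                                  amplitude_range = c(0.3, 0.8),
                                  mesor_range = c(5, 50),
                                  noise_cv = 0.2,
                                  genotype_effects = c(WT = 1),
                                  mesor_shift = NULL,
                                  seed = 1L) {
  stopifnot(n_genes >= 1, frac_rhythmic >= 0, frac_rhythmic <= 1,
            noise_cv >= 0, n_replicates >= 1, period_h > 0)
  if (any(diff(timepoints_h) <= 0) || any(timepoints_h < 0) ||
      any(timepoints_h >= period_h))
    stop("timepoints must be strictly increasing within [0, period)")
  if (max(amplitude_range) >= 1)
    stop("relative amplitude must be < 1 (negative expectations otherwise)")
  if (is.null(names(genotype_effects)) || any(!nzchar(names(genotype_effects))))
    stop("genotype_effects must be a named vector")
  if (any(genotype_effects < 0 | genotype_effects > 1))
    stop("genotype attenuation factors must lie in [0,1]")
  structure(list(
    n_genes = as.integer(n_genes), frac_rhythmic = frac_rhythmic,
    timepoints_h = timepoints_h, n_replicates = as.integer(n_replicates),
    period_h = period_h, amplitude_range = amplitude_range,
    mesor_range = mesor_range, noise_cv = noise_cv,
    genotype_effects = genotype_effects, mesor_shift = mesor_shift,
    seed = as.integer(seed)
  ), class = "sim_expression_config")
}

#' Simulate a gene-by-sample expression matrix with known rhythm truth
#'
#' @param cfg a [sim_expression_config()].
#' @param truth optional truth from a previous call; when supplied, the same
#'   per-gene mesor/amplitude/phase/rhythmic assignments are reused (e.g. to
#'   generate a mutant matrix on a different sampling grid for differential
#'   rhythmicity), and only the noise is redrawn.
#' @return list with `matrix` (genes x samples, colnames
#'   `<genotype>_ZT<hh>_<rep>`) and `truth` (data.frame per gene:
#'   `gene_id`, `rhythmic`, `mesor`, `amplitude` (relative), `phase_h`).
#' @export
simulate_expression <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_expression_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  if (is.null(truth)) {
    n_r <- round(ng * cfg$frac_rhythmic)
    rhythmic <- c(rep(TRUE, n_r), rep(FALSE, ng - n_r))
    truth <- data.frame(
      gene_id = sprintf("g%05d", seq_len(ng)),
      rhythmic = rhythmic,
      mesor = stats::runif(ng, cfg$mesor_range[1], cfg$mesor_range[2]),
      amplitude = ifelse(rhythmic,
                         stats::runif(ng, cfg$amplitude_range[1],
                                      cfg$amplitude_range[2]), 0),
      phase_h = ifelse(rhythmic, stats::runif(ng, 0, cfg$period_h), NA_real_),
      stringsAsFactors = FALSE
    )
  } else {
    if (nrow(truth) != ng) stop("truth does not match n_genes")
  }
  if (any(truth$amplitude >= 1))
    stop("relative amplitude must be < 1")
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  cols <- list(); labels <- character(0)
  for (gt in names(cfg$genotype_effects)) {
    att <- cfg$genotype_effects[[gt]]
    mshift <- if (!is.null(cfg$mesor_shift) && gt %in% names(cfg$mesor_shift))
      cfg$mesor_shift[[gt]] else 1
    for (t in cfg$timepoints_h) {
      phase_term <- cos(2 * pi * (t - truth$phase_h) / cfg$period_h)
      phase_term[is.na(phase_term)] <- 0
      mu <- truth$mesor * mshift *
        (1 + truth$amplitude * att * phase_term)
      for (r in seq_len(cfg$n_replicates)) {
        eps <- if (cfg$noise_cv > 0)
          stats::rlnorm(ng, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, ng)
        cols[[length(cols) + 1L]] <- mu * eps
        labels <- c(labels, sprintf("%s_ZT%02d_%d", gt, as.integer(t), r))
      }
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(truth$gene_id, labels)
  list(matrix = m, truth = truth)
}
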