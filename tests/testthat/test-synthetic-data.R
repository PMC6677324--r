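# The generators and their planted ground truth.

test_that("noise-free cosinor genes hit their exact expected values", {
  cfg <- sim_expression_config(n_genes = 50, frac_rhythmic = 1,
                               noise_cv = 0, seed = 4)
  sim <- simulate_expression(cfg)
  tru <- sim$truth
  # at the gene's own phase the value is mesor * (1 + amplitude)
  for (i in c(1, 25, 50)) {
    y <- sim$matrix[i, ]
    t <- parse_sample_labels(colnames(sim$matrix))$zt
    expect_equal(unname(y),
                 tru$mesor[i] * (1 + tru$amplitude[i] *
                                   cos(2 * pi * (t - tru$phase_h[i]) / 24)))
    fit <- harmonic_fit(y, t)
    expect_equal(fit$amplitude, tru$mesor[i] * tru$amplitude[i],
                 tolerance = 1e-8)
    expect_equal(fit$phase_h, tru$phase_h[i], tolerance = 1e-6)
  }
})

test_that("expression generator is bit-identical under a fixed seed and rejects a >= 1", {
  cfg <- sim_expression_config(n_genes = 30, seed = 11)
  expect_identical(simulate_expression(cfg)$matrix,
                   simulate_expression(cfg)$matrix)
  expect_error(sim_expression_config(amplitude_range = c(0.5, 1.2)),
               "amplitude")
  expect_error(sim_expression_config(timepoints_h = c(4, 4, 10)),
               "increasing")
})

test_that("mutant attenuation flattens amplitude but preserves mesor", {
  cfg <- sim_expression_config(n_genes = 40, frac_rhythmic = 1, noise_cv = 0,
                               genotype_effects = c(WT = 1, Clk = 0),
                               seed = 12)
  sim <- simulate_expression(cfg)
  info <- parse_sample_labels(colnames(sim$matrix))
  clk <- sim$matrix[, info$genotype == "Clk", drop = FALSE]
  wt <- sim$matrix[, info$genotype == "WT", drop = FALSE]
  expect_true(all(abs(clk - sim$truth$mesor) < 1e-9))   # flat at mesor
  expect_equal(unname(rowMeans(wt)), unname(rowMeans(clk)), tolerance = 0.05)
})

test_that("null expression (frac_rhythmic = 0) gives uniform harmonic p-values", {
  sim <- simulate_expression(sim_expression_config(n_genes = 500,
                                                   frac_rhythmic = 0,
                                                   seed = 13))
  t <- parse_sample_labels(colnames(sim$matrix))$zt
  p <- apply(sim$matrix, 1, function(y) harmonic_fit(y, t)$p)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("toy genome respects GC, motif planting, and geometry invariants", {
  cfg <- sim_genome_config(n_scaffolds = 1, scaffold_len_bp = 10000,
                           n_genes = 2, n_peaks = 4,
                           peak_len_bp = c(250, 400),
                           n_footprints_per_peak = 1, background_gc = 0.5,
                           seed = 21)
  g <- simulate_genome(cfg)
  gc <- mean(strsplit(g$sequences[[1]], "")[[1]] %in% c("C", "G"))
  expect_true(gc >= 0.45 && gc <= 0.55)   # binomial bound, prob >= 0.99
  fp <- g$truth$footprints
  lens <- fp$end - fp$start
  expect_true(all(lens >= 11 & lens <= 25))
  # every footprint inside exactly one peak, with room for 35 bp flanks
  for (i in seq_len(nrow(fp))) {
    host <- g$peaks[g$peaks$scaffold == fp$scaffold[i] &
                      g$peaks$start <= fp$start[i] - 35 &
                      g$peaks$end >= fp$end[i] + 35, ]
    expect_equal(nrow(host), 1L)
  }
  # planted consensus present at the truth coordinate
  for (i in which(fp$has_motif)) {
    expect_equal(substr(g$sequences[[fp$scaffold[i]]],
                        fp$motif_start[i] + 1,
                        fp$motif_start[i] + nchar(cfg$planted_motif)),
                 cfg$planted_motif)
  }
  expect_equal(nrow(simulate_genome(sim_genome_config(
    n_peaks = 0, n_genes = 2, scaffold_len_bp = 20000, seed = 1))$peaks), 0L)
  expect_error(sim_genome_config(planted_motif = "CACGTGCACGTGCA"),
               "longer than")
})

test_that("cut tracks: full occupancy empties footprints; naked mode is uniform", {
  g <- simulate_genome(sim_genome_config(n_scaffolds = 1,
                                         scaffold_len_bp = 20000,
                                         n_genes = 2, n_peaks = 4, seed = 31))
  tr <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4,
                            occupancy = 1, seed = 32)
  # WT_ZT04 depth factor defaults to 0.9; force full protection
  g$truth$depth_factors["WT_ZT04"] <- 1
  tr <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4,
                            occupancy = 1, seed = 32)
  fp <- g$truth$footprints
  for (i in seq_len(nrow(fp))) {
    idx <- (fp$start[i] + 1):fp$end[i]
    expect_equal(sum(tr$plus[[fp$scaffold[i]]][idx]) +
                   sum(tr$minus[[fp$scaffold[i]]][idx]), 0)
  }
  naked <- simulate_cut_tracks(g$truth, naked = TRUE, depth = 2, seed = 33)
  expect_equal(mean(naked$plus[[1]]), 2, tolerance = 0.05)
  expect_error(simulate_cut_tracks(g$truth, genotype = "Xyz", zt = 4),
               "unknown condition")
  expect_identical(simulate_cut_tracks(g$truth, seed = 5),
                   simulate_cut_tracks(g$truth, seed = 5))
})

test_that("footprint sequence sets plant the motif in the stated fraction", {
  s <- simulate_footprint_sequences(200, motif = "CACGTG", plant_frac = 0.5,
                                    seed = 9)
  planted <- attr(s, "planted")
  expect_equal(sum(planted), 100)
  has <- vapply(s, function(x)
    grepl("CACGTG", x, fixed = TRUE), TRUE)
  expect_true(all(has[planted]))
  d <- simulate_footprint_sequences(50, motif = NULL, seed = 10)
  has_decoy <- vapply(d[attr(d, "planted")], function(x)
    any(vapply(c("CACCTG", "CAGCTG", "CAGGTG"), grepl, TRUE, x = x,
               fixed = TRUE)), TRUE)
  expect_true(all(has_decoy))
})
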