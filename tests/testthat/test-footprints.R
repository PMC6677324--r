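# Strand-imbalance footprint detection, profiles, FOS, group statistics.

# Build a single-peak track with an engineered footprint: the plus strand
# has 40 cuts in the 35-bp upstream flank and 2 inside the footprint; the
# minus strand mirrors this downstream, so both one-sided binomial tests
# equal pbinom(2, 42, 15/50).
engineered_peak <- function() {
  L <- 400L
  plus <- integer(L); minus <- integer(L)
  s <- 200L; l <- 15L; flank <- 35L
  set.seed(71)
  plus[(s - flank + 1L):s] <- as.integer(rmultinom(1, 40, rep(1, flank)))
  plus[s + 1L] <- 1L; plus[s + 8L] <- 1L
  minus[(s + l + 1L):(s + l + flank)] <-
    as.integer(rmultinom(1, 40, rep(1, flank)))
  minus[s + 8L] <- 1L; minus[s + l] <- 1L
  list(track = track_from_vectors(list(s1 = plus), list(s1 = minus)),
       peak = genomic_intervals("s1", 100L, 350L, name = "pk"),
       s = s, l = l)
}

test_that("wellington scan matches the binomial depletion oracle", {
  e <- engineered_peak()
  # restrict to the true size and the exact flank-fitting peak so a single
  # candidate start exists: its p must equal the binomial oracle
  one <- genomic_intervals("s1", e$s - 35L, e$s + e$l + 35L)
  fp1 <- wellington_scan(e$track, one, sizes = 15L, max_p = 1)
  oracle <- pbinom(2, 42, 15 / 50)
  expect_equal(nrow(fp1), 1L)
  expect_equal(fp1$start, e$s)
  expect_equal(fp1$p, oracle, tolerance = 1e-12)
  expect_equal(oracle, sum(dbinom(0:2, 42, 0.3)), tolerance = 1e-12)
  # the full multi-size scan localises a footprint overlapping the truth
  fp <- wellington_scan(e$track, e$peak, max_p = 1)
  best <- fp[which.min(fp$p), ]
  expect_true(best$start < e$s + e$l && best$end > e$s)
})

test_that("wellington p is monotone as interior cuts decrease", {
  e <- engineered_peak()
  p_with <- min(wellington_scan(e$track, e$peak, max_p = 1)$p)
  tr2 <- e$track
  tr2$plus$s1[(e$s + 1L):(e$s + e$l)] <- 0L
  tr2$minus$s1[(e$s + 1L):(e$s + e$l)] <- 0L
  p_without <- min(wellington_scan(tr2, e$peak, max_p = 1)$p)
  expect_lt(p_without, p_with)
})

test_that("wellington is silent on uniform or empty tracks and narrow peaks", {
  set.seed(72)
  unif <- track_from_vectors(list(s1 = rpois(2000, 3)),
                             list(s1 = rpois(2000, 3)))
  peaks <- genomic_intervals("s1", 200L, 1800L)
  cand <- wellington_scan(unif, peaks, max_p = 1)
  expect_equal(nrow(wellington_scan(unif, peaks, max_p = 1e-10)), 0L)
  expect_gt(median(cand$p), 0.1)   # no systematic depletion
  zero <- track_from_vectors(list(s1 = integer(2000)))
  expect_equal(nrow(wellington_scan(zero, peaks, max_p = 1)), 0L)
  narrow <- genomic_intervals("s1", 100L, 150L)  # < 11 + 70
  expect_equal(nrow(wellington_scan(unif, narrow)), 0L)
})

test_that("footprint FDR gate is deterministic and passes planted signal", {
  g <- simulate_genome(sim_genome_config(n_scaffolds = 1,
                                         scaffold_len_bp = 60000,
                                         n_genes = 2, n_peaks = 12,
                                         n_footprints_per_peak = 1,
                                         seed = 73))
  tr <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4, seed = 74)
  f1 <- footprint_fdr(tr, g$peaks, n_shuffles = 3, seed = 7)
  f2 <- footprint_fdr(tr, g$peaks, n_shuffles = 3, seed = 7)
  expect_identical(attr(f1, "empirical_fdr"), attr(f2, "empirical_fdr"))
  expect_gt(nrow(f1), 0L)
  expect_lte(attr(f1, "empirical_fdr"), 0.01)
  empty <- footprint_fdr(track_from_vectors(list(s1 = integer(60000))),
                         g$peaks[g$peaks$scaffold == "scaf1", ][0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "empirical_fdr")))
})

test_that("timepoint specificity partitions both footprint sets", {
  a <- genomic_intervals("s1", c(100L, 300L, 500L), c(120L, 320L, 520L))
  b <- genomic_intervals("s1", c(110L, 700L), c(130L, 720L))
  sp <- timepoint_specific(a, b)
  expect_equal(sp$specific_a$start, c(300L, 500L))
  expect_equal(sp$shared_a$start, 100L)
  expect_equal(sp$specific_b$start, 700L)
  expect_equal(nrow(sp$specific_a) + nrow(sp$shared_a), nrow(a))
  expect_equal(nrow(sp$specific_b) + nrow(sp$shared_b), nrow(b))
  all_spec <- timepoint_specific(a, b[0, ])
  expect_equal(nrow(all_spec$specific_a), nrow(a))
})

test_that("profiles are centered 201-bp windows with bounds handling", {
  v <- integer(1000); v[108] <- 5L   # bp 107 (0-based)
  tr <- track_from_vectors(list(s1 = v))
  fp <- genomic_intervals("s1", c(100L, 950L), c(115L, 965L),
                          name = c("in", "out"))
  pm <- extract_profiles(tr, fp, halfwidth = 100)
  expect_equal(dim(pm), c(1L, 201L))     # center 107: [7, 208); row kept
  expect_equal(attr(pm, "n_dropped"), 1L)
  expect_equal(unname(pm[1, "0"]), 5)
  expect_equal(sum(pm), 5)
  zero <- extract_profiles(track_from_vectors(list(s1 = integer(1000))),
                           fp[1, ])
  expect_equal(sum(zero), 0)
})

test_that("rolling average shrinks at edges and is exact on the oracle", {
  expect_equal(rolling_average(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  expect_equal(rolling_average(rep(2.5, 10), 3), rep(2.5, 10))
  expect_equal(rolling_average(1:7, 1), 1:7)
  expect_error(rolling_average(1:5, 2), "odd")
  expect_error(rolling_average(1:3, 5), "wider")
  # definition oracle on a random vector
  set.seed(75)
  v <- rnorm(30)
  manual <- vapply(seq_along(v), function(i)
    mean(v[max(1, i - 1):min(30, i + 1)]), 0)
  expect_equal(rolling_average(v, 3), manual)
})

test_that("FOS follows (C+1)/L + (C+1)/R with the pseudo-count fallback", {
  # C = 9, L = R = 10: interior 10 bp with 90 cuts, 35-bp flanks with 350
  v <- integer(200)
  v[(100 - 35 + 1):100] <- 10L
  v[101:110] <- 9L
  v[111:(110 + 35)] <- 10L
  tr <- track_from_vectors(list(s1 = v))
  r <- fos(tr, list(scaffold = "s1", start = 100L, end = 110L))
  expect_equal(r$C, 9); expect_equal(r$L, 10); expect_equal(r$R, 10)
  expect_equal(r$fos, 2); expect_equal(r$inv_fos, 0.5)
  expect_false(r$flagged)
  # C = 0, L = R = 5
  v2 <- integer(200)
  v2[(100 - 35 + 1):100] <- 5L; v2[111:(110 + 35)] <- 5L
  r2 <- fos(track_from_vectors(list(s1 = v2)),
            list(scaffold = "s1", start = 100L, end = 110L))
  expect_equal(r2$fos, 0.4); expect_equal(r2$inv_fos, 2.5)
  # zero flank: pseudo-count 1/35 and a flag
  r3 <- fos(track_from_vectors(list(s1 = integer(200))),
            list(scaffold = "s1", start = 100L, end = 110L))
  expect_true(r3$flagged)
  expect_equal(r3$L, 1 / 35)
  expect_error(fos(tr, list(scaffold = "s1", start = 10L, end = 20L)),
               "bounds")
})

test_that("flat chromatin with large counts gives FOS near 2", {
  v <- rep(50L, 300)
  r <- fos(track_from_vectors(list(s1 = v)),
           list(scaffold = "s1", start = 150L, end = 165L))
  expect_equal(r$fos, 2 * 51 / 50)
  expect_gt(r$fos, 2)
})

test_that("Kruskal-Wallis + Dunn letters separate a planted deep group", {
  set.seed(76)
  mk <- function(g, mu) data.frame(
    footprint_id = paste0("f", 1:40), group = g,
    inv_fos = rlnorm(40, log(mu), 0.3), flagged = FALSE)
  rec <- rbind(mk("WT_ZT04", 2.0), mk("WT_ZT16", 0.7), mk("Clk_ZT04", 0.7),
               mk("Clk_ZT16", 0.7), mk("Cyc_ZT04", 0.7), mk("Cyc_ZT16", 0.7))
  st <- compare_fos_groups(rec)
  expect_lt(st$kw$p, 0.001)
  l <- st$letters
  expect_false(any(vapply(strsplit(l["WT_ZT04"], "")[[1]],
                          function(ch) any(grepl(ch, l[names(l) != "WT_ZT04"],
                                                 fixed = TRUE)), TRUE)))
})

test_that("Dunn p-values are near 1 for identical groups and KW is calibrated", {
  set.seed(77)
  x <- rnorm(30)
  rec <- data.frame(footprint_id = rep(paste0("f", 1:30), 2),
                    group = rep(c("g1", "g2"), each = 30),
                    inv_fos = c(x, x), flagged = FALSE)
  st <- compare_fos_groups(rec)
  expect_gte(min(st$dunn$adjP), 0.9)
  expect_equal(length(unique(unlist(st$letters))), 1L)
  # null calibration over repeated draws
  rej <- replicate(200, {
    r <- data.frame(footprint_id = 1:60,
                    group = rep(c("a", "b", "c"), each = 20),
                    inv_fos = rnorm(60), flagged = FALSE)
    compare_fos_groups(r)$kw$p <= 0.05
  })
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})
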