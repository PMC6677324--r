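# Fragment shifting, Poisson window peak calling, consensus merging,
# quantification, NB-Wald differential accessibility, annotation,
# feature enrichment.

test_that("fragments shift +4 (plus) and -5 (minus) and conserve mass", {
  frags <- data.frame(
    scaffold = c("s1", "s1", "s1"),
    start = c(100L, 150L, 998L),
    end = c(150L, 200L, 1003L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  tr <- shift_fragments_to_cuts(frags, c(s1 = 1000L))
  expect_equal(which(tr$plus$s1 == 1) - 1L, 104L)
  expect_equal(which(tr$minus$s1 == 1) - 1L, 195L)
  expect_equal(attr(tr, "n_dropped"), 1L)    # 998 + 4 = 1002 out of bounds
  expect_equal(sum(tr$plus$s1) + sum(tr$minus$s1), 2L)
  empty <- shift_fragments_to_cuts(frags[0, ], c(s1 = 1000L))
  expect_equal(sum(empty$plus$s1) + sum(empty$minus$s1), 0L)
})

test_that("Poisson window caller finds an enriched window and merges neighbours", {
  # flat background of 1 cut/bp plus a 300-cut injection in one window
  set.seed(61)
  v <- rpois(10000, 1)
  v[5001:5200] <- v[5001:5200] + rpois(200, 1.5)
  tr <- track_from_vectors(list(s1 = v))
  pk <- call_peaks(tr, window = 200, step = 50, q_thresh = 0.01)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= 5000 && pk$end >= 5200)
  expect_true(pk$summit >= pk$start && pk$summit < pk$end)
  # window p-value agrees with the Poisson tail oracle
  lam <- mean(v) * 200
  obs <- sum(v[5001:5200])
  expect_equal(stats::ppois(obs - 1, lam, lower.tail = FALSE),
               sum(stats::dpois(obs:(obs + 2000), lam)), tolerance = 1e-10)
})

test_that("track equal to its control yields no peaks", {
  set.seed(62)
  v <- rpois(20000, 2)
  tr <- track_from_vectors(list(s1 = v))
  expect_equal(nrow(call_peaks(tr, control = tr)), 0L)
  zero <- track_from_vectors(list(s1 = integer(1000)))
  expect_equal(nrow(call_peaks(zero)), 0L)
})

test_that("consensus merging coalesces overlaps, idempotently and order-invariantly", {
  a <- genomic_intervals("s1", c(100L, 400L), c(200L, 500L))
  b <- genomic_intervals("s1", 150L, 250L)
  m <- merge_consensus(list(a, b))
  expect_equal(m$start, c(100L, 400L))
  expect_equal(m$end, c(250L, 500L))
  expect_equal(merge_consensus(list(m))[, 1:3], m[, 1:3])
  m2 <- merge_consensus(list(b, a))
  expect_equal(m2[, 1:3], m[, 1:3])
  many <- merge_consensus(rep(list(a), 37))
  expect_equal(many[, c("start", "end")], a[, c("start", "end")],
               ignore_attr = TRUE)
})

test_that("quantification normalises to 10M cuts and correlates replicates", {
  g <- simulate_genome(sim_genome_config(n_scaffolds = 1,
                                         scaffold_len_bp = 50000,
                                         n_genes = 2, n_peaks = 10, seed = 63))
  t1 <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4, seed = 64)
  t2 <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4, seed = 65)
  q <- quantify_and_correlate(g$peaks, list(r1 = t1, r2 = t2, dup = t1))
  expect_equal(unname(colSums(q$counts) > 0), rep(TRUE, 3))
  expect_equal(q$cor["r1", "dup"], 1)
  expect_gte(q$cor["r1", "r2"], 0.7)
  # anti-correlated constructed counts
  up <- track_from_vectors(list(s1 = c(rep(10L, 100), rep(1L, 100))))
  dn <- track_from_vectors(list(s1 = c(rep(1L, 100), rep(10L, 100))))
  pk2 <- genomic_intervals("s1", c(0L, 100L), c(100L, 200L))
  q2 <- quantify_and_correlate(pk2, list(a = up, b = dn))
  expect_lt(q2$cor["a", "b"], 0)
})

test_that("differential accessibility is invariant to depth scaling", {
  set.seed(66)
  base <- matrix(rnbinom(400 * 2, mu = 100, size = 10), ncol = 2)
  counts <- cbind(base, base * 2L)   # group B = exact 2x copy
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  res <- diff_access(counts, c("A", "A", "B", "B"))
  expect_equal(res$log2FC, rep(0, 400), tolerance = 1e-12)
  expect_equal(sum(res$significant), 0L)
})

test_that("differential accessibility recovers planted 4-fold changes", {
  set.seed(67)
  n <- 1200
  mu <- rep(100, n)
  changed <- seq_len(n) <= 0.05 * n
  muB <- ifelse(changed, mu * 4, mu)
  counts <- cbind(
    matrix(rnbinom(n * 2, mu = mu, size = 20), ncol = 2),
    matrix(rnbinom(n * 2, mu = muB, size = 20), ncol = 2))
  res <- diff_access(counts, c("A", "A", "B", "B"))
  recall <- mean(res$significant[changed])
  efdr <- sum(res$significant & !changed) / max(1, sum(res$significant))
  expect_gte(recall, 0.8)
  expect_lte(efdr, 0.1)
  # an all-zero peak gives an NA row
  counts[1, ] <- 0L
  res0 <- diff_access(counts, c("A", "A", "B", "B"))
  expect_true(is.na(res0$log2FC[1]))
})

test_that("peak annotation follows strand-aware windows with precedence", {
  f <- withr::local_tempfile()
  write_gtf_lines(f,
    genes = data.frame(
      gene_id = c("gPlus", "gMinus"), scaffold = c("s1", "s1"),
      start1 = c(5001L, 20001L), end1 = c(9000L, 24000L),
      strand = c("+", "-")),
    exons = data.frame(
      gene_id = c("gPlus", "gPlus", "gMinus"), scaffold = "s1",
      start1 = c(5001L, 8001L, 20001L), end1 = c(5600L, 9000L, 24000L),
      strand = c("+", "+", "-")))
  gm <- read_gene_models(f)
  peaks <- genomic_intervals(
    "s1",
    start = c(4400L, 6500L, 7500L, 24500L, 15000L, 40000L),
    end   = c(4600L, 6700L, 7700L, 24700L, 15200L, 40200L),
    name = c("upstream500", "inGeneIntron", "inGeneIntron2",
             "minusPromoter", "intergenicNear", "intergenicFar"))
  ann <- annotate_peaks(peaks, gm)
  # midpoint 4500 is 500 bp upstream of the + TSS (5000): promoter
  expect_equal(ann$category[1], "promoter-TSS")
  expect_equal(ann$gene_id[1], "gPlus")
  expect_equal(ann$category[2], "intron")
  # midpoint 24600: 600 bp upstream of the - strand TSS at 23999
  expect_equal(ann$category[4], "promoter-TSS")
  expect_equal(ann$gene_id[4], "gMinus")
  expect_equal(ann$category[5], "intergenic")
  expect_equal(ann$gene_id[5], "gMinus")  # nearest TSS within 10 kb
  expect_true(is.na(ann$gene_id[6]))
  # precedence: midpoint in an exon of gPlus but within the promoter
  # window of a nearby gene wins promoter-TSS; verified by category sweep
  p2 <- genomic_intervals("s1", 8390L, 8410L)   # in exon2 of gPlus
  f2 <- withr::local_tempfile()
  write_gtf_lines(f2,
    genes = data.frame(gene_id = c("gPlus", "gNear"), scaffold = "s1",
                       start1 = c(5001L, 8501L), end1 = c(9000L, 12000L),
                       strand = c("+", "+")),
    exons = data.frame(gene_id = c("gPlus", "gNear"), scaffold = "s1",
                       start1 = c(8001L, 8501L), end1 = c(9000L, 9000L),
                       strand = "+"))
  ann2 <- annotate_peaks(p2, read_gene_models(f2))
  expect_equal(ann2$category, "promoter-TSS")
  expect_equal(ann2$gene_id, "gNear")
  # annotation is a partition
  expect_equal(nrow(ann), nrow(peaks))
  expect_true(all(ann$category %in%
                    c("promoter-TSS", "TTS", "exon", "intron", "intergenic")))
})

test_that("feature enrichment follows the length-normalised formula", {
  fe <- feature_enrichment(c(promoter = 5, rest = 5),
                           c(promoter = 100, rest = 900))
  expect_equal(fe$log2_enrichment[1], log2((5 / 10) / (100 / 1000)))
  expect_equal(round(fe$log2_enrichment[1], 4), 2.3219)
  one <- feature_enrichment(c(all = 7), c(all = 5000))
  expect_equal(one$log2_enrichment, 0)
  z <- feature_enrichment(c(a = 0, b = 10), c(a = 100, b = 100))
  expect_true(is.na(z$log2_enrichment[1]))
})

test_that("uniform random peaks show no feature enrichment", {
  lens <- c(promoter = 2e5, tts = 2e5, exon = 6e5, intron = 4e5,
            intergenic = 6e5)
  set.seed(68)
  cat_draw <- sample(names(lens), 10000, replace = TRUE,
                     prob = lens / sum(lens))
  fe <- feature_enrichment(table(cat_draw)[names(lens)], lens)
  expect_true(all(abs(fe$log2_enrichment) <= 0.2))
})
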