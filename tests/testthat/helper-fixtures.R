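# Shared fixture builders: everything is generated in code at test time.

# A cut track built from explicit per-scaffold vectors.
track_from_vectors <- function(plus, minus = NULL) {
  if (is.null(minus)) minus <- lapply(plus, function(v) integer(length(v)))
  lens <- vapply(plus, length, 1L)
  tr <- cut_track(lens)
  tr$plus <- lapply(plus, as.integer)
  tr$minus <- lapply(minus, as.integer)
  tr
}

# The wild-type diurnal sampling design: ZT1..ZT22 every 3 h, 2 replicates.
wt_timepoints <- function() rep(seq(1, 22, by = 3), each = 2)

# A deterministic cosinor series on the wild-type grid.
cosinor_series <- function(mesor = 5, amp = 2, phase = 7, period = 24,
                           t = wt_timepoints()) {
  mesor + amp * cos(2 * pi * (t - phase) / period)
}

# Write a small GTF-lite file; genes is a data.frame with gene_id,
# scaffold, start1, end1 (1-based inclusive), strand; exons likewise.
write_gtf_lines <- function(path, genes, exons = NULL) {
  fmt <- function(df, feat)
    sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            df$scaffold, feat, df$start1, df$end1, df$strand, df$gene_id)
  lines <- fmt(genes, "gene")
  if (!is.null(exons)) lines <- c(lines, fmt(exons, "exon"))
  writeLines(lines, path)
  path
}

# Random DNA of a given length/GC.
random_dna <- function(n, len, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""), "")
}

# Brute-force BH step-up definition, the independent oracle for bh_adjust.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  # running minimum from the largest p downwards
  for (i in n:1)
    adj[i] <- min(sorted[i:n], 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
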