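# ATAC-seq peak arm: fragment -> cut-site conversion, Poisson
# sliding-window peak calling against a naked-DNA control, consensus
# merging, quantification, NB-Wald differential accessibility, annotation
# to genomic features, and length-normalised feature enrichment.

#' Convert mapped fragments to shifted Tn5 cut sites
#'
#' Each plus-strand fragment contributes one cut at `start + 4`; each
#' minus-strand fragment one cut at `end - 5` (0-based half-open
#' coordinates), the standard Tn5 dyad correction. Cuts shifted outside
#' their scaffold are dropped and counted.
#'
#' @param fragments data.frame with `scaffold`, `start`, `end`, `strand`.
#' @param scaffold_lengths named integer vector.
#' @return `cut_track`; attribute `n_dropped` counts out-of-bounds cuts.
#' @export
shift_fragments_to_cuts <- function(fragments, scaffold_lengths) {
  tr <- cut_track(scaffold_lengths)
  if (nrow(fragments) == 0L) {
    attr(tr, "n_dropped") <- 0L
    return(tr)
  }
  if (any(!fragments$strand %in% c("+", "-")))
    stop("fragment strand must be '+' or '-'")
  pos <- ifelse(fragments$strand == "+", fragments$start + 4L,
                fragments$end - 5L)
  lens <- scaffold_lengths[fragments$scaffold]
  ok <- !is.na(lens) & pos >= 0L & pos < lens
  dropped <- sum(!ok)
  f <- fragments[ok, , drop = FALSE]; pos <- pos[ok]
  for (scf in unique(f$scaffold)) {
    i <- f$scaffold == scf
    for (strand in c("+", "-")) {
      j <- i & f$strand == strand
      if (!any(j)) next
      tb <- tabulate(pos[j] + 1L, nbins = scaffold_lengths[[scf]])
      slot <- if (strand == "+") "plus" else "minus"
      tr[[slot]][[scf]] <- tr[[slot]][[scf]] + tb
    }
  }
  attr(tr, "n_dropped") <- dropped
  tr
}

# Internal: combined-strand counts for one scaffold.
combined_counts <- function(track, scf) track$plus[[scf]] + track$minus[[scf]]

# Internal: sliding-window sums via cumsum; windows start at 0, step apart.
window_sums <- function(v, window, step) {
  n <- length(v)
  if (n < window) return(list(start = integer(0), sum = numeric(0)))
  cs <- c(0, cumsum(v))
  starts <- seq(0L, n - window, by = step)
  list(start = starts, sum = cs[starts + window + 1L] - cs[starts + 1L])
}

#' Call accessibility peaks by Poisson sliding windows
#'
#' For each `window`-bp window (stepped by `step`), the combined-strand
#' cut count is tested against a Poisson null with rate
#' `lambda = max(genome-wide rate, depth-scaled control rate in the same
#' window) * window`. Window p-values are BH-adjusted genome-wide;
#' windows with q <= `q_thresh` that overlap or touch are merged into
#' peaks. The peak summit is the bp of maximal combined count and the
#' score is `-log10` of the best window q in the peak.
#'
#' @param track treatment `cut_track`.
#' @param control optional naked-DNA `cut_track` on the same scaffolds.
#' @param window,step window size and step (bp).
#' @param q_thresh BH q-value threshold.
#' @return interval data.frame of peaks with `name`, `score`
#'   (`-log10 q`) plus columns `summit` and `count`.
#' @export
call_peaks <- function(track, control = NULL, window = 200L, step = 50L,
                       q_thresh = 0.01) {
  scfs <- names(track$lengths)
  tot <- sum(vapply(scfs, function(s) sum(combined_counts(track, s)), 0))
  if (tot == 0) {
    out <- genomic_intervals(character(0), integer(0), integer(0))
    out$summit <- integer(0); out$count <- numeric(0)
    return(out)
  }
  gw_rate <- tot / sum(track$lengths)
  ctl_scale <- if (!is.null(control)) {
    ctot <- sum(vapply(scfs, function(s) sum(combined_counts(control, s)), 0))
    if (ctot == 0) NULL else tot / ctot
  } else NULL
  ws <- lapply(scfs, function(s) {
    v <- combined_counts(track, s)
    w <- window_sums(v, window, step)
    lam <- rep(gw_rate * window, length(w$start))
    if (!is.null(ctl_scale)) {
      cw <- window_sums(combined_counts(control, s), window, step)
      lam <- pmax(lam, cw$sum * ctl_scale)
    }
    data.frame(scaffold = s, start = w$start, count = w$sum, lambda = lam,
               stringsAsFactors = FALSE)
  })
  ws <- do.call(rbind, ws)
  ws$p <- stats::ppois(ws$count - 1, ws$lambda, lower.tail = FALSE)
  ws$q <- bh_adjust(ws$p)
  sig <- ws[ws$q <= q_thresh, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- genomic_intervals(character(0), integer(0), integer(0))
    out$summit <- integer(0); out$count <- numeric(0)
    return(out)
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sig$scaffold, IRanges::IRanges(sig$start + 1L, sig$start + window)),
    min.gapwidth = 1L)
  peaks <- from_granges(gr)
  peaks$name <- sprintf("peak%04d", seq_len(nrow(peaks)))
  peaks$summit <- NA_integer_; peaks$count <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    v <- combined_counts(track, peaks$scaffold[i])
    span <- (peaks$start[i] + 1L):peaks$end[i]
    peaks$summit[i] <- peaks$start[i] + which.max(v[span]) - 1L
    peaks$count[i] <- sum(v[span])
    inpk <- sig$scaffold == peaks$scaffold[i] &
      sig$start < peaks$end[i] & sig$start + window > peaks$start[i]
    peaks$score[i] <- -log10(max(min(sig$q[inpk]), 1e-300))
  }
  peaks
}

#' Merge peak sets into consensus peaks
#'
#' Union of all intervals with overlapping (>= 1 bp) intervals coalesced
#' into their envelope. Idempotent and order-invariant.
#'
#' @param peak_sets list of interval data.frames.
#' @return interval data.frame of consensus peaks.
#' @export
merge_consensus <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 1L)
  all <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("scaffold", "start", "end")]))
  if (nrow(all) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all$scaffold, IRanges::IRanges(all$start + 1L, all$end)),
    min.gapwidth = 1L)
  gr <- GenomicRanges::sort(gr)
  out <- from_granges(gr)
  out$name <- sprintf("consensus%04d", seq_len(nrow(out)))
  out
}

#' Quantify peaks across samples and correlate replicates
#'
#' Per-peak combined-strand cut totals per sample, normalised to 10
#' million total cuts per sample; pairwise Pearson correlation on
#' `log2(x + 1)` of the normalised counts.
#'
#' @param peaks interval data.frame (non-empty).
#' @param tracks named list of `cut_track`s.
#' @return list `counts` (peaks x samples raw counts), `normalized`
#'   (scaled to 1e7 total cuts), `cor` (Pearson matrix).
#' @export
quantify_and_correlate <- function(peaks, tracks) {
  stopifnot(nrow(peaks) > 0L, length(tracks) >= 1L)
  counts <- sapply(tracks, function(tr) {
    vapply(seq_len(nrow(peaks)), function(i) {
      v <- combined_counts(tr, peaks$scaffold[i])
      sum(v[(peaks$start[i] + 1L):peaks$end[i]])
    }, 0)
  })
  counts <- matrix(counts, nrow = nrow(peaks),
                   dimnames = list(peaks$name, names(tracks)))
  totals <- vapply(tracks, function(tr)
    sum(vapply(names(tr$lengths), function(s)
      sum(combined_counts(tr, s)), 0)), 0)
  if (any(totals == 0)) stop("sample with zero total cuts")
  norm <- sweep(counts, 2L, 1e7 / totals, "*")
  list(counts = counts, normalized = norm,
       cor = stats::cor(log2(norm + 1), method = "pearson"))
}

#' Differential accessibility by a negative-binomial Wald test
#'
#' Median-of-ratios size factors, per-peak log2 fold change of normalised
#' group means, a method-of-moments common dispersion, and a Wald z-test
#' with BH adjustment. A peak is significant when `adjP < fdr` and
#' `|log2FC| > lfc_thresh`.
#'
#' @param counts peaks x samples integer matrix.
#' @param groups factor/character of length `ncol(counts)` with two levels.
#' @param lfc_thresh absolute log2 fold-change cutoff (default
#'   `0.3785 = log2(1.3)` to 4 decimals).
#' @param fdr BH FDR cutoff.
#' @return data.frame `peak`, `baseMean`, `log2FC`, `p`, `adjP`,
#'   `significant`; all-zero peaks give NA rows.
#' @export
diff_access <- function(counts, groups, lfc_thresh = 0.3785, fdr = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  # median-of-ratios size factors
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no peak with all-positive counts for size factors")
  sf <- apply(counts, 2L, function(cnt)
    exp(stats::median(log(cnt[use]) - logg[use])))
  norm <- sweep(counts, 2L, sf, "/")
  a <- levels(groups)[1L]; b <- levels(groups)[2L]
  mA <- rowMeans(norm[, groups == a, drop = FALSE])
  mB <- rowMeans(norm[, groups == b, drop = FALSE])
  nA <- sum(groups == a); nB <- sum(groups == b)
  # method-of-moments common dispersion from within-group variability
  vA <- apply(norm[, groups == a, drop = FALSE], 1L, stats::var)
  vB <- apply(norm[, groups == b, drop = FALSE], 1L, stats::var)
  mu <- (mA * nA + mB * nB) / (nA + nB)
  v <- (vA * (nA - 1L) + vB * (nB - 1L)) / (nA + nB - 2L)
  ok <- mu > 0
  # per-peak moment estimates are chi-square-noisy at few replicates and
  # their median is biased low; a trimmed mean is nearly unbiased while
  # still shrugging off strongly differential peaks
  disp_i <- (v[ok] - mu[ok]) / mu[ok]^2
  alpha <- max(0, mean(disp_i, trim = 0.05, na.rm = TRUE))
  zero <- mA == 0 & mB == 0
  lfc <- log2(mB / mA)
  se <- sqrt((1 / log(2))^2 * ((mA + alpha * mA^2) / (nA * pmax(mA, 1e-8)^2) +
                                 (mB + alpha * mB^2) / (nB * pmax(mB, 1e-8)^2)))
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[zero | !is.finite(z)] <- NA
  lfc[zero] <- NA
  res <- data.frame(
    peak = if (!is.null(rownames(counts))) rownames(counts)
           else sprintf("peak%04d", seq_len(nrow(counts))),
    baseMean = mu, log2FC = lfc, p = p, adjP = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  res$significant <- !is.na(res$adjP) & res$adjP < fdr &
    !is.na(res$log2FC) & abs(res$log2FC) > lfc_thresh
  res
}

#' Annotate peaks to genomic feature categories
#'
#' Each peak is assigned exactly one category by the precedence
#' promoter-TSS > TTS > exon > intron > intergenic, decided by containment
#' of the peak midpoint in strand-aware windows: promoter-TSS = -1 kb to
#' +100 bp around the TSS (in gene orientation), TTS = -100 bp to +1 kb
#' around the TTS, exon = within any exon, intron = within a gene body but
#' no exon. Intergenic peaks are assigned to the nearest TSS within
#' `max_tss_dist` bp, else left unassigned.
#'
#' @param peaks interval data.frame.
#' @param gene_models a `gene_models` object.
#' @param max_tss_dist nearest-TSS cap for intergenic assignment (bp).
#' @return data.frame `peak`, `category`, `gene_id` (NA when unassigned).
#' @export
annotate_peaks <- function(peaks, gene_models, max_tss_dist = 10000L) {
  g <- gene_models$genes; e <- gene_models$exons
  n <- nrow(peaks)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  # oriented offset of position p from an anchor on a stranded gene
  for (i in seq_len(n)) {
    gs <- g[g$scaffold == peaks$scaffold[i], , drop = FALSE]
    if (nrow(gs) == 0L) next
    d_tss <- ifelse(gs$strand == "+", mid[i] - gs$tss, gs$tss - mid[i])
    d_tts <- ifelse(gs$strand == "+", mid[i] - gs$tts, gs$tts - mid[i])
    prom <- d_tss >= -1000L & d_tss <= 100L
    tts <- d_tts >= -100L & d_tts <= 1000L
    es <- e[e$scaffold == peaks$scaffold[i] & e$start <= mid[i] &
              e$end > mid[i], , drop = FALSE]
    inex <- nrow(es) > 0L
    ingene <- gs$start <= mid[i] & gs$end > mid[i]
    if (any(prom)) {
      category[i] <- "promoter-TSS"
      j <- which(prom)[order(abs(d_tss[prom]))][1L]
      gene_id[i] <- gs$gene_id[j]
    } else if (any(tts)) {
      category[i] <- "TTS"
      j <- which(tts)[order(abs(d_tts[tts]))][1L]
      gene_id[i] <- gs$gene_id[j]
    } else if (inex) {
      category[i] <- "exon"
      gene_id[i] <- es$gene_id[1L]
    } else if (any(ingene)) {
      category[i] <- "intron"
      gene_id[i] <- gs$gene_id[which(ingene)[1L]]
    } else {
      dist <- abs(gs$tss - mid[i])
      if (min(dist) <= max_tss_dist) gene_id[i] <- gs$gene_id[which.min(dist)]
    }
  }
  data.frame(peak = peaks$name, category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Length-normalised genomic feature enrichment
#'
#' `log2[(n_cat / n_total) / (len_cat / len_total)]`: the share of peaks
#' in a category relative to the genomic share of that category.
#'
#' @param category_counts named integer vector of peak counts.
#' @param category_lengths named numeric vector of category lengths (bp),
#'   same names.
#' @return data.frame `category`, `n_peaks`, `category_len_bp`,
#'   `log2_enrichment` (`NA` when `n_peaks` = 0).
#' @export
feature_enrichment <- function(category_counts, category_lengths) {
  stopifnot(sum(category_counts) > 0, all(category_lengths > 0))
  cats <- names(category_counts)
  if (is.null(cats) || !setequal(cats, names(category_lengths)))
    stop("counts and lengths must share category names")
  lens <- category_lengths[cats]
  ratio <- (category_counts / sum(category_counts)) / (lens / sum(lens))
  l2 <- ifelse(category_counts > 0, log2(ratio), NA_real_)
  data.frame(category = cats, n_peaks = as.integer(category_counts),
             category_len_bp = as.numeric(lens),
             log2_enrichment = as.numeric(l2),
             stringsAsFactors = FALSE, row.names = NULL)
}
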