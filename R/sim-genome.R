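#' Configuration for the toy-genome generator
#'
#' Generates scaffold sequences of i.i.d. nucleotides at a target GC
#' content, non-overlapping gene models, non-overlapping accessible peak
#' regions, and footprints planted inside peaks. Footprint lengths are
#' restricted to 11-25 bp, the size class resolved by strand-imbalance
#' footprinting, and each footprint keeps at least a 35-bp flank plus
#' margin inside its peak so the flanking windows stay within the peak.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_len_bp length of every scaffold.
#' @param n_genes genes to place (across scaffolds).
#' @param n_peaks accessible peaks to place.
#' @param peak_len_bp length-2 range of peak lengths.
#' @param n_footprints_per_peak average footprints per peak; total planted
#'   footprints = `round(n_peaks * n_footprints_per_peak)`.
#' @param footprint_len_bp length-2 range within \[11, 25\].
#' @param planted_motif consensus sequence written into motif-bearing
#'   footprints (must fit inside the shortest footprint).
#' @param motif_frac fraction of footprints that carry the planted motif.
#' @param background_gc background GC fraction.
#' @param depth_factors named numeric map `<genotype>_ZT<hh>` -> footprint
#'   depth factor in \[0,1\] (1 = fully protected when occupancy = 1). The
#'   default mimics a clock-driven footprint that is deep in wild-type
#'   at ZT04 and shallow at ZT16 and in clock-compromised mutants.
#' @param seed integer seed.
#' @return a `sim_genome_config` list.
#' @export
sim_genome_config <- function(n_scaffolds = 2,
                              scaffold_len_bp = 200000,
                              n_genes = 20,
                              n_peaks = 40,
                              peak_len_bp = c(300, 500),
                              n_footprints_per_peak = 1.25,
                              footprint_len_bp = c(11, 25),
                              planted_motif = "CACGTG",
                              motif_frac = 0.5,
                              background_gc = 0.4,
                              depth_factors = c(WT_ZT04 = 0.9, WT_ZT16 = 0.3,
                                                Clk_ZT04 = 0.3, Clk_ZT16 = 0.3,
                                                Cyc_ZT04 = 0.3, Cyc_ZT16 = 0.3),
                              seed = 1L) {
  stopifnot(n_scaffolds >= 1, scaffold_len_bp >= 1000,
            background_gc > 0, background_gc < 1)
  if (footprint_len_bp[1] < 11 || footprint_len_bp[2] > 25)
    stop("footprint lengths must lie within [11, 25]")
  if (nchar(planted_motif) > footprint_len_bp[1])
    stop("planted motif is longer than the shortest footprint")
  if (any(depth_factors < 0 | depth_factors > 1))
    stop("depth factors must lie in [0,1]")
  structure(list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_len_bp = as.integer(scaffold_len_bp),
    n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
    peak_len_bp = as.integer(peak_len_bp),
    n_footprints_per_peak = n_footprints_per_peak,
    footprint_len_bp = as.integer(footprint_len_bp),
    planted_motif = toupper(planted_motif), motif_frac = motif_frac,
    background_gc = background_gc, depth_factors = depth_factors,
    seed = as.integer(seed)
  ), class = "sim_genome_config")
}

# Place n non-overlapping intervals of the given lengths on scaffolds,
# round-robin, with a gap between neighbours. Deterministic given the RNG
# state.
place_intervals <- function(n, lens, scaffolds, scaffold_len, min_gap = 100) {
  per <- split(seq_len(n), rep_len(seq_along(scaffolds), n))
  out <- vector("list", length(per))
  for (k in seq_along(per)) {
    idx <- per[[k]]
    need <- sum(lens[idx]) + (length(idx) + 1L) * min_gap
    if (need > scaffold_len)
      stop("scaffold too short to place requested intervals")
    slack <- scaffold_len - sum(lens[idx]) - (length(idx) + 1L) * min_gap
    gaps <- stats::rmultinom(1, slack, rep(1, length(idx) + 1L))[, 1L]
    starts <- integer(length(idx)); pos <- 0L
    for (i in seq_along(idx)) {
      pos <- pos + min_gap + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[idx[i]]
    }
    out[[k]] <- data.frame(scaffold = scaffolds[k], start = starts,
                           end = starts + lens[idx],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a toy genome with planted peaks, footprints, and motifs
#'
#' @param cfg a [sim_genome_config()].
#' @return list with `sequences` (named character vector of scaffold
#'   sequences), `gene_models` (a `gene_models` object), `peaks`
#'   (interval data.frame), and `truth`: list with `footprints` (interval
#'   data.frame with `name`, `peak`, `has_motif`, `motif_start` columns),
#'   `depth_factors`, `scaffold_lengths`, `background_gc`, and
#'   `planted_motif`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_genome_config"))
  set.seed(cfg$seed)
  scaffolds <- sprintf("scaf%d", seq_len(cfg$n_scaffolds))
  L <- cfg$scaffold_len_bp
  gc <- cfg$background_gc
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(scaffolds, function(s)
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = ""), "")

  # gene models: two-exon genes, random strand; lengths and spacing scale
  # down on small scaffolds so placement always succeeds
  per_scaf <- ceiling(cfg$n_genes / cfg$n_scaffolds)
  cap <- max(500L, as.integer(0.4 * L / per_scaf))
  gene_gap <- min(2000L, max(100L, as.integer(0.2 * L / per_scaf)))
  lo <- min(2000L, cap); hi <- max(lo, min(5000L, cap))
  gene_len <- sample(lo:hi, cfg$n_genes, replace = TRUE)
  gpos <- place_intervals(cfg$n_genes, gene_len, scaffolds, L,
                          min_gap = gene_gap)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
    scaffold = gpos$scaffold, start = gpos$start, end = gpos$end,
    strand = strand, stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(strand == "+", genes$end - 1L, genes$start)
  glen <- genes$end - genes$start
  e1_end <- genes$start + pmax(200L, as.integer(glen * 0.3))
  e2_start <- genes$end - pmax(200L, as.integer(glen * 0.3))
  exons <- rbind(
    data.frame(gene_id = genes$gene_id, scaffold = genes$scaffold,
               start = genes$start, end = e1_end, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, scaffold = genes$scaffold,
               start = e2_start, end = genes$end, stringsAsFactors = FALSE)
  )
  gm <- structure(list(genes = genes, exons = exons), class = "gene_models")

  # peaks, then footprints inside peaks with >= 45 bp interior margin
  if (cfg$n_peaks > 0) {
    plen <- sample(cfg$peak_len_bp[1]:cfg$peak_len_bp[2], cfg$n_peaks,
                   replace = TRUE)
    ppos <- place_intervals(cfg$n_peaks, plen, scaffolds, L, min_gap = 1000)
    peaks <- genomic_intervals(ppos$scaffold, ppos$start, ppos$end,
                               name = sprintf("peak%03d", seq_len(cfg$n_peaks)))
  } else {
    peaks <- genomic_intervals(character(0), integer(0), integer(0))
  }

  n_fp <- round(cfg$n_peaks * cfg$n_footprints_per_peak)
  fp <- NULL
  if (n_fp > 0) {
    host <- rep_len(seq_len(cfg$n_peaks), n_fp)
    margin <- 45L  # 35 bp flank + 10 bp flank-boost stays inside the peak
    rows <- lapply(seq_len(n_fp), function(i) {
      pk <- peaks[host[i], ]
      flen <- sample(cfg$footprint_len_bp[1]:cfg$footprint_len_bp[2], 1L)
      nth <- sum(host[seq_len(i)] == host[i])   # 1st or 2nd fp in this peak
      ntot <- sum(host == host[i])
      span <- (pk$end - margin - flen) - (pk$start + margin)
      lo <- pk$start + margin + as.integer(span * (nth - 1) / ntot)
      hi <- pk$start + margin + as.integer(span * nth / ntot) - 60L
      s <- if (hi > lo) sample(lo:hi, 1L) else lo
      data.frame(scaffold = pk$scaffold, start = s, end = s + flen,
                 peak = pk$name, stringsAsFactors = FALSE)
    })
    fp <- do.call(rbind, rows)
    fp$name <- sprintf("fp%03d", seq_len(n_fp))
    fp$has_motif <- seq_len(n_fp) %in%
      sample(n_fp, round(n_fp * cfg$motif_frac))
    fp$motif_start <- NA_integer_
    motif <- cfg$planted_motif
    for (i in which(fp$has_motif)) {
      off <- (fp$end[i] - fp$start[i] - nchar(motif)) %/% 2L
      ms <- fp$start[i] + off
      substr(seqs[[fp$scaffold[i]]], ms + 1L, ms + nchar(motif)) <- motif
      fp$motif_start[i] <- ms
    }
  } else {
    fp <- data.frame(scaffold = character(0), start = integer(0),
                     end = integer(0), peak = character(0),
                     name = character(0), has_motif = logical(0),
                     motif_start = integer(0), stringsAsFactors = FALSE)
  }

  truth <- list(
    footprints = fp,
    peaks = peaks,
    depth_factors = cfg$depth_factors,
    scaffold_lengths = stats::setNames(rep(L, cfg$n_scaffolds), scaffolds),
    background_gc = cfg$background_gc,
    planted_motif = cfg$planted_motif
  )
  list(sequences = seqs, gene_models = gm, peaks = peaks, truth = truth)
}

#' Simulate stranded Tn5 cut tracks over a toy genome
#'
#' Cut counts are Poisson per bp and strand. Inside peaks the rate is
#' `depth`; the 10 bp immediately flanking each footprint get a +50\%
#' flank boost (elevated Tn5 integration next to a bound factor); inside a
#' footprint the rate is multiplied by
#' `1 - occupancy * depth_factor(genotype, ZT)`; outside peaks a low
#' uniform background applies. `naked = TRUE` emits a uniform rate
#' everywhere (deproteinized-DNA control).
#'
#' @param truth the `truth` element of [simulate_genome()].
#' @param genotype,zt,replicate condition labels; `<genotype>_ZT<hh>` must
#'   be a key of `truth$depth_factors` (unless `naked`).
#' @param depth mean cuts/bp/strand inside peaks.
#' @param occupancy fraction of cells with the factor bound, in \[0,1\].
#' @param background_frac outside-peak rate as a fraction of `depth`.
#' @param flank_boost_bp,flank_boost_rate flank window and rate multiplier.
#' @param naked if `TRUE`, uniform rate `depth` everywhere.
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson counts.
#' @param seed integer seed.
#' @return a `cut_track`.
#' @export
simulate_cut_tracks <- function(truth, genotype = "WT", zt = 4, replicate = 1,
                                depth = 5, occupancy = 0.9,
                                background_frac = 0.1,
                                flank_boost_bp = 10, flank_boost_rate = 1.5,
                                naked = FALSE, dispersion = NULL, seed = 1L) {
  stopifnot(depth > 0)
  key <- sprintf("%s_ZT%02d", genotype, as.integer(zt))
  if (!naked) {
    if (!key %in% names(truth$depth_factors))
      stop("unknown condition label: ", key)
    dfac <- truth$depth_factors[[key]]
  }
  set.seed(seed)
  tr <- cut_track(truth$scaffold_lengths)
  for (scf in names(truth$scaffold_lengths)) {
    L <- truth$scaffold_lengths[[scf]]
    rate <- rep(if (naked) depth else depth * background_frac, L)
    if (!naked) {
      pk <- truth$peaks[truth$peaks$scaffold == scf, , drop = FALSE]
      for (i in seq_len(nrow(pk)))
        rate[(pk$start[i] + 1L):pk$end[i]] <- depth
      fp <- truth$footprints[truth$footprints$scaffold == scf, , drop = FALSE]
      for (i in seq_len(nrow(fp))) {
        s <- fp$start[i]; e <- fp$end[i]
        lb <- max(0L, s - flank_boost_bp); rb <- min(L, e + flank_boost_bp)
        if (s > lb) rate[(lb + 1L):s] <- rate[(lb + 1L):s] * flank_boost_rate
        if (rb > e) rate[(e + 1L):rb] <- rate[(e + 1L):rb] * flank_boost_rate
        rate[(s + 1L):e] <- rate[(s + 1L):e] * (1 - occupancy * dfac)
      }
    }
    draw <- function() {
      if (is.null(dispersion)) stats::rpois(L, rate)
      else stats::rnbinom(L, size = dispersion, mu = rate)
    }
    tr$plus[[scf]] <- draw()
    tr$minus[[scf]] <- draw()
  }
  tr
}

#' Simulate footprint sequence sets for motif-enrichment analysis
#'
#' Generates random footprint-length sequences at a given GC content and
#' plants a motif block into a fraction of them at a random offset. Real
#' footprints are occupied binding sites, so sequences representing the
#' genome-wide footprint compendium should carry a bound-motif block too;
#' passing `motif = NULL` plants decoy blocks with the same GC content and
#' the same border dinucleotides as the default target motif, so that both
#' the block-fragmentation and the flank-junction structure of bound sites
#' cancel between target and genome-wide sets in the doubly-normalised
#' fold change.
#'
#' @param n number of sequences.
#' @param len_range footprint length range (bp), within \[11, 25\].
#' @param gc background GC fraction.
#' @param motif consensus to plant, or `NULL` for decoy blocks.
#' @param plant_frac fraction of sequences receiving a block.
#' @param decoys decoy consensi used when `motif` is `NULL`.
#' @param seed integer seed.
#' @return character vector of sequences; attribute `planted` flags the
#'   sequences that received a block.
#' @export
simulate_footprint_sequences <- function(n, len_range = c(15, 25), gc = 0.4,
                                         motif = "CACGTG", plant_frac = 0.5,
                                         decoys = c("CACCTG", "CAGCTG",
                                                    "CAGGTG"),
                                         seed = 1L) {
  set.seed(seed)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(names(base_p), l, replace = TRUE, prob = base_p),
          collapse = ""), "")
  planted <- seq_len(n) %in% sample(n, round(n * plant_frac))
  for (i in which(planted)) {
    m <- if (is.null(motif)) decoys[sample.int(length(decoys), 1L)] else motif
    if (nchar(m) > lens[i]) next
    off <- sample.int(lens[i] - nchar(m) + 1L, 1L)
    substr(seqs[i], off, off + nchar(m) - 1L) <- m
  }
  attr(seqs, "planted") <- planted
  seqs
}

#' Write toy-genome FASTA
#' @param sequences named character vector of scaffold sequences.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
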