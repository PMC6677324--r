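# Motif scanning in footprint sequences, GC/length-matched background
# selection, the doubly-normalised fold-change enrichment, and TF-class
# summaries.

#' Read position weight matrices from the bundled text format
#'
#' Format: header line `>motif_id class`, then four whitespace-separated
#' rows of per-position probabilities in A, C, G, T order. Columns must
#' sum to 1.
#'
#' @param path file path; default the PWM library bundled with the
#'   package (exemplar motifs across the bHLH, forkhead, HTH, MADS, bZIP,
#'   homeodomain, nuclear-receptor and zinc-finger classes).
#' @return named list of `pwm` objects: list `motif_id`, `class`,
#'   `matrix` (4 x L, rownames ACGT).
#' @export
read_pwms <- function(path = system.file("extdata", "motifs.txt",
                                         package = "circatac")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no PWM records found")
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1L]]
    if (length(hdr) < 2L) stop("PWM header needs '>motif_id class'")
    rows <- lines[(i + 1L):(i + 4L)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    rownames(m) <- c("A", "C", "G", "T")
    if (ncol(m) < 4L) stop("PWM must have length >= 4: ", hdr[1L])
    if (any(abs(colSums(m) - 1) > 1e-9))
      stop("PWM columns must sum to 1: ", hdr[1L])
    out[[hdr[1L]]] <- structure(
      list(motif_id = hdr[1L], class = hdr[2L], matrix = m), class = "pwm")
  }
  out
}

# log-odds score matrix vs uniform background, with a pseudocount; a 5th
# row scores N (and any other ambiguity) as the worst base per column.
pwm_score_matrix <- function(pwm, pseudo = 1e-3) {
  m <- pwm$matrix
  lo <- log2((m + pseudo) / (0.25 + pseudo))
  rbind(lo, N = apply(lo, 2L, min))
}

encode_dna <- function(seq) {
  x <- chartr("acgtn", "ACGTN", seq)
  v <- match(strsplit(x, "")[[1L]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

revcomp <- function(seq) {
  x <- chartr("ACGTacgtn", "TGCAtgcan", seq)
  paste(rev(strsplit(x, "")[[1L]]), collapse = "")
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds score against a uniform background at every offset; a hit is
#' an offset scoring at least `score_frac` of the maximum achievable
#' score. `N` (or any ambiguity code) scores as the worst base.
#'
#' @param sequence character scalar over A/C/G/T/N (case-insensitive).
#' @param pwm a `pwm` object.
#' @param score_frac fraction of the maximal score required for a hit.
#' @return data.frame `start` (0-based offset on the given sequence),
#'   `strand`, `score`; zero rows when nothing reaches the threshold or
#'   the sequence is shorter than the motif.
#' @export
pwm_scan <- function(sequence, pwm, score_frac = 0.8) {
  sm <- pwm_score_matrix(pwm)
  L <- ncol(sm)
  thr <- score_frac * sum(apply(sm[1:4, , drop = FALSE], 2L, max))
  scan1 <- function(seq) {
    v <- encode_dna(seq)
    n <- length(v) - L + 1L
    if (n < 1L) return(data.frame(start = integer(0), score = numeric(0)))
    sc <- rep(0, n)
    for (j in seq_len(L)) sc <- sc + sm[cbind(v[j:(j + n - 1L)], j)]
    hits <- which(sc >= thr)
    data.frame(start = hits - 1L, score = sc[hits])
  }
  fw <- scan1(sequence)
  rv <- scan1(revcomp(sequence))
  slen <- nchar(sequence)
  out <- rbind(
    if (nrow(fw)) data.frame(start = fw$start, strand = "+",
                             score = fw$score, stringsAsFactors = FALSE),
    if (nrow(rv)) data.frame(start = slen - rv$start - L, strand = "-",
                             score = rv$score, stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  out
}

gc_content <- function(seq) {
  v <- encode_dna(seq)
  v <- v[v <= 4L]
  if (length(v) == 0L) return(NA_real_)
  mean(v == 2L | v == 3L)
}

#' Select a GC- and length-matched background sequence set
#'
#' For each target footprint sequence, samples (seeded) a substring of a
#' pool sequence with identical length and GC content within `gc_tol`.
#' Pool sequences containing lowercase (repeat-masked) bases are
#' excluded. If no match is found for some target, the tolerance is
#' relaxed stepwise by +0.05 (with a warning) up to `max_tol`, else the
#' call fails.
#'
#' @param pool character vector of candidate sequences (must not overlap
#'   footprint intervals; the caller guarantees disjointness).
#' @param targets character vector of footprint sequences.
#' @param gc_tol initial GC tolerance (default 0.05).
#' @param max_tol maximum tolerance after relaxation (default 0.25).
#' @param tries_per_target sampling attempts per tolerance step.
#' @param seed integer seed.
#' @return character vector, one background sequence per target.
#' @export
select_background <- function(pool, targets, gc_tol = 0.05, max_tol = 0.25,
                              tries_per_target = 200L, seed = 1L) {
  if (length(pool) == 0L) stop("empty background pool")
  masked <- grepl("[acgt]", pool)
  pool <- pool[!masked]
  if (length(pool) == 0L) stop("background pool entirely repeat-masked")
  set.seed(seed)
  out <- character(length(targets))
  for (i in seq_along(targets)) {
    l <- nchar(targets[i])
    gt <- gc_content(targets[i])
    eligible <- pool[nchar(pool) >= l]
    if (length(eligible) == 0L)
      stop("no pool sequence long enough for target of length ", l)
    tol <- gc_tol; found <- NA_character_
    repeat {
      for (k in seq_len(tries_per_target)) {
        s <- eligible[sample.int(length(eligible), 1L)]
        off <- sample.int(nchar(s) - l + 1L, 1L)
        cand <- substr(s, off, off + l - 1L)
        if (abs(gc_content(cand) - gt) <= tol) { found <- cand; break }
      }
      if (!is.na(found)) break
      tol <- tol + 0.05
      if (tol > max_tol + 1e-9)
        stop("no GC-matched background for target ", i,
             " within tolerance ", max_tol)
      warning("relaxing GC tolerance to ", tol, " for target ", i)
    }
    out[i] <- found
  }
  out
}

# TRUE per sequence iff >= 1 hit on either strand; vectorised across
# sequences grouped by length (same scoring rules as pwm_scan).
pwm_hits_any <- function(seqs, pwm, score_frac = 0.8) {
  sm <- pwm_score_matrix(pwm)
  L <- ncol(sm)
  thr <- score_frac * sum(apply(sm[1:4, , drop = FALSE], 2L, max))
  out <- logical(length(seqs))
  enc <- lapply(seqs, encode_dna)
  lens <- lengths(enc)
  for (n in unique(lens)) {
    if (n < L) next
    idx <- which(lens == n)
    M <- do.call(cbind, enc[idx])          # n x m codes
    hit <- rep(FALSE, length(idx))
    for (o in seq_len(n - L + 1L)) {
      sc_f <- sc_r <- 0
      for (j in seq_len(L)) {
        sc_f <- sc_f + sm[cbind(M[o + j - 1L, ], j)]
        # reverse strand: complement code (A<->T, C<->G, N fixed)
        comp <- c(4L, 3L, 2L, 1L, 5L)[M[o + L - j, ]]
        sc_r <- sc_r + sm[cbind(comp, j)]
      }
      hit <- hit | sc_f >= thr | sc_r >= thr
    }
    out[idx] <- hit
  }
  out
}

# fraction of sequences with >= 1 hit of the motif
hit_proportion <- function(seqs, pwm, score_frac = 0.8) {
  mean(pwm_hits_any(seqs, pwm, score_frac))
}

#' Doubly-normalised motif fold-change enrichment
#'
#' `fold_change = (prop_fp / prop_bg) / (prop_gw_fp / prop_gw_bg)`: the
#' motif's background-normalised frequency in target footprints relative
#' to its background-normalised frequency in genome-wide footprints. A
#' zero proportion in a denominator position is replaced by the
#' pseudo-proportion `1/(2n)` and the result flagged. A motif is enriched
#' when `fold_change > 1.5`.
#'
#' @param target_fp_seqs,target_bg,genomewide_fp_seqs,genomewide_bg
#'   character vectors of sequences (all non-empty).
#' @param pwm a `pwm` object.
#' @param score_frac hit threshold, see [pwm_scan()].
#' @return one-row data.frame `motif_id`, `class`, `prop_fp`, `prop_bg`,
#'   `prop_gw_fp`, `prop_gw_bg`, `fold_change`, `enriched`, `flagged`.
#' @export
motif_fold_change <- function(target_fp_seqs, target_bg,
                              genomewide_fp_seqs, genomewide_bg, pwm,
                              score_frac = 0.8) {
  sets <- list(target_fp_seqs, target_bg, genomewide_fp_seqs, genomewide_bg)
  if (any(lengths(sets) == 0L)) stop("all four sequence sets must be non-empty")
  props <- vapply(sets, hit_proportion, 0, pwm = pwm,
                  score_frac = score_frac)
  flagged <- FALSE
  fix <- function(p, n, denom) {
    if (denom && p == 0) { flagged <<- TRUE; 1 / (2 * n) } else p
  }
  pf <- props[1L]
  pb <- fix(props[2L], length(sets[[2L]]), TRUE)
  pg <- fix(props[3L], length(sets[[3L]]), TRUE)
  pgb <- props[4L]
  # the genome-wide numerator/background ratio is itself a denominator
  ratio_t <- pf / pb
  ratio_g <- if (pgb == 0) {
    if (pg == 0) 1 else { flagged <- TRUE; pg / (1 / (2 * length(sets[[4L]]))) }
  } else pg / pgb
  if (ratio_g == 0) { flagged <- TRUE; ratio_g <- 1 / (2 * length(sets[[3L]])) }
  fc <- ratio_t / ratio_g
  data.frame(motif_id = pwm$motif_id, class = pwm$class,
             prop_fp = props[1L], prop_bg = props[2L],
             prop_gw_fp = props[3L], prop_gw_bg = props[4L],
             fold_change = fc, enriched = fc > 1.5, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Collapse motif hits to one per TF class per footprint
#'
#' When several motifs of the same class hit the same footprint only one
#' (lowest `motif_id`, for determinism) is retained; returns per-class
#' counts over footprints. Never increases counts; idempotent.
#'
#' @param hits data.frame with `footprint_id`, `motif_id`, `class`.
#' @return named integer vector of class counts.
#' @export
collapse_by_class <- function(hits) {
  if (nrow(hits) == 0L) return(integer(0))
  if (any(is.na(hits$class) | !nzchar(hits$class)))
    stop("every motif must carry a class label")
  hits <- hits[order(hits$footprint_id, hits$class, hits$motif_id), ]
  dedup <- hits[!duplicated(hits[, c("footprint_id", "class")]), ]
  tab <- table(dedup$class)
  stats::setNames(as.integer(tab), names(tab))
}

#' Percentage distribution of motif classes across footprint sets
#'
#' Normalises each set's class counts to percentages of all retained
#' class hits in that set; sets with zero total are omitted with a
#' warning.
#'
#' @param count_sets named list of named count vectors (e.g.
#'   `both`, `ZT04_only`, `ZT16_only`).
#' @return data.frame `set`, `class`, `count`, `percent`.
#' @export
class_distribution <- function(count_sets) {
  rows <- list()
  for (nm in names(count_sets)) {
    ct <- count_sets[[nm]]
    if (length(ct) == 0L || sum(ct) == 0) {
      warning("empty class-count set omitted: ", nm)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, class = names(ct), count = as.integer(ct),
      percent = 100 * as.numeric(ct) / sum(ct), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Extract interval sequences from scaffold sequences
#'
#' @param sequences named character vector of scaffold sequences.
#' @param intervals interval data.frame (0-based half-open).
#' @return character vector of subsequences.
#' @export
interval_sequences <- function(sequences, intervals) {
  vapply(seq_len(nrow(intervals)), function(i)
    substr(sequences[[intervals$scaffold[i]]],
           intervals$start[i] + 1L, intervals$end[i]), "")
}
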