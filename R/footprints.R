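# Strand-imbalance footprinting inside accessibility peaks, footprint-set
# algebra across timepoints, Tn5 profile extraction, the footprint
# occupancy score (FOS), and group statistics on inverse FOS.

#' Scan peaks for TF footprints by strand-imbalance depletion
#'
#' For every candidate start and footprint size `l` (11-25 bp) inside a
#' peak, two one-sided binomial depletion tests are computed: the
#' plus-strand cuts inside the footprint vs the upstream `flank`-bp flank
#' (`p_plus = P[Binom(f + F, l/(l + flank)) <= f]`), and symmetrically the
#' minus-strand cuts vs the downstream flank. A bound factor must protect
#' both strands, so the combined p is the worse of the two,
#' `max(p_plus, p_minus)`. Per start the best (smallest-p) size is kept;
#' candidates are then selected greedily by ascending p under a
#' non-overlap constraint.
#'
#' @param track `cut_track`.
#' @param peaks interval data.frame; peaks narrower than
#'   `max(sizes) + 2*flank` are scanned over the sizes that fit, and
#'   skipped entirely if none fit.
#' @param sizes candidate footprint lengths (bp).
#' @param flank flank width (bp), default 35.
#' @param max_p only candidates with combined p <= `max_p` are returned.
#' @return interval data.frame of disjoint candidate footprints with
#'   `score = -log10 p` and column `p`.
#' @export
wellington_scan <- function(track, peaks, sizes = 11:25, flank = 35L,
                            max_p = 1) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    scf <- peaks$scaffold[i]
    ps <- peaks$start[i]; pe <- peaks$end[i]
    fit <- sizes[sizes + 2L * flank <= pe - ps]
    if (length(fit) == 0L) next
    plus <- track$plus[[scf]]; minus <- track$minus[[scf]]
    cp <- c(0, cumsum(plus)); cm <- c(0, cumsum(minus))
    segsum <- function(cs, s, e) cs[e + 1L] - cs[s + 1L]  # [s, e), 0-based
    best_p <- NULL; best_l <- NULL; starts <- NULL
    for (l in fit) {
      s <- seq.int(ps + flank, pe - flank - l)   # candidate starts
      fplus <- segsum(cp, s, s + l)
      Fplus <- segsum(cp, s - flank, s)
      fminus <- segsum(cm, s, s + l)
      Rminus <- segsum(cm, s + l, s + l + flank)
      pr <- l / (l + flank)
      pp <- stats::pbinom(fplus, fplus + Fplus, pr)
      pm <- stats::pbinom(fminus, fminus + Rminus, pr)
      pcomb <- pmax(pp, pm)
      # degenerate windows (no cuts on a strand) carry no evidence
      pcomb[fplus + Fplus == 0 | fminus + Rminus == 0] <- Inf
      if (is.null(best_p)) {
        starts <- s; best_p <- pcomb; best_l <- rep(l, length(s))
      } else {
        idx <- seq_along(s)   # same start grid; longer l has fewer starts
        better <- pcomb < best_p[idx]
        best_p[idx][better] <- pcomb[better]
        best_l[idx][better] <- l
      }
    }
    keep <- which(best_p <= max_p)
    if (length(keep) == 0L) next
    ord <- keep[order(best_p[keep])]
    taken_s <- integer(0); taken_e <- integer(0)
    sel <- integer(0)
    for (j in ord) {
      s0 <- starts[j]; e0 <- starts[j] + best_l[j]
      if (!any(s0 < taken_e & taken_s < e0)) {
        sel <- c(sel, j)
        taken_s <- c(taken_s, s0); taken_e <- c(taken_e, e0)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      scaffold = scf, start = starts[sel], end = starts[sel] + best_l[sel],
      p = best_p[sel], peak = peaks$name[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    fp <- genomic_intervals(character(0), integer(0), integer(0))
    fp$p <- numeric(0); fp$peak <- character(0)
    return(fp)
  }
  df <- do.call(rbind, out)
  fp <- genomic_intervals(df$scaffold, df$start, df$end,
                          name = sprintf("fp%04d", seq_len(nrow(df))),
                          score = -log10(pmax(df$p, 1e-300)))
  fp$p <- df$p
  fp$peak <- df$peak
  fp
}

#' Footprint detection with an empirical FDR gate
#'
#' Runs [wellington_scan()] at `p_thresh`, then estimates the empirical
#' FDR by re-running the scan on `n_shuffles` null tracks in which the cut
#' counts of each peak are circularly rotated, each strand by an
#' independent random offset: FDR = mean detections per shuffle /
#' observed detections. The observed set is emitted only if the estimated
#' FDR is at most `fdr`. Rotation preserves each strand's marginal count
#' structure while destroying the plus/minus phasing that defines a
#' footprint; because two independent rotations re-align a genuine
#' footprint's strand patterns with probability about (footprint +
#' flank)/peak-width per peak, offset pairs whose difference would
#' re-align the strand patterns of any pair of footprint candidates in
#' the peak (within `min_sep` bp, including the trivial zero difference)
#' are excluded -- the self-overlap exclusion standard for circular
#' permutation nulls, generalised to multi-footprint peaks. The protected
#' candidate set is taken from a looser scan at `protect_p`, so that
#' sub-threshold footprints cannot re-align with detected ones either.
#'
#' @param track `cut_track`.
#' @param peaks interval data.frame.
#' @param n_shuffles number of circular-shuffle null tracks.
#' @param p_thresh footprint p-value threshold (default 1e-10).
#' @param fdr empirical FDR threshold (default 0.01).
#' @param seed integer seed for the rotations.
#' @param min_sep exclusion margin (bp) around re-aligning offset
#'   differences; capped at a third of the peak width.
#' @param protect_p candidate threshold defining the strand patterns
#'   protected from re-alignment in the rotation null.
#' @param ... passed to [wellington_scan()].
#' @return footprint data.frame (possibly empty); attributes
#'   `empirical_fdr` (NA when nothing observed) and `n_observed`.
#' @export
footprint_fdr <- function(track, peaks, n_shuffles = 5L, p_thresh = 1e-10,
                          fdr = 0.01, seed = 1L, min_sep = 60L,
                          protect_p = 1e-4, ...) {
  obs <- wellington_scan(track, peaks, max_p = p_thresh, ...)
  protected <- wellington_scan(track, peaks, max_p = protect_p, ...)
  if (nrow(obs) == 0L) {
    attr(obs, "empirical_fdr") <- NA_real_
    attr(obs, "n_observed") <- 0L
    return(obs)
  }
  set.seed(seed)
  # per peak, enumerate the circular offset differences d = o_plus -
  # o_minus that keep every pair of protected strand patterns at least
  # `sep` bp from re-alignment; shrink sep if the exclusion zones cover
  # the circle, and mark the peak unrotatable if none remains
  allowed <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    scf <- peaks$scaffold[i]
    L <- peaks$end[i] - peaks$start[i]
    s_obs <- protected$start[protected$scaffold == scf &
                               protected$start < peaks$end[i] &
                               protected$end > peaks$start[i]]
    bad <- if (length(s_obs)) unique(as.vector(outer(s_obs, s_obs, "-")))
           else 0L
    d <- 0:(L - 1L)
    for (sep in c(min(min_sep, L %/% 3L), 40L, 26L)) {
      circ <- vapply(bad, function(b) {
        dd <- abs(((d - b) + L %/% 2L) %% L - L %/% 2L)
        dd < sep
      }, logical(L))
      ok <- d[!apply(matrix(circ, nrow = L), 1L, any)]
      if (length(ok)) break
    }
    allowed[[i]] <- ok      # may be empty: peak excluded from the null
  }
  rotatable <- lengths(allowed) > 0L
  null_counts <- vapply(seq_len(n_shuffles), function(k) {
    sh <- track
    for (i in which(rotatable)) {
      scf <- peaks$scaffold[i]
      idx <- (peaks$start[i] + 1L):peaks$end[i]
      L <- length(idx)
      o_minus <- sample.int(L, 1L)
      dpick <- allowed[[i]][sample.int(length(allowed[[i]]), 1L)]
      o_plus <- ((o_minus - 1L + dpick) %% L) + 1L
      for (k2 in 1:2) {
        slot <- c("plus", "minus")[k2]
        v <- sh[[slot]][[scf]][idx]
        o <- c(o_plus, o_minus)[k2]
        sh[[slot]][[scf]][idx] <- c(v[-seq_len(o)], v[seq_len(o)])
      }
    }
    nrow(wellington_scan(sh, peaks[rotatable, , drop = FALSE],
                         max_p = p_thresh, ...))
  }, 0)
  obs_rot <- sum(vapply(seq_len(nrow(obs)), function(j)
    any(peaks$name[rotatable] == obs$peak[j]), TRUE))
  efdr <- if (obs_rot > 0) mean(null_counts) / obs_rot
          else mean(null_counts) / nrow(obs)
  res <- if (efdr <= fdr) obs else obs[0, , drop = FALSE]
  attr(res, "empirical_fdr") <- efdr
  attr(res, "n_observed") <- nrow(obs)
  res
}

#' Partition two footprint sets into time-specific and shared footprints
#'
#' A footprint is shared iff it overlaps (>= 1 bp) any footprint of the
#' other set, else specific to its own set; `|specific| + |shared| = |set|`
#' for each set.
#'
#' @param fp_a,fp_b interval data.frames (e.g. footprints at ZT04 and
#'   ZT16).
#' @return list `specific_a`, `specific_b`, `shared_a`, `shared_b`.
#' @export
timepoint_specific <- function(fp_a, fp_b) {
  ov <- function(x, y) {
    if (nrow(x) == 0L) return(logical(0))
    if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
    IRanges::overlapsAny(as_granges(x), as_granges(y), ignore.strand = TRUE)
  }
  sa <- ov(fp_a, fp_b); sb <- ov(fp_b, fp_a)
  list(specific_a = fp_a[!sa, , drop = FALSE],
       specific_b = fp_b[!sb, , drop = FALSE],
       shared_a = fp_a[sa, , drop = FALSE],
       shared_b = fp_b[sb, , drop = FALSE])
}

#' Extract per-footprint Tn5 cut profiles
#'
#' One row per footprint: combined-strand cut counts over the footprint
#' center +/- `halfwidth` bp (center = `start + floor(length/2)`,
#' left-biased for even lengths). Footprints whose window leaves the
#' scaffold are dropped and counted.
#'
#' @param track `cut_track`.
#' @param footprints interval data.frame.
#' @param halfwidth half window (bp), default 100 -> 201 columns.
#' @return matrix footprints x (2*halfwidth + 1); attribute `n_dropped`.
#' @export
extract_profiles <- function(track, footprints, halfwidth = 100L) {
  n <- nrow(footprints)
  rows <- list(); kept <- character(0); dropped <- 0L
  for (i in seq_len(n)) {
    scf <- footprints$scaffold[i]
    L <- track$lengths[[scf]]
    center <- footprints$start[i] +
      (footprints$end[i] - footprints$start[i]) %/% 2L
    s <- center - halfwidth; e <- center + halfwidth
    if (s < 0L || e >= L) { dropped <- dropped + 1L; next }
    v <- track$plus[[scf]][(s + 1L):(e + 1L)] +
      track$minus[[scf]][(s + 1L):(e + 1L)]
    rows[[length(rows) + 1L]] <- v
    kept <- c(kept, if ("name" %in% names(footprints)) footprints$name[i]
              else as.character(i))
  }
  m <- if (length(rows)) do.call(rbind, rows)
  else matrix(numeric(0), 0L, 2L * halfwidth + 1L)
  rownames(m) <- kept
  colnames(m) <- as.character(-halfwidth:halfwidth)
  attr(m, "n_dropped") <- dropped
  m
}

#' Centered rolling average with edge shrinkage
#'
#' Window of odd width `w`; at the edges the window shrinks so the output
#' has the input length.
#'
#' @param vec numeric vector.
#' @param w odd window width (default 3).
#' @return smoothed vector of the same length.
#' @export
rolling_average <- function(vec, w = 3L) {
  if (w %% 2L == 0L) stop("window width must be odd")
  n <- length(vec)
  if (w > n) stop("window wider than the vector")
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(vec))
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Footprint occupancy score
#'
#' `FOS = (C + 1)/L + (C + 1)/R` with `C` the mean combined-strand cuts/bp
#' over the footprint and `L`, `R` the means over the `flank`-bp left and
#' right flanks; lower FOS (higher inverse FOS) means a deeper footprint.
#' A zero flank mean is replaced by `1/flank` (one pseudo-cut) and the
#' record is flagged.
#'
#' @param track `cut_track`.
#' @param footprint single-row interval data.frame (or list with
#'   `scaffold`, `start`, `end`).
#' @param flank flank width (bp), default 35.
#' @return list `C`, `L`, `R`, `fos`, `inv_fos`, `flagged`.
#' @export
fos <- function(track, footprint, flank = 35L) {
  scf <- footprint$scaffold
  s <- footprint$start; e <- footprint$end
  L_scf <- track$lengths[[scf]]
  if (is.null(L_scf)) stop("unknown scaffold: ", scf)
  if (s - flank < 0L || e + flank > L_scf)
    stop("footprint flanks outside scaffold bounds")
  v <- track$plus[[scf]] + track$minus[[scf]]
  mean_in <- function(a, b) mean(v[(a + 1L):b])   # [a, b), 0-based
  C <- mean_in(s, e)
  Lm <- mean_in(s - flank, s)
  Rm <- mean_in(e, e + flank)
  flagged <- FALSE
  if (Lm == 0) { Lm <- 1 / flank; flagged <- TRUE }
  if (Rm == 0) { Rm <- 1 / flank; flagged <- TRUE }
  f <- (C + 1) / Lm + (C + 1) / Rm
  list(C = C, L = Lm, R = Rm, fos = f, inv_fos = 1 / f, flagged = flagged)
}

#' FOS records for a footprint set across conditions
#'
#' @param tracks named list of `cut_track`s; names are the group labels
#'   (e.g. `"WT_ZT04"`).
#' @param footprints interval data.frame.
#' @param flank flank width (bp).
#' @return data.frame `footprint_id`, `group`, `C`, `L`, `R`, `fos`,
#'   `inv_fos`, `flagged`.
#' @export
fos_table <- function(tracks, footprints, flank = 35L) {
  rows <- list()
  for (g in names(tracks)) {
    for (i in seq_len(nrow(footprints))) {
      r <- fos(tracks[[g]], footprints[i, ], flank)
      rows[[length(rows) + 1L]] <- data.frame(
        footprint_id = if ("name" %in% names(footprints))
          footprints$name[i] else as.character(i),
        group = g, C = r$C, L = r$L, R = r$R, fos = r$fos,
        inv_fos = r$inv_fos, flagged = r$flagged, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Dunn pairwise z-tests on a Kruskal-Wallis ranking, BH-adjusted.
dunn_pairwise <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  tt <- table(values)
  tiecor <- sum(tt^3 - tt) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             adjP = bh_adjust(p), stringsAsFactors = FALSE)
}

# Compact letter display: groups sharing a letter are not significantly
# different. Insert-and-absorb heuristic over groups ordered by mean rank.
letter_display <- function(levels_ord, sig_pairs) {
  differs <- function(a, b)
    any((sig_pairs$group1 == a & sig_pairs$group2 == b) |
          (sig_pairs$group1 == b & sig_pairs$group2 == a))
  groups <- list()
  for (g in levels_ord) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (!any(vapply(groups[[k]], differs, TRUE, b = g))) {
        groups[[k]] <- c(groups[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- g
  }
  letters_out <- stats::setNames(rep("", length(levels_ord)), levels_ord)
  for (k in seq_along(groups))
    for (g in groups[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  letters_out
}

#' Compare inverse FOS across genotype-by-timepoint groups
#'
#' Kruskal-Wallis test (tie-corrected) on inverse FOS followed by Dunn
#' pairwise z-tests with BH adjustment and a compact letter display
#' (groups sharing a letter are not significantly different at `alpha`).
#' Flagged records (pseudo-count flanks) are excluded by default.
#'
#' @param records data.frame from [fos_table()] (needs `inv_fos`,
#'   `group`, optionally `flagged`).
#' @param alpha significance level for the letters (default 0.05).
#' @param drop_flagged exclude flagged records (default TRUE).
#' @return list `kw` (`statistic`, `df`, `p`), `dunn` (pairwise table),
#'   `letters` (named by group, ordered by decreasing mean inverse FOS).
#' @export
compare_fos_groups <- function(records, alpha = 0.05, drop_flagged = TRUE) {
  if (drop_flagged && "flagged" %in% names(records))
    records <- records[!records$flagged, , drop = FALSE]
  cnt <- table(records$group)
  if (any(cnt == 0L) || length(cnt) != length(unique(records$group)))
    warning("empty group(s) excluded")
  keep <- records$group %in% names(cnt)[cnt >= 2L]
  if (sum(cnt >= 2L) < 2L) stop("need >= 2 groups with n >= 2")
  records <- records[keep, , drop = FALSE]
  kw <- stats::kruskal.test(records$inv_fos, factor(records$group))
  dunn <- dunn_pairwise(records$inv_fos, records$group)
  sig <- dunn[!is.na(dunn$adjP) & dunn$adjP <= alpha, , drop = FALSE]
  ord <- names(sort(tapply(records$inv_fos, records$group, mean),
                    decreasing = TRUE))
  list(kw = list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value),
       dunn = dunn, letters = letter_display(ord, sig))
}
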