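# Rhythm detection: two complementary per-gene statistics -- a parametric
# cosinor (harmonic regression F-test at fixed 24-h period) and a
# nonparametric circular umbrella rank test (Mack-Wolfe style) -- combined
# by minP, BH-adjusted, and gated on peak/trough fold change.

#' Filter an expression matrix to expressed genes
#'
#' Keeps genes whose replicate-mean expression reaches `min_rpkm` at one or
#' more timepoints (replicates averaged within each genotype x ZT group).
#'
#' @param mat genes x samples matrix; colnames parseable by
#'   [parse_sample_labels()].
#' @param min_rpkm expression floor (RPKM), default 3.
#' @return the filtered matrix, gene order preserved.
#' @export
filter_expressed <- function(mat, min_rpkm = 3) {
  info <- parse_sample_labels(colnames(mat))
  grp <- paste(info$genotype, info$zt)
  means <- sapply(unique(grp), function(g)
    rowMeans(mat[, grp == g, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(mat))
  keep <- apply(means, 1L, max) >= min_rpkm
  mat[keep, , drop = FALSE]
}

#' Peak/trough fold change of a time series
#'
#' Ratio of the maximal to minimal per-timepoint expression. By default
#' replicates are averaged within timepoints first (`mode =
#' "replicate_mean"`); `mode = "raw"` takes the extremes over individual
#' replicate values.
#'
#' @param values numeric expression values (>= 0).
#' @param timepoints timepoint label per value.
#' @param mode `"replicate_mean"` or `"raw"`.
#' @return the ratio (>= 1); `Inf` when the minimum is 0 but the maximum is
#'   not; `NA` (with a warning) for an all-zero series.
#' @export
fold_change <- function(values, timepoints,
                        mode = c("replicate_mean", "raw")) {
  mode <- match.arg(mode)
  if (any(values < 0)) stop("expression values must be >= 0")
  v <- if (mode == "replicate_mean")
    tapply(values, timepoints, mean) else values
  if (max(v) == 0) {
    warning("all-zero series: fold change undefined")
    return(NA_real_)
  }
  if (min(v) == 0) return(Inf)
  max(v) / min(v)
}

#' Cosinor fit by harmonic regression at a fixed period
#'
#' Least-squares fit of `y = m + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`.
#' Amplitude is `sqrt(a^2 + b^2)`, phase (hours of peak) is
#' `(T/2/pi) * atan2(b, a)` mapped into \[0, T), and the p-value is the
#' F-test of `(a, b) = (0, 0)` against the intercept-only model. A constant
#' series has zero model sum of squares and is assigned p = 1.
#'
#' @param values numeric observations.
#' @param timepoints hours for each observation.
#' @param period period in hours (default 24).
#' @return list `mesor`, `amplitude`, `phase_h`, `p`, plus coefficients
#'   `a`, `b`.
#' @export
harmonic_fit <- function(values, timepoints, period = 24) {
  if (length(unique(timepoints %% period)) < 4L)
    stop("need >= 4 distinct timepoints (mod period)")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * timepoints), sin(w * timepoints))
  if (qr(X)$rank < 3L) stop("rank-deficient cosinor design")
  fit <- stats::lm.fit(X, values)
  cf <- fit$coefficients
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  n <- length(values)
  ss_model <- rss0 - rss1
  p <- if (ss_model <= .Machine$double.eps * max(rss0, 1)) 1 else {
    f <- (ss_model / 2) / (rss1 / (n - 3L))
    stats::pf(f, 2, n - 3L, lower.tail = FALSE)
  }
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (atan2(cf[3], cf[2]) / w) %% period
  list(mesor = unname(cf[1]), amplitude = unname(amp),
       phase_h = unname(phase), p = unname(p),
       a = unname(cf[2]), b = unname(cf[3]))
}

# ---- circular umbrella rank test -------------------------------------------

# Pairwise Mann-Whitney count U_ij = #{x in grp i < y in grp j} + 0.5 ties,
# for all ordered group pairs, returned as a T x T matrix.
mw_count_matrix <- function(values, grp_index) {
  T_ <- max(grp_index)
  U <- matrix(0, T_, T_)
  vs <- split(values, grp_index)
  for (i in seq_len(T_ - 1L)) for (j in (i + 1L):T_) {
    cmp <- outer(vs[[i]], vs[[j]], "<")
    tie <- outer(vs[[i]], vs[[j]], "==")
    U[i, j] <- sum(cmp) + 0.5 * sum(tie)
    U[j, i] <- length(vs[[i]]) * length(vs[[j]]) - U[i, j]
  }
  U
}

# Mack-Wolfe umbrella statistic for peak at rotated position p, given the
# pairwise U matrix in rotated group order: A_p = sum_{i<j<=p} U_ij +
# sum_{p<=i<j} U_ji.
mack_wolfe_stat <- function(U, p) {
  T_ <- nrow(U); A <- 0
  if (p >= 2L) for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
    A <- A + U[i, j]
  if (p <= T_ - 1L) for (i in p:(T_ - 1L)) for (j in (i + 1L):T_)
    A <- A + U[j, i]
  A
}

# Null mean and variance of A_p (Mack & Wolfe), equal or unequal group
# sizes, no-tie form; callers apply a tie-correction factor to the variance.
mack_wolfe_moments <- function(sizes, p) {
  n <- sizes; N <- sum(n)
  N1 <- sum(n[seq_len(p)]); N2 <- sum(n[p:length(n)])
  np <- n[p]
  E <- (N1^2 + N2^2 - sum(n^2) - np^2) / 4
  V <- (2 * (N1^3 + N2^3) + 3 * (N1^2 + N2^2) -
          sum(n^2 * (2 * n + 3)) - np^2 * (2 * np + 3) +
          12 * np * N1 * N2 - 12 * np^2 * N) / 72
  list(mean = E, var = V)
}

# Rotated group order for a candidate peak k among T circular timepoints:
# start just after the antipodal trough, ascend to k, descend back.
umbrella_rotation <- function(T_, k) {
  tr <- ((k - 1L + T_ %/% 2L) %% T_) + 1L
  ord <- ((tr + seq_len(T_) - 1L) %% T_) + 1L
  list(order = ord, p = match(k, ord))
}

# Per-peak one-sided normal-approximation p-values for all T candidate
# peaks, given values and integer group index in temporal order.
umbrella_peak_pvalues <- function(values, grp_index, tie_factor = NULL) {
  T_ <- max(grp_index)
  U <- mw_count_matrix(values, grp_index)
  sizes <- tabulate(grp_index, T_)
  if (is.null(tie_factor)) {
    N <- length(values)
    tt <- table(values)
    tie_factor <- 1 - sum(tt^3 - tt) / (N^3 - N)
  }
  vapply(seq_len(T_), function(k) {
    rot <- umbrella_rotation(T_, k)
    Ur <- U[rot$order, rot$order, drop = FALSE]
    A <- mack_wolfe_stat(Ur, rot$p)
    mo <- mack_wolfe_moments(sizes[rot$order], rot$p)
    s <- sqrt(mo$var * tie_factor)
    if (!is.finite(s) || s <= 0) return(1)   # zero-information ranks
    stats::pnorm((A - mo$mean) / s, lower.tail = FALSE)
  }, 0)
}

# Cache of Monte Carlo null distributions of min_k p_k, keyed by the
# sampling design (group sizes) and simulation size. Distribution-free
# under H0 for continuous data, so one table serves every gene measured on
# the same design.
.umbrella_calib <- new.env(parent = emptyenv())

umbrella_null_minp <- function(sizes, n_calib = 20000L, calib_seed = 20240101L) {
  key <- paste(c(sizes, n_calib, calib_seed), collapse = "_")
  if (!is.null(.umbrella_calib[[key]])) return(.umbrella_calib[[key]])
  T_ <- length(sizes); N <- sum(sizes)
  grp <- rep(seq_len(T_), sizes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(calib_seed)
  X <- matrix(stats::rnorm(n_calib * N), n_calib, N)
  # vectorised pairwise U counts across simulations
  idx <- split(seq_len(N), grp)
  U <- array(0, dim = c(n_calib, T_, T_))
  for (i in seq_len(T_ - 1L)) for (j in (i + 1L):T_) {
    cnt <- 0
    for (a in idx[[i]]) for (b in idx[[j]])
      cnt <- cnt + (X[, a] < X[, b])
    U[, i, j] <- cnt
    U[, j, i] <- length(idx[[i]]) * length(idx[[j]]) - cnt
  }
  minp <- rep(Inf, n_calib)
  sump <- rep(0, n_calib)
  for (k in seq_len(T_)) {
    rot <- umbrella_rotation(T_, k)
    A <- rep(0, n_calib)
    p <- rot$p; ord <- rot$order
    if (p >= 2L) for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      A <- A + U[, ord[i], ord[j]]
    if (p <= T_ - 1L) for (i in p:(T_ - 1L)) for (j in (i + 1L):T_)
      A <- A + U[, ord[j], ord[i]]
    mo <- mack_wolfe_moments(sizes[ord], p)
    pk <- stats::pnorm((A - mo$mean) / sqrt(mo$var), lower.tail = FALSE)
    minp <- pmin(minp, pk)
    sump <- sump + pk
  }
  out <- sort(umbrella_refined_stat(minp, sump / T_))
  .umbrella_calib[[key]] <- out
  out
}

# Refined umbrella statistic: the minimum per-peak p, tie-broken by the
# mean per-peak p. The perturbation is far below the spacing of distinct
# min-p values, so it only resolves ties among rank configurations sharing
# the same minimum; this makes the calibrated null effectively continuous.
umbrella_refined_stat <- function(minp, meanp) minp * (1 + 1e-9) + 1e-6 * meanp

#' Circular umbrella rank test for rhythmicity
#'
#' Scans every timepoint as a candidate peak of an umbrella-ordered
#' alternative (monotone rise to the peak, monotone fall to the antipodal
#' trough, wrapping circularly) using the Mack-Wolfe extension of the
#' Jonckheere-Terpstra statistic; each candidate peak gets a one-sided
#' normal-approximation p-value (midrank ties, tie-corrected variance).
#' The minimum over candidate peaks is then either mapped through its
#' distribution-free Monte Carlo null distribution (`method =
#' "calibrated"`, default; approximately uniform under H0) or
#' Bonferroni-multiplied by the number of candidate peaks (`method =
#' "bonferroni"`, conservative).
#'
#' @param values numeric observations.
#' @param timepoints hours for each observation (>= 3 distinct).
#' @param period period in hours.
#' @param method `"calibrated"` or `"bonferroni"`.
#' @param n_calib Monte Carlo size for the calibrated null (cached per
#'   sampling design).
#' @return the rhythm p-value (scalar).
#' @export
umbrella_test <- function(values, timepoints, period = 24,
                          method = c("calibrated", "bonferroni"),
                          n_calib = 20000L) {
  method <- match.arg(method)
  tp <- sort(unique(timepoints %% period))
  if (length(tp) < 3L) stop("need >= 3 distinct timepoints")
  grp <- match(timepoints %% period, tp)
  pk <- umbrella_peak_pvalues(values, grp)
  if (method == "bonferroni") return(min(1, min(pk) * length(tp)))
  m <- umbrella_refined_stat(min(pk), mean(pk))
  null_m <- umbrella_null_minp(tabulate(grp, length(tp)), n_calib)
  nl <- length(null_m)
  less <- findInterval(m, null_m)            # null values <= m
  eq <- sum(null_m == m)
  p <- (less - eq + 0.5 * eq) / nl           # mid-p against the MC null
  max(p, 0.5 / nl)
}

#' Combine two p-values by minP (Tippett)
#'
#' `p = 1 - (1 - min(p1, p2))^2`, the exact distribution of the smaller of
#' two independent uniform p-values.
#'
#' @param p1,p2 p-values in \[0,1\] (vectorised).
#' @return combined p-values.
#' @export
combine_minp <- function(p1, p2) {
  if (any(stats::na.omit(c(p1, p2)) < 0) || any(stats::na.omit(c(p1, p2)) > 1))
    stop("p-values must lie in [0,1]")
  m <- pmin(p1, p2)
  1 - (1 - m)^2
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (input order preserved); a thin wrapper
#' over [stats::p.adjust()].
#'
#' @param p vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Call rhythmically expressed genes
#'
#' Runs the umbrella rank test and the cosinor F-test on every gene,
#' combines them by minP, BH-adjusts across all tested genes, and flags
#' genes with adjusted p <= `alpha` and peak/trough fold change >=
#' `min_fc`. Also returns per-gene z-scored series (for heatmaps) and a
#' phase histogram of rhythmic genes in 1-h bins.
#'
#' @param mat expression matrix (after [filter_expressed()]); one genotype.
#' @param period period in hours.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_fc fold-change threshold (default 1.3).
#' @param fc_mode see [fold_change()].
#' @param umbrella_method see [umbrella_test()].
#' @return data.frame with columns `gene_id`, `p_umbrella`, `p_harmonic`,
#'   `p_combined`, `adjP`, `fold_change`, `phase_h`, `amplitude`, `mesor`,
#'   `is_rhythmic`; attributes `zscores` (matrix) and `phase_hist`
#'   (table over bins 0..23).
#' @export
call_rhythmic <- function(mat, period = 24, alpha = 0.05, min_fc = 1.3,
                          fc_mode = "replicate_mean",
                          umbrella_method = "calibrated") {
  info <- parse_sample_labels(colnames(mat))
  t <- info$zt
  ng <- nrow(mat)
  res <- data.frame(
    gene_id = rownames(mat), p_umbrella = NA_real_, p_harmonic = NA_real_,
    p_combined = NA_real_, adjP = NA_real_, fold_change = NA_real_,
    phase_h = NA_real_, amplitude = NA_real_, mesor = NA_real_,
    is_rhythmic = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(ng)) {
    y <- mat[i, ]
    ok <- tryCatch({
      hf <- harmonic_fit(y, t, period)
      res$p_harmonic[i] <- hf$p
      res$phase_h[i] <- hf$phase_h
      res$amplitude[i] <- hf$amplitude
      res$mesor[i] <- hf$mesor
      res$p_umbrella[i] <- umbrella_test(y, t, period,
                                         method = umbrella_method)
      res$fold_change[i] <- suppressWarnings(fold_change(y, t, fc_mode))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
  res$p_combined <- combine_minp(res$p_umbrella, res$p_harmonic)
  res$adjP <- bh_adjust(res$p_combined)
  res$is_rhythmic <- !is.na(res$adjP) & res$adjP <= alpha &
    !is.na(res$fold_change) & res$fold_change >= min_fc
  z <- t(apply(mat, 1L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(mat)
  attr(res, "zscores") <- z
  ph <- floor(res$phase_h[res$is_rhythmic]) %% 24
  attr(res, "phase_hist") <- table(factor(ph, levels = 0:23))
  res
}
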