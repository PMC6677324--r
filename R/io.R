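#' Read a BED3/BED6 file of genomic intervals
#'
#' BED's native 0-based half-open coordinates are preserved unchanged.
#'
#' @param path file path.
#' @param sorted if `TRUE`, sort by (scaffold, start).
#' @return interval `data.frame` (see [genomic_intervals()]); `name`,
#'   `score`, `strand` filled with defaults when the file is BED3.
#' @export
read_bed <- function(path, sorted = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2L, NA)))
  end <- suppressWarnings(as.integer(get(3L, NA)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0L)
  if (length(bad))
    stop("malformed BED coordinates at line ", bad[1L],
         ": need 0 <= start < end")
  df <- genomic_intervals(
    scaffold = get(1L, NA), start = start, end = end,
    name = get(4L, "."),
    score = suppressWarnings(as.numeric(ifelse(get(5L, "0") == ".", "0",
                                               get(5L, "0")))),
    strand = get(6L, ".")
  )
  if (sorted) df <- df[order(df$scaffold, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED6
#' @param df interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$scaffold, df$start, df$end,
                   df$name, format(df$score, trim = TRUE, scientific = FALSE),
                   df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF-lite file
#'
#' The GTF-lite dialect carries `gene` and `exon` features with 1-based
#' inclusive coordinates and a `gene_id "..."` attribute. Coordinates are
#' converted to the internal 0-based half-open convention; TSS/TTS are
#' derived from strand (TSS = start on `+`, `end - 1` on `-`).
#'
#' @param path file path.
#' @return object of class `gene_models`: a list with `genes` (data.frame
#'   `gene_id`, `scaffold`, `start`, `end`, `strand`, `tss`, `tts`) and
#'   `exons` (data.frame `gene_id`, `scaffold`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(fields) && any(nf < 9L))
    stop("malformed GTF line ", which(nf < 9L)[1L], ": fewer than 9 fields")
  feat <- vapply(fields, `[`, "", 3L)
  keep <- feat %in% c("gene", "exon")
  fields <- fields[keep]; feat <- feat[keep]
  gid <- vapply(fields, function(f) {
    m <- regmatches(f[9L], regexec("gene_id \"([^\"]+)\"", f[9L]))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }, "")
  if (anyNA(gid)) stop("GTF record without gene_id attribute")
  scaffold <- vapply(fields, `[`, "", 1L)
  start1 <- as.integer(vapply(fields, `[`, "", 4L))
  end1 <- as.integer(vapply(fields, `[`, "", 5L))
  strand <- vapply(fields, `[`, "", 7L)
  # 1-based inclusive -> 0-based half-open
  start0 <- start1 - 1L
  end0 <- end1
  g <- feat == "gene"
  genes <- data.frame(
    gene_id = gid[g], scaffold = scaffold[g],
    start = start0[g], end = end0[g], strand = strand[g],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in GTF")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  exons <- data.frame(
    gene_id = gid[!g], scaffold = scaffold[!g],
    start = start0[!g], end = end0[!g],
    stringsAsFactors = FALSE
  )
  if (nrow(exons)) {
    i <- match(exons$gene_id, genes$gene_id)
    if (anyNA(i)) stop("exon references unknown gene_id")
    out <- exons$start < genes$start[i] | exons$end > genes$end[i] |
      exons$scaffold != genes$scaffold[i]
    if (any(out))
      stop("exon outside its gene: ", exons$gene_id[which(out)[1L]])
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as GTF-lite
#' @param gm `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  fmt <- function(scaffold, feature, start0, end0, strand, gene_id) {
    sprintf("%s\tcircatac\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            scaffold, feature, start0 + 1L, end0, strand, gene_id)
  }
  g <- gm$genes
  lines <- fmt(g$scaffold, "gene", g$start, g$end, g$strand, g$gene_id)
  if (nrow(gm$exons)) {
    e <- gm$exons
    st <- g$strand[match(e$gene_id, g$gene_id)]
    lines <- c(lines, fmt(e$scaffold, "exon", e$start, e$end, st, e$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an empty stranded Tn5 cut track
#'
#' A cut track stores one integer vector of Tn5 cut counts per scaffold and
#' strand. Base pair `b` (0-based) lives at vector index `b + 1`.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @return object of class `cut_track` with elements `plus`, `minus`
#'   (named lists of integer vectors) and `lengths`.
#' @export
cut_track <- function(scaffold_lengths) {
  if (is.null(names(scaffold_lengths)) || any(!nzchar(names(scaffold_lengths))))
    stop("scaffold_lengths must be a named vector")
  mk <- function() lapply(scaffold_lengths, function(L) integer(L))
  structure(list(plus = mk(), minus = mk(),
                 lengths = vapply(scaffold_lengths, as.integer, 1L)),
            class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  tot <- sum(vapply(x$plus, sum, 0)) + sum(vapply(x$minus, sum, 0))
  cat("Stranded Tn5 cut track:", length(x$lengths), "scaffold(s),",
      sum(x$lengths), "bp,", tot, "cuts\n")
  invisible(x)
}

# Internal: fill one strand of a track from bedGraph lines.
parse_bedgraph_into <- function(vecs, lengths, path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(vecs)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("malformed bedGraph line ", which(lengths(fields) < 4L)[1L])
  sc <- vapply(fields, `[`, "", 1L)
  s <- as.integer(vapply(fields, `[`, "", 2L))
  e <- as.integer(vapply(fields, `[`, "", 3L))
  v <- as.numeric(vapply(fields, `[`, "", 4L))
  if (any(is.na(s) | is.na(e) | e <= s)) stop("malformed bedGraph coordinates")
  unknown <- !sc %in% names(lengths)
  if (any(unknown)) stop("bedGraph scaffold not in track: ", sc[unknown][1L])
  if (any(e > lengths[sc] | s < 0L))
    stop("bedGraph record outside scaffold bounds at line ",
         which(e > lengths[sc] | s < 0L)[1L])
  for (scf in unique(sc)) {
    i <- which(sc == scf)
    o <- i[order(s[i])]
    if (any(s[o][-1L] < e[o][-length(o)]))
      stop("overlapping bedGraph records on ", scf)
    for (j in o) vecs[[scf]][(s[j] + 1L):e[j]] <- v[j]
  }
  vecs
}

#' Read a stranded cut track from a pair of bedGraph files
#'
#' Positions absent from the bedGraph are zero.
#'
#' @param plus_path,minus_path bedGraph files of per-bp cut counts for the
#'   plus and minus strands.
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @return `cut_track` object.
#' @export
read_cut_track <- function(plus_path, minus_path, scaffold_lengths) {
  tr <- cut_track(scaffold_lengths)
  tr$plus <- parse_bedgraph_into(tr$plus, tr$lengths, plus_path)
  tr$minus <- parse_bedgraph_into(tr$minus, tr$lengths, minus_path)
  tr$plus <- lapply(tr$plus, as.integer)
  tr$minus <- lapply(tr$minus, as.integer)
  tr
}

# Internal: write one strand vector as bedGraph (run-length encoded, zeros
# omitted).
write_bedgraph_strand <- function(vecs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (scf in names(vecs)) {
    r <- rle(vecs[[scf]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", scf, s[keep], e[keep],
                         format(r$values[keep], trim = TRUE,
                                scientific = FALSE)), con)
  }
  invisible(path)
}

#' Write a stranded cut track as a pair of bedGraph files
#' @param track `cut_track` object.
#' @param prefix output path prefix; files are `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @return the two paths, invisibly.
#' @export
write_cut_track <- function(track, prefix) {
  p <- paste0(prefix, ".plus.bedGraph")
  m <- paste0(prefix, ".minus.bedGraph")
  write_bedgraph_strand(track$plus, p)
  write_bedgraph_strand(track$minus, m)
  invisible(c(p, m))
}

#' Read an expression matrix from TSV
#'
#' First column `gene_id`; remaining column headers are sample labels of
#' the form `<genotype>_ZT<hour>_<replicate>` (e.g. `WT_ZT04_1`).
#'
#' @param path TSV file.
#' @return numeric matrix (genes x samples) with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression values must be >= 0")
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels")
  m
}

#' Write an expression matrix as TSV
#' @param mat genes x samples matrix with rownames and sample-label colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse sample labels into genotype / ZT / replicate
#'
#' @param labels character vector like `"WT_ZT04_1"`.
#' @return data.frame with `label`, `genotype`, `zt` (hours, numeric),
#'   `replicate` (integer).
#' @export
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+)_ZT([0-9]+(?:\\.[0-9]+)?)_([0-9]+)$",
                                  labels))
  bad <- lengths(m) < 4L
  if (any(bad)) stop("unparseable sample label: ", labels[bad][1L])
  data.frame(
    label = labels,
    genotype = vapply(m, `[`, "", 2L),
    zt = as.numeric(vapply(m, `[`, "", 3L)),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}
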