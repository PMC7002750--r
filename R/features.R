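#' @title Per-element covariate features
#'
#' @description Covariates predictive of the background mutation rate:
#' nucleotide content (k-mer fractions of the element sequence), mean signal
#' of genome-wide tracks over covered element bases, and the fraction of
#' element bases overlapping peak sets. Missing values are imputed with 0 and
#' features are robust-scaled (median / IQR) for the lasso + GLM path; the
#' gradient-boosted model consumes unscaled, imputed features.
#'
#' @name features
NULL

#' k-mer fractions of a nucleotide sequence
#'
#' Counts overlapping windows of width `k` over the sequence and returns the
#' fraction of each of the 4^k k-mers. Windows containing N are skipped. When
#' no valid window exists the whole vector is missing (NA). For elements with
#' several intervals pass each interval's sequence separately and sum counts
#' (k-mers are never counted across interval junctions).
#'
#' @param seq character string (or `DNAString`) over A,C,G,T,N.
#' @param k 2 or 3.
#' @param as_counts return raw counts instead of fractions.
#' @return named numeric vector of length 4^k.
#' @export
kmer_fractions <- function(seq, k, as_counts = FALSE) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  cnt <- Biostrings::oligonucleotideFrequency(seq, width = k, step = 1)
  if (as_counts) return(cnt)
  tot <- sum(cnt)
  if (tot == 0) return(setNames(rep(NA_real_, length(cnt)), names(cnt)))
  cnt / tot
}

#' k-mer fraction features for every element in a set
#'
#' Sequence is taken from the element's (masked) intervals in genomic order;
#' counts are pooled over intervals without crossing junctions.
#'
#' @param es an `element_set`
#' @param genome a `DNAStringSet` named by chromosome
#' @param k vector of k values (subset of 2:3)
#' @return numeric matrix, rows = elements, cols = k-mers (e.g. "AA", "ACG")
#' @export
element_kmer_features <- function(es, genome, k = c(2L, 3L)) {
  stopifnot(all(k %in% c(2L, 3L)))
  ids <- es$info$element_id
  gr <- es$gr
  seqs <- .interval_seqs(genome, gr)
  eid <- S4Vectors::mcols(gr)$element_id
  mats <- lapply(k, function(kk) {
    cnt <- Biostrings::oligonucleotideFrequency(seqs, width = kk, step = 1)
    agg <- rowsum(cnt, group = eid)
    tot <- rowSums(agg)
    frac <- agg / ifelse(tot == 0, 1, tot)
    frac[tot == 0, ] <- NA_real_
    # elements with no surviving interval at all
    full <- matrix(NA_real_, nrow = length(ids), ncol = ncol(frac),
                   dimnames = list(ids, colnames(frac)))
    full[rownames(agg), ] <- frac
    full
  })
  do.call(cbind, mats)
}

#' Read a genome (or any chromosome set) from FASTA
#'
#' Thin wrapper returning a `DNAStringSet` named by chromosome, the form
#' consumed by [element_kmer_features()].
#'
#' @param path FASTA file
#' @return named `DNAStringSet`
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# extract interval sequences from a chromosome-named DNAStringSet
.interval_seqs <- function(genome, gr) {
  ch <- as.character(GenomicRanges::seqnames(gr))
  missing_chr <- setdiff(unique(ch), names(genome))
  if (length(missing_chr)) {
    stop("chromosomes absent from the genome: ", paste(missing_chr, collapse = ", "))
  }
  out <- vector("list", length(gr))
  for (c_name in unique(ch)) {
    i <- which(ch == c_name)
    out[i] <- as.list(Biostrings::extractAt(
      genome[[c_name]],
      IRanges::IRanges(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
  }
  do.call(c, lapply(out, Biostrings::DNAStringSet))
}

#' Read a per-base signal track from TSV
#'
#' Text dialect for genome-wide signal tracks (the same information a bigWig
#' carries): columns `chrom start end value`, 0-based half-open, uncovered
#' bases simply absent.
#'
#' @param path TSV file, with or without header.
#' @return `GRanges` with a `score` column.
#' @export
read_track_tsv <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end),
                         score = as.numeric(dt$value))
}

#' Mean track signal over covered element bases
#'
#' For each element, the mean of the track value over bases that are both in
#' the element and covered by the track; elements with zero covered bases get
#' NA (later imputed to 0).
#'
#' @param es an `element_set`
#' @param track `GRanges` with `score` (see [read_track_tsv()])
#' @return named numeric vector over elements
#' @export
mean_track_signal <- function(es, track) {
  ids <- es$info$element_id
  hits <- GenomicRanges::findOverlaps(es$gr, track, ignore.strand = TRUE)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  if (length(hits) == 0) return(out)
  ov <- GenomicRanges::pintersect(es$gr[S4Vectors::queryHits(hits)],
                                  track[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  v <- S4Vectors::mcols(track)$score[S4Vectors::subjectHits(hits)]
  eid <- S4Vectors::mcols(es$gr)$element_id[S4Vectors::queryHits(hits)]
  num <- tapply(w * v, eid, sum)
  den <- tapply(w, eid, sum)
  out[names(num)] <- as.numeric(num) / as.numeric(den)
  out
}

#' Fraction of element bases intersecting a peak set
#'
#' @param es an `element_set`
#' @param peaks a `region_mask` or `GRanges` of peaks (e.g. ChIP-seq narrow
#'   peaks read from BED3)
#' @return named numeric vector in [0,1]; NA for elements with zero
#'   effective length
#' @export
overlap_fraction <- function(es, peaks) {
  if (inherits(peaks, "region_mask")) peaks <- peaks$gr
  peaks <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  ids <- es$info$element_id
  eff <- setNames(es$info$effective_length, ids)
  hits <- GenomicRanges::findOverlaps(es$gr, peaks, ignore.strand = TRUE)
  bp <- setNames(rep(0, length(ids)), ids)
  if (length(hits) > 0) {
    ov <- GenomicRanges::pintersect(es$gr[S4Vectors::queryHits(hits)],
                                    peaks[S4Vectors::subjectHits(hits)])
    eid <- S4Vectors::mcols(es$gr)$element_id[S4Vectors::queryHits(hits)]
    s <- tapply(GenomicRanges::width(ov), eid, sum)
    bp[names(s)] <- as.numeric(s)
  }
  ifelse(eff > 0, bp / eff, NA_real_)
}

#' Assemble a feature matrix for an element set
#'
#' Convenience wrapper combining k-mer content, mean track signals and peak
#' overlap fractions into one matrix (rows = elements). No imputation or
#' scaling is applied here; see [impute_and_scale()].
#'
#' @param es an `element_set`
#' @param genome optional `DNAStringSet` for k-mer features
#' @param k k-mer widths when `genome` is given
#' @param tracks named list of track `GRanges` (see [read_track_tsv()])
#' @param peaks named list of peak `GRanges`/`region_mask`
#' @return numeric matrix with rownames = element ids
#' @export
build_features <- function(es, genome = NULL, k = c(2L, 3L),
                           tracks = list(), peaks = list()) {
  parts <- list()
  if (!is.null(genome)) parts$kmer <- element_kmer_features(es, genome, k)
  for (nm in names(tracks)) {
    parts[[nm]] <- matrix(mean_track_signal(es, tracks[[nm]]),
                          dimnames = list(es$info$element_id, nm))
  }
  for (nm in names(peaks)) {
    parts[[paste0(nm, "_frac")]] <- matrix(overlap_fraction(es, peaks[[nm]]),
      dimnames = list(es$info$element_id, paste0(nm, "_frac")))
  }
  if (!length(parts)) stop("no feature sources given")
  do.call(cbind, parts)
}

#' Impute missing values and robust-scale features
#'
#' Missing values are filled with 0 first (on the raw scale); each feature is
#' then centered by its training median and divided by its training IQR
#' (Q3 - Q1, linear-interpolation quantiles). Features with zero IQR get
#' spread 1, so constant columns scale to all zeros. When `stats` is NULL the
#' scaler is fitted on the rows of `X` (training); pass the returned `stats`
#' to transform test rows with training statistics.
#'
#' Scaling is used only for the randomised-lasso / GLM path; the GBM consumes
#' the imputed, unscaled matrix.
#'
#' @param X numeric matrix (rows = elements, cols = features)
#' @param stats optional `scaling_stats` fitted on training rows
#' @return list with `X` (imputed, scaled matrix) and `stats`
#' @export
impute_and_scale <- function(X, stats = NULL) {
  X <- as.matrix(X)
  X[is.na(X)] <- 0
  if (is.null(stats)) {
    center <- apply(X, 2, median)
    q <- apply(X, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
    spread <- q[2, ] - q[1, ]
    spread[spread == 0] <- 1
    stats <- structure(list(center = center, spread = spread,
                            feature_names = colnames(X)),
                       class = "scaling_stats")
  } else {
    if (!identical(colnames(X), stats$feature_names)) {
      stop("feature names of X do not match the fitted scaling stats")
    }
  }
  Xs <- sweep(sweep(X, 2, stats$center, "-"), 2, stats$spread, "/")
  list(X = Xs, stats = stats)
}

#' Write / read a feature matrix as TSV
#'
#' Header row `element_id<TAB>feature1...`; one row per element.
#' @param X matrix with rownames = element ids
#' @param path file path
#' @export
write_feature_tsv <- function(X, path) {
  dt <- data.table::data.table(element_id = rownames(X))
  dt <- cbind(dt, data.table::as.data.table(X))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  X <- as.matrix(dt[, -1])
  rownames(X) <- dt[[1]]
  X
}
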