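#' @title Genomic element sets
#'
#' @description An element set is a named collection of genomic elements,
#' each element being the union of one or more intervals (for example, all
#' coding exons of one gene, or a promoter window). Coordinates follow the
#' BED convention (0-based, half-open) in all files; internally intervals
#' are held as `GRanges` (1-based, closed). Each element carries its raw
#' length and, after mask subtraction, its effective length L — the number
#' of callable bases actually at risk of mutation.
#'
#' @name element_set
NULL

.gr_from_bed0 <- function(chrom, start0, end0, element_id) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    element_id = element_id
  )
}

# normalize: per-element sorted, merged intervals
.normalize_element_gr <- function(gr) {
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, S4Vectors::mcols(gr)$element_id))
  flat <- unlist(grl, use.names = FALSE)
  S4Vectors::mcols(flat)$element_id <- rep(names(grl), S4Vectors::elementNROWS(grl))
  GenomicRanges::sort(flat, ignore.strand = TRUE)
}

.lengths_by_element <- function(gr, ids) {
  w <- tapply(GenomicRanges::width(gr), S4Vectors::mcols(gr)$element_id, sum)
  out <- setNames(rep(0, length(ids)), ids)
  out[names(w)] <- as.numeric(w)
  out
}

#' Construct an element set from intervals
#'
#' @param intervals a `GRanges` with an `element_id` metadata column, or a
#'   data.frame with columns `chrom`, `start` (0-based), `end` (exclusive),
#'   `element_id`.
#' @param name label for the set (e.g. "CDS", "training").
#' @return an object of class `element_set` with components `name`, `gr`
#'   (normalized masked intervals) and `info` (per-element table with
#'   `raw_length`, `effective_length`, `untestable`).
#' @export
element_set <- function(intervals, name = "elements") {
  if (is.data.frame(intervals)) {
    intervals <- .gr_from_bed0(intervals$chrom, intervals$start, intervals$end,
                               as.character(intervals$element_id))
  }
  stopifnot(is(intervals, "GRanges"), !is.null(S4Vectors::mcols(intervals)$element_id))
  gr <- .normalize_element_gr(intervals)
  ids <- unique(S4Vectors::mcols(gr)$element_id)
  len <- .lengths_by_element(gr, ids)
  info <- data.table::data.table(
    element_id = ids,
    raw_length = as.numeric(len[ids]),
    effective_length = as.numeric(len[ids]),
    untestable = len[ids] == 0
  )
  structure(list(name = name, gr = gr, info = info), class = "element_set")
}

#' @export
print.element_set <- function(x, ...) {
  cat(sprintf("element_set '%s': %d elements, %d intervals, %.0f bp (%.0f bp effective)\n",
              x$name, nrow(x$info), length(x$gr),
              sum(x$info$raw_length), sum(x$info$effective_length)))
  invisible(x)
}

#' Per-element summary table
#' @param es an `element_set`
#' @return data.table with element_id, raw_length, effective_length, untestable
#' @export
element_info <- function(es) data.table::copy(es$info)

#' Read an element set from a BED file
#'
#' Accepts BED4 (one interval per record, element id in column 4; several
#' records may share an id) or BED12 (blocks expanded to intervals).
#' Intervals of one element are merged and sorted.
#'
#' @param path BED file (tab-separated, no header).
#' @param name label for the set.
#' @return an `element_set`.
#' @export
load_elements <- function(path, name = basename(path)) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(bed) < 4) stop("BED file must have at least 4 columns (BED4): ", path)
  chrom <- as.character(bed[[1]])
  start0 <- suppressWarnings(as.integer(bed[[2]]))
  end0 <- suppressWarnings(as.integer(bed[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0 | start0 < 0)
  if (length(bad)) {
    stop(sprintf("malformed BED record at line %d of %s (need integer 0 <= start < end)",
                 bad[1], path))
  }
  id <- as.character(bed[[4]])
  if (ncol(bed) >= 12) {
    # BED12: expand blocks
    nblock <- as.integer(bed[[10]])
    sizes <- strsplit(sub(",$", "", as.character(bed[[11]])), ",", fixed = TRUE)
    offs <- strsplit(sub(",$", "", as.character(bed[[12]])), ",", fixed = TRUE)
    nb <- lengths(sizes)
    if (any(nb != nblock | lengths(offs) != nblock)) {
      stop("BED12 block counts inconsistent in ", path)
    }
    chrom <- rep(chrom, nb)
    id <- rep(id, nb)
    bstart <- rep(start0, nb) + as.integer(unlist(offs))
    bend <- bstart + as.integer(unlist(sizes))
    start0 <- bstart
    end0 <- bend
  }
  element_set(data.frame(chrom = chrom, start = start0, end = end0, element_id = id),
              name = name)
}

#' Write an element set as BED4
#' @param es an `element_set`
#' @param path output path
#' @export
write_bed_elements <- function(es, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(es$gr)),
    start = GenomicRanges::start(es$gr) - 1L,
    end = GenomicRanges::end(es$gr),
    element_id = S4Vectors::mcols(es$gr)$element_id
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Region masks
#'
#' A mask is a merged, sorted set of intervals with a polarity: `excluded`
#' regions are removed from every element before analysis (N-bases, blacklist,
#' low-mappability); a `callable` mask is its complement — only bases inside
#' it are kept.
#'
#' @param intervals `GRanges` or data.frame (`chrom`, `start` 0-based, `end`).
#' @param polarity `"excluded"` or `"callable"`.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(intervals, polarity = c("excluded", "callable")) {
  polarity <- match.arg(polarity)
  if (is.data.frame(intervals)) {
    intervals <- GenomicRanges::GRanges(intervals$chrom,
      IRanges::IRanges(intervals$start + 1L, intervals$end))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::sort(intervals, ignore.strand = TRUE),
                              ignore.strand = TRUE)
  structure(list(gr = gr, polarity = polarity), class = "region_mask")
}

#' Read a mask from BED3
#' @param path BED3 file
#' @param polarity `"excluded"` or `"callable"`
#' @export
read_region_mask <- function(path, polarity = c("excluded", "callable")) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  region_mask(data.frame(chrom = as.character(bed[[1]]), start = bed[[2]], end = bed[[3]]),
              polarity = match.arg(polarity))
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask (%s): %d intervals, %.0f bp\n", x$polarity,
              length(x$gr), sum(GenomicRanges::width(x$gr))))
  invisible(x)
}

#' Subtract excluded regions from every element
#'
#' All bases falling in the excluded regions are removed before any analysis;
#' the effective length of each element is updated. Elements losing all their
#' bases are retained but flagged untestable. With a `callable` mask, elements
#' are instead intersected with the callable space (same arithmetic on the
#' complement). Applying the same mask twice equals applying it once.
#'
#' @param es an `element_set`
#' @param mask a `region_mask`
#' @return a masked `element_set`
#' @export
apply_mask <- function(es, mask) {
  stopifnot(inherits(es, "element_set"), inherits(mask, "region_mask"))
  if (length(mask$gr) == 0 && mask$polarity == "excluded") return(es)
  if (mask$polarity == "excluded") {
    grl <- GenomicRanges::subtract(es$gr, mask$gr, ignore.strand = TRUE)
    flat <- unlist(grl, use.names = FALSE)
    S4Vectors::mcols(flat)$element_id <-
      rep(S4Vectors::mcols(es$gr)$element_id, S4Vectors::elementNROWS(grl))
  } else {
    hits <- GenomicRanges::findOverlaps(es$gr, mask$gr, ignore.strand = TRUE)
    flat <- GenomicRanges::pintersect(
      es$gr[S4Vectors::queryHits(hits)], mask$gr[S4Vectors::subjectHits(hits)])
    S4Vectors::mcols(flat) <- S4Vectors::mcols(es$gr[S4Vectors::queryHits(hits)])
  }
  flat <- flat[GenomicRanges::width(flat) > 0]
  out <- es
  out$gr <- GenomicRanges::sort(flat, ignore.strand = TRUE)
  eff <- .lengths_by_element(out$gr, es$info$element_id)
  out$info <- data.table::copy(es$info)
  out$info[, `:=`(effective_length = as.numeric(eff[element_id]),
                  untestable = eff[element_id] == 0)]
  out
}

#' Tile chromosomes into fixed-width bins
#'
#' Consecutive non-overlapping bins of constant width per chromosome;
#' trailing partial bins are dropped, so every bin has identical length.
#'
#' @param chrom_sizes named numeric vector of chromosome sizes (bp), or a
#'   two-column data.frame (chrom, size) as read by [read_chrom_sizes()].
#' @param width bin width in bp (default 1e6).
#' @param chroms optional character vector restricting which chromosomes
#'   are binned (e.g. autosomes only).
#' @return an `element_set` of bins with ids `<chrom>.bin<k>`.
#' @export
make_fixed_bins <- function(chrom_sizes, width = 1e6, chroms = NULL) {
  stopifnot(width > 0)
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  }
  if (!is.null(chroms)) chrom_sizes <- chrom_sizes[names(chrom_sizes) %in% chroms]
  recs <- lapply(names(chrom_sizes), function(ch) {
    nb <- floor(chrom_sizes[[ch]] / width)
    if (nb < 1) return(NULL)
    k <- seq_len(nb) - 1
    data.frame(chrom = ch, start = k * width, end = (k + 1) * width,
               element_id = sprintf("%s.bin%d", ch, k + 1))
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    return(element_set(GenomicRanges::GRanges(element_id = character(0)), name = "bins"))
  }
  element_set(recs, name = "bins")
}

#' Read a UCSC-style .chrom.sizes file
#' @param path two-column TSV: chrom, size
#' @return named numeric vector
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Sample neutral training elements from callable space
#'
#' Training elements for the BMR model are random single-interval regions:
#' each length is drawn with replacement from the pooled raw-length
#' distribution of the test elements and multiplied by `length_factor`;
#' a chromosome is drawn with probability proportional to its callable bp,
#' and a start is drawn uniformly over callable runs long enough to hold the
#' element. Candidates overlapping any test element are rejected and
#' redrawn; sampling is deterministic under `seed`.
#'
#' @param test_sets a single `element_set` or list of them.
#' @param callable a `region_mask` with polarity `"callable"`.
#' @param n number of training elements to produce.
#' @param length_factor multiplier on drawn lengths (default 3).
#' @param seed integer seed.
#' @param max_tries total draw budget (default `100 * n`); exceeded means
#'   the callable space is too small and an error is raised.
#' @return an `element_set` named "training".
#' @export
sample_training_elements <- function(test_sets, callable, n, length_factor = 3,
                                     seed = 1, max_tries = 100 * n) {
  stopifnot(n > 0, inherits(callable, "region_mask"), callable$polarity == "callable")
  if (inherits(test_sets, "element_set")) test_sets <- list(test_sets)
  pool <- unlist(lapply(test_sets, function(s) s$info$raw_length))
  pool <- pool[pool > 0]
  if (!length(pool)) stop("pooled test-element length distribution is empty")
  test_gr <- GenomicRanges::reduce(do.call(c, lapply(test_sets, function(s) {
    g <- s$gr; S4Vectors::mcols(g) <- NULL; g
  })), ignore.strand = TRUE)
  runs <- callable$gr
  run_chrom <- as.character(GenomicRanges::seqnames(runs))
  run_start <- GenomicRanges::start(runs)
  run_w <- GenomicRanges::width(runs)

  withr::with_seed(seed, {
    out <- vector("list", n)
    accepted <- 0L
    tries <- 0L
    while (accepted < n) {
      if (tries >= max_tries) {
        stop(sprintf("could not place %d training elements in %d tries; callable space too small",
                     n, tries))
      }
      tries <- tries + 1L
      len <- round(length_factor * sample(pool, 1))
      # valid start positions per run for this length
      slots <- pmax(0, run_w - len + 1)
      tot <- sum(slots)
      if (tot == 0) next
      ri <- sample.int(length(runs), 1, prob = slots)
      st <- run_start[ri] + sample.int(slots[ri], 1) - 1L   # 1-based start
      cand <- GenomicRanges::GRanges(run_chrom[ri], IRanges::IRanges(st, st + len - 1L))
      if (length(GenomicRanges::findOverlaps(cand, test_gr, ignore.strand = TRUE)) > 0) next
      accepted <- accepted + 1L
      out[[accepted]] <- data.frame(chrom = run_chrom[ri], start = st - 1L,
                                    end = st - 1L + len,
                                    element_id = sprintf("train%06d", accepted))
    }
    element_set(do.call(rbind, out), name = "training")
  })
}
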