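#' @title Somatic mutation catalogs
#'
#' @description Somatic SNVs and indels are consumed as a simple tab-separated
#' table (`chrom pos0 ref alt donor_id`, 0-based positions — the fields
#' extractable from any VCF/MAF). Counting against an element set yields, per
#' element, the observed mutation count y and the number of distinct mutated
#' donors n_d, with the cohort size N fixed by the donor roster (donors with
#' zero mutations still count toward N).
#'
#' @name mutations
NULL

#' Read a mutation table
#'
#' Expected columns (header optional): `chrom`, `pos0` (0-based), `ref`,
#' `alt`, `donor_id`. An `is_indel` flag is derived from allele lengths when
#' absent.
#'
#' @param path TSV file
#' @return data.table of mutation records
#' @export
read_mutations <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, seq_len(5), c("chrom", "pos0", "ref", "alt", "donor_id"))
  dt[, chrom := as.character(chrom)]
  dt[, donor_id := as.character(donor_id)]
  if (!"is_indel" %in% names(dt)) {
    dt[, is_indel := nchar(ref) != 1L | nchar(alt) != 1L]
  }
  if (any(dt$pos0 < 0)) stop("negative mutation position")
  if (any(dt$ref == dt$alt)) stop("ref == alt in mutation table")
  dt[]
}

#' Convert single-sample VCF records to the mutation table dialect
#'
#' Minimal converter: takes `CHROM POS REF ALT` (1-based VCF positions) plus
#' a donor id, returns the 0-based table used throughout.
#'
#' @param vcf data.frame with columns CHROM, POS, REF, ALT
#' @param donor_id donor label for all records
#' @return data.table mutation records
#' @export
mutations_from_vcf <- function(vcf, donor_id) {
  data.table::data.table(
    chrom = as.character(vcf$CHROM), pos0 = as.integer(vcf$POS) - 1L,
    ref = as.character(vcf$REF), alt = as.character(vcf$ALT),
    donor_id = donor_id,
    is_indel = nchar(as.character(vcf$REF)) != 1L | nchar(as.character(vcf$ALT)) != 1L
  )
}

#' Count mutations per element
#'
#' A mutation is counted for every element whose masked intervals contain its
#' position (0-based; half-open element ends excluded). Indels are assigned
#' by their start position and contribute one count. Donors whose
#' genome-wide burden exceeds `hypermut_per_mb` mutations per Mb (requires
#' `genome_mb`) are excluded from the roster before counting — the
#' hypermutator filter.
#'
#' @param mutations data.table of mutation records (see [read_mutations()])
#' @param es a (masked) `element_set`
#' @param donors optional character vector: the full cohort roster. Defaults
#'   to the donors present in `mutations`; pass explicitly so that donors
#'   with zero mutations still count toward N.
#' @param hypermut_per_mb hypermutator threshold (default 30 mutations/Mb)
#' @param genome_mb callable genome size in Mb used for the hypermutator
#'   filter; NULL disables the filter.
#' @return object of class `mutation_catalog`: list with `counts`
#'   (data.table element_id, y, n_d, L), `N`, `donors`, and the retained
#'   mutation table with an `element_id` column (`hits`).
#' @export
count_mutations <- function(mutations, es, donors = NULL,
                            hypermut_per_mb = 30, genome_mb = NULL) {
  mutations <- data.table::as.data.table(mutations)
  if (is.null(donors)) donors <- sort(unique(mutations$donor_id))
  if (!is.null(genome_mb)) {
    burden <- mutations[, .N, by = donor_id]
    hyper <- burden[N / genome_mb > hypermut_per_mb, donor_id]
    if (length(hyper)) {
      mutations <- mutations[!donor_id %in% hyper]
      donors <- setdiff(donors, hyper)
    }
  } else {
    mutations <- mutations[donor_id %in% donors]
  }
  known <- as.character(unique(GenomicRanges::seqnames(es$gr)))
  unknown <- setdiff(unique(mutations$chrom), known)
  if (length(unknown)) {
    warning("skipping mutations on chromosomes absent from the element set: ",
            paste(head(unknown, 5), collapse = ", "))
    mutations <- mutations[chrom %in% known]
  }
  mgr <- GenomicRanges::GRanges(mutations$chrom,
                                IRanges::IRanges(mutations$pos0 + 1L, mutations$pos0 + 1L))
  hits <- GenomicRanges::findOverlaps(mgr, es$gr, ignore.strand = TRUE)
  hit_dt <- data.table::data.table(
    mutations[S4Vectors::queryHits(hits)],
    element_id = S4Vectors::mcols(es$gr)$element_id[S4Vectors::subjectHits(hits)]
  )
  agg <- hit_dt[, .(y = .N, n_d = data.table::uniqueN(donor_id)), by = element_id]
  counts <- data.table::data.table(element_id = es$info$element_id,
                                   L = es$info$effective_length)
  counts <- merge(counts, agg, by = "element_id", all.x = TRUE, sort = FALSE)
  counts[is.na(y), y := 0L]
  counts[is.na(n_d), n_d := 0L]
  data.table::setcolorder(counts, c("element_id", "y", "n_d", "L"))
  structure(list(counts = counts[], N = length(donors), donors = donors,
                 hits = hit_dt[]),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog: %d elements, N = %d donors, %d counted mutations (mean y = %.2f)\n",
              nrow(x$counts), x$N, sum(x$counts$y), mean(x$counts$y)))
  invisible(x)
}

# internal: align a catalog to a set of element ids, dropping untestable rows
.catalog_table <- function(catalog, testable_only = TRUE) {
  ct <- catalog$counts
  if (testable_only) ct <- ct[L > 0]
  ct
}
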