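#' @title Functional impact scores
#'
#' @description Raw per-mutation functional impact scores (from external
#' scoring schemes such as CADD-, DANN-, EIGEN- or LINSIGHT-style models)
#' are converted to phred-like scores by ranking all scored mutations of the
#' cohort: phred = -10*log10(rank / N_m), rank 1 being the most impactful
#' mutation, so a phred of 20 marks the top 1%. Per element and scheme, the
#' element score S is the mean over mutated donors of each donor's mean
#' phred score, and the functional weight w = mean_schemes(S / S_T) with
#' S_T = -10*log10(F) encoding the assumed fraction F of functionally
#' relevant variants.
#'
#' @name functional
NULL

#' Phred-like rank transform of raw scores
#'
#' @param raw numeric vector of raw scores for one scheme over all scored
#'   mutations of the cohort; higher = more impactful. Ties receive the
#'   average of their ranks.
#' @return numeric vector of phred-like scores, -10*log10(rank / N_m);
#'   the worst-ranked mutation scores 0.
#' @export
phred_rank_transform <- function(raw) {
  if (!length(raw)) stop("cannot rank an empty score vector")
  rk <- rank(-raw, ties.method = "average")
  -10 * log10(rk / length(raw))
}

#' Derived threshold score from the functional-variant fraction
#' @param F assumed fraction of functionally relevant variants, in (0,1)
#' @return S_T = -10*log10(F)
#' @export
threshold_score <- function(F) {
  stopifnot(F > 0, F < 1)
  -10 * log10(F)
}

#' Per-element functional score for one scheme
#'
#' For each element, each mutated donor i contributes s_i, the mean phred
#' score of that donor's scored mutations in the element; the element score
#' S is the mean of s_i over donors contributing at least one scored
#' mutation. Invariant under permutation of donors and mutations.
#'
#' @param scored data.frame/data.table with columns `element_id`,
#'   `donor_id`, `phred` — one row per scored mutation falling in an element
#' @return data.table `element_id`, `S`, `n_scored`
#' @export
element_functional_score <- function(scored) {
  dt <- data.table::as.data.table(scored)
  if (!nrow(dt)) return(data.table::data.table(element_id = character(0),
                                               S = numeric(0), n_scored = integer(0)))
  per_donor <- dt[, .(s_i = mean(phred), n = .N), by = .(element_id, donor_id)]
  per_donor[, .(S = mean(s_i), n_scored = sum(n)), by = element_id]
}

#' Combine per-scheme element scores into a functional weight
#'
#' w = mean over available schemes of S_scheme / S_T. Schemes with no scored
#' mutation in an element are simply absent from the mean.
#'
#' @param S_schemes numeric vector of per-scheme S values for one element
#'   (NA / missing schemes dropped)
#' @param S_T threshold score, must be > 0 (see [threshold_score()])
#' @return combined weight w
#' @export
combine_schemes <- function(S_schemes, S_T) {
  if (S_T <= 0) stop("S_T must be > 0")
  S_schemes <- S_schemes[!is.na(S_schemes)]
  if (!length(S_schemes)) return(NA_real_)
  mean(S_schemes / S_T)
}

#' Read a per-mutation raw-score table
#'
#' Dialect: `chrom pos0 ref alt scheme raw_score` (header optional).
#' Mutations without a score under a scheme are absent, not zero.
#'
#' @param path TSV file
#' @return data.table
#' @export
read_raw_scores <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, seq_len(6),
                       c("chrom", "pos0", "ref", "alt", "scheme", "raw_score"))
  dt[, chrom := as.character(chrom)][]
}

#' Per-element functional impact across schemes
#'
#' Joins the cohort's counted mutations (catalog `hits`) with the raw score
#' table, rank-transforms each scheme over all scored mutations of the
#' cohort (the ranking universe is cohort-wide, not per element), aggregates
#' to per-element scores and combines schemes into the functional weight
#' w = mean(S / S_T). Elements with no scored mutation get w = 1 so that the
#' functional adjustment is a no-op rather than a penalty for missing
#' annotation.
#'
#' @param catalog a `mutation_catalog` (its `hits` table links mutations to
#'   elements)
#' @param raw_scores data.table `chrom pos0 ref alt scheme raw_score`
#' @param F assumed fraction of functionally relevant variants (default 0.01,
#'   i.e. S_T = 20)
#' @param mutations optional full cohort mutation table; when given, the
#'   ranking universe (N_m) is every scored observed mutation of the cohort,
#'   not only mutations falling inside elements. Defaults to the catalog's
#'   in-element mutations.
#' @return object of class `element_impact`: data.table with `element_id`,
#'   one `S_<scheme>` column per scheme, `S_combined`, and `w`
#' @export
functional_impact <- function(catalog, raw_scores, F = 0.01, mutations = NULL) {
  S_T <- threshold_score(F)
  scores <- data.table::as.data.table(raw_scores)
  hits <- catalog$hits
  if (is.null(hits)) stop("catalog carries no per-mutation hit table")
  universe <- if (is.null(mutations)) {
    hits[, .(chrom, pos0, ref, alt)]
  } else {
    data.table::as.data.table(mutations)[, .(chrom, pos0, ref, alt)]
  }
  out <- data.table::data.table(element_id = catalog$counts$element_id)
  schemes <- sort(unique(scores$scheme))
  s_cols <- character(0)
  for (sc in schemes) {
    sub <- scores[scheme == sc]
    # rank over ALL scored observed mutations of the cohort under this
    # scheme, one entry per occurrence (recurrent variants count each time;
    # average ranking gives equal phred to identical raw scores)
    uni <- merge(universe, sub, by = c("chrom", "pos0", "ref", "alt"))
    if (!nrow(uni)) next
    uni[, phred := phred_rank_transform(raw_score)]
    keyed <- unique(uni[, .(chrom, pos0, ref, alt, phred)])
    sub2 <- merge(hits[, .(chrom, pos0, ref, alt, donor_id, element_id)],
                  keyed, by = c("chrom", "pos0", "ref", "alt"))
    if (!nrow(sub2)) next
    es <- element_functional_score(sub2[, .(element_id, donor_id, phred)])
    col <- paste0("S_", sc)
    s_cols <- c(s_cols, col)
    out <- merge(out, setNames(es[, .(element_id, S)], c("element_id", col)),
                 by = "element_id", all.x = TRUE, sort = FALSE)
  }
  if (length(s_cols)) {
    out[, w := apply(.SD, 1, combine_schemes, S_T = S_T), .SDcols = s_cols]
    out[, S_combined := rowMeans(.SD, na.rm = TRUE), .SDcols = s_cols]
    out[is.nan(S_combined), S_combined := NA_real_]
  } else {
    out[, w := NA_real_]
    out[, S_combined := NA_real_]
  }
  out[is.na(w), w := 1]
  structure(out[], class = c("element_impact", class(out)))
}
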