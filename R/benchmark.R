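#' @title Benchmarking driver call sets
#'
#' @description Driver candidates from several methods are compared with
#' reference lists using precision, a lower-bound recall and F1. Because the
#' full set of true drivers per cohort is unknown, the recall denominator is
#' approximated from below: for coding elements, by the union of every
#' method's true positives against a gold-standard gene list; for non-coding
#' elements, true positives are elements called by at least `agreement_k`
#' methods. Calls mutated in fewer than three samples are removed first.
#'
#' @name benchmark
NULL

#' Remove low-recurrence driver calls
#'
#' @param calls data.table with columns `method`, `cohort`, `element_id`,
#'   `n_samples` (number of mutated samples behind the call)
#' @param min_samples minimum mutated samples (default 3)
#' @return filtered data.table
#' @export
filter_recurrence <- function(calls, min_samples = 3) {
  dt <- data.table::as.data.table(calls)
  dt[n_samples >= min_samples]
}

# micro (pool counts over cohorts) or macro (average per-cohort metrics)
.pool_metrics <- function(tab, pooling) {
  if (pooling == "micro") {
    agg <- tab[, .(TP = sum(TP), FP = sum(FP), FN = sum(FN)), by = method]
    agg[, precision := ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)]
    agg[, recall := ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)]
  } else {
    tab[, precision := ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)]
    tab[, recall := ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)]
    agg <- tab[, .(TP = sum(TP), FP = sum(FP), FN = sum(FN),
                   precision = mean(precision, na.rm = TRUE),
                   recall = mean(recall, na.rm = TRUE)), by = method]
  }
  agg[, F1 := ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
                     2 * precision * recall / (precision + recall), 0)]
  agg[]
}

#' Benchmark coding calls against a gold-standard gene list
#'
#' True positives are called genes present in the gold standard. Precision
#' is TP / called. The recall denominator per cohort is the union over
#' methods of their true-positive genes (a lower bound on the unknown driver
#' set); cohorts are pooled by summing TP/FP/FN before forming ratios
#' (micro-average; macro averages per-cohort metrics instead).
#'
#' @param calls recurrence-filtered data.table (`method`, `cohort`,
#'   `element_id`)
#' @param gold character vector of gold-standard identifiers
#' @param pooling "micro" (default) or "macro"
#' @return data.table per method: TP, FP, FN, precision, recall, F1
#' @export
coding_benchmark <- function(calls, gold, pooling = c("micro", "macro")) {
  pooling <- match.arg(pooling)
  dt <- unique(data.table::as.data.table(calls)[, .(method, cohort, element_id)])
  if (!length(gold)) stop("empty reference set")
  dt[, tp := element_id %in% gold]
  per <- dt[, .(called = .N, TP = sum(tp)), by = .(method, cohort)]
  union_tp <- dt[tp == TRUE, .(union_n = data.table::uniqueN(element_id)), by = cohort]
  grid <- data.table::CJ(method = unique(dt$method), cohort = unique(dt$cohort))
  per <- merge(grid, per, by = c("method", "cohort"), all.x = TRUE)
  per[is.na(called), `:=`(called = 0L, TP = 0L)]
  per <- merge(per, union_tp, by = "cohort", all.x = TRUE)
  per[is.na(union_n), union_n := 0L]
  per[, `:=`(FP = called - TP, FN = union_n - TP)]
  .pool_metrics(per, pooling)
}

#' Benchmark non-coding calls by cross-method agreement
#'
#' With no gold standard for non-coding elements, per-cohort true positives
#' are elements called by at least `agreement_k` methods; precision, recall
#' and F1 then follow the coding protocol.
#'
#' @param calls recurrence-filtered data.table (`method`, `cohort`,
#'   `element_id`)
#' @param agreement_k methods required for an element to count as a true
#'   positive (default 3)
#' @param pooling "micro" (default) or "macro"
#' @return data.table per method: TP, FP, FN, precision, recall, F1
#' @export
consensus_benchmark <- function(calls, agreement_k = 3,
                                pooling = c("micro", "macro")) {
  pooling <- match.arg(pooling)
  dt <- unique(data.table::as.data.table(calls)[, .(method, cohort, element_id)])
  support <- dt[, .(n_methods = data.table::uniqueN(method)),
                by = .(cohort, element_id)]
  tp_set <- support[n_methods >= agreement_k]
  dt <- merge(dt, tp_set[, .(cohort, element_id, tp = TRUE)],
              by = c("cohort", "element_id"), all.x = TRUE)
  dt[is.na(tp), tp := FALSE]
  per <- dt[, .(called = .N, TP = sum(tp)), by = .(method, cohort)]
  union_tp <- tp_set[, .(union_n = .N), by = cohort]
  grid <- data.table::CJ(method = unique(dt$method), cohort = unique(dt$cohort))
  per <- merge(grid, per, by = c("method", "cohort"), all.x = TRUE)
  per[is.na(called), `:=`(called = 0L, TP = 0L)]
  per <- merge(per, union_tp, by = "cohort", all.x = TRUE)
  per[is.na(union_n), union_n := 0L]
  per[, `:=`(FP = called - TP, FN = union_n - TP)]
  .pool_metrics(per, pooling)
}

#' Read a two/three-column call-set or reference TSV
#'
#' Dialect: `cohort element_id [n_samples]`, header optional.
#' @param path TSV file
#' @param method method label attached to every row
#' @return data.table `method`, `cohort`, `element_id`, `n_samples`
#' @export
read_callset <- function(path, method) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, seq_len(min(3, ncol(dt))),
                       c("cohort", "element_id", "n_samples")[seq_len(min(3, ncol(dt)))])
  if (!"n_samples" %in% names(dt)) dt[, n_samples := NA_integer_]
  dt[, method := method]
  dt[, .(method, cohort = as.character(cohort),
         element_id = as.character(element_id), n_samples)]
}
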