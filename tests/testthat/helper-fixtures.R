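# Shared fixtures: tiny element sets, toy genomes and brute-force per-base
# oracles used to cross-check the interval arithmetic.

toy_elements <- function(df = NULL, name = "toy") {
  if (is.null(df)) {
    df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(10, 50, 0), end = c(30, 80, 100),
                     element_id = c("e1", "e1", "e2"))
  }
  element_set(df, name = name)
}

write_temp_bed <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = envir)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  path
}

# per-base membership of a 0-based half-open interval table on a toy genome
bases_of <- function(df) {
  unlist(lapply(seq_len(nrow(df)), function(i) {
    if (df$end[i] <= df$start[i]) return(character(0))
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1))
  }))
}

# brute-force per-base mean signal over one element (track: chrom,start,end,value)
bf_mean_signal <- function(elem_df, track_df) {
  vals <- c()
  for (i in seq_len(nrow(elem_df))) {
    for (p in seq(elem_df$start[i], elem_df$end[i] - 1)) {
      covered <- track_df$chrom == elem_df$chrom[i] & track_df$start <= p & p < track_df$end
      if (any(covered)) vals <- c(vals, track_df$value[which(covered)[1]])
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# brute-force quadratic-time BH step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) m * p[o[j]] / j, 0))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# small simulated catalog + aligned feature matrix for model tests
toy_catalog <- function(y, L, N = 100, ids = sprintf("e%03d", seq_along(y))) {
  counts <- data.table::data.table(element_id = ids, y = y,
                                   n_d = pmin(y, N), L = L)
  structure(list(counts = counts, N = N,
                 donors = sprintf("d%03d", seq_len(N)), hits = NULL),
            class = "mutation_catalog")
}
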