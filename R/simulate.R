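#' @title Synthetic cohorts with known ground truth
#'
#' @description Generates a complete, self-contained study: test and training
#' element sets on synthetic chromosomes, a covariate feature matrix with a
#' known log-linear effect on the mutation rate, a somatic mutation table
#' drawn Poisson or NB2 around the implied rates, per-scheme raw functional
#' scores, and a truth record with every generated parameter. Optional
#' "spiked" driver elements receive a rate fold-change and an upward shift
#' of their mutations' raw scores, so burden and functional stages can both
#' be validated against known positives.
#'
#' @name synthetic
NULL

#' Configuration of a synthetic cohort
#'
#' Defaults emulate a moderately mutated adult solid-tumour cohort: 200
#' donors, ~4 kb elements (log-normal lengths), a background rate of 8
#' mutations per Mb per donor modulated log-linearly by 10 standard-normal
#' features, and Poisson counts (no overdispersion). Training elements are
#' 3x longer, as neutral training regions are in practice.
#'
#' @param n_elements test elements (default 5000)
#' @param n_train training elements (default `n_elements`)
#' @param n_donors cohort size N (default 200)
#' @param length_meanlog,length_sdlog log-normal element length parameters
#'   (defaults log(4000), 0.5)
#' @param min_length floor on element length in bp (default 200)
#' @param train_length_factor multiplier on training-element lengths
#'   (default 3)
#' @param n_features number of covariates (default 10)
#' @param effects numeric vector of true log-rate coefficients (padded with
#'   zeros to `n_features`); default `c(0.5, -0.4, 0.3, -0.2, 0.1, 0, ...)`
#' @param mu0 background mutation rate per bp per donor (default 8e-6,
#'   i.e. 8 mutations/Mb/donor)
#' @param theta NB2 dispersion of counts; 0 gives Poisson (default 0)
#' @param n_drivers number of spiked driver elements (default 0)
#' @param driver_fold rate fold-change of spiked elements (default 5, must
#'   be > 1 when spiking)
#' @param driver_score_shift upward shift (in raw-score standard deviations)
#'   of spiked elements' mutation scores (default 2)
#' @param schemes names of functional scoring schemes (default two schemes)
#' @param score_sd raw-score noise standard deviation (default 1)
#' @param indel_frac fraction of mutations emitted as 2-bp indels
#'   (default 0.05)
#' @param donor_burden_sd log-normal spread of per-donor burden multipliers;
#'   0 assigns donors uniformly (default 0)
#' @param seed root seed for the cohort (default 1)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_elements = 5000, n_train = n_elements,
                       n_donors = 200, length_meanlog = log(4000),
                       length_sdlog = 0.5, min_length = 200,
                       train_length_factor = 3, n_features = 10,
                       effects = c(0.5, -0.4, 0.3, -0.2, 0.1),
                       mu0 = 8e-6, theta = 0, n_drivers = 0,
                       driver_fold = 5, driver_score_shift = 2,
                       schemes = c("schemeA", "schemeB"), score_sd = 1,
                       indel_frac = 0.05, donor_burden_sd = 0, seed = 1) {
  stopifnot(n_elements > 0, n_donors > 0, theta >= 0, mu0 > 0)
  if (n_drivers > 0 && driver_fold <= 1) stop("driver_fold must exceed 1 for spiked drivers")
  effects <- c(effects, rep(0, max(0, n_features - length(effects))))[seq_len(n_features)]
  structure(as.list(environment()), class = "sim_config")
}

# lay single-interval elements end to end with fixed gaps on synthetic chroms
.place_elements <- function(lengths, prefix, gap = 1000, chrom_max = 6e7) {
  n <- length(lengths)
  chrom <- character(n); start <- numeric(n)
  cur_chrom <- 1L; cur_pos <- gap
  for (i in seq_len(n)) {
    if (cur_pos + lengths[i] + gap > chrom_max) {
      cur_chrom <- cur_chrom + 1L
      cur_pos <- gap
    }
    chrom[i] <- sprintf("%s%d", prefix, cur_chrom)
    start[i] <- cur_pos
    cur_pos <- cur_pos + lengths[i] + gap
  }
  data.frame(chrom = chrom, start = start, end = start + lengths)
}

#' Simulate a cohort
#'
#' Per element i, the neutral rate is lambda_i = N * L_i * mu0 *
#' exp(x_i . effects); counts are Poisson(lambda) (theta = 0) or
#' NB2(lambda, theta), with the rate multiplied by `driver_fold` for spiked
#' elements. Mutations are placed uniformly on element bases, each assigned
#' an independent uniform donor (so the mutated-donor count follows the
#' occupancy of y balls in N bins), and each unique variant receives one raw
#' score per scheme, shifted upward by `driver_score_shift` standard
#' deviations inside spiked elements. Identical seeds give byte-identical
#' outputs.
#'
#' @param cfg a [sim_config()]
#' @return list with `elements`, `training` (element sets), `X`, `X_train`
#'   (feature matrices), `mutations`, `raw_scores`, `donors`, `chrom_sizes`,
#'   and `truth` (every generated parameter, incl. per-element rates and
#'   driver ids)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    donors <- sprintf("donor%04d", seq_len(cfg$n_donors))
    donor_w <- if (cfg$donor_burden_sd > 0) {
      w <- stats::rlnorm(cfg$n_donors, -cfg$donor_burden_sd^2 / 2, cfg$donor_burden_sd)
      w / sum(w)
    } else rep(1 / cfg$n_donors, cfg$n_donors)

    len_test <- pmax(cfg$min_length,
                     round(stats::rlnorm(cfg$n_elements, cfg$length_meanlog,
                                         cfg$length_sdlog)))
    len_train <- cfg$train_length_factor *
      pmax(cfg$min_length, round(stats::rlnorm(cfg$n_train, cfg$length_meanlog,
                                               cfg$length_sdlog)))
    test_df <- .place_elements(len_test, "sim")
    test_df$element_id <- sprintf("elem%05d", seq_len(cfg$n_elements))
    train_df <- .place_elements(len_train, "simT")
    train_df$element_id <- sprintf("train%05d", seq_len(cfg$n_train))
    elements <- element_set(test_df, name = "test")
    training <- element_set(train_df, name = "training")

    X <- matrix(rnorm(cfg$n_elements * cfg$n_features), cfg$n_elements,
                dimnames = list(test_df$element_id,
                                sprintf("feat%02d", seq_len(cfg$n_features))))
    X_train <- matrix(rnorm(cfg$n_train * cfg$n_features), cfg$n_train,
                      dimnames = list(train_df$element_id,
                                      sprintf("feat%02d", seq_len(cfg$n_features))))

    driver_idx <- if (cfg$n_drivers > 0) {
      sort(sample.int(cfg$n_elements, cfg$n_drivers))
    } else integer(0)
    fold <- rep(1, cfg$n_elements)
    fold[driver_idx] <- cfg$driver_fold

    lam_test <- cfg$n_donors * len_test * cfg$mu0 * exp(drop(X %*% cfg$effects)) * fold
    lam_train <- cfg$n_donors * len_train * cfg$mu0 * exp(drop(X_train %*% cfg$effects))
    draw_counts <- function(lam) {
      if (cfg$theta > 0) rnbinom(length(lam), size = 1 / cfg$theta, mu = lam)
      else rpois(length(lam), lam)
    }
    y_test <- draw_counts(lam_test)
    y_train <- draw_counts(lam_train)

    place_mutations <- function(df, lens, y) {
      idx <- rep(seq_along(y), y)
      if (!length(idx)) return(data.table::data.table())
      off <- floor(runif(length(idx)) * lens[idx])
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, length(idx), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      indel <- runif(length(idx)) < cfg$indel_frac
      ref[indel] <- paste0(ref[indel], sample(bases, sum(indel), replace = TRUE))
      data.table::data.table(
        chrom = df$chrom[idx], pos0 = as.integer(df$start[idx] + off),
        ref = ref, alt = alt,
        donor_id = sample(donors, length(idx), replace = TRUE, prob = donor_w),
        is_indel = indel, element_id = df$element_id[idx])
    }
    mut_test <- place_mutations(test_df, len_test, y_test)
    mut_train <- place_mutations(train_df, len_train, y_train)
    mutations <- rbind(mut_test, mut_train)

    # one raw score per unique variant per scheme; spiked elements' variants
    # are shifted on the raw scale so the rank transform is exercised honestly
    raw_scores <- data.table::data.table()
    if (length(cfg$schemes) && nrow(mutations)) {
      uniq <- unique(mutations[, .(chrom, pos0, ref, alt, element_id)])
      shift <- ifelse(uniq$element_id %in% test_df$element_id[driver_idx],
                      cfg$driver_score_shift * cfg$score_sd, 0)
      raw_scores <- data.table::rbindlist(lapply(cfg$schemes, function(sc) {
        data.table::data.table(chrom = uniq$chrom, pos0 = uniq$pos0,
                               ref = uniq$ref, alt = uniq$alt, scheme = sc,
                               raw_score = rnorm(nrow(uniq), shift, cfg$score_sd))
      }))
    }

    chrom_sizes <- c(
      tapply(test_df$end + 1000, test_df$chrom, max),
      tapply(train_df$end + 1000, train_df$chrom, max))

    list(elements = elements, training = training, X = X, X_train = X_train,
         mutations = mutations[, .(chrom, pos0, ref, alt, donor_id, is_indel)],
         raw_scores = raw_scores, donors = donors,
         chrom_sizes = setNames(as.numeric(chrom_sizes), names(chrom_sizes)),
         truth = list(config = unclass(cfg), lambda_test = lam_test,
                      lambda_train = lam_train, y_test = y_test,
                      y_train = y_train,
                      driver_ids = test_df$element_id[driver_idx],
                      donor_weights = donor_w))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the text dialects the rest of the package consumes:
#' `elements.bed`, `training.bed`, `mutations.tsv`, `features_test.tsv`,
#' `features_train.tsv`, `raw_scores.tsv`, `chrom.sizes`, and `truth.json`.
#'
#' @param sim output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed_elements(sim$elements, file.path(dir, "elements.bed"))
  write_bed_elements(sim$training, file.path(dir, "training.bed"))
  data.table::fwrite(sim$mutations, file.path(dir, "mutations.tsv"), sep = "\t")
  write_feature_tsv(sim$X, file.path(dir, "features_test.tsv"))
  write_feature_tsv(sim$X_train, file.path(dir, "features_train.tsv"))
  if (nrow(sim$raw_scores)) {
    data.table::fwrite(sim$raw_scores, file.path(dir, "raw_scores.tsv"), sep = "\t")
  }
  data.table::fwrite(data.table::data.table(chrom = names(sim$chrom_sizes),
                                            size = sim$chrom_sizes),
                     file.path(dir, "chrom.sizes"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
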