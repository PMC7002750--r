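test_that("BED4 parsing groups records by element id and merges overlaps", {
  p <- write_temp_bed(data.frame(chrom = c("chr1", "chr2"), start = c(10, 0),
                                 end = c(30, 100), id = c("e1", "e2")))
  es <- load_elements(p, name = "two")
  expect_s3_class(es, "element_set")
  expect_equal(nrow(element_info(es)), 2)
  expect_equal(sort(element_info(es)$element_id), c("e1", "e2"))

  p2 <- write_temp_bed(data.frame(chrom = "chr1", start = c(10, 15),
                                  end = c(20, 30), id = "e1"))
  es2 <- load_elements(p2)
  info <- element_info(es2)
  expect_equal(nrow(info), 1)
  expect_equal(info$raw_length, 20)           # union [10,30)
  expect_equal(length(es2$gr), 1)             # one merged interval
})

test_that("malformed BED records raise a parse error naming the line", {
  p <- write_temp_bed(data.frame(chrom = c("chr1", "chr1"), start = c(0, 20),
                                 end = c(10, 10), id = c("ok", "bad")))
  expect_error(load_elements(p), "line 2")
  p2 <- write_temp_bed(data.frame(chrom = "chr1", start = "x", end = 10, id = "e"))
  expect_error(load_elements(p2), "line 1")
})

test_that("BED12 blocks expand to the element's intervals", {
  df <- data.frame(chrom = "chr1", start = 100, end = 200, id = "g1",
                   score = 0, strand = "+", thickStart = 100, thickEnd = 200,
                   rgb = 0, blockCount = 2, blockSizes = "10,20,",
                   blockStarts = "0,80,")
  es <- load_elements(write_temp_bed(df))
  info <- element_info(es)
  expect_equal(info$raw_length, 30)
  expect_equal(GenomicRanges::start(es$gr) - 1, c(100, 180))
  expect_equal(GenomicRanges::end(es$gr), c(110, 200))
})

test_that("mask subtraction updates effective length and flags empty elements", {
  es <- toy_elements(data.frame(chrom = "chr1", start = c(0, 200),
                                end = c(100, 250),
                                element_id = c("a", "b")))
  empty <- region_mask(GenomicRanges::GRanges(), polarity = "excluded")
  expect_equal(element_info(apply_mask(es, empty))$effective_length, c(100, 50))

  m <- region_mask(data.frame(chrom = "chr1", start = 0, end = 50), "excluded")
  masked <- apply_mask(es, m)
  expect_equal(element_info(masked)$effective_length, c(50, 50))

  m2 <- region_mask(data.frame(chrom = "chr1", start = 0, end = 120), "excluded")
  masked2 <- apply_mask(es, m2)
  info <- element_info(masked2)
  expect_equal(info$effective_length[info$element_id == "a"], 0)
  expect_true(info$untestable[info$element_id == "a"])
  expect_equal(info$raw_length, c(100, 50))  # raw lengths untouched
})

test_that("masking is idempotent and callable masks behave as complements", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 6
    st <- sort(sample(0:400, n))
    es <- element_set(data.frame(chrom = "chrZ", start = st, end = st + sample(5:60, n, TRUE),
                                 element_id = sprintf("e%d", 1:n)))
    mst <- sort(sample(0:400, 4))
    m <- region_mask(data.frame(chrom = "chrZ", start = mst, end = mst + sample(10:80, 4, TRUE)),
                     "excluded")
    once <- apply_mask(es, m)
    twice <- apply_mask(once, m)
    expect_equal(element_info(twice), element_info(once))
    expect_equal(as.data.frame(twice$gr), as.data.frame(once$gr))
  }
  # callable polarity: keeping [0,50) equals excluding everything else
  es <- toy_elements(data.frame(chrom = "chr1", start = 0, end = 100, element_id = "a"))
  keep <- region_mask(data.frame(chrom = "chr1", start = 0, end = 50), "callable")
  expect_equal(element_info(apply_mask(es, keep))$effective_length, 50)
})

test_that("fixed bins drop trailing partials and have constant length", {
  expect_equal(nrow(element_info(make_fixed_bins(c(chrA = 2.5e6), 1e6))), 2)
  expect_equal(nrow(element_info(make_fixed_bins(c(chrA = 999999), 1e6))), 0)
  bins <- make_fixed_bins(c(chrA = 3e6, chrB = 1e6), 1e6)
  info <- element_info(bins)
  expect_equal(nrow(info), 4)
  expect_equal(sum(info$effective_length), 1e6 * nrow(info))
  expect_error(make_fixed_bins(c(chrA = 10), 0))
})

test_that("training-element sampling is disjoint from test elements, scaled, and seeded", {
  test_es <- element_set(data.frame(chrom = "chr1", start = c(2000, 5000),
                                    end = c(2100, 5100),
                                    element_id = c("t1", "t2")), name = "test")
  callable <- region_mask(data.frame(chrom = "chr1", start = 0, end = 10000),
                          polarity = "callable")
  tr <- sample_training_elements(test_es, callable, n = 12, length_factor = 3,
                                 seed = 7)
  info <- element_info(tr)
  expect_equal(nrow(info), 12)
  expect_true(all(info$raw_length == 300))  # 3 x the only test length (100)

  # brute-force per-base disjointness on the 10 kb toy genome
  tr_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(tr$gr)),
                      start = GenomicRanges::start(tr$gr) - 1,
                      end = GenomicRanges::end(tr$gr))
  te_df <- data.frame(chrom = "chr1", start = c(2000, 5000), end = c(2100, 5100))
  expect_length(intersect(bases_of(tr_df), bases_of(te_df)), 0)
  # all sampled bases inside callable space
  expect_true(all(tr_df$start >= 0 & tr_df$end <= 10000))

  tr2 <- sample_training_elements(test_es, callable, n = 12, length_factor = 3,
                                  seed = 7)
  expect_identical(as.data.frame(tr2$gr), as.data.frame(tr$gr))

  # callable space too small for the retry budget -> explicit failure
  tiny <- region_mask(data.frame(chrom = "chr1", start = 0, end = 150), "callable")
  expect_error(sample_training_elements(test_es, tiny, n = 5, seed = 1,
                                        max_tries = 50),
               "callable space")
})
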