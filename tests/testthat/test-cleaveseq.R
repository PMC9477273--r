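test_that("fold change matches direct odds-ratio arithmetic", {
  # symmetric counts: fc = 1, p = 1
  rec <- fold_change(50, 50, 50, 50)
  expect_equal(rec$fc, 1)
  expect_equal(rec$p_value, 1)

  # (80,20,20,80): fc = 16 raw; with half-pseudocounts the direct
  # arithmetic oracle gives (80.5 * 80.5) / (20.5 * 20.5)
  rec2 <- fold_change(80, 20, 20, 80)
  expect_equal(rec2$fc, (80.5 * 80.5) / (20.5 * 20.5), tolerance = 1e-12)
  expect_equal((80 / 100) * (80 / 100) / ((20 / 100) * (20 / 100)), 16)
  expect_equal(rec2$se_log_fc,
               sqrt(1 / 80.5 + 1 / 20.5 + 1 / 20.5 + 1 / 80.5),
               tolerance = 1e-12)
  expect_equal(rec2$cleavage_fraction_ref, 0.8)
  expect_equal(rec2$cleavage_fraction_test, 0.2)

  # normalization divides the odds ratio
  rec3 <- fold_change(80, 20, 20, 80, k = 2)
  expect_equal(rec3$fc, rec2$fc / 2)

  # CI nesting and containment
  expect_lt(rec2$ci95_lo, rec2$ci90_lo)
  expect_gt(rec2$ci95_hi, rec2$ci90_hi)
  expect_true(rec2$ci90_lo < rec2$fc && rec2$fc < rec2$ci90_hi)

  expect_error(fold_change(-1, 2, 3, 4), class = "ribosense_input_error")
})

test_that("fold change is antisymmetric and zero-safe", {
  set.seed(1)
  a <- rpois(20, 50); b <- rpois(20, 50)
  cc <- rpois(20, 50); d <- rpois(20, 50)
  fwd <- fold_change(a, b, cc, d)
  rev <- fold_change(cc, d, a, b)
  expect_equal(fwd$fc, 1 / rev$fc, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)

  # all-zero counts: fc = 1 with maximal se, p well-defined
  z <- fold_change(0, 0, 0, 0)
  expect_equal(z$fc, 1)
  expect_equal(z$se_log_fc, sqrt(4 / 0.5))
  expect_true(z$p_value > 0 && z$p_value <= 1)
})

test_that("se_log_fc strictly decreases as any count grows", {
  base <- fold_change(10, 10, 10, 10)$se_log_fc
  for (i in 1:4) {
    counts <- c(10, 10, 10, 10)
    counts[i] <- 100
    expect_lt(fold_change(counts[1], counts[2], counts[3], counts[4])$se_log_fc,
              base)
  }
})

test_that("fold-change estimator is consistent in depth", {
  # |fc_hat - fc_true| shrinks with depth: c_ref = 0.5, c_test = 0.2, fc = 4
  set.seed(42)
  err <- vapply(c(100, 1000, 10000), function(depth) {
    a <- rbinom(200, depth, 0.5)
    cc <- rbinom(200, depth, 0.2)
    rec <- fold_change(a, depth - a, cc, depth - cc)
    mean(abs(log(rec$fc) - log(4)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("reference normalization recovers an injected odds bias", {
  lib <- generate_library(2, n_references = 20, seed = 5)
  mod <- generate_response_models(lib, seed = 6)
  ref <- simulate_cleaveseq_counts(lib, mod, NULL, "ref", depth = 2e5,
                                   seed = 7)
  test <- simulate_cleaveseq_counts(lib, mod, NULL, "test", depth = 2e5,
                                    bias = 1.5, seed = 8)
  ref_ids <- lib$sensor_id[lib$is_reference]
  k <- normalize_by_references(ref, test, ref_ids, min_reads = 50)
  expect_equal(k, 1 / 1.5, tolerance = 0.1)

  # corrected reference fold changes sit near 1
  fcs <- compare_conditions(dplyr::bind_rows(ref, test), "ref",
                            reference_ids = ref_ids, min_reads = 50)
  ref_fc <- fcs$fc[fcs$sensor_id %in% ref_ids]
  expect_equal(median(ref_fc), 1, tolerance = 0.05)
})

test_that("normalization edge cases: identical counts give k = 1; too few references warn", {
  counts <- tibble::tibble(sensor_id = c("r1", "r2", "r3"),
                           cleaved = c(100L, 150L, 200L),
                           uncleaved = c(100L, 60L, 120L))
  expect_equal(normalize_by_references(counts, counts, counts$sensor_id), 1)
  expect_warning(
    k <- normalize_by_references(counts[1:2, ], counts[1:2, ],
                                 c("r1", "r2")),
    "reference"
  )
  expect_equal(k, 1)
})

test_that("significance calls apply the Bonferroni, depth and fold rules", {
  rec <- fold_change(c(80, 52, 80), c(20, 48, 20), c(20, 48, 4),
                     c(80, 52, 16),
                     sensor_id = c("strong", "null", "shallow"))
  called <- call_significant(rec, n_tested = 1e4, min_reads = 100)
  expect_true(called$significant[called$sensor_id == "strong"])
  expect_false(called$significant[called$sensor_id == "null"])
  # strong fold change but only 20 test reads: fails the depth gate
  expect_false(called$significant[called$sensor_id == "shallow"])

  # p exactly at 2/N is never significant
  rec_border <- rec[1, ]
  rec_border$p_value <- 2 / 1e4
  expect_false(call_significant(rec_border, 1e4)$significant)

  expect_error(call_significant(rec, n_tested = 0),
               class = "ribosense_input_error")
})

test_that("prefix mismatch tolerance routes reads as specified", {
  lib <- generate_library(1, seed = 9)
  good <- paste0(default_prefix_map[["cleaved"]], lib$template_seq,
                 default_suffix)
  one_off <- sub("^.", ifelse(startsWith(good, "A"), "C", "A"), good)
  tab0 <- count_reads(c(good, one_off), sensors = lib,
                      mismatch_tolerance = 0)
  expect_equal(sum(tab0$cleaved), 1)
  expect_equal(unname(attr(tab0, "unassigned")[["no_prefix"]]), 1)

  tab1 <- count_reads(c(good, one_off), sensors = lib,
                      mismatch_tolerance = 1)
  expect_equal(sum(tab1$cleaved), 2)

  # 5 reads, 3 cleaved-prefixed: (a, b) = (3, 2)
  reads <- c(rep(good, 3),
             rep(paste0(default_prefix_map[["uncleaved"]], lib$template_seq,
                        default_suffix), 2))
  tab <- count_reads(reads, sensors = lib)
  expect_equal(tab$cleaved, 3L)
  expect_equal(tab$uncleaved, 2L)
})

test_that("barcoded multi-condition reads round-trip through counting", {
  lib <- generate_library(30, seed = 10)
  mod <- generate_response_models(lib, seed = 11)
  bt <- tibble::tibble(condition_id = c("ref", "test"),
                       barcode = c("ACGTA", "TG"))
  tab <- dplyr::bind_rows(
    simulate_cleaveseq_counts(lib, mod, NULL, "ref", depth = 5000, seed = 12),
    simulate_cleaveseq_counts(lib, mod, NULL, "test", depth = 5000, seed = 13)
  )
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(tab, lib, path, barcode_table = bt)
  back <- count_reads(path, sensors = lib, barcode_table = bt)
  orig <- dplyr::arrange(dplyr::filter(tab, cleaved + uncleaved > 0),
                         sensor_id, condition_id)
  expect_equal(back$cleaved, as.integer(orig$cleaved))
  expect_equal(back$uncleaved, as.integer(orig$uncleaved))
  expect_equal(back$condition_id, orig$condition_id)
})

test_that("count tables survive a TSV round trip", {
  tab <- tibble::tibble(sensor_id = c("s1", "s2"), condition_id = "c",
                        cleaved = c(3L, 0L), uncleaved = c(2L, 5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  expect_equal(as.data.frame(read_count_table(path)), as.data.frame(tab))
})
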