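toy_matrix <- function() {
  tibble::tibble(
    sensor_id = rep(c("a", "b"), each = 2),
    condition_id = rep(c("x", "y"), 2),
    fc = c(4, 1, 1, 1),
    se_log_fc = 0.2
  )
}

test_that("d' reproduces direct arithmetic and is a symmetric premetric", {
  m <- toy_matrix()
  # |log 4| / sqrt(0.04 + 0.04)
  expect_equal(dprime(m, "a", "b"), log(4) / sqrt(0.08), tolerance = 1e-12)
  expect_equal(dprime(m, "a", "b"), dprime(m, "b", "a"))
  expect_equal(dprime(m, "a", "a"), 0)

  # identical profiles are at distance zero
  m2 <- m
  m2$fc <- c(4, 1, 4, 1)
  expect_equal(dprime(m2, "a", "b"), 0)

  # no shared conditions is an error
  m3 <- tibble::tibble(sensor_id = c("a", "b"), condition_id = c("x", "y"),
                       fc = 1, se_log_fc = 0.1)
  expect_error(dprime(m3, "a", "b"), class = "ribosense_input_error")
})

test_that("d' matrix equals the brute-force maximum over conditions", {
  set.seed(1)
  m <- tidyr::crossing(sensor_id = paste0("s", 1:10),
                       condition_id = paste0("c", 1:5)) |>
    dplyr::mutate(fc = exp(rnorm(dplyr::n(), 0, 1)),
                  se_log_fc = runif(dplyr::n(), 0.1, 0.5))
  # knock out a few cells to exercise missing-data handling
  m$fc[c(3, 17, 41)] <- NA
  d <- as.matrix(dprime_matrix(m))
  for (pair in list(c("s1", "s2"), c("s3", "s9"), c("s5", "s10"))) {
    expect_equal(d[pair[1], pair[2]],
                 oracle_dprime(m, pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("clustering recovers planted response archetypes", {
  set.seed(2)
  archetype <- list(c(6, 1, 1), c(1, 6, 1), c(1, 1, 6))
  m <- tidyr::crossing(sensor_id = sprintf("s%02d", 1:12),
                       condition_id = c("c1", "c2", "c3")) |>
    dplyr::arrange(sensor_id, condition_id)
  idx <- rep(1:3, each = 4)
  m$fc <- unlist(lapply(idx, function(i) {
    archetype[[i]] * exp(rnorm(3, 0, 0.02))
  }))
  m$se_log_fc <- 0.15
  cl <- cluster_sensors(m, cutoff = 3)
  expect_equal(dplyr::n_distinct(cl$cluster), 3)
  # all sensors of an archetype share a cluster
  assigned <- cl$cluster[match(sprintf("s%02d", 1:12), cl$sensor_id)]
  expect_equal(dplyr::n_distinct(paste(idx, assigned)), 3)
  # one representative per cluster; highest-abundance member wins
  expect_equal(sum(cl$is_representative), 3)
  ab <- tibble::tibble(sensor_id = sprintf("s%02d", 1:12),
                       abundance = c(1:4, 4:1, 1, 4, 2, 3) / 10)
  cl2 <- cluster_sensors(m, cutoff = 3, abundance = ab)
  reps <- cl2$sensor_id[cl2$is_representative]
  expect_setequal(reps, c("s04", "s05", "s10"))

  # two identical sensors collapse to one cluster; singleton stands alone
  two <- toy_matrix()
  two$fc <- c(4, 1, 4, 1)
  cl3 <- cluster_sensors(two, cutoff = 3)
  expect_equal(dplyr::n_distinct(cl3$cluster), 1)
  single <- two[two$sensor_id == "a", ]
  cl4 <- cluster_sensors(single, cutoff = 3)
  expect_equal(cl4$cluster, 1L)
  expect_true(cl4$is_representative)

  expect_error(cluster_sensors(two, cutoff = 0),
               class = "ribosense_config_error")
})

test_that("complete linkage bounds all within-cluster pairwise distances", {
  set.seed(3)
  m <- tidyr::crossing(sensor_id = paste0("s", 1:15),
                       condition_id = paste0("c", 1:6)) |>
    dplyr::mutate(fc = exp(rnorm(dplyr::n(), 0, 0.8)),
                  se_log_fc = 0.3)
  cutoff <- 4
  cl <- cluster_sensors(m, cutoff = cutoff)
  d <- as.matrix(dprime_matrix(m))
  for (g in split(cl$sensor_id, cl$cluster)) {
    if (length(g) > 1) {
      expect_lte(max(d[g, g]), cutoff)
    }
  }
})

test_that("dendrogram exports as Newick with sensor labels", {
  m <- toy_matrix()
  m <- dplyr::bind_rows(m, tibble::tibble(sensor_id = "c",
                                          condition_id = c("x", "y"),
                                          fc = c(1, 8), se_log_fc = 0.2))
  cl <- cluster_sensors(m, cutoff = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("cross-reactivity follows the min rule and matches brute force", {
  m <- tibble::tibble(
    sensor_id = c("s1", "s1", "s1", "s2"),
    condition_id = c("c1", "c2", "c3", "c1"),
    fc = c(5, 3, 2.5, 5),
    se_log_fc = 0.1
  )
  xr <- cross_reactivity(m, f_grid = 2)
  # s1 responds to 3 compounds, s2 to 1; c1 takes the min over its sensors
  expect_equal(xr$sensor_xr$xr[xr$sensor_xr$sensor_id == "s1"], 3L)
  expect_equal(xr$compound_xr$xr[xr$compound_xr$compound_id == "c1"], 1L)

  one <- m[1, ]
  xr1 <- cross_reactivity(one, f_grid = 2)
  expect_equal(xr1$sensor_xr$xr, 1L)
  expect_equal(xr1$compound_xr$xr, 1L)

  set.seed(4)
  big <- tidyr::crossing(sensor_id = paste0("s", 1:20),
                         condition_id = paste0("c", 1:15)) |>
    dplyr::mutate(fc = exp(rnorm(dplyr::n(), 0, 1)), se_log_fc = 0.1)
  for (f in c(1.5, 2, 4)) {
    got <- cross_reactivity(big, f_grid = f)
    want <- oracle_xr(big, f)
    expect_equal(setNames(got$sensor_xr$xr, got$sensor_xr$sensor_id),
                 want$sensor)
    expect_equal(setNames(got$compound_xr$xr, got$compound_xr$compound_id),
                 want$compound)
  }
})

test_that("cross-reactivity curves are monotone in C and f", {
  set.seed(5)
  m <- tidyr::crossing(sensor_id = paste0("s", 1:10),
                       condition_id = paste0("c", 1:10)) |>
    dplyr::mutate(fc = exp(rnorm(dplyr::n(), 0.3, 1)), se_log_fc = 0.1)
  xr <- cross_reactivity(m, f_grid = c(2, 3, 5), C_grid = 1:10)
  curve <- xr$curve
  # cumulative in C: non-decreasing for every threshold
  for (f in unique(curve$f)) {
    expect_true(all(diff(curve$n_compounds[curve$f == f]) >= 0))
  }
  # the sensed-compound total (any cross-reactivity) shrinks as f rises;
  # per-sensor cross-reactivities are non-increasing in f
  totals <- vapply(sort(unique(curve$f)), function(f) {
    sum(!is.na(xr$compound_xr$xr[xr$compound_xr$f == f]))
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  sx <- tidyr::pivot_wider(xr$sensor_xr, names_from = "f",
                           values_from = "xr")
  expect_true(all(sx[["3"]] <= sx[["2"]] & sx[["5"]] <= sx[["3"]]))
})

test_that("minimum detectable concentration is the lowest measured crossing", {
  series <- tibble::tibble(
    sensor_id = "s1", compound_id = "c1",
    concentration_uM = c(10, 1, 0.1, 0.025, 0.01),
    fc = c(8, 6, 3.5, 2.1, 1.5),
    ci95_lo = c(6, 4.5, 2.5, 1.4, 0.8)
  )
  res <- min_detectable_concentration(series)
  expect_equal(res$min_conc_uM, 0.025)
  expect_equal(res$fc_at_max, 8)

  # monotone series never reaching threshold reports none
  flat <- series
  flat$fc <- c(1.8, 1.5, 1.3, 1.1, 1.0)
  flat$ci95_lo <- flat$fc * 0.7
  res2 <- min_detectable_concentration(flat)
  expect_true(is.na(res2$min_conc_uM))
  expect_match(res2$reason, "max tested")

  # crossing without CI support does not count
  shaky <- series
  shaky$ci95_lo <- c(6, 4.5, 2.5, 0.9, 0.8)
  expect_equal(min_detectable_concentration(shaky)$min_conc_uM, 0.1)
})

test_that("sensors responding to a companion compound are masked", {
  series <- tibble::tibble(
    sensor_id = "s1", compound_id = "c1",
    concentration_uM = c(10, 1),
    fc = c(8, 3), ci95_lo = c(6, 2),
    companions = list(c("c2", "c3"), c("c2", "c3"))
  )
  single <- tibble::tibble(sensor_id = "s1", condition_id = c("c2", "c3"),
                           fc = c(3.5, 1.1))
  res <- min_detectable_concentration(series, single_matrix = single)
  expect_true(res$masked)
  expect_match(res$reason, "c2")
  expect_true(is.na(res$min_conc_uM))

  clean <- single
  clean$fc <- c(1.2, 1.1)
  res2 <- min_detectable_concentration(series, single_matrix = clean)
  expect_false(res2$masked)
  expect_equal(res2$min_conc_uM, 1)
})

test_that("detection threshold lands within one dilution step of the model value", {
  # FC(x) = 2 at x = ec50 / (fc_max - 2): fc_max 6, ec50 0.4 -> 0.1 uM
  lib <- generate_library(1, seed = 6)
  lib$abundance <- 1
  mod <- tibble::tibble(sensor_id = lib$sensor_id, c0 = 0.6,
                        targets = list(tibble::tibble(
                          compound_id = "X", fc_max = 6, ec50_uM = 0.4)))
  concs <- 10 / 2^(0:9)
  ref <- simulate_cleaveseq_counts(lib, mod, NULL, "ref", depth = 2e4,
                                   seed = 7)
  series <- dplyr::bind_rows(lapply(seq_along(concs), function(i) {
    ct <- simulate_cleaveseq_counts(
      lib, mod, tibble::tibble(compound_id = "X", concentration_uM = concs[i]),
      "test", depth = 2e4, seed = 7 + i)
    rec <- fold_change(ref$cleaved, ref$uncleaved, ct$cleaved, ct$uncleaved)
    tibble::tibble(sensor_id = lib$sensor_id, compound_id = "X",
                   concentration_uM = concs[i], fc = rec$fc,
                   ci95_lo = rec$ci95_lo)
  }))
  res <- min_detectable_concentration(series)
  analytic <- 0.4 / (6 - 2)
  steps <- sort(concs)
  crossing_step <- steps[findInterval(analytic, steps) + 1]
  expect_true(res$min_conc_uM %in%
                c(crossing_step / 2, crossing_step, crossing_step * 2))
})
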