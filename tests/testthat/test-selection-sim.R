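two_species <- function(c0, amplicon = c(FALSE, FALSE)) {
  lib <- generate_library(2, seed = 1)
  lib$abundance <- c(0.5, 0.5)
  lib$is_amplicon <- amplicon
  mod <- tibble::tibble(sensor_id = lib$sensor_id, c0 = c0,
                        targets = list(tibble::tibble(compound_id = character(),
                                                      fc_max = numeric(),
                                                      ec50_uM = numeric()),
                                       tibble::tibble(compound_id = character(),
                                                      fc_max = numeric(),
                                                      ec50_uM = numeric())))
  list(lib = lib, mod = mod)
}

test_that("the default schedule reproduces the canonical round structure", {
  sched <- default_schedule(95)
  expect_equal(nrow(sched), 95)
  expect_true(all(sched$sense[1:7] == "select_cleaved"))
  expect_true(all(sched$mixture[1:7] == "none"))
  # strict alternation after the initial phase
  after <- sched$sense[8:95]
  expect_true(all(after[-1] != after[-length(after)]))
  expect_false(sched$sense[9] == sched$sense[10])
  # main phase at 2 uM, reduced to 1 uM from round 88
  expect_equal(sched$concentration_uM[10], 2)
  expect_equal(sched$concentration_uM[88], 1)
  # counter-mixture enters the cleave-selection rounds of the late phase
  late_cleave <- sched$mixture[sched$round >= 88 &
                                 sched$sense == "select_cleaved"]
  expect_true(all(late_cleave == "counter"))
  # positive-selection rounds always carry a mixture
  expect_true(all(sched$mixture[sched$sense == "select_uncleaved"] != "none"))

  expect_error(default_schedule(5), class = "ribosense_input_error")
  bad <- sched
  bad$mixture[8] <- "none"
  expect_error(validate_schedule(bad), class = "ribosense_input_error")
})

test_that("deterministic two-species dynamics match the closed-form weight product", {
  ts <- two_species(c0 = c(0.8, 0.6))
  sched <- default_schedule(12, initial_cleave_rounds = 2,
                            sample_size = Inf)
  traj <- run_selection(ts$lib, ts$mod, sched,
                        mixtures = list(target = "X", counter = "Y"),
                        seed = 1)
  # per-round weights: c under select_cleaved, 1 - c under select_uncleaved
  w <- function(c0) {
    ifelse(sched$sense == "select_cleaved", c0, 1 - c0)
  }
  expected_ratio <- prod(w(0.8) / w(0.6))
  final <- traj$abundance[nrow(traj$abundance), ]
  expect_equal(unname(final[1] / final[2]), expected_ratio,
               tolerance = 1e-9)
  # abundance conservation every round
  expect_equal(unname(rowSums(traj$abundance)), rep(1, nrow(traj$abundance)),
               tolerance = 1e-9)
})

test_that("a switching sensor outcompetes a constitutive cleaver", {
  lib <- generate_library(2, seed = 2)
  lib$abundance <- c(0.5, 0.5)
  mod <- tibble::tibble(
    sensor_id = lib$sensor_id,
    c0 = c(0.9, 0.9),
    targets = list(
      tibble::tibble(compound_id = "X", fc_max = 12, ec50_uM = 1e-3),
      tibble::tibble(compound_id = character(), fc_max = numeric(),
                     ec50_uM = numeric())
    )
  )
  sched <- default_schedule(20, initial_cleave_rounds = 0,
                            sample_size = Inf, reduced_from_round = 99)
  traj <- run_selection(lib, mod, sched, mixtures = list(target = "X"),
                        seed = 3)
  ratio <- traj$abundance[, 1] / traj$abundance[, 2]
  # the ratio grows across every cleave/non-cleave round pair
  pair_end <- ratio[seq(3, length(ratio), by = 2)]
  expect_true(all(diff(c(ratio[1], pair_end)) > 0))
})

test_that("a sensor cleaving fully under ligand goes extinct at the first positive round", {
  ts <- two_species(c0 = c(0.9999, 0.6))
  ts$mod$c0[1] <- 1  # cleaves always, also with ligand
  sched <- default_schedule(10, initial_cleave_rounds = 2, sample_size = 1e5)
  traj <- run_selection(ts$lib, ts$mod, sched,
                        mixtures = list(target = "X"), seed = 4)
  first_pos <- min(which(sched$sense == "select_uncleaved"))
  expect_lt(traj$abundance[first_pos + 1, 1], 1e-6)

  # all-zero survival is an explicit extinction error naming the round
  ts2 <- two_species(c0 = c(1, 1))
  expect_error(
    run_selection(ts2$lib, ts2$mod, sched, mixtures = list(target = "X"),
                  seed = 5),
    regexp = "round 3",
    class = "ribosense_extinction_error"
  )
})

test_that("amplicons hold a sense-independent survival weight", {
  ts <- two_species(c0 = c(0.5, 0.5), amplicon = c(TRUE, FALSE))
  sched <- default_schedule(8, initial_cleave_rounds = 2, sample_size = Inf)
  traj <- run_selection(ts$lib, ts$mod, sched,
                        mixtures = list(target = "X"),
                        amplicon_fitness = 0.8, seed = 6)
  # per round pair: amplicon 0.8 * 0.8 vs sensor 0.5 * 0.5
  final <- traj$abundance[nrow(traj$abundance), ]
  expect_equal(unname(final[1] / final[2]),
               prod(rep(0.8, 8)) / prod(rep(0.5, 8)), tolerance = 1e-9)
})

test_that("checkpoint tracking subsamples abundances with a detection floor", {
  ts <- two_species(c0 = c(0.7, 0.7))
  ts$lib$abundance <- c(0.5, 0.5)
  sched <- default_schedule(8, initial_cleave_rounds = 2, sample_size = Inf)
  traj <- run_selection(ts$lib, ts$mod, sched,
                        mixtures = list(target = "X"), seed = 7)
  reads <- 1000
  ta <- track_abundance(traj, c(0, 8), reads, seed = 8)
  r0 <- ta[ta$round == 0, ]
  expect_equal(r0$detection_floor, rep(1 / reads, 2))
  # abundance 0.5 sampled within 3 binomial SEs
  expect_lt(abs(r0$est_abundance[1] - 0.5), 3 * sqrt(0.25 / reads))

  # an absent species samples to zero and is reported below floor
  traj$abundance[nrow(traj$abundance), 1] <- 0
  traj$abundance[nrow(traj$abundance), 2] <- 1
  ta2 <- track_abundance(traj, 8, reads, seed = 9)
  expect_equal(ta2$reads[1], 0L)
  expect_true(ta2$below_floor[1])

  expect_error(track_abundance(traj, 99, reads),
               class = "ribosense_input_error")
})

test_that("schedules survive a CSV round trip", {
  sched <- default_schedule(12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(sched))
})
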