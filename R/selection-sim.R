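#' Default alternating selection schedule
#'
#' The canonical 95-round schedule: rounds 1-7 select cleaving sequences with
#' no ligand (enriching active ribozymes), then alternating rounds of
#' positive selection (non-cleavers in the presence of the target mixture)
#' and negative selection (cleavers without ligand), with the target mixture
#' at 2 uM per compound. From round 88 the target concentration drops to
#' 1 uM and the counter-mixture (the other selection set) is added during
#' the negative (cleave-selection) rounds to remove cross-reactive sensors.
#'
#' @param n_rounds Total rounds (>= 7; default 95).
#' @param initial_cleave_rounds Ligand-free cleave-selection rounds at the
#'   start (default 7).
#' @param concentration_uM Per-compound target concentration in the main
#'   phase (default 2).
#' @param reduced_concentration_uM Concentration from `reduced_from_round`
#'   (default 1).
#' @param reduced_from_round First round of the reduced-concentration /
#'   counter-selection phase (default 88).
#' @param sample_size Molecules carried into each round.
#' @return A schedule tibble: `round`, `sense` (`select_cleaved` /
#'   `select_uncleaved`), `mixture` (`none`, `target`, `counter`),
#'   `concentration_uM`, `sample_size`.
#' @export
default_schedule <- function(n_rounds = 95,
                             initial_cleave_rounds = 7,
                             concentration_uM = 2,
                             reduced_concentration_uM = 1,
                             reduced_from_round = 88,
                             sample_size = 1e5) {
  if (n_rounds < initial_cleave_rounds) {
    abort("`n_rounds` must be at least the initial cleave-round count.",
          class = "ribosense_input_error")
  }
  round <- seq_len(n_rounds)
  # first round after the initial phase is a positive (non-cleave) selection
  uncleave <- round > initial_cleave_rounds &
    (round - initial_cleave_rounds) %% 2 == 1
  sense <- if_else(uncleave, "select_uncleaved", "select_cleaved")
  late <- round >= reduced_from_round
  conc <- dplyr::case_when(
    round <= initial_cleave_rounds ~ 0,
    late ~ reduced_concentration_uM,
    TRUE ~ concentration_uM
  )
  mixture <- dplyr::case_when(
    round <= initial_cleave_rounds ~ "none",
    uncleave ~ "target",
    late ~ "counter",
    TRUE ~ "none"
  )
  tibble(round = round, sense = sense, mixture = mixture,
         concentration_uM = conc, sample_size = sample_size)
}

#' Read / write a selection schedule
#'
#' CSV with the schedule columns; YAML is also accepted on read.
#'
#' @param schedule Schedule tibble.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    round = readr::col_integer(),
    sense = readr::col_character(),
    mixture = readr::col_character(),
    concentration_uM = readr::col_double(),
    sample_size = readr::col_double()
  ))
}

validate_schedule <- function(schedule) {
  assert_columns(schedule, c("round", "sense", "mixture",
                             "concentration_uM", "sample_size"))
  if (!identical(as.integer(schedule$round),
                 seq_len(nrow(schedule)))) {
    abort("Schedule rounds must be contiguous from 1.",
          class = "ribosense_input_error")
  }
  bad <- schedule$sense == "select_uncleaved" & schedule$mixture == "none"
  if (any(bad)) {
    abort("select_uncleaved rounds require a mixture (positive selection).",
          class = "ribosense_input_error")
  }
  invisible(schedule)
}

#' Simulate alternating-round selection dynamics
#'
#' Per round, each sensor survives with weight `w = c` (cleave selection) or
#' `w = 1 - c` (non-cleave selection), where `c` is its model cleavage
#' fraction under the round's mixture; amplicon parasites get a fixed weight
#' `amplicon_fitness` regardless of the round's sense (emulating their
#' RT-evasion advantage). Abundances are re-weighted, renormalized (PCR
#' amplification preserves only relative abundance), and multinomially
#' resampled at the round's `sample_size` to model the diversity bottleneck.
#'
#' @param library Sensor tibble.
#' @param models Response-model tibble.
#' @param schedule Schedule tibble (see [default_schedule()]).
#' @param mixtures Named list mapping mixture labels used in the schedule
#'   (other than `"none"`) to character vectors of compound ids.
#' @param amplicon_fitness Constant per-round weight of amplicon members
#'   (default 0.8: above any non-switching ribozyme's alternating-phase
#'   fitness, below a good switcher's).
#' @param seed Integer seed.
#' @return A `selection_trajectory`: abundance matrix ((rounds + 1) x
#'   sensors, row 0 = input library), the schedule, and sensor metadata.
#' @export
run_selection <- function(library,
                          models,
                          schedule,
                          mixtures = list(),
                          amplicon_fitness = 0.8,
                          seed = NULL) {
  validate_schedule(schedule)
  assert_columns(library, c("sensor_id", "abundance", "is_amplicon"))
  m <- models[match(library$sensor_id, models$sensor_id), ]
  if (anyNA(m$sensor_id)) {
    abort("Every library sensor needs a response model.",
          class = "ribosense_input_error")
  }
  needed <- setdiff(unique(schedule$mixture), "none")
  missing_mix <- setdiff(needed, names(mixtures))
  if (length(missing_mix) > 0) {
    abort(paste0("Schedule uses undefined mixture(s): ",
                 paste(missing_mix, collapse = ", ")),
          class = "ribosense_input_error")
  }

  # cleavage per sensor for each distinct (mixture, concentration)
  conds <- distinct(schedule, .data$mixture, .data$concentration_uM)
  cleavage <- purrr::pmap(conds, function(mixture, concentration_uM) {
    condition <- if (mixture == "none") {
      NULL
    } else {
      tibble(compound_id = mixtures[[mixture]],
             concentration_uM = concentration_uM)
    }
    fc <- vapply(m$targets, model_fold_change, numeric(1),
                 condition = condition)
    plogis(qlogis(m$c0) - log(fc))
  })
  names(cleavage) <- paste(conds$mixture, conds$concentration_uM)

  n <- nrow(library)
  abundance <- matrix(NA_real_, nrow(schedule) + 1L, n,
                      dimnames = list(c(0, schedule$round),
                                      library$sensor_id))
  abundance[1L, ] <- library$abundance / sum(library$abundance)
  with_seed(seed, {
    a <- abundance[1L, ]
    for (r in seq_len(nrow(schedule))) {
      key <- paste(schedule$mixture[r], schedule$concentration_uM[r])
      cl <- cleavage[[key]]
      w <- if (schedule$sense[r] == "select_cleaved") cl else 1 - cl
      w[library$is_amplicon] <- amplicon_fitness
      surv <- a * w
      if (sum(surv) <= 0) {
        abort(paste0("Library extinct at round ", r,
                     " (all survival weights zero)."),
              class = "ribosense_extinction_error")
      }
      p <- surv / sum(surv)
      size <- schedule$sample_size[r]
      if (is.finite(size) && size > 0) {
        counts <- as.vector(rmultinom(1, size = size, prob = p))
        a <- counts / size
      } else {
        a <- p
      }
      abundance[r + 1L, ] <- a
    }
  })
  structure(
    list(abundance = abundance, schedule = schedule,
         sensor_id = library$sensor_id,
         is_amplicon = library$is_amplicon),
    class = "selection_trajectory"
  )
}

#' @export
print.selection_trajectory <- function(x, ...) {
  cat("<selection_trajectory> ", nrow(x$schedule), " rounds x ",
      length(x$sensor_id), " sensors\n", sep = "")
  invisible(x)
}

#' Tidy a selection trajectory into long form
#'
#' @param x A `selection_trajectory`.
#' @param ... Unused.
#' @return Tibble `round`, `sensor_id`, `abundance`.
#' @export
tidy.selection_trajectory <- function(x, ...) {
  ab <- x$abundance
  tibble(
    round = rep(as.integer(rownames(ab)), times = ncol(ab)),
    sensor_id = rep(colnames(ab), each = nrow(ab)),
    abundance = as.vector(ab)
  )
}

#' @export
glance.selection_trajectory <- function(x, ...) {
  final <- x$abundance[nrow(x$abundance), ]
  tibble(
    n_rounds = nrow(x$schedule),
    n_sensors = length(x$sensor_id),
    final_max_abundance = max(final),
    final_amplicon_abundance = sum(final[x$is_amplicon])
  )
}

#' Sequencing-checkpoint abundances along a trajectory
#'
#' Emulates tracking by NGS at checkpoints: abundances are multinomially
#' subsampled at the checkpoint's read budget, with detection floor
#' `1/reads` (a sensor sampled to zero reads is below the floor).
#'
#' @param trajectory A `selection_trajectory`.
#' @param checkpoints Rounds to sample (must exist in the trajectory; round
#'   0 is the input library).
#' @param reads_per_checkpoint Total reads per checkpoint.
#' @param seed Integer seed.
#' @return Tibble `round`, `sensor_id`, `reads`, `est_abundance`,
#'   `detection_floor`, `below_floor`.
#' @export
track_abundance <- function(trajectory,
                            checkpoints,
                            reads_per_checkpoint,
                            seed = NULL) {
  rounds <- as.integer(rownames(trajectory$abundance))
  missing_cp <- setdiff(checkpoints, rounds)
  if (length(missing_cp) > 0) {
    abort(paste0("Checkpoint round(s) not in trajectory: ",
                 paste(missing_cp, collapse = ", ")),
          class = "ribosense_input_error")
  }
  with_seed(seed, {
    purrr::map(checkpoints, function(cp) {
      a <- trajectory$abundance[match(cp, rounds), ]
      counts <- as.vector(rmultinom(1, size = reads_per_checkpoint, prob = a))
      tibble(
        round = cp,
        sensor_id = trajectory$sensor_id,
        reads = counts,
        est_abundance = counts / reads_per_checkpoint,
        detection_floor = 1 / reads_per_checkpoint,
        below_floor = counts == 0
      )
    }) |>
      bind_rows()
  })
}
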