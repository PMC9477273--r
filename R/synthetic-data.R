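#' Ribozyme scaffold used for simulated sensor libraries
#'
#' A minimal hammerhead-style scaffold with two variable loops. Stem I uses the
#' helix `ACTGGA:TCCGGT` (one G-C pair weakened to G-U relative to the classic
#' sTRSV stem, which aids splint hybridisation after reverse transcription).
#' The small loop sits inside stem I, the 30-nt aptamer loop inside stem II.
#' Sequences are represented as DNA (the cDNA/read alphabet); the transcribed
#' RNA is the same sequence with T read as U.
#'
#' @format A named character vector of fixed scaffold segments.
#' @keywords internal
scaffold_segments <- c(
  leader  = "GCTGTC",
  stem1a  = "ACTGGA",
  stem1b  = "TCCGGT",
  core    = "CTGATGAGTCC",
  stem2a  = "GTGAGG",
  stem2b  = "CCTCAC",
  tail    = "GAAACAGC"
)

#' Assemble a sensor template sequence from its two loops
#'
#' @param small_loop Character vector of 4-8 nt loop sequences.
#' @param large_loop Character vector of 30 nt aptamer loop sequences.
#' @return Character vector of full template sequences.
#' @export
build_template <- function(small_loop, large_loop) {
  s <- scaffold_segments
  paste0(s[["leader"]], s[["stem1a"]], small_loop, s[["stem1b"]], s[["core"]],
         s[["stem2a"]], large_loop, s[["stem2b"]], s[["tail"]])
}

#' Extract the variable loops from a template sequence
#'
#' Inverse of [build_template()]; loops are located positionally from the
#' fixed scaffold segment lengths.
#'
#' @param template_seq Character vector of template sequences.
#' @return A tibble with columns `small_loop` and `large_loop`.
#' @export
template_loops <- function(template_seq) {
  s <- scaffold_segments
  fixed_len <- sum(nchar(s))
  small_start <- nchar(s[["leader"]]) + nchar(s[["stem1a"]]) + 1L
  small_len <- nchar(template_seq) - fixed_len - 30L
  small <- substr(template_seq, small_start, small_start + small_len - 1L)
  large_start <- small_start + small_len + nchar(s[["stem1b"]]) +
    nchar(s[["core"]]) + nchar(s[["stem2a"]])
  large <- substr(template_seq, large_start, large_start + 29L)
  tibble(small_loop = small, large_loop = large)
}

random_loops <- function(n, length_weights) {
  lens <- as.integer(names(length_weights))
  drawn <- lens[sample.int(length(lens), n, replace = TRUE,
                           prob = length_weights)]
  vapply(drawn, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

check_length_weights <- function(w, allowed, what) {
  if (is.null(names(w)) || anyNA(suppressWarnings(as.integer(names(w))))) {
    abort(paste0(what, " loop length weights must be named by integer length."),
          class = "ribosense_config_error")
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort(paste0(what, " loop length weights must sum to 1."),
          class = "ribosense_config_error")
  }
  if (!all(as.integer(names(w)) %in% allowed)) {
    abort(paste0(what, " loop lengths must be within {",
                 paste(range(allowed), collapse = ".."), "}."),
          class = "ribosense_config_error")
  }
  invisible(w)
}

#' Generate a randomized ribozyme sensor library
#'
#' Simulates a selection library of hammerhead ribozymes in which the two
#' loops are randomized: a short loop of 4-8 nt and a 30-nt aptamer loop, both
#' drawn uniformly over the four bases per position (emulating hand-mixed
#' 25:25:25:25 degenerate synthesis). Reference members (ligand-unresponsive
#' controls used for between-condition normalization) and amplicon parasites
#' (sequences with a condition-independent survival advantage) are flagged.
#' Relative abundances are drawn from a flat Dirichlet over all members.
#'
#' @param n_sensors Number of ordinary library members.
#' @param n_references Number of unresponsive reference members.
#' @param n_amplicons Number of parasitic amplicon members.
#' @param loop_length_weights Optional list with elements `small` and `large`,
#'   each a named numeric vector of probabilities over loop lengths (names are
#'   lengths). Defaults: uniform over 4..8 for the small loop and all mass on
#'   30 for the large loop.
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG.
#' @return A tibble with one row per member: `sensor_id`, `small_loop`,
#'   `large_loop`, `template_seq`, `abundance`, `is_reference`, `is_amplicon`.
#' @export
generate_library <- function(n_sensors,
                             n_references = 0,
                             n_amplicons = 0,
                             loop_length_weights = NULL,
                             seed = NULL) {
  if (n_sensors < 1) {
    abort("`n_sensors` must be >= 1.", class = "ribosense_input_error")
  }
  small_w <- loop_length_weights$small %||% setNames(rep(0.2, 5), 4:8)
  large_w <- loop_length_weights$large %||% c("30" = 1)
  check_length_weights(small_w, 4:8, "Small")
  check_length_weights(large_w, 30L, "Large")

  n_total <- n_sensors + n_references + n_amplicons
  with_seed(seed, {
    small <- random_loops(n_total, small_w)
    large <- random_loops(n_total, large_w)
    abundance <- rgamma(n_total, shape = 1)
    abundance <- abundance / sum(abundance)
    tibble(
      sensor_id = c(
        sprintf("S%06d", seq_len(n_sensors)),
        if (n_references > 0) sprintf("REF%03d", seq_len(n_references)),
        if (n_amplicons > 0) sprintf("AMP%03d", seq_len(n_amplicons))
      ),
      small_loop = small,
      large_loop = large,
      template_seq = build_template(small, large),
      abundance = abundance,
      is_reference = rep(c(FALSE, TRUE, FALSE), c(n_sensors, n_references, n_amplicons)),
      is_amplicon = rep(c(FALSE, FALSE, TRUE), c(n_sensors, n_references, n_amplicons))
    )
  })
}

#' Generate a synthetic small-molecule compound library
#'
#' Compound identifiers follow the plate-well convention (e.g. `"125F11"`).
#' SMILES are drawn from a small template grammar — a scaffold plus one or two
#' substituents from a shared fragment alphabet — so that compounds share
#' substructures and fragment-based response prediction is learnable.
#' Monoisotopic masses are drawn uniformly on `mass_range` (masses are
#' synthetic bookkeeping values, deliberately not computed from the SMILES).
#' Selection-set assignment (A/B) is a balanced random split.
#'
#' @param n_compounds Even number of compounds.
#' @param mass_range Length-2 numeric, Daltons, low then high.
#' @param seed Integer seed.
#' @return A tibble: `compound_id`, `smiles`, `mono_mass`, `selection_set`.
#' @export
generate_compound_library <- function(n_compounds,
                                      mass_range = c(112, 500),
                                      seed = NULL) {
  if (n_compounds %% 2 != 0) {
    abort("`n_compounds` must be even for a balanced A/B split.",
          class = "ribosense_input_error")
  }
  if (mass_range[1] >= mass_range[2]) {
    abort("`mass_range` must be increasing.", class = "ribosense_config_error")
  }
  scaffolds <- c(
    "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCNCC1", "C1CCOC1",
    "c1ccc2[nH]ccc2c1", "c1cnc2ccccc2n1", "C1CCCCC1"
  )
  substituents <- c(
    "C(=O)N", "C(=O)O", "OC", "N(C)C", "CCl", "C#N", "S(=O)(=O)N",
    "CC(C)C", "C(F)(F)F", "OCC", "NC(=O)C", "Cc1ccco1", "Cc1ccccn1"
  )
  with_seed(seed, {
    plate <- sample(100:499, n_compounds, replace = TRUE)
    row <- sample(LETTERS[1:8], n_compounds, replace = TRUE)
    col <- sample(1:12, n_compounds, replace = TRUE)
    compound_id <- sprintf("%d%s%02d", plate, row, col)
    compound_id <- make.unique(compound_id, sep = "x")
    sc <- sample(scaffolds, n_compounds, replace = TRUE)
    s1 <- sample(substituents, n_compounds, replace = TRUE)
    s2 <- sample(c(substituents, ""), n_compounds, replace = TRUE)
    smiles <- paste0(sc, s1, s2)
    half <- n_compounds / 2
    set <- sample(rep(c("A", "B"), each = half))
    tibble(
      compound_id = compound_id,
      smiles = smiles,
      mono_mass = runif(n_compounds, mass_range[1], mass_range[2]),
      selection_set = set
    )
  })
}

#' Generate ground-truth response models for a sensor library
#'
#' Each sensor gets a baseline cleavage fraction `c0 ~ Beta(5, 2)` (the
#' enriched-library regime: most survivors of cleave-selection rounds cleave
#' well). A chosen subset of ordinary sensors ("switchers") respond to one or
#' more target compounds: ligand presence divides the cleavage odds by a
#' saturating fold change `FC(x) = 1 + (fc_max - 1) x / (x + ec50)`, so
#' `FC(0) = 1` and `FC(Inf) = fc_max`. Multiple cognate ligands combine
#' multiplicatively on FC. References and amplicons never get targets.
#'
#' @param library Sensor tibble from [generate_library()].
#' @param compounds Compound tibble; required when `n_responsive > 0` unless
#'   `target_map` is given.
#' @param n_responsive Number of ordinary sensors to make responsive.
#' @param targets_per_sensor Cognate ligands per responsive sensor.
#' @param fc_max_range Log-uniform range for the saturating fold change.
#' @param ec50_range_uM Log-uniform range (micromolar) for the half-effect
#'   concentration.
#' @param c0_shape Beta shape parameters for baseline cleavage.
#' @param target_map Optional explicit tibble (`sensor_id`, `compound_id`,
#'   `fc_max`, `ec50_uM`) overriding the random assignment.
#' @param seed Integer seed.
#' @return A tibble: `sensor_id`, `c0`, and `targets` (list-column of tibbles
#'   with `compound_id`, `fc_max`, `ec50_uM`; empty for non-responders).
#' @export
generate_response_models <- function(library,
                                     compounds = NULL,
                                     n_responsive = 0,
                                     targets_per_sensor = 1,
                                     fc_max_range = c(2, 17),
                                     ec50_range_uM = c(0.025, 5),
                                     c0_shape = c(5, 2),
                                     target_map = NULL,
                                     seed = NULL) {
  assert_columns(library, c("sensor_id", "is_reference", "is_amplicon"))
  with_seed(seed, {
    c0 <- rbeta_clamped(nrow(library), c0_shape[1], c0_shape[2])
    if (is.null(target_map)) {
      target_map <- tibble(sensor_id = character(), compound_id = character(),
                           fc_max = numeric(), ec50_uM = numeric())
      if (n_responsive > 0) {
        if (is.null(compounds)) {
          abort("`compounds` is required when `n_responsive` > 0.",
                class = "ribosense_input_error")
        }
        eligible <- library$sensor_id[!library$is_reference & !library$is_amplicon]
        chosen <- sample(eligible, n_responsive)
        target_map <- tibble(
          sensor_id = rep(chosen, each = targets_per_sensor),
          compound_id = unlist(lapply(chosen, function(s) {
            sample(compounds$compound_id, targets_per_sensor)
          })),
          fc_max = exp(runif(n_responsive * targets_per_sensor,
                             log(fc_max_range[1]), log(fc_max_range[2]))),
          ec50_uM = exp(runif(n_responsive * targets_per_sensor,
                              log(ec50_range_uM[1]), log(ec50_range_uM[2])))
        )
      }
    }
    bad <- intersect(
      target_map$sensor_id,
      library$sensor_id[library$is_reference | library$is_amplicon]
    )
    if (length(bad) > 0) {
      abort("Reference/amplicon sensors cannot have targets.",
            class = "ribosense_input_error")
    }
    targets <- split(
      target_map[c("compound_id", "fc_max", "ec50_uM")],
      factor(target_map$sensor_id, levels = library$sensor_id)
    )
    tibble(
      sensor_id = library$sensor_id,
      c0 = c0,
      targets = lapply(targets, as_tibble)
    )
  })
}

# Beta draw bounded away from the {0, 1} boundary so odds are finite.
rbeta_clamped <- function(n, a, b, eps = 1e-4) {
  pmin(1 - eps, pmax(eps, stats::rbeta(n, a, b)))
}

#' Saturating fold-change of a response model at given ligand concentrations
#'
#' `FC(x) = 1 + (fc_max - 1) x / (x + ec50)`, combined multiplicatively over
#' all cognate ligands present in the condition.
#'
#' @param targets Tibble with `compound_id`, `fc_max`, `ec50_uM` (one model).
#' @param condition Tibble with `compound_id`, `concentration_uM`, or `NULL`
#'   for the no-ligand condition.
#' @return A single fold-change multiplier (>= 1).
#' @export
model_fold_change <- function(targets, condition = NULL) {
  if (is.null(condition) || nrow(condition) == 0 ||
      is.null(targets) || nrow(targets) == 0) {
    return(1)
  }
  idx <- match(targets$compound_id, condition$compound_id)
  hit <- which(!is.na(idx))
  if (length(hit) == 0) {
    return(1)
  }
  x <- condition$concentration_uM[idx[hit]]
  prod(1 + (targets$fc_max[hit] - 1) * x / (x + targets$ec50_uM[hit]))
}

#' Simulate a cleavage-sequencing count table for one condition
#'
#' Forward model of the assay: reads per sensor are multinomial over the
#' library abundances at the given total depth, and cleaved reads per sensor
#' are binomial with cleavage probability `c` where
#' `odds(c) = bias * odds(c0) / FC(condition)`. A `bias` other than 1 emulates
#' a condition-wide odds shift (e.g. ligation or RT efficiency differences)
#' that reference sensors are used to remove downstream.
#'
#' @param library Sensor tibble.
#' @param models Response-model tibble from [generate_response_models()].
#' @param condition Tibble (`compound_id`, `concentration_uM`) or `NULL`.
#' @param condition_id Label stored in the output.
#' @param depth Total read count across the library.
#' @param bias Condition-wide odds multiplier (default 1 = unbiased).
#' @param compounds Optional compound tibble; if given, condition compounds
#'   must exist in it.
#' @param seed Integer seed.
#' @return A count table tibble: `sensor_id`, `condition_id`, `cleaved`,
#'   `uncleaved`.
#' @export
simulate_cleaveseq_counts <- function(library,
                                      models,
                                      condition = NULL,
                                      condition_id = "cond",
                                      depth = 1e5,
                                      bias = 1,
                                      compounds = NULL,
                                      seed = NULL) {
  assert_columns(library, c("sensor_id", "abundance"))
  assert_columns(models, c("sensor_id", "c0", "targets"))
  if (depth < 1) {
    abort("`depth` must be >= 1.", class = "ribosense_input_error")
  }
  if (!is.null(condition) && nrow(condition) > 0) {
    assert_columns(condition, c("compound_id", "concentration_uM"))
    if (!is.null(compounds)) {
      unknown <- setdiff(condition$compound_id, compounds$compound_id)
      if (length(unknown) > 0) {
        abort(paste0("Condition references unknown compound(s): ",
                     paste(head(unknown, 5), collapse = ", ")),
              class = "ribosense_input_error")
      }
    }
  }
  missing_models <- setdiff(library$sensor_id, models$sensor_id)
  if (length(missing_models) > 0) {
    abort("Every library sensor needs a response model.",
          class = "ribosense_input_error")
  }
  m <- models[match(library$sensor_id, models$sensor_id), ]
  fc <- vapply(m$targets, model_fold_change, numeric(1), condition = condition)
  p_cleave <- plogis(log(bias) + qlogis(m$c0) - log(fc))
  with_seed(seed, {
    reads <- as.integer(rmultinom(1, size = depth, prob = library$abundance))
    cleaved <- rbinom(length(reads), size = reads, prob = p_cleave)
    tibble(
      sensor_id = library$sensor_id,
      condition_id = condition_id,
      cleaved = cleaved,
      uncleaved = reads - cleaved
    )
  })
}

#' Default read-structure constants for simulated runs
#'
#' The cleaved and uncleaved products carry distinct 5' prefixes (ligated
#' after reverse transcription) that a counting step uses to separate the two
#' populations; all reads share a common 3' suffix.
#'
#' @export
default_prefix_map <- c(cleaved = "CTTCAGCG", uncleaved = "AAGTGACC")

#' @rdname default_prefix_map
#' @export
default_suffix <- "CTGCAGGTCGAC"

#' Write simulated reads for a count table
#'
#' Emits one read per counted molecule: `[barcode] + prefix + template +
#' suffix`, with the prefix chosen by cleavage state. Round-trips through
#' [count_reads()] to the identical count table.
#'
#' @param table Count table (`sensor_id`, `condition_id`, `cleaved`,
#'   `uncleaved`).
#' @param library Sensor tibble supplying `template_seq` per sensor.
#' @param path Output file path.
#' @param format `"fastq"` or `"fasta"`.
#' @param prefix_map Named character vector with entries `cleaved` and
#'   `uncleaved`; the two prefixes must differ and neither may be a prefix of
#'   the other.
#' @param suffix Common 3' suffix.
#' @param barcode_table Optional tibble (`condition_id`, `barcode`) prepended
#'   per condition; required when `table` holds multiple conditions.
#' @return The path, invisibly.
#' @export
emit_reads <- function(table,
                       library,
                       path,
                       format = c("fastq", "fasta"),
                       prefix_map = default_prefix_map,
                       suffix = default_suffix,
                       barcode_table = NULL) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort("`format` must be \"fastq\" or \"fasta\".",
          class = "ribosense_input_error")
  })
  check_prefix_map(prefix_map)
  assert_columns(table, c("sensor_id", "condition_id", "cleaved", "uncleaved"))
  assert_columns(library, c("sensor_id", "template_seq"))
  if (is.null(barcode_table) && n_distinct(table$condition_id) > 1) {
    abort("Multiple conditions require a `barcode_table`.",
          class = "ribosense_input_error")
  }
  tab <- left_join(table, library[c("sensor_id", "template_seq")],
                   by = "sensor_id")
  if (anyNA(tab$template_seq)) {
    abort("Count table contains sensors absent from `library`.",
          class = "ribosense_input_error")
  }
  bc <- rep("", nrow(tab))
  if (!is.null(barcode_table)) {
    assert_columns(barcode_table, c("condition_id", "barcode"))
    bc <- barcode_table$barcode[match(tab$condition_id, barcode_table$condition_id)]
    if (anyNA(bc)) {
      abort("Count table contains conditions absent from `barcode_table`.",
            class = "ribosense_input_error")
    }
  }
  seqs <- if (nrow(tab) == 0) {
    character(0)
  } else {
    c(
      rep(paste0(bc, prefix_map[["cleaved"]], tab$template_seq, suffix),
          tab$cleaved),
      rep(paste0(bc, prefix_map[["uncleaved"]], tab$template_seq, suffix),
          tab$uncleaved)
    )
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read%07d", seq_along(reads))
  if (format == "fastq") {
    quals <- Biostrings::PhredQuality(
      vapply(Biostrings::width(reads),
             function(w) paste(rep("I", w), collapse = ""), character(1))
    )
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(reads, path, format = "fasta")
  }
  invisible(path)
}

check_prefix_map <- function(prefix_map) {
  if (!all(c("cleaved", "uncleaved") %in% names(prefix_map))) {
    abort("`prefix_map` needs named entries `cleaved` and `uncleaved`.",
          class = "ribosense_config_error")
  }
  z <- prefix_map[["cleaved"]]
  w <- prefix_map[["uncleaved"]]
  if (z == w || startsWith(z, w) || startsWith(w, z)) {
    abort("Cleaved/uncleaved prefixes must differ and neither may be a prefix of the other.",
          class = "ribosense_config_error")
  }
  invisible(prefix_map)
}

#' Simulate pooled LC-MS peak lists for mixture verification
#'
#' Each compound is assigned a true retention time; every analyzed pool that
#' contains the compound then yields one peak per adduct (with small m/z and
#' retention-time jitter and log-normal intensity), unless the compound drops
#' out of that pool (probability `dropout`, applied per compound-pool pair so
#' all adducts vanish together — emulating injection/ionisation failures).
#'
#' @param compounds Compound tibble (`compound_id`, `mono_mass`).
#' @param membership Long pool membership tibble (`compound_id`, `pool_id`),
#'   e.g. `tidy(design)` restricted to the analyzed pools.
#' @param adducts Adduct names understood by [expected_adduct_mz()].
#' @param dropout Per compound-pool dropout probability.
#' @param rt_range Retention-time window (minutes) for true elution times.
#' @param mz_sd_ppm,rt_sd Measurement jitter (ppm of m/z; minutes).
#' @param seed Integer seed.
#' @return A peak tibble (`pool_id`, `mz`, `rt`, `intensity`) with the true
#'   per-compound retention times attached as attribute `true_rt`.
#' @export
simulate_peak_lists <- function(compounds,
                                membership,
                                adducts = c("M+H", "M+Na", "M+NH4"),
                                dropout = 0,
                                rt_range = c(0.5, 12),
                                mz_sd_ppm = 2,
                                rt_sd = 0.01,
                                seed = NULL) {
  assert_columns(compounds, c("compound_id", "mono_mass"))
  assert_columns(membership, c("compound_id", "pool_id"))
  with_seed(seed, {
    true_rt <- tibble(
      compound_id = compounds$compound_id,
      rt = runif(nrow(compounds), rt_range[1], rt_range[2])
    )
    mem <- membership |>
      inner_join(compounds[c("compound_id", "mono_mass")], by = "compound_id") |>
      inner_join(true_rt, by = "compound_id")
    keep <- runif(nrow(mem)) >= dropout
    mem <- mem[keep, , drop = FALSE]
    peaks <- tidyr::crossing(mem, adduct = adducts) |>
      mutate(
        mz = expected_adduct_mz(.data$mono_mass, .data$adduct),
        mz = .data$mz * (1 + rnorm(n(), 0, mz_sd_ppm * 1e-6)),
        rt = .data$rt + rnorm(n(), 0, rt_sd),
        intensity = rlnorm(n(), meanlog = 10, sdlog = 0.5)
      ) |>
      select("pool_id", "mz", "rt", "intensity")
    attr(peaks, "true_rt") <- true_rt
    peaks
  })
}

#' Dump ground truth for a simulated study as JSON
#'
#' Persists the sensor library and response models so recovery tests can be
#' scored offline.
#'
#' @param library,models Tibbles from the generators.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(library, models, path) {
  truth <- list(
    library = library,
    models = list(
      sensor_id = models$sensor_id,
      c0 = models$c0,
      targets = models$targets
    )
  )
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}
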