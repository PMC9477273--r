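#' Count cleaved/uncleaved reads per ribozyme
#'
#' Assigns each merged read to a condition (exact barcode match, optional), a
#' cleavage state (5' prefix, within `mismatch_tolerance` substitutions), and
#' a ribozyme (exact insert identity), and tallies a count table. Unassignable
#' reads are never silently dropped: they are tallied by failure mode in the
#' `unassigned` attribute of the result.
#'
#' @param reads A file path (FASTA/FASTQ, by extension), a
#'   `Biostrings::DNAStringSet`, or a character vector of read sequences.
#' @param prefix_map Named character vector (`cleaved`, `uncleaved`).
#' @param suffix Common 3' suffix (matched at the read end within
#'   `mismatch_tolerance`).
#' @param sensors Optional sensor tibble (`sensor_id`, `template_seq`); when
#'   given, inserts are mapped to sensor ids and unmatched inserts keep the
#'   insert sequence as their id.
#' @param barcode_table Optional tibble (`condition_id`, `barcode`): reads
#'   must start with exactly one of the barcodes (matched exactly; variable
#'   lengths 1-10 nt supported, longest match wins).
#' @param condition_id Condition label used when no `barcode_table` is given.
#' @param mismatch_tolerance Substitutions allowed in prefix and suffix
#'   matches. A read within tolerance of both prefixes is ambiguous and goes
#'   to the unassigned tally.
#' @return A count table tibble (`sensor_id`, `condition_id`, `cleaved`,
#'   `uncleaved`) with attribute `unassigned`, a named integer vector with
#'   entries `unknown_barcode`, `no_prefix`, `ambiguous_prefix`, `no_suffix`.
#' @export
count_reads <- function(reads,
                        prefix_map = default_prefix_map,
                        suffix = default_suffix,
                        sensors = NULL,
                        barcode_table = NULL,
                        condition_id = "sample",
                        mismatch_tolerance = 0) {
  check_prefix_map(prefix_map)
  seqs <- read_sequences(reads)
  unassigned <- c(unknown_barcode = 0L, no_prefix = 0L,
                  ambiguous_prefix = 0L, no_suffix = 0L)
  if (length(seqs) == 0) {
    out <- tibble(sensor_id = character(), condition_id = character(),
                  cleaved = integer(), uncleaved = integer())
    attr(out, "unassigned") <- unassigned
    return(out)
  }

  cond <- rep(condition_id, length(seqs))
  if (!is.null(barcode_table)) {
    assert_columns(barcode_table, c("condition_id", "barcode"))
    bt <- barcode_table[order(-nchar(barcode_table$barcode)), ]
    cond <- rep(NA_character_, length(seqs))
    consumed <- integer(length(seqs))
    for (i in seq_len(nrow(bt))) {
      hit <- is.na(cond) & startsWith(seqs, bt$barcode[i])
      cond[hit] <- bt$condition_id[i]
      consumed[hit] <- nchar(bt$barcode[i])
    }
    unassigned[["unknown_barcode"]] <- sum(is.na(cond))
    keep <- !is.na(cond)
    seqs <- substr(seqs[keep], consumed[keep] + 1L, nchar(seqs[keep]))
    cond <- cond[keep]
  }

  dz <- hamming_to(seqs, prefix_map[["cleaved"]])
  dw <- hamming_to(seqs, prefix_map[["uncleaved"]])
  z_ok <- dz <= mismatch_tolerance
  w_ok <- dw <= mismatch_tolerance
  ambiguous <- z_ok & w_ok
  none <- !z_ok & !w_ok
  unassigned[["ambiguous_prefix"]] <- sum(ambiguous)
  unassigned[["no_prefix"]] <- sum(none)
  keep <- xor(z_ok, w_ok)
  seqs <- seqs[keep]
  cond <- cond[keep]
  cleaved_state <- z_ok[keep]
  plen <- ifelse(cleaved_state, nchar(prefix_map[["cleaved"]]),
                 nchar(prefix_map[["uncleaved"]]))

  slen <- nchar(suffix)
  tail_seq <- substr(seqs, nchar(seqs) - slen + 1L, nchar(seqs))
  suffix_ok <- nchar(seqs) >= plen + slen &
    hamming_to(tail_seq, suffix) <= mismatch_tolerance
  unassigned[["no_suffix"]] <- sum(!suffix_ok)
  seqs <- seqs[suffix_ok]
  cond <- cond[suffix_ok]
  cleaved_state <- cleaved_state[suffix_ok]
  plen <- plen[suffix_ok]
  insert <- substr(seqs, plen + 1L, nchar(seqs) - slen)

  sensor <- insert
  if (!is.null(sensors)) {
    assert_columns(sensors, c("sensor_id", "template_seq"))
    idx <- match(insert, sensors$template_seq)
    sensor <- ifelse(is.na(idx), insert, sensors$sensor_id[idx])
  }

  out <- tibble(sensor_id = sensor, condition_id = cond,
                state = ifelse(cleaved_state, "cleaved", "uncleaved")) |>
    count(.data$sensor_id, .data$condition_id, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L)
  for (col in c("cleaved", "uncleaved")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- out |>
    select("sensor_id", "condition_id", "cleaved", "uncleaved") |>
    arrange(.data$sensor_id, .data$condition_id)
  attr(out, "unassigned") <- unassigned
  out
}

read_sequences <- function(reads) {
  if (inherits(reads, "DNAStringSet")) {
    return(as.character(reads))
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  as.character(reads)
}

#' Between-condition normalization factor from reference sequences
#'
#' Reference sensors are known to be unaffected by the condition difference,
#' so their raw fold changes estimate a condition-wide odds bias `k` (from
#' e.g. ligation or RT efficiency differences). `k` is the median raw fold
#' change over usable references — robust to a responsive contaminant — and
#' downstream fold changes are divided by it. With fewer than
#' `min_references` usable references a warning is issued and `k = 1`.
#'
#' @param counts_ref,counts_test Count tibbles (`sensor_id`, `cleaved`,
#'   `uncleaved`) for the reference (no-ligand) and test conditions.
#' @param reference_ids Sensor ids of the reference set.
#' @param min_reads Minimum total reads per condition for a usable reference.
#' @param min_references Minimum usable references.
#' @param pseudocount Added to every count before forming odds.
#' @return The scalar odds multiplier `k`.
#' @export
normalize_by_references <- function(counts_ref,
                                    counts_test,
                                    reference_ids,
                                    min_reads = 100,
                                    min_references = 3,
                                    pseudocount = 0.5) {
  assert_columns(counts_ref, c("sensor_id", "cleaved", "uncleaved"))
  assert_columns(counts_test, c("sensor_id", "cleaved", "uncleaved"))
  refs <- inner_join(
    counts_ref[counts_ref$sensor_id %in% reference_ids, ],
    counts_test[counts_test$sensor_id %in% reference_ids, ],
    by = "sensor_id", suffix = c("_ref", "_test")
  ) |>
    filter(.data$cleaved_ref + .data$uncleaved_ref >= min_reads,
           .data$cleaved_test + .data$uncleaved_test >= min_reads)
  if (nrow(refs) < min_references) {
    warn(paste0("Only ", nrow(refs), " usable reference sensor(s) (need ",
                min_references, "); using k = 1."))
    return(1)
  }
  fc <- ((refs$cleaved_ref + pseudocount) * (refs$uncleaved_test + pseudocount)) /
    ((refs$uncleaved_ref + pseudocount) * (refs$cleaved_test + pseudocount))
  median(fc)
}

#' Fold change of cleavage with delta-method intervals
#'
#' The core statistic: for a sensor measured without ligand (`a_ref` cleaved,
#' `b_ref` uncleaved reads) and with ligand (`a_test`, `b_test`), the fold
#' change of cleavage is the odds ratio
#' `fc = (a_ref * b_test) / (b_ref * a_test) / k`
#' computed on Haldane-Anscombe pseudocounted counts (default +1/2, making
#' zero counts usable), where `k` is the reference-based normalization
#' multiplier. On the log scale the delta-method standard error is
#' `se = sqrt(1/a' + 1/b' + 1/c' + 1/d')`, giving Wald intervals
#' `exp(log fc +/- z * se)` and a two-sided normal p-value for `log fc = 0`.
#' A fold change above 1 means the ligand inhibits cleavage.
#'
#' All count arguments are vectorised.
#'
#' @param a_ref,b_ref Cleaved/uncleaved counts without ligand.
#' @param a_test,b_test Cleaved/uncleaved counts with ligand.
#' @param k Normalization odds multiplier (scalar or vector).
#' @param pseudocount Added to every count (default 0.5).
#' @param sensor_id,condition_id Optional labels carried into the output.
#' @return A tibble with one row per input element: cleavage fractions (raw
#'   counts), `fc`, `log_fc`, `se_log_fc`, 90% and 95% CI bounds, `p_value`,
#'   per-condition and total read counts.
#' @export
fold_change <- function(a_ref, b_ref, a_test, b_test,
                        k = 1,
                        pseudocount = 0.5,
                        sensor_id = NULL,
                        condition_id = NULL) {
  if (any(c(a_ref, b_ref, a_test, b_test) < 0)) {
    abort("Counts must be non-negative.", class = "ribosense_input_error")
  }
  ap <- a_ref + pseudocount
  bp <- b_ref + pseudocount
  cp <- a_test + pseudocount
  dp <- b_test + pseudocount
  log_fc <- log(ap) + log(dp) - log(bp) - log(cp) - log(k)
  se <- sqrt(1 / ap + 1 / bp + 1 / cp + 1 / dp)
  z90 <- qnorm(0.95)
  z95 <- qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(log_fc) / se)
  out <- tibble(
    cleavage_fraction_ref = a_ref / (a_ref + b_ref),
    cleavage_fraction_test = a_test / (a_test + b_test),
    fc = exp(log_fc),
    log_fc = log_fc,
    se_log_fc = se,
    ci90_lo = exp(log_fc - z90 * se),
    ci90_hi = exp(log_fc + z90 * se),
    ci95_lo = exp(log_fc - z95 * se),
    ci95_hi = exp(log_fc + z95 * se),
    p_value = p,
    n_reads_ref = a_ref + b_ref,
    n_reads_test = a_test + b_test,
    n_total_reads = a_ref + b_ref + a_test + b_test
  )
  if (!is.null(condition_id)) {
    out <- mutate(out, condition_id = condition_id, .before = 1)
  }
  if (!is.null(sensor_id)) {
    out <- mutate(out, sensor_id = sensor_id, .before = 1)
  }
  out
}

#' Fold changes for all sensors between a reference and test conditions
#'
#' Data-frame-first wrapper around [fold_change()]: joins the count table's
#' reference (no-ligand) condition against each test condition, estimates the
#' normalization multiplier `k` from `reference_ids` when provided, and
#' returns one fold-change record per sensor per test condition.
#'
#' @param counts Count table (`sensor_id`, `condition_id`, `cleaved`,
#'   `uncleaved`).
#' @param reference_condition The no-ligand condition id.
#' @param test_conditions Test condition ids; default all others.
#' @param reference_ids Optional reference sensor ids for normalization.
#' @param pseudocount,min_reads,min_references Passed through.
#' @return A fold-change tibble; attribute `k` holds the per-test-condition
#'   normalization multipliers.
#' @export
compare_conditions <- function(counts,
                               reference_condition,
                               test_conditions = NULL,
                               reference_ids = NULL,
                               pseudocount = 0.5,
                               min_reads = 100,
                               min_references = 3) {
  assert_columns(counts, c("sensor_id", "condition_id", "cleaved", "uncleaved"))
  ref <- counts[counts$condition_id == reference_condition, ]
  if (nrow(ref) == 0) {
    abort("Reference condition not present in `counts`.",
          class = "ribosense_input_error")
  }
  test_conditions <- test_conditions %||%
    setdiff(unique(counts$condition_id), reference_condition)
  ks <- setNames(numeric(length(test_conditions)), test_conditions)
  res <- purrr::map(test_conditions, function(tc) {
    test <- counts[counts$condition_id == tc, ]
    k <- 1
    if (!is.null(reference_ids)) {
      k <- normalize_by_references(ref, test, reference_ids,
                                   min_reads = min_reads,
                                   min_references = min_references,
                                   pseudocount = pseudocount)
    }
    ks[[tc]] <<- k
    joined <- inner_join(ref, test, by = "sensor_id",
                         suffix = c("_ref", "_test"))
    fold_change(joined$cleaved_ref, joined$uncleaved_ref,
                joined$cleaved_test, joined$uncleaved_test,
                k = k, pseudocount = pseudocount,
                sensor_id = joined$sensor_id,
                condition_id = tc)
  })
  out <- bind_rows(res)
  attr(out, "k") <- ks
  out
}

#' Flag significant responders under Bonferroni control
#'
#' A record is significant when its two-sided p-value clears the Bonferroni
#' threshold `p < 1/n_tested`, both conditions have at least `min_reads`
#' reads, and the fold change clears `fc_threshold` in the tested direction
#' (`"gain"`: fc >= threshold, ligand-inhibited cleavage; `"loss"`:
#' fc <= 1/threshold; `"both"`: either).
#'
#' @param records Fold-change tibble from [fold_change()] /
#'   [compare_conditions()].
#' @param n_tested Number of sequences tested (the Bonferroni family size N).
#' @param min_reads Minimum reads per condition.
#' @param fc_threshold Fold-change threshold.
#' @param direction `"gain"`, `"loss"`, or `"both"`.
#' @return `records` with a logical `significant` column.
#' @export
call_significant <- function(records,
                             n_tested,
                             min_reads = 100,
                             fc_threshold = 2.0,
                             direction = c("gain", "loss", "both")) {
  direction <- match.arg(direction)
  if (is.null(n_tested) || length(n_tested) != 1 || is.na(n_tested) ||
      n_tested < 1) {
    abort("`n_tested` must be a positive count.",
          class = "ribosense_input_error")
  }
  assert_columns(records, c("fc", "p_value", "n_reads_ref", "n_reads_test"))
  fc_ok <- switch(direction,
    gain = records$fc >= fc_threshold,
    loss = records$fc <= 1 / fc_threshold,
    both = records$fc >= fc_threshold | records$fc <= 1 / fc_threshold
  )
  mutate(records,
         significant = .data$p_value < 1 / n_tested &
           .data$n_reads_ref >= min_reads &
           .data$n_reads_test >= min_reads &
           fc_ok)
}

#' Read / write count tables as TSV
#'
#' @param x Count table tibble.
#' @param path File path.
#' @return `write_count_table()` the path invisibly; `read_count_table()` the
#'   tibble.
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sensor_id = readr::col_character(),
    condition_id = readr::col_character(),
    cleaved = readr::col_integer(),
    uncleaved = readr::col_integer()
  ))
}

#' Write fold-change records as TSV
#'
#' @param records Fold-change tibble.
#' @param path File path.
#' @export
write_fold_changes <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
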