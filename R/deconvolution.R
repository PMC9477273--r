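#' Classify pools as responsive / nonresponsive / indeterminate
#'
#' Applies the significance rule per pool measurement: a pool is responsive
#' when the record is significant (Bonferroni p < 1/N, read depth, fold
#' change >= threshold), nonresponsive when even the upper 95% confidence
#' bound stays below the threshold, and indeterminate otherwise (too noisy to
#' call either way). Pools in the design but absent from the records are
#' treated as indeterminate by [decode_pools()].
#'
#' @param records Fold-change tibble for sensors x pools (`condition_id` is
#'   the pool id).
#' @param n_tested Bonferroni family size N.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param min_reads Minimum reads per condition for a significant call.
#' @return `records` with `significant` and a `pool_class` factor column.
#' @export
classify_pools <- function(records,
                           n_tested,
                           fc_threshold = 2.0,
                           min_reads = 100) {
  records <- call_significant(records, n_tested = n_tested,
                              min_reads = min_reads,
                              fc_threshold = fc_threshold,
                              direction = "gain")
  assert_columns(records, "ci95_hi")
  mutate(records,
         pool_class = dplyr::case_when(
           .data$significant ~ "responsive",
           .data$ci95_hi < fc_threshold ~ "nonresponsive",
           TRUE ~ "indeterminate"
         ))
}

#' Group-testing decode of sensor-ligand assignments from pooled responses
#'
#' For each sensor, compares its set of responsive pools against the pool
#' membership of every compound. A compound is a candidate when it is present
#' in at least `support_min` of its measured pools that are responsive and in
#' at most `violations_max` nonresponsive pools. A greedy set cover over the
#' responsive pools (ties broken by higher support, then fewer violations,
#' then lexical compound id) gives the minimal explanation. Sensors
#' responding in more than `pool_fraction_cap` of their measured pools, or
#' whose minimal explanation needs more than `promiscuity_cap` distinct
#' compounds, are flagged promiscuous — their pool pattern carries too
#' little information to decode.
#'
#' @param classified Output of [classify_pools()] (may span many sensors;
#'   `condition_id` is the pool id).
#' @param design A `pool_design`.
#' @param support_min Fraction of a compound's measured pools that must be
#'   responsive (default 0.8, tolerating one dropped pool of 9).
#' @param violations_max Nonresponsive pools tolerated per candidate.
#' @param promiscuity_cap Minimal-explanation size above which a sensor is
#'   promiscuous.
#' @param pool_fraction_cap Responsive-fraction guard for promiscuity.
#' @param exact For sensors with at most 12 candidates, verify the greedy
#'   cover against exhaustive minimal-cover enumeration and use the
#'   enumerated cover when they differ.
#' @return A tibble with one row per sensor: `sensor_id`, `status`
#'   (`decoded`, `incomplete_cover`, `promiscuous`, `no_response`), pool
#'   class counts, a `candidates` list-column (tibbles with `compound_id`,
#'   `support`, `violations`, `n_measured`, `max_pool_fc`), and a
#'   `minimal_cover` list-column (character vectors).
#' @export
decode_pools <- function(classified,
                         design,
                         support_min = 0.8,
                         violations_max = 1,
                         promiscuity_cap = 10,
                         pool_fraction_cap = 0.5,
                         exact = FALSE) {
  assert_columns(classified, c("sensor_id", "condition_id", "fc", "pool_class"))
  all_pools <- unique(design$membership$pool_id)
  unknown <- setdiff(unique(classified$condition_id), all_pools)
  if (length(unknown) > 0) {
    abort(paste0("Measured pool(s) absent from design: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "ribosense_input_error")
  }
  res <- classified |>
    group_by(.data$sensor_id) |>
    dplyr::group_map(function(rows, key) {
      decode_one(key$sensor_id, rows, design, support_min, violations_max,
                 promiscuity_cap, pool_fraction_cap, exact)
    }) |>
    bind_rows()
  res
}

decode_one <- function(sensor_id, rows, design, support_min, violations_max,
                       promiscuity_cap, pool_fraction_cap, exact) {
  measured <- rows$condition_id
  responsive <- measured[rows$pool_class == "responsive"]
  nonresponsive <- measured[rows$pool_class == "nonresponsive"]
  unmeasured <- setdiff(unique(design$membership$pool_id), measured)
  indeterminate <- c(measured[rows$pool_class == "indeterminate"], unmeasured)

  base <- tibble(
    sensor_id = sensor_id,
    n_responsive = length(responsive),
    n_nonresponsive = length(nonresponsive),
    n_indeterminate = length(indeterminate)
  )
  empty_cand <- tibble(compound_id = character(), support = integer(),
                       violations = integer(), n_measured = integer(),
                       max_pool_fc = numeric())
  if (length(responsive) == 0) {
    return(mutate(base, status = "no_response",
                  candidates = list(empty_cand),
                  minimal_cover = list(character())))
  }

  stats <- design$membership |>
    mutate(class = dplyr::case_when(
      .data$pool_id %in% responsive ~ "responsive",
      .data$pool_id %in% nonresponsive ~ "nonresponsive",
      TRUE ~ "indeterminate"
    )) |>
    group_by(.data$compound_id) |>
    summarise(
      support = sum(.data$class == "responsive"),
      violations = sum(.data$class == "nonresponsive"),
      n_measured = sum(.data$class != "indeterminate"),
      .groups = "drop"
    )
  cand <- stats |>
    filter(.data$n_measured > 0,
           .data$support >= support_min * .data$n_measured,
           .data$violations <= violations_max)

  pool_fc <- setNames(rows$fc, rows$condition_id)
  cand_pools <- compound_pools(design, cand$compound_id)
  cand$max_pool_fc <- vapply(cand$compound_id, function(cid) {
    rp <- intersect(cand_pools[[cid]], responsive)
    if (length(rp) == 0) NA_real_ else max(pool_fc[rp], na.rm = TRUE)
  }, numeric(1))
  cand <- arrange(cand, desc(.data$support), .data$violations,
                  .data$compound_id)

  # promiscuity: the sensor responds in most pools, or explaining its
  # pattern needs more distinct compounds than the cap
  if (length(responsive) / length(measured) > pool_fraction_cap) {
    return(mutate(base, status = "promiscuous",
                  candidates = list(cand),
                  minimal_cover = list(character())))
  }

  cover <- greedy_set_cover(responsive, cand, cand_pools)
  if (exact && nrow(cand) <= 12) {
    pools_of <- lapply(cand_pools, function(p) intersect(p, responsive))
    exact_covers <- minimal_exact_covers(cand$compound_id, pools_of,
                                         covered_pattern(pools_of, responsive),
                                         max_size = nrow(cand))
    if (length(exact_covers) > 0 &&
        length(exact_covers[[1]]) < length(cover)) {
      cover <- sort(exact_covers[[1]])
    }
  }
  covered <- unique(unlist(cand_pools[cover]))
  status <- if (length(cover) > promiscuity_cap) {
    "promiscuous"
  } else if (all(responsive %in% covered)) {
    "decoded"
  } else {
    "incomplete_cover"
  }
  mutate(base, status = status,
         candidates = list(cand),
         minimal_cover = list(cover))
}

covered_pattern <- function(pools_of, responsive) {
  sort(intersect(unique(unlist(pools_of)), responsive))
}

greedy_set_cover <- function(responsive, cand, cand_pools) {
  uncovered <- responsive
  cover <- character()
  remaining <- cand
  while (length(uncovered) > 0 && nrow(remaining) > 0) {
    gain <- vapply(remaining$compound_id, function(cid) {
      length(intersect(cand_pools[[cid]], uncovered))
    }, integer(1))
    if (max(gain) == 0) break
    # ties: remaining is pre-sorted by support desc, violations, id
    pick <- remaining$compound_id[which.max(gain)]
    cover <- c(cover, pick)
    uncovered <- setdiff(uncovered, cand_pools[[pick]])
    remaining <- remaining[remaining$compound_id != pick, ]
  }
  cover
}

#' Rank compounds for single-compound confirmation runs
#'
#' Deduplicates the candidate compounds across decoded (and
#' incomplete-cover) sensors and ranks them by the number of sensors
#' implicating each compound, then by the maximum pooled fold change,
#' truncating to `max_singles`.
#'
#' @param results Output of [decode_pools()].
#' @param max_singles Maximum compounds returned.
#' @return A tibble `compound_id`, `n_sensors`, `max_pool_fc`, `sensors`
#'   (list-column), ranked.
#' @export
propose_confirmations <- function(results, max_singles = Inf) {
  usable <- results[results$status %in% c("decoded", "incomplete_cover"), ]
  if (nrow(usable) == 0) {
    return(tibble(compound_id = character(), n_sensors = integer(),
                  max_pool_fc = numeric(), sensors = list()))
  }
  long <- usable |>
    select("sensor_id", "candidates") |>
    tidyr::unnest("candidates")
  long |>
    group_by(.data$compound_id) |>
    summarise(
      n_sensors = n_distinct(.data$sensor_id),
      max_pool_fc = suppressWarnings(max(.data$max_pool_fc, na.rm = TRUE)),
      sensors = list(sort(unique(.data$sensor_id))),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_sensors), desc(.data$max_pool_fc),
            .data$compound_id) |>
    (\(d) if (is.finite(max_singles)) slice_head(d, n = max_singles) else d)()
}

#' Write deconvolution results as a flat TSV
#'
#' One row per sensor with candidate compounds serialized as
#' `id;support;violations` triples.
#'
#' @param results Output of [decode_pools()].
#' @param path File path.
#' @export
write_deconvolution <- function(results, path) {
  flat <- results |>
    mutate(candidates = vapply(.data$candidates, function(tb) {
      paste(sprintf("%s;%d;%d", tb$compound_id, tb$support, tb$violations),
            collapse = ",")
    }, character(1)),
    minimal_cover = vapply(.data$minimal_cover, paste, character(1),
                           collapse = ",")) |>
    select("sensor_id", "status", "n_responsive", "n_nonresponsive",
           "n_indeterminate", "candidates", "minimal_cover")
  readr::write_tsv(flat, path)
  invisible(path)
}
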