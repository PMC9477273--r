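#' Noise-scaled response distance between two sensors
#'
#' The d' distance between two sensors' response profiles is the maximum,
#' over the conditions measured for both, of the absolute log fold-change
#' difference divided by the combined standard error:
#' `d' = max_v |log fc_i,v - log fc_j,v| / sqrt(se_i,v^2 + se_j,v^2)`.
#' It is a symmetric premetric (d'(i,i) = 0); missing cells are excluded
#' from the maximum rather than imputed.
#'
#' @param matrix Long response tibble (`sensor_id`, `condition_id`, `fc`,
#'   `se_log_fc`).
#' @param sensor_i,sensor_j Sensor ids.
#' @return The scalar distance.
#' @export
dprime <- function(matrix, sensor_i, sensor_j) {
  assert_columns(matrix, c("sensor_id", "condition_id", "fc", "se_log_fc"))
  a <- matrix[matrix$sensor_id == sensor_i, ]
  b <- matrix[matrix$sensor_id == sensor_j, ]
  shared <- inner_join(a, b, by = "condition_id", suffix = c("_i", "_j"))
  shared <- shared[stats::complete.cases(shared[c("fc_i", "fc_j")]), ]
  if (nrow(shared) == 0) {
    abort(paste0("Sensors ", sensor_i, " and ", sensor_j,
                 " share no measured conditions; d' undefined."),
          class = "ribosense_input_error")
  }
  max(abs(log(shared$fc_i) - log(shared$fc_j)) /
        sqrt(shared$se_log_fc_i^2 + shared$se_log_fc_j^2))
}

#' All pairwise d' distances
#'
#' @param matrix Long response tibble.
#' @return A `dist` object over sensors (ordered by sensor id).
#' @export
dprime_matrix <- function(matrix) {
  assert_columns(matrix, c("sensor_id", "condition_id", "fc", "se_log_fc"))
  sensors <- sort(unique(matrix$sensor_id))
  conds <- sort(unique(matrix$condition_id))
  logfc <- matrix(NA_real_, length(sensors), length(conds),
                  dimnames = list(sensors, conds))
  se2 <- logfc
  i <- cbind(match(matrix$sensor_id, sensors),
             match(matrix$condition_id, conds))
  logfc[i] <- log(matrix$fc)
  se2[i] <- matrix$se_log_fc^2
  n <- length(sensors)
  d <- stats::as.dist(matrix(0, n, n, dimnames = list(sensors, sensors)))
  out <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      num <- abs(logfc[a, ] - logfc[b, ])
      den <- sqrt(se2[a, ] + se2[b, ])
      v <- num / den
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        abort(paste0("Sensors ", sensors[a], " and ", sensors[b],
                     " share no measured conditions; d' undefined."),
              class = "ribosense_input_error")
      }
      out[a, b] <- out[b, a] <- max(v)
    }
  }
  stats::as.dist(structure(out, dimnames = list(sensors, sensors)))
}

#' Cluster sensors by response pattern
#'
#' Complete-linkage agglomerative clustering on the d' distance, cut at a
#' flat height: complete linkage guarantees every within-cluster pair is
#' within `cutoff` d' units. The representative of each cluster is its
#' highest-abundance member (ties broken by sensor id); without abundances
#' the lexically first member represents.
#'
#' @param matrix Long response tibble.
#' @param cutoff Flat-cluster height in d' units (default 3, roughly three
#'   combined standard errors).
#' @param abundance Optional tibble (`sensor_id`, `abundance`).
#' @return A tibble (`sensor_id`, `cluster`, `is_representative`) with the
#'   `hclust` tree attached as attribute `hclust`.
#' @export
cluster_sensors <- function(matrix, cutoff = 3, abundance = NULL) {
  if (cutoff <= 0) {
    abort("`cutoff` must be positive.", class = "ribosense_config_error")
  }
  sensors <- sort(unique(matrix$sensor_id))
  if (length(sensors) == 1) {
    out <- tibble(sensor_id = sensors, cluster = 1L, is_representative = TRUE)
    attr(out, "hclust") <- NULL
    return(out)
  }
  d <- dprime_matrix(matrix)
  hc <- hclust(d, method = "complete")
  cl <- cutree(hc, h = cutoff)
  out <- tibble(sensor_id = names(cl), cluster = unname(cl))
  if (!is.null(abundance)) {
    assert_columns(abundance, c("sensor_id", "abundance"))
    out <- left_join(out, abundance, by = "sensor_id")
  } else {
    out$abundance <- 0
  }
  out <- out |>
    arrange(.data$cluster, desc(.data$abundance), .data$sensor_id) |>
    group_by(.data$cluster) |>
    mutate(is_representative = row_number() == 1L) |>
    ungroup() |>
    arrange(.data$sensor_id) |>
    select(-"abundance")
  attr(out, "hclust") <- hc
  out
}

#' Export a sensor dendrogram as Newick with d' heights
#'
#' @param clustering Output of [cluster_sensors()] (or an `hclust`).
#' @param path File path.
#' @export
export_dendrogram <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering
        else attr(clustering, "hclust")
  if (is.null(hc)) {
    abort("No dendrogram available (singleton clustering).",
          class = "ribosense_input_error")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cross-reactivity profiles over fold-change thresholds
#'
#' At a fold-change threshold `f`, the cross-reactivity of a sensor is the
#' number of compounds inducing at least `f`-fold change; the
#' cross-reactivity of a compound is the minimum over the sensors it
#' activates (at `f`) of their sensor cross-reactivities. The summary curve
#' counts compounds with cross-reactivity at most `C` as a function of `C`.
#'
#' @param matrix Long single-compound response tibble (`sensor_id`,
#'   `condition_id` = compound id, `fc`).
#' @param f_grid Fold-change thresholds.
#' @param C_grid Cross-reactivity grid; defaults to 1..max observed.
#' @return A `cross_reactivity` object: list of tibbles `sensor_xr`
#'   (`f`, `sensor_id`, `xr`), `compound_xr` (`f`, `compound_id`, `xr`; NA
#'   when no sensor reaches `f`), and `curve` (`f`, `C`, `n_compounds`).
#' @export
cross_reactivity <- function(matrix, f_grid = c(2, 4, 8), C_grid = NULL) {
  assert_columns(matrix, c("sensor_id", "condition_id", "fc"))
  per_f <- purrr::map(f_grid, function(f) {
    hits <- matrix[!is.na(matrix$fc) & matrix$fc >= f, ]
    sensor_xr <- hits |>
      count(.data$sensor_id, name = "xr")
    all_sensors <- tibble(sensor_id = sort(unique(matrix$sensor_id)))
    sensor_xr <- left_join(all_sensors, sensor_xr, by = "sensor_id") |>
      mutate(xr = tidyr::replace_na(.data$xr, 0L), f = f)
    compound_xr <- hits |>
      left_join(sensor_xr[c("sensor_id", "xr")], by = "sensor_id") |>
      group_by(compound_id = .data$condition_id) |>
      summarise(xr = min(.data$xr), .groups = "drop")
    all_compounds <- tibble(compound_id = sort(unique(matrix$condition_id)))
    compound_xr <- left_join(all_compounds, compound_xr, by = "compound_id") |>
      mutate(f = f)
    list(sensor_xr = sensor_xr, compound_xr = compound_xr)
  })
  sensor_xr <- bind_rows(purrr::map(per_f, "sensor_xr")) |>
    select("f", "sensor_id", "xr")
  compound_xr <- bind_rows(purrr::map(per_f, "compound_xr")) |>
    select("f", "compound_id", "xr")
  if (is.null(C_grid)) {
    top <- max(c(compound_xr$xr, 1), na.rm = TRUE)
    C_grid <- seq_len(top)
  }
  curve <- tidyr::crossing(f = f_grid, C = C_grid) |>
    dplyr::rowwise() |>
    mutate(n_compounds = sum(!is.na(compound_xr$xr) &
                               compound_xr$f == .data$f &
                               compound_xr$xr <= .data$C)) |>
    ungroup()
  structure(list(sensor_xr = sensor_xr, compound_xr = compound_xr,
                 curve = curve),
            class = "cross_reactivity")
}

#' @export
print.cross_reactivity <- function(x, ...) {
  cat("<cross_reactivity> thresholds f = ",
      paste(unique(x$curve$f), collapse = ", "), "; ",
      n_distinct(x$compound_xr$compound_id), " compounds, ",
      n_distinct(x$sensor_xr$sensor_id), " sensors\n", sep = "")
  invisible(x)
}

#' @export
tidy.cross_reactivity <- function(x, ...) {
  x$curve
}

#' Minimum detectable concentration from a dilution series
#'
#' For each sensor-compound dose series, reports the minimum measured
#' concentration at which the fold change reaches `fc_threshold` with its
#' 95% CI lower bound above 1 (no interpolation between dilution points —
#' the result is a measured concentration). Series whose sensor responds
#' (fold change >= `fc_threshold`) to any companion compound co-assayed in
#' the same well — judged from single-compound measurements at the reference
#' concentration — are masked: the result is withheld with a reason.
#'
#' @param series Dose tibble (`sensor_id`, `compound_id`,
#'   `concentration_uM`, `fc`, `ci95_lo`; optional `companions` list-column
#'   of co-assayed compound ids).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param single_matrix Optional single-compound response tibble
#'   (`sensor_id`, `condition_id`, `fc`) used for the companion mask.
#' @return A tibble per (sensor, compound): `min_conc_uM` (NA when never
#'   reached), `fc_at_max` (fold change at the highest tested
#'   concentration), `max_conc_uM`, `masked`, `reason`.
#' @export
min_detectable_concentration <- function(series,
                                         fc_threshold = 2.0,
                                         single_matrix = NULL) {
  assert_columns(series, c("sensor_id", "compound_id", "concentration_uM",
                           "fc", "ci95_lo"))
  if (nrow(series) == 0) {
    abort("`series` is empty.", class = "ribosense_input_error")
  }
  has_companions <- "companions" %in% names(series)
  series |>
    group_by(.data$sensor_id, .data$compound_id) |>
    dplyr::group_map(function(rows, key) {
      masked <- FALSE
      reason <- NA_character_
      if (has_companions && !is.null(single_matrix)) {
        comp <- unique(unlist(rows$companions))
        comp <- setdiff(comp, key$compound_id)
        if (length(comp) > 0) {
          sm <- single_matrix[single_matrix$sensor_id == key$sensor_id &
                                single_matrix$condition_id %in% comp, ]
          bad <- sm$condition_id[!is.na(sm$fc) & sm$fc >= fc_threshold]
          if (length(bad) > 0) {
            masked <- TRUE
            reason <- paste0("responds to companion(s): ",
                             paste(sort(unique(bad)), collapse = ", "))
          }
        }
      }
      rows <- arrange(rows, desc(.data$concentration_uM))
      detected <- rows$fc >= fc_threshold & rows$ci95_lo > 1
      min_conc <- if (any(detected)) {
        min(rows$concentration_uM[detected])
      } else {
        NA_real_
      }
      if (!masked && is.na(min_conc)) {
        reason <- paste0("> max tested (",
                         format(max(rows$concentration_uM)), " uM)")
      }
      tibble(
        sensor_id = key$sensor_id,
        compound_id = key$compound_id,
        min_conc_uM = if (masked) NA_real_ else min_conc,
        fc_at_max = if (masked) NA_real_ else rows$fc[1],
        max_conc_uM = max(rows$concentration_uM),
        masked = masked,
        reason = reason
      )
    }) |>
    bind_rows()
}
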