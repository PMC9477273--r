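#' Positive-mode adduct mass shifts (Da, singly charged)
#'
#' Monoisotopic shifts from neutral mass to observed m/z: proton (M+H),
#' sodium minus electron (M+Na), ammonium (M+NH4).
#'
#' @export
adduct_mass_shifts <- c(
  "M+H" = 1.007276,
  "M+Na" = 22.989218,
  "M+NH4" = 18.033823
)

#' Expected m/z of an adduct of a neutral compound
#'
#' @param mono_mass Monoisotopic neutral mass(es), Da.
#' @param adduct Adduct name(s) among `names(adduct_mass_shifts)`; recycled
#'   against `mono_mass`.
#' @return Numeric m/z values.
#' @export
expected_adduct_mz <- function(mono_mass, adduct) {
  unknown <- setdiff(unique(adduct), names(adduct_mass_shifts))
  if (length(unknown) > 0) {
    abort(paste0("Unknown adduct(s): ", paste(unknown, collapse = ", ")),
          class = "ribosense_config_error")
  }
  mono_mass + unname(adduct_mass_shifts[adduct])
}

# 1-D single-linkage clustering of retention times: split at gaps > rt_tol.
cluster_rt <- function(rt, rt_tol) {
  ord <- order(rt)
  gaps <- c(FALSE, diff(rt[ord]) > rt_tol)
  cl <- cumsum(gaps) + 1L
  cl[order(ord)] <- cl
  cl
}

#' Identify one compound from expected-pool and control-pool peak lists
#'
#' For each adduct, collects peaks matching the expected m/z within
#' `ppm_tol` across all pools, clusters them by retention time (single
#' linkage at `rt_tol`), and scores each (adduct, rt cluster) signature by
#' the number of distinct expected pools in which it appears, then by the
#' number of control pools (fewer is better), then by mean intensity. The
#' compound is `identified` when the best signature appears in at least
#' `presence_min` expected pools and at most `fp_max` control pools;
#' `ambiguous` when another library compound shares the winning signature
#' within tolerances; `unassigned` otherwise.
#'
#' @param compound One-row tibble or list with `compound_id`, `mono_mass`.
#' @param expected_peaks Peak tibble (`pool_id`, `mz`, `rt`, `intensity`)
#'   for the pools expected to contain the compound.
#' @param control_peaks Peak tibble for control pools that should not.
#' @param ppm_tol m/z tolerance in parts per million.
#' @param rt_tol Retention-time tolerance, minutes.
#' @param presence_min Minimum expected pools showing the signature.
#' @param fp_max Maximum control pools allowed to show it.
#' @param adducts Adducts tried.
#' @param library Optional compound tibble (`compound_id`, `mono_mass`,
#'   optional `rt`) used for the ambiguity check.
#' @return One-row tibble: `compound_id`, `status`, `adduct`, `mz`, `rt`,
#'   `n_expected_present`, `n_control_present`, `mean_intensity`,
#'   `n_expected_pools`.
#' @export
identify_compound <- function(compound,
                              expected_peaks,
                              control_peaks,
                              ppm_tol = 10,
                              rt_tol = 0.1,
                              presence_min = 4,
                              fp_max = 0,
                              adducts = names(adduct_mass_shifts),
                              library = NULL) {
  assert_columns(expected_peaks, c("pool_id", "mz", "rt", "intensity"))
  assert_columns(control_peaks, c("pool_id", "mz", "rt", "intensity"))
  cid <- compound$compound_id
  mass <- compound$mono_mass
  n_expected_pools <- n_distinct(expected_peaks$pool_id)

  best <- NULL
  for (ad in adducts) {
    target <- expected_adduct_mz(mass, ad)
    tol <- target * ppm_tol * 1e-6
    exp_hit <- expected_peaks[abs(expected_peaks$mz - target) <= tol, ]
    ctl_hit <- control_peaks[abs(control_peaks$mz - target) <= tol, ]
    if (nrow(exp_hit) == 0) next
    all_hit <- bind_rows(
      mutate(exp_hit, role = "expected"),
      mutate(ctl_hit, role = "control")
    )
    all_hit$rt_cluster <- cluster_rt(all_hit$rt, rt_tol)
    sig <- all_hit |>
      group_by(.data$rt_cluster) |>
      summarise(
        n_expected_present = n_distinct(.data$pool_id[.data$role == "expected"]),
        n_control_present = n_distinct(.data$pool_id[.data$role == "control"]),
        rt = median(.data$rt),
        mean_intensity = mean(.data$intensity),
        .groups = "drop"
      ) |>
      mutate(adduct = ad, mz = target)
    cand <- arrange(sig, desc(.data$n_expected_present),
                    .data$n_control_present, desc(.data$mean_intensity))[1, ]
    if (is.null(best) ||
        cand$n_expected_present > best$n_expected_present ||
        (cand$n_expected_present == best$n_expected_present &&
           cand$n_control_present < best$n_control_present) ||
        (cand$n_expected_present == best$n_expected_present &&
           cand$n_control_present == best$n_control_present &&
           cand$mean_intensity > best$mean_intensity)) {
      best <- cand
    }
  }

  if (is.null(best)) {
    return(tibble(
      compound_id = cid, status = "unassigned", adduct = NA_character_,
      mz = NA_real_, rt = NA_real_, n_expected_present = 0L,
      n_control_present = 0L, mean_intensity = NA_real_,
      n_expected_pools = n_expected_pools
    ))
  }

  status <- if (best$n_expected_present >= presence_min &&
                best$n_control_present <= fp_max) "identified" else "unassigned"
  if (status == "identified" && !is.null(library)) {
    others <- library[library$compound_id != cid, ]
    if (nrow(others) > 0) {
      other_mz <- outer(others$mono_mass,
                        adduct_mass_shifts[adducts], `+`)
      mz_close <- abs(other_mz - best$mz) <= best$mz * ppm_tol * 1e-6
      clash <- apply(mz_close, 1, any)
      if ("rt" %in% names(others)) {
        clash <- clash & abs(others$rt - best$rt) <= rt_tol
      }
      if (any(clash)) {
        status <- "ambiguous"
      }
    }
  }
  tibble(
    compound_id = cid, status = status, adduct = best$adduct,
    mz = best$mz, rt = best$rt,
    n_expected_present = as.integer(best$n_expected_present),
    n_control_present = as.integer(best$n_control_present),
    mean_intensity = best$mean_intensity,
    n_expected_pools = n_expected_pools
  )
}

#' Verify a compound library against pooled peak lists
#'
#' Convenience wrapper: for every compound, splits `peaks` into the pools
#' expected to contain it (from the design membership, restricted to the
#' analyzed pools) and randomly chosen control pools that do not, then calls
#' [identify_compound()].
#'
#' @param compounds Compound tibble (`compound_id`, `mono_mass`).
#' @param peaks Peak tibble covering the analyzed pools.
#' @param design A `pool_design`.
#' @param n_control Control pools per compound (default 5).
#' @param seed Integer seed for control-pool choice.
#' @param ... Passed to [identify_compound()].
#' @return A calls tibble, one row per compound.
#' @export
verify_library <- function(compounds, peaks, design, n_control = 5,
                           seed = NULL, ...) {
  analyzed <- unique(peaks$pool_id)
  pools_of <- compound_pools(design, compounds$compound_id)
  with_seed(seed, {
    purrr::map(seq_len(nrow(compounds)), function(i) {
      cid <- compounds$compound_id[i]
      expected <- intersect(pools_of[[cid]], analyzed)
      ctrl_pool_ids <- sample(setdiff(analyzed, pools_of[[cid]]),
                              min(n_control, length(analyzed) -
                                    length(expected)))
      identify_compound(
        compounds[i, ],
        expected_peaks = peaks[peaks$pool_id %in% expected, ],
        control_peaks = peaks[peaks$pool_id %in% ctrl_pool_ids, ],
        library = compounds,
        ...
      )
    }) |>
      bind_rows()
  })
}

#' Summarise identification calls over a library
#'
#' @param calls Calls tibble from [identify_compound()] /
#'   [verify_library()].
#' @return A summary tibble with one row per status (`status`, `n`,
#'   `fraction`); zero rows and totals for empty input. The input calls are
#'   the per-compound report.
#' @export
library_report <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(status = character(), n = integer(), fraction = numeric()))
  }
  calls |>
    count(.data$status, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}
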