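# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive quantities with naive loops / enumeration and
# never call the code paths they verify.

# max over shared conditions of |log fc_i - log fc_j| / sqrt(se_i^2 + se_j^2)
oracle_dprime <- function(matrix, si, sj) {
  best <- -Inf
  conds <- unique(matrix$condition_id)
  for (v in conds) {
    ri <- matrix[matrix$sensor_id == si & matrix$condition_id == v, ]
    rj <- matrix[matrix$sensor_id == sj & matrix$condition_id == v, ]
    if (nrow(ri) == 1 && nrow(rj) == 1 && !is.na(ri$fc) && !is.na(rj$fc)) {
      d <- abs(log(ri$fc) - log(rj$fc)) /
        sqrt(ri$se_log_fc^2 + rj$se_log_fc^2)
      if (d > best) best <- d
    }
  }
  best
}

# per-sensor and per-compound cross-reactivity at threshold f, by loops
oracle_xr <- function(matrix, f) {
  sensors <- sort(unique(matrix$sensor_id))
  compounds <- sort(unique(matrix$condition_id))
  sxr <- setNames(integer(length(sensors)), sensors)
  for (s in sensors) {
    rows <- matrix[matrix$sensor_id == s, ]
    sxr[s] <- sum(!is.na(rows$fc) & rows$fc >= f)
  }
  cxr <- setNames(rep(NA_integer_, length(compounds)), compounds)
  for (cc in compounds) {
    rows <- matrix[matrix$condition_id == cc, ]
    hit_sensors <- rows$sensor_id[!is.na(rows$fc) & rows$fc >= f]
    if (length(hit_sensors) > 0) {
      cxr[cc] <- min(sxr[hit_sensors])
    }
  }
  list(sensor = sxr, compound = cxr)
}

# all-pairs scan for the closest within-pool adduct m/z pair of a design
oracle_min_pool_gap <- function(design) {
  shifts <- ribosense::adduct_mass_shifts[design$adducts]
  mem <- design$membership
  best <- Inf
  for (p in unique(mem$pool_id)) {
    ids <- mem$compound_id[mem$pool_id == p]
    mass <- design$compounds$mono_mass[match(ids, design$compounds$compound_id)]
    mz <- as.vector(outer(mass, shifts, `+`))
    for (i in seq_along(mz)) {
      for (j in seq_along(mz)) {
        if (i < j) {
          gap <- abs(mz[i] - mz[j])
          if (gap < best) best <- gap
        }
      }
    }
  }
  best
}

# all compound subsets of size <= max_size whose pool unions equal the
# responsive set and whose members touch no nonresponsive pool
oracle_consistent_subsets <- function(membership, responsive, nonresponsive,
                                      max_size = 3) {
  pools_of <- split(membership$pool_id, membership$compound_id)
  ids <- names(pools_of)
  ok_member <- vapply(pools_of, function(p) {
    !any(p %in% nonresponsive)
  }, logical(1))
  ids <- ids[ok_member]
  out <- list()
  for (k in seq_len(min(max_size, length(ids)))) {
    for (combo in utils::combn(ids, k, simplify = FALSE)) {
      u <- unique(unlist(pools_of[combo]))
      if (setequal(u, responsive)) {
        out[[length(out) + 1L]] <- sort(combo)
      }
    }
  }
  out
}

# noiseless pool classification for a sensor responding to `targets`
noiseless_classification <- function(design, sensor_id, targets, fc_hit = 6) {
  pools <- sort(unique(design$membership$pool_id))
  responsive <- sort(unique(
    design$membership$pool_id[design$membership$compound_id %in% targets]))
  tibble::tibble(
    sensor_id = sensor_id,
    condition_id = pools,
    fc = ifelse(pools %in% responsive, fc_hit, 1),
    pool_class = ifelse(pools %in% responsive, "responsive", "nonresponsive")
  )
}

# simulate a pooled deconvolution screen: counts for the no-ligand reference
# and every pool condition, at `depth` reads per sensor per condition
simulate_pool_screen <- function(library, models, design, compounds,
                                 depth_per_sensor = 200,
                                 concentration_uM = 2,
                                 seed = 1) {
  pools <- sort(unique(design$membership$pool_id))
  n <- nrow(library)
  counts <- purrr::map(seq_along(pools), function(i) {
    members <- design$membership$compound_id[design$membership$pool_id == pools[i]]
    cond <- tibble::tibble(compound_id = members,
                           concentration_uM = concentration_uM)
    simulate_cleaveseq_counts(library, models, cond, pools[i],
                              depth = depth_per_sensor * n,
                              seed = seed + i)
  })
  ref <- simulate_cleaveseq_counts(library, models, NULL, "noligand",
                                   depth = depth_per_sensor * n, seed = seed)
  dplyr::bind_rows(ref, counts)
}
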