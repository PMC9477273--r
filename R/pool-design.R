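#' Split a compound library into the two selection sets
#'
#' Produces the balanced A/B split used for parallel selections: two disjoint
#' halves of equal size whose union is the whole library.
#'
#' @param compounds Compound tibble with `compound_id`.
#' @param seed Integer seed.
#' @return The input tibble with a (re)assigned `selection_set` column.
#' @export
split_selection_sets <- function(compounds, seed = NULL) {
  assert_columns(compounds, "compound_id")
  n <- nrow(compounds)
  if (n %% 2 != 0) {
    abort("Library size must be even for an A/B split.",
          class = "ribosense_input_error")
  }
  with_seed(seed, {
    compounds$selection_set <- sample(rep(c("A", "B"), each = n / 2))
    compounds
  })
}

pool_name <- function(partition, index, pool_size) {
  sprintf("V%d-%d.%02d", pool_size, partition, index)
}

# Integer m/z bins of width `window`; a conflict can only involve masses in
# the same or adjacent bins.
mz_bins <- function(mz, window) as.integer(floor(mz / window))

#' Design orthogonal pool partitions under an m/z non-overlap constraint
#'
#' Partitions the compound library `n_partitions` times independently into
#' pools of exactly `pool_size` compounds, such that within any pool no two
#' compounds have expected adduct m/z values (over the configured adduct set)
#' closer than `mz_window`. The constraint keeps pooled LC-MS verification
#' unambiguous. The assignment is a randomized greedy pass per partition
#' (shuffle compounds, place each into the first open pool without an m/z
#' conflict, rotating the starting pool to balance fill), followed by a swap
#' repair for stragglers, restarting with a fresh shuffle on failure.
#'
#' @param compounds Compound tibble (`compound_id`, `mono_mass`).
#' @param n_partitions Number of independent partitions (the full-scale
#'   default design is 9 partitions of 20 pools x 256 compounds).
#' @param pool_size Compounds per pool; must divide the library size.
#' @param mz_window Minimum allowed separation (Da) between any two expected
#'   adduct m/z values within a pool; `0` (or `adducts = NULL`) disables the
#'   constraint.
#' @param adducts Positive-mode adducts considered for overlap.
#' @param max_restarts Restart budget before declaring infeasibility.
#' @param seed Integer seed.
#' @return A `pool_design` object: list with `membership` (tibble
#'   `compound_id`, `partition`, `pool_id`), `partitions`, `pool_size`,
#'   `mz_window`, `adducts`, and the `compounds` table.
#' @export
design_pools <- function(compounds,
                         n_partitions = 9,
                         pool_size = 256,
                         mz_window = 0.01,
                         adducts = c("M+H", "M+Na", "M+NH4"),
                         max_restarts = 10,
                         seed = NULL) {
  assert_columns(compounds, c("compound_id", "mono_mass"))
  n <- nrow(compounds)
  if (n_partitions < 1) {
    abort("`n_partitions` must be >= 1.", class = "ribosense_input_error")
  }
  if (n %% pool_size != 0) {
    abort("`pool_size` must divide the library size.",
          class = "ribosense_input_error")
  }
  n_pools <- n / pool_size
  constrained <- mz_window > 0 && length(adducts) > 0
  adduct_mz <- if (constrained) {
    outer(compounds$mono_mass, adduct_mass_shifts[adducts], `+`)
  } else {
    NULL
  }

  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      membership <- vector("list", n_partitions)
      ok <- TRUE
      for (p in seq_len(n_partitions)) {
        assign_p <- assign_partition(n, n_pools, pool_size, adduct_mz, mz_window)
        if (is.null(assign_p)) {
          ok <- FALSE
          break
        }
        membership[[p]] <- tibble(
          compound_id = compounds$compound_id,
          partition = p,
          pool_id = pool_name(p, assign_p, pool_size)
        )
      }
      if (ok) {
        design <- structure(
          list(
            membership = bind_rows(membership),
            partitions = seq_len(n_partitions),
            pool_size = pool_size,
            mz_window = if (constrained) mz_window else 0,
            adducts = if (constrained) adducts else character(),
            compounds = compounds
          ),
          class = "pool_design"
        )
        return(design)
      }
    }
    clique <- conflict_clique(compounds, adduct_mz, mz_window)
    abort(
      paste0(
        "Pool design infeasible after ", max_restarts, " restarts; ",
        "tightest m/z conflict clique (", length(clique), " compounds > ",
        "pool capacity under the constraint): ",
        paste(clique, collapse = ", ")
      ),
      class = "ribosense_infeasible_error"
    )
  })
}

# One randomized greedy + swap-repair pass for a single partition. Returns an
# integer pool index per compound, or NULL on failure.
assign_partition <- function(n, n_pools, pool_size, adduct_mz, mz_window) {
  order <- sample.int(n)
  assignment <- integer(n)
  room <- rep(pool_size, n_pools)
  constrained <- !is.null(adduct_mz)
  # bin -> integer vector of pools already holding a mass in that bin
  bin_pools <- if (constrained) new.env(hash = TRUE, parent = emptyenv())
  forbidden_pools <- function(i) {
    if (!constrained) return(integer())
    bins <- mz_bins(adduct_mz[i, ], mz_window)
    hits <- integer()
    for (b in unique(c(bins - 1L, bins, bins + 1L))) {
      key <- as.character(b)
      v <- bin_pools[[key]]
      if (!is.null(v)) hits <- c(hits, v)
    }
    unique(hits)
  }
  register <- function(i, pool) {
    if (!constrained) return(invisible())
    for (b in unique(mz_bins(adduct_mz[i, ], mz_window))) {
      key <- as.character(b)
      bin_pools[[key]] <- c(bin_pools[[key]], pool)
    }
  }
  leftovers <- integer()
  for (idx in seq_along(order)) {
    i <- order[idx]
    bad <- forbidden_pools(i)
    start <- ((idx - 1L) %% n_pools) + 1L
    candidates <- c(start:n_pools, if (start > 1L) 1:(start - 1L))
    placed <- FALSE
    for (pool in candidates) {
      if (room[pool] > 0L && !(pool %in% bad)) {
        assignment[i] <- pool
        room[pool] <- room[pool] - 1L
        register(i, pool)
        placed <- TRUE
        break
      }
    }
    if (!placed) leftovers <- c(leftovers, i)
  }
  if (length(leftovers) == 0L) {
    return(assignment)
  }
  # Swap repair: for each leftover c, find a conflict-free pool q that is
  # full, and a member m of q that fits a pool with room; move m there, put c
  # into q.
  for (i in leftovers) {
    bad <- forbidden_pools(i)
    open_pools <- which(room > 0L)
    repaired <- FALSE
    for (q in setdiff(seq_len(n_pools), bad)) {
      members_q <- which(assignment == q)
      for (m in members_q) {
        bad_m <- forbidden_pools(m)
        dest <- setdiff(open_pools, c(bad_m, q))
        if (length(dest) > 0L) {
          p <- dest[1L]
          assignment[m] <- p
          room[p] <- room[p] - 1L
          register(m, p)
          assignment[i] <- q
          register(i, q)
          repaired <- TRUE
          break
        }
      }
      if (repaired) break
    }
    if (!repaired) {
      return(NULL)
    }
  }
  # Note: the repair may reintroduce a conflict if the moved member lands in
  # a pool sharing one of its bins registered after the greedy pass; audit and
  # reject the attempt in that case (caller restarts).
  if (!is.null(adduct_mz) &&
      !audit_assignment(assignment, adduct_mz, mz_window)) {
    return(NULL)
  }
  assignment
}

audit_assignment <- function(assignment, adduct_mz, mz_window) {
  for (pool in unique(assignment)) {
    mz <- sort(as.vector(adduct_mz[assignment == pool, ]))
    if (any(diff(mz) < mz_window)) {
      return(FALSE)
    }
  }
  TRUE
}

# Largest connected component of the pairwise m/z conflict graph, reported
# when the design is infeasible.
conflict_clique <- function(compounds, adduct_mz, mz_window) {
  if (is.null(adduct_mz)) {
    return(character())
  }
  n <- nrow(compounds)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  long <- tibble(
    i = rep(seq_len(n), times = ncol(adduct_mz)),
    mz = as.vector(adduct_mz)
  ) |> arrange(.data$mz)
  close_pair <- which(diff(long$mz) < mz_window)
  for (k in close_pair) {
    a <- find(long$i[k])
    b <- find(long$i[k + 1L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  biggest <- comp[[which.max(lengths(comp))]]
  sort(compounds$compound_id[biggest])
}

#' @export
print.pool_design <- function(x, ...) {
  cat("<pool_design> ", length(x$partitions), " partitions x ",
      nrow(x$compounds) / x$pool_size, " pools of ", x$pool_size,
      " compounds (", nrow(x$compounds), " compounds total)\n", sep = "")
  if (x$mz_window > 0) {
    cat("  m/z constraint: >= ", x$mz_window, " Da over adducts ",
        paste(x$adducts, collapse = ", "), "\n", sep = "")
  } else {
    cat("  m/z constraint: disabled\n")
  }
  invisible(x)
}

#' Tidy a pool design into its long membership table
#'
#' @param x A `pool_design`.
#' @param ... Unused.
#' @return Tibble with `compound_id`, `partition`, `pool_id`.
#' @export
tidy.pool_design <- function(x, ...) {
  x$membership
}

#' One-row summary of a pool design
#'
#' @param x A `pool_design`.
#' @param ... Unused.
#' @export
glance.pool_design <- function(x, ...) {
  tibble(
    n_compounds = nrow(x$compounds),
    n_partitions = length(x$partitions),
    n_pools = n_distinct(x$membership$pool_id),
    pool_size = x$pool_size,
    mz_window = x$mz_window
  )
}

#' Pools containing each compound
#'
#' @param design A `pool_design`.
#' @param compound_ids Optional subset.
#' @return Named list of character vectors of pool ids.
#' @export
compound_pools <- function(design, compound_ids = NULL) {
  mem <- design$membership
  if (!is.null(compound_ids)) {
    mem <- mem[mem$compound_id %in% compound_ids, ]
  }
  split(mem$pool_id, mem$compound_id)
}

#' Audit a pool design against its own invariants
#'
#' Checks pool sizes, per-compound membership counts, and (via an all-pairs
#' minimum-gap scan on sorted adduct masses per pool) the m/z constraint.
#'
#' @param design A `pool_design`.
#' @return A one-row tibble of audit results; all `*_ok` columns TRUE for a
#'   valid design.
#' @export
audit_pool_design <- function(design) {
  mem <- design$membership
  sizes <- count(mem, .data$partition, .data$pool_id)
  per_compound <- count(mem, .data$compound_id)
  mz_ok <- TRUE
  min_gap <- NA_real_
  if (design$mz_window > 0) {
    shifts <- adduct_mass_shifts[design$adducts]
    mass <- design$compounds$mono_mass[
      match(mem$compound_id, design$compounds$compound_id)]
    gaps <- vapply(split(mass, mem$pool_id), function(m) {
      mz <- sort(as.vector(outer(m, shifts, `+`)))
      min(diff(mz))
    }, numeric(1))
    min_gap <- min(gaps)
    mz_ok <- min_gap >= design$mz_window
  }
  tibble(
    sizes_ok = all(sizes$n == design$pool_size),
    membership_ok = all(per_compound$n == length(design$partitions)),
    disjoint_ok = !anyDuplicated(mem[c("compound_id", "partition")]),
    mz_ok = mz_ok,
    min_mz_gap = min_gap
  )
}

#' Monte-Carlo decodability of a pool design
#'
#' For target-set sizes 1..`max_targets`, estimates the fraction of random
#' target sets whose responsive-pool pattern (the union of their pools) has a
#' unique minimal explanation — i.e. the drawn set is the only minimal-size
#' subset of compatible compounds covering exactly that pattern. This
#' quantifies why group-testing decoding fails for promiscuous sensors.
#'
#' @param design A `pool_design`.
#' @param max_targets Largest target-set size probed.
#' @param n_sim Random target sets per size.
#' @param candidate_cap If the number of pattern-compatible compounds exceeds
#'   this, the pattern is declared non-decodable without search (the
#'   explanation space is combinatorially ambiguous).
#' @param seed Integer seed.
#' @return Tibble with `set_size`, `decodable_fraction`, `n_sim`.
#' @export
decodability_report <- function(design,
                                max_targets = 5,
                                n_sim = 200,
                                candidate_cap = 30,
                                seed = NULL) {
  pools_of <- compound_pools(design)
  ids <- names(pools_of)
  with_seed(seed, {
    frac <- vapply(seq_len(max_targets), function(k) {
      hits <- vapply(seq_len(n_sim), function(rep) {
        target <- sample(ids, k)
        pattern <- sort(unique(unlist(pools_of[target])))
        is_uniquely_decodable(target, pattern, pools_of, candidate_cap)
      }, logical(1))
      mean(hits)
    }, numeric(1))
    tibble(set_size = seq_len(max_targets),
           decodable_fraction = frac,
           n_sim = n_sim)
  })
}

is_uniquely_decodable <- function(target, pattern, pools_of, candidate_cap) {
  compatible <- names(pools_of)[
    vapply(pools_of, function(p) all(p %in% pattern), logical(1))]
  if (length(compatible) > candidate_cap) {
    return(FALSE)
  }
  covers <- minimal_exact_covers(compatible, pools_of, pattern,
                                 max_size = length(target))
  length(covers) == 1 && setequal(covers[[1]], target)
}

# All minimal-cardinality subsets of `candidates` whose pool union equals
# `pattern`, searched in increasing size with early exit once a size yields
# any cover.
minimal_exact_covers <- function(candidates, pools_of, pattern, max_size) {
  for (size in seq_len(min(max_size, length(candidates)))) {
    combos <- utils::combn(candidates, size, simplify = FALSE)
    covers <- Filter(function(s) {
      setequal(unique(unlist(pools_of[s])), pattern)
    }, combos)
    if (length(covers) > 0) {
      return(covers)
    }
  }
  list()
}

#' Write / read a pool design as JSON
#'
#' @param design A `pool_design`.
#' @param path File path.
#' @return `write_pool_design()` returns the path invisibly;
#'   `read_pool_design()` returns the `pool_design`.
#' @export
write_pool_design <- function(design, path) {
  jsonlite::write_json(
    list(
      membership = design$membership,
      partitions = design$partitions,
      pool_size = design$pool_size,
      mz_window = design$mz_window,
      adducts = design$adducts,
      compounds = design$compounds
    ),
    path, dataframe = "columns", digits = NA
  )
  invisible(path)
}

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      membership = as_tibble(raw$membership),
      partitions = as.integer(raw$partitions),
      pool_size = as.integer(raw$pool_size),
      mz_window = raw$mz_window,
      adducts = as.character(raw$adducts),
      compounds = as_tibble(raw$compounds)
    ),
    class = "pool_design"
  )
}
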