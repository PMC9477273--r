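#' Label sensor-compound pairs as hit / miss / indeterminate
#'
#' Pure function of the fold-change confidence interval: a pair is a hit when
#' the lower bound of the CI (default 90%) exceeds the threshold, a miss when
#' the upper bound stays below it, and indeterminate otherwise. No model is
#' involved.
#'
#' @param records Single-compound fold-change tibble (`sensor_id`,
#'   `condition_id` = compound id, `fc`, `log_fc`, `se_log_fc`).
#' @param ci_level Confidence level of the interval used (default 0.90).
#' @param fc_threshold Fold threshold (default 2).
#' @return A tibble (`sensor_id`, `compound_id`, `fc`, `ci_lo`, `ci_hi`,
#'   `label`), with class counts in attribute `label_counts`.
#' @export
label_pairs <- function(records, ci_level = 0.90, fc_threshold = 2.0) {
  assert_columns(records, c("sensor_id", "condition_id", "fc",
                            "log_fc", "se_log_fc"))
  z <- qnorm(1 - (1 - ci_level) / 2)
  out <- tibble(
    sensor_id = records$sensor_id,
    compound_id = records$condition_id,
    fc = records$fc,
    ci_lo = exp(records$log_fc - z * records$se_log_fc),
    ci_hi = exp(records$log_fc + z * records$se_log_fc)
  ) |>
    mutate(label = dplyr::case_when(
      .data$ci_lo > fc_threshold ~ "hit",
      .data$ci_hi < fc_threshold ~ "miss",
      TRUE ~ "indeterminate"
    ))
  attr(out, "label_counts") <- table(out$label)
  out
}

#' Build a circular-fragment vocabulary for a compound library
#'
#' Parses each compound's SMILES (via ChemmineR/OpenBabel) into its molecular
#' graph and enumerates canonical circular atom environments of radius
#' 0..`radius_max`: the radius-0 key is the element symbol, and the radius-r
#' key appends the sorted multiset of (bond order, neighbour radius-(r-1)
#' key) pairs — a Morgan-style relabeling whose distinct strings form the
#' fragment vocabulary. The vocabulary is the union over the library, sorted,
#' with a fixed bit order. Unparseable SMILES exclude the compound with a
#' warning.
#'
#' @param compounds Tibble (`compound_id`, `smiles`).
#' @param radius_max Largest environment radius (default 3).
#' @return A `fragment_vocabulary`: list with `keys` (ordered fragment keys),
#'   `bits` (named list: compound id -> integer indices of present keys),
#'   `radius_max`, `excluded` (ids of unparseable compounds).
#' @export
build_fragments <- function(compounds, radius_max = 3) {
  assert_columns(compounds, c("compound_id", "smiles"))
  frag_sets <- vector("list", nrow(compounds))
  names(frag_sets) <- compounds$compound_id
  excluded <- character()
  for (i in seq_len(nrow(compounds))) {
    frags <- tryCatch(
      smiles_fragments(compounds$smiles[i], radius_max),
      error = function(e) NULL
    )
    if (is.null(frags)) {
      excluded <- c(excluded, compounds$compound_id[i])
    } else {
      frag_sets[[i]] <- frags
    }
  }
  if (length(excluded) > 0) {
    warn(paste0("Excluded ", length(excluded),
                " compound(s) with unparseable SMILES: ",
                paste(head(excluded, 5), collapse = ", ")))
    frag_sets <- frag_sets[!names(frag_sets) %in% excluded]
  }
  keys <- sort(unique(unlist(frag_sets, use.names = FALSE)))
  bits <- lapply(frag_sets, function(f) match(unique(f), keys))
  structure(
    list(keys = keys, bits = bits, radius_max = radius_max,
         excluded = excluded),
    class = "fragment_vocabulary"
  )
}

# Circular environment keys for one SMILES string.
smiles_fragments <- function(smiles, radius_max) {
  # single-atom molecules (no bonds) are not representable in V2000 SDF;
  # their only environment at any radius is the bare element
  single <- regmatches(smiles,
                       regexec("^\\[?([A-Z][a-z]?)[H0-9+-]*\\]?$", smiles))[[1]]
  if (length(single) == 2) {
    return(paste0("[", single[2], "]"))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms == 0 ||
      !all(grepl("_", rownames(ab), fixed = TRUE))) {
    stop("no atoms parsed")
  }
  element <- sub("_.*$", "", rownames(ab))
  nbrs <- vector("list", n_atoms)
  orders <- vector("list", n_atoms)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]
      b <- bb[k, 2]
      o <- bb[k, 3]
      nbrs[[a]] <- c(nbrs[[a]], b)
      orders[[a]] <- c(orders[[a]], o)
      nbrs[[b]] <- c(nbrs[[b]], a)
      orders[[b]] <- c(orders[[b]], o)
    }
  }
  labels <- paste0("[", element, "]")
  keys <- labels
  for (r in seq_len(radius_max)) {
    labels <- vapply(seq_len(n_atoms), function(v) {
      if (length(nbrs[[v]]) == 0) {
        return(labels[v])
      }
      env <- sort(paste0(orders[[v]], ":", labels[nbrs[[v]]]))
      paste0(labels[v], "(", paste(env, collapse = ","), ")")
    }, character(1))
    keys <- c(keys, labels)
  }
  unique(keys)
}

#' @export
print.fragment_vocabulary <- function(x, ...) {
  cat("<fragment_vocabulary> ", length(x$keys), " fragments (radius <= ",
      x$radius_max, ") over ", length(x$bits), " compounds\n", sep = "")
  invisible(x)
}

#' Dense presence/absence matrix for selected compounds
#'
#' @param vocabulary A `fragment_vocabulary`.
#' @param compound_ids Compounds wanted (must be in the vocabulary).
#' @return A 0/1 matrix, compounds x fragments.
#' @export
fragment_bit_matrix <- function(vocabulary, compound_ids) {
  missing_ids <- setdiff(compound_ids, names(vocabulary$bits))
  if (length(missing_ids) > 0) {
    abort(paste0("Compound(s) absent from vocabulary: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "ribosense_input_error")
  }
  m <- matrix(0L, length(compound_ids), length(vocabulary$keys),
              dimnames = list(compound_ids,
                              paste0("f", seq_along(vocabulary$keys))))
  for (i in seq_along(compound_ids)) {
    m[i, vocabulary$bits[[compound_ids[i]]]] <- 1L
  }
  m
}

#' Persist a fragment vocabulary as JSON
#'
#' @param vocabulary A `fragment_vocabulary`.
#' @param path File path.
#' @export
write_fragment_vocabulary <- function(vocabulary, path) {
  jsonlite::write_json(
    list(keys = vocabulary$keys, bits = vocabulary$bits,
         radius_max = vocabulary$radius_max, excluded = vocabulary$excluded),
    path, digits = NA
  )
  invisible(path)
}

#' Leave-one-out random-forest evaluation for one sensor
#'
#' Using the sensor's hit/miss labels (indeterminate pairs excluded), trains
#' a random forest on all other labeled compounds' fragment bit vectors and
#' predicts the held-out compound, for every labeled compound in turn. The
#' held-out label is never visible to training. Sensors with fewer than
#' `min_hits` hits are skipped (too little training signal). A degenerate
#' training set (single class) predicts the majority class with a flag.
#'
#' @param labels Label tibble (from [label_pairs()]) for one sensor.
#' @param vocabulary A `fragment_vocabulary`.
#' @param min_hits Minimum hits required (default 3).
#' @param ntree Trees per forest (default 200).
#' @param score_threshold Hit-probability threshold for the class call.
#' @param seed Integer seed (forests are seeded per held-out compound).
#' @return A `loo_result`: list with `sensor_id`, `skipped`, `scores`
#'   (tibble `compound_id`, `label`, `score`, `predicted`, `degenerate`),
#'   `confusion` (named tn/fp/fn/tp), `auc`.
#' @export
loo_evaluate <- function(labels,
                         vocabulary,
                         min_hits = 3,
                         ntree = 200,
                         score_threshold = 0.5,
                         seed = NULL) {
  assert_columns(labels, c("sensor_id", "compound_id", "label"))
  sensor_id <- unique(labels$sensor_id)
  if (length(sensor_id) != 1) {
    abort("`loo_evaluate()` expects labels for exactly one sensor.",
          class = "ribosense_input_error")
  }
  lab <- labels[labels$label %in% c("hit", "miss"), ]
  lab <- lab[lab$compound_id %in% names(vocabulary$bits), ]
  n_hits <- sum(lab$label == "hit")
  empty_scores <- tibble(compound_id = character(), label = character(),
                         score = numeric(), predicted = character(),
                         degenerate = logical())
  if (n_hits < min_hits) {
    return(structure(
      list(sensor_id = sensor_id, skipped = TRUE, scores = empty_scores,
           confusion = c(tn = 0L, fp = 0L, fn = 0L, tp = 0L), auc = NA_real_),
      class = "loo_result"
    ))
  }
  x <- fragment_bit_matrix(vocabulary, lab$compound_id)
  y <- factor(lab$label, levels = c("miss", "hit"))
  n <- nrow(lab)
  scores <- numeric(n)
  degenerate <- logical(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      y_tr <- y[-i]
      if (n_distinct(y_tr) < 2) {
        scores[i] <- if (levels(y)[which.max(table(y_tr))] == "hit") 1 else 0
        degenerate[i] <- TRUE
        next
      }
      fit <- randomForest::randomForest(
        x = x[-i, , drop = FALSE], y = y_tr, ntree = ntree
      )
      scores[i] <- stats::predict(fit, x[i, , drop = FALSE],
                                  type = "prob")[, "hit"]
    }
  })
  predicted <- ifelse(scores >= score_threshold, "hit", "miss")
  confusion <- c(
    tn = sum(predicted == "miss" & lab$label == "miss"),
    fp = sum(predicted == "hit" & lab$label == "miss"),
    fn = sum(predicted == "miss" & lab$label == "hit"),
    tp = sum(predicted == "hit" & lab$label == "hit")
  )
  auc <- score_auc(lab$label, scores)
  structure(
    list(
      sensor_id = sensor_id, skipped = FALSE,
      scores = tibble(compound_id = lab$compound_id, label = lab$label,
                      score = scores, predicted = predicted,
                      degenerate = degenerate),
      confusion = confusion, auc = auc
    ),
    class = "loo_result"
  )
}

score_auc <- function(label, score) {
  if (n_distinct(label) < 2) {
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = score,
    levels = c("miss", "hit"), direction = "<", quiet = TRUE
  )))
}

#' @export
print.loo_result <- function(x, ...) {
  if (x$skipped) {
    cat("<loo_result> sensor ", x$sensor_id, ": skipped (too few hits)\n",
        sep = "")
  } else {
    cat("<loo_result> sensor ", x$sensor_id, ": ",
        sum(x$confusion), " compounds, AUC ",
        formatC(x$auc, digits = 3, format = "f"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.loo_result <- function(x, ...) {
  x$scores
}

#' @export
glance.loo_result <- function(x, ...) {
  cf <- as.list(x$confusion)
  tibble(
    sensor_id = x$sensor_id, skipped = x$skipped,
    n_compounds = sum(x$confusion),
    n_hits = cf$tp + cf$fn,
    tn = cf$tn, fp = cf$fp, fn = cf$fn, tp = cf$tp,
    precision = ifelse(cf$tp + cf$fp > 0, cf$tp / (cf$tp + cf$fp), NA_real_),
    tpr = ifelse(cf$tp + cf$fn > 0, cf$tp / (cf$tp + cf$fn), NA_real_),
    tnr = ifelse(cf$tn + cf$fp > 0, cf$tn / (cf$tn + cf$fp), NA_real_),
    auc = x$auc
  )
}

#' Leave-one-out evaluation across all sensors
#'
#' @param labels Label tibble for many sensors.
#' @param vocabulary A `fragment_vocabulary`.
#' @param ... Passed to [loo_evaluate()].
#' @return A per-sensor tibble (S6-table shape: compounds, hits, confusion,
#'   precision, rates, AUC) with the per-compound scores in a `scores`
#'   list-column.
#' @export
loo_evaluate_all <- function(labels, vocabulary, ...) {
  labels |>
    group_by(.data$sensor_id) |>
    dplyr::group_map(function(rows, key) {
      res <- loo_evaluate(mutate(rows, sensor_id = key$sensor_id),
                          vocabulary, ...)
      mutate(glance(res), scores = list(res$scores))
    }) |>
    bind_rows()
}

#' Aggregate confusion statistics across sensors
#'
#' Sums the per-sensor confusion counts and reports aggregate precision
#' `TP / (TP + FP)` (undefined and NA when no positives are predicted),
#' true-positive and true-negative rates, and — when per-compound scores are
#' available — the AUC of the pooled scores across all (sensor, compound)
#' pairs.
#'
#' @param per_sensor Tibble with columns `tn`, `fp`, `fn`, `tp` (e.g. from
#'   [loo_evaluate_all()]); an optional `scores` list-column feeds the pooled
#'   AUC and an optional `skipped` column excludes skipped sensors.
#' @return One-row tibble: `tn`, `tp`, `fp`, `fn`, `precision`, `tpr`,
#'   `tnr`, `auc`.
#' @export
aggregate_metrics <- function(per_sensor) {
  assert_columns(per_sensor, c("tn", "fp", "fn", "tp"))
  if ("skipped" %in% names(per_sensor)) {
    per_sensor <- per_sensor[!per_sensor$skipped, ]
  }
  if (nrow(per_sensor) == 0) {
    abort("No evaluated sensors.", class = "ribosense_input_error")
  }
  tn <- sum(per_sensor$tn)
  fp <- sum(per_sensor$fp)
  fn <- sum(per_sensor$fn)
  tp <- sum(per_sensor$tp)
  auc <- NA_real_
  if ("scores" %in% names(per_sensor)) {
    pooled <- bind_rows(per_sensor$scores)
    if (nrow(pooled) > 0) {
      auc <- score_auc(pooled$label, pooled$score)
    }
  }
  tibble(
    tn = tn, tp = tp, fp = fp, fn = fn,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    tpr = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    tnr = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_),
    auc = auc
  )
}
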