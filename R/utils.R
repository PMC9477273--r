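#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   left_join inner_join anti_join bind_rows n n_distinct distinct rename
#'   row_number desc across first slice_head pull if_else count
#' @importFrom stats median rbinom rmultinom rgamma runif rnorm qnorm plogis
#'   qlogis hclust cutree as.dist setNames rlnorm
#' @importFrom utils head
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.", class = "ribosense_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_columns <- function(data, cols, arg = deparse(substitute(data))) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`", arg, "` is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ribosense_input_error"
    )
  }
  invisible(data)
}

# Hamming distance between each string in `x` (first `nchar(target)` chars)
# and `target`; vectorised over x, all compared strings assumed long enough.
hamming_to <- function(x, target) {
  len <- nchar(target)
  mism <- integer(length(x))
  for (i in seq_len(len)) {
    mism <- mism + (substr(x, i, i) != substr(target, i, i))
  }
  mism + pmax(0L, len - nchar(x)) * 0L
}
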