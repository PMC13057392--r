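# Internal helpers shared across modules.

#' Derive a named RNG substream seed from a master seed
#'
#' Each pipeline stage draws from its own substream so that adding or
#' reordering stages never perturbs the draws of another stage. The substream
#' seed is a deterministic 31-bit hash of the master seed and the stage name.
#'
#' @param master Integer master seed.
#' @param name Character stage name.
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}

# Metadata columns every platform table carries, in order.
META_COLS <- c("batch_id", "group", "grade", "replicate")

# Extract the numeric feature matrix (rownames batch_id.replicate) from a
# platform table.
feature_matrix <- function(tbl) {
  vars <- setdiff(names(tbl), META_COLS)
  x <- as.matrix(tbl[, vars, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- paste(tbl$batch_id, tbl$replicate, sep = ".")
  x
}

# Average replicate rows to one row per batch (arithmetic mean of features).
batch_level <- function(tbl) {
  vars <- setdiff(names(tbl), META_COLS)
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$batch_id, .data$group, .data$grade),
    dplyr::across(dplyr::all_of(vars), mean),
    .groups = "drop"
  )
  dplyr::arrange(out, match(.data$batch_id, unique(tbl$batch_id)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
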