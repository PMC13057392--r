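#' Criterion weights from a binary (pairwise) comparison matrix
#'
#' In the binary comparison determination method every pair of evaluation
#' criteria is compared once, the more important criterion receiving 1 point
#' and the less important 0; each criterion also scores 1 against itself
#' (diagonal convention), so a strict ranking over n criteria yields weights
#' (n, n-1, ..., 1) / sum. The weight of criterion i is its row total divided
#' by the grand total.
#'
#' @param wins Square 0/1 matrix; `wins[i, j] = 1` means criterion i beats j.
#'   Off-diagonal pairs must satisfy `wins[i, j] + wins[j, i] = 1` (ties are
#'   not representable) and the diagonal must be 1.
#' @return Named numeric weight vector summing to 1.
#' @export
binary_comparison_weights <- function(wins) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (ncol(wins) != n) stop("wins must be square", call. = FALSE)
  if (!all(wins %in% c(0, 1))) stop("wins entries must be 0 or 1",
                                    call. = FALSE)
  if (any(diag(wins) != 1)) {
    stop("diagonal must be 1 (each criterion scores against itself)",
         call. = FALSE)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (wins[i, j] + wins[j, i] != 1) {
          nm <- if (!is.null(rownames(wins))) rownames(wins) else seq_len(n)
          stop(sprintf(
            "asymmetric comparison between %s and %s: exactly one must win",
            nm[i], nm[j]), call. = FALSE)
        }
      }
    }
  }
  w <- rowSums(wins) / sum(wins)
  names(w) <- rownames(wins)
  w
}

#' Wins matrix of a strict importance ranking
#'
#' Convenience constructor: criteria listed from most to least important beat
#' every later criterion (and themselves, per the diagonal convention).
#'
#' @param criteria Character vector of criterion names, most important first.
#' @return Square 0/1 wins matrix for [binary_comparison_weights()].
#' @export
ranking_wins <- function(criteria) {
  n <- length(criteria)
  wins <- outer(seq_len(n), seq_len(n), `<=`) * 1
  dimnames(wins) <- list(criteria, criteria)
  wins
}

#' Membership-degree matrix from evaluator counts
#'
#' @param counts Criteria x levels matrix of evaluator counts (non-negative
#'   integers), or a long tibble with columns `criterion`, `level`, `count`.
#' @param panel_size Number of evaluators; every criterion's counts must sum
#'   to it.
#' @return Criteria x levels matrix of evaluator fractions (rows sum to 1).
#' @export
membership_matrix <- function(counts, panel_size) {
  if (is.data.frame(counts)) {
    wide <- tidyr::pivot_wider(counts[, c("criterion", "level", "count")],
                               names_from = "level", values_from = "count")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$criterion
    counts <- m
  }
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  sums <- rowSums(counts)
  bad <- which(sums != panel_size)
  if (length(bad)) {
    nm <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    stop(sprintf("counts for criterion %s sum to %d, not panel size %d",
                 nm[bad[1]], sums[bad[1]], panel_size), call. = FALSE)
  }
  counts / panel_size
}

#' Default grade bands for the fuzzy sensory score
#'
#' Bands are lower-closed and upper-open, except the topmost band which is
#' upper-closed; scores of 60-80 map to Grade I and 40-60 to Grade II.
#'
#' @return Tibble with columns `label`, `lower`, `upper`.
#' @export
grade_bands <- function() {
  tibble::tibble(
    label = c("Grade I", "Grade II"),
    lower = c(60, 40),
    upper = c(80, 60)
  )
}

#' Band label for a fuzzy sensory score
#'
#' @param score Numeric score.
#' @param bands Band table as in [grade_bands()]; bands must not overlap.
#' @return The band label, or `"out-of-range"` when no band contains the
#'   score (no silent clamping).
#' @export
classify_grade <- function(score, bands = grade_bands()) {
  stopifnot(is.numeric(score), length(score) == 1L)
  bands <- bands[order(-bands$upper), ]
  top <- which(score >= bands$lower & (score < bands$upper |
                 (score == bands$upper & seq_len(nrow(bands)) == 1L)))
  if (length(top) == 0L) return("out-of-range")
  if (length(top) > 1L) stop("overlapping grade bands", call. = FALSE)
  bands$label[top]
}

#' Fuzzy comprehensive sensory score
#'
#' Combines criterion weights w, the membership matrix M and the level value
#' vector V into the weighted score B = w' M V, and attaches the grade band.
#'
#' @param w Criterion weights (non-negative, summing to 1).
#' @param M Membership matrix (criteria x levels, rows summing to 1).
#' @param V Strictly decreasing level values (default `c(90, 70, 50, 30)`).
#' @param bands Grade bands, see [classify_grade()].
#' @return List of class `sensory_result` with elements `score` and `grade`.
#' @export
fuzzy_score <- function(w, M, V = c(90, 70, 50, 30), bands = grade_bands()) {
  M <- as.matrix(M)
  if (length(w) != nrow(M)) {
    stop(sprintf("dimension mismatch: %d weights for %d criteria",
                 length(w), nrow(M)), call. = FALSE)
  }
  if (length(V) != ncol(M)) {
    stop(sprintf("dimension mismatch: %d level values for %d levels",
                 length(V), ncol(M)), call. = FALSE)
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(M) - 1) > 1e-8)) {
    stop("membership matrix rows must sum to 1", call. = FALSE)
  }
  if (any(diff(V) >= 0)) stop("level values must be strictly decreasing",
                              call. = FALSE)
  b <- drop(crossprod(w, M %*% V))
  structure(list(score = b, grade = classify_grade(b, bands)),
            class = "sensory_result")
}

#' @export
print.sensory_result <- function(x, ...) {
  cat(sprintf("Fuzzy sensory score B = %.2f (%s)\n", x$score, x$grade))
  invisible(x)
}

#' Score every batch of an evaluator-count table
#'
#' @param counts Long evaluator-count tibble (`batch_id`, `criterion`,
#'   `level`, `count`), e.g. from [generate_evaluator_counts()].
#' @param w Criterion weights; default: strict-ranking weights over the four
#'   criteria in their table order.
#' @param V Level values.
#' @param panel_size Evaluators per criterion; defaults to the table's
#'   `panel_size` attribute or the per-criterion count sums.
#' @param bands Grade bands.
#' @return Tibble with `batch_id`, `score`, `grade`.
#' @export
score_batches <- function(counts, w = NULL, V = c(90, 70, 50, 30),
                          panel_size = NULL, bands = grade_bands()) {
  panel_size <- panel_size %||% attr(counts, "panel_size") %||%
    sum(counts$count[counts$batch_id == counts$batch_id[1] &
                       counts$criterion == counts$criterion[1]])
  criteria <- unique(counts$criterion)
  if (is.null(w)) {
    w <- binary_comparison_weights(ranking_wins(criteria))
  }
  out <- lapply(unique(counts$batch_id), function(b) {
    M <- membership_matrix(counts[counts$batch_id == b, ], panel_size)
    M <- M[criteria, , drop = FALSE]
    r <- fuzzy_score(w, M, V, bands)
    tibble::tibble(batch_id = b, score = r$score, grade = r$grade)
  })
  dplyr::bind_rows(out)
}
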