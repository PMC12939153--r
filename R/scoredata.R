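# Multi-rater score data model.
#
# Each image is scored in [1, 10] by a human subject over several sessions
# (subject A: 2 sessions, subject B: 4).  A scored dataset carries, per
# image, the raw session scores, their mean, and one assigned score per
# spatial orientation, drawn without replacement from the session scores
# (refilling the pool each time it empties, so the assignment stays
# balanced when there are more orientations than sessions).

#' Mean of a set of session scores
#'
#' @param scores numeric vector of session scores, each in \[1, 10\].
#' @return Their arithmetic mean.
#' @examples
#' mean_session_score(c(3, 4, 5, 6))
#' @export
mean_session_score <- function(scores) {
  if (length(scores) == 0L) stop("no sessions")
  stopifnot(all(scores >= 1 & scores <= 10))
  mean(scores)
}

#' Session-count-weighted mean of two subjects' scores
#'
#' Combines the two subjects' per-image means in proportion to how many
#' scoring sessions each contributed.
#'
#' @param sA,sB per-image mean scores of subjects A and B.
#' @param PA,PB session counts of the two subjects (2 and 4 in the study
#'   design this package models).
#' @return `(PA * sA + PB * sB) / (PA + PB)`, vectorized over `sA`/`sB`.
#' @examples
#' weighted_mean_score(3, 6, PA = 2, PB = 4)  # 5
#' @export
weighted_mean_score <- function(sA, sB, PA = 2L, PB = 4L) {
  stopifnot(PA >= 1, PB >= 1)
  (PA * sA + PB * sB) / (PA + PB)
}

#' Assign a session score to each orientation
#'
#' Draws scores randomly and without replacement from the session-score
#' multiset; whenever the pool is exhausted it is refilled with the full
#' multiset.  Each session score therefore appears either `floor(L / P)` or
#' `ceiling(L / P)` times among the `L` assignments, and when `L <= P` the
#' result is simply a random sub-permutation of the session scores.
#'
#' @param session_scores numeric vector of the image's session scores.
#' @param L number of orientations to score.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return Numeric vector of length `L`.
#' @export
assign_orientation_scores <- function(session_scores, L, seed = NULL) {
  if (length(session_scores) == 0L) stop("no sessions")
  stopifnot(L >= 1)
  with_seed(seed, {
    rounds <- ceiling(L / length(session_scores))
    pool <- unlist(lapply(seq_len(rounds), function(r) sample(session_scores)))
    pool[seq_len(L)]
  })
}

#' Build a scored dataset from session scores
#'
#' Assembles the per-subject data model: images, session scores, per-image
#' means and one assigned score per orientation.
#'
#' @param scores data frame with columns `image_id`, `session`, `score`
#'   (one row per image x session), restricted to a single subject.
#' @param subject subject label stored with the dataset.
#' @param L orientation count per image (8 for the dihedral set).
#' @param seed integer seed controlling orientation score assignment.
#' @return An object of class `scored_dataset`: a list with `subject`, `L`,
#'   `images` (ids), `session_scores` (named list), `mean_scores` (named
#'   numeric) and `manifest`, a data frame with one row per image x
#'   orientation (`image_id`, `orientation`, `assigned_score`, `mean_score`).
#' @export
scored_dataset <- function(scores, subject = "A", L = 8L, seed = NULL) {
  stopifnot(all(c("image_id", "session", "score") %in% names(scores)))
  if (any(scores$score < 1 | scores$score > 10)) {
    stop("scores must lie in [1, 10]")
  }
  ids <- unique(as.character(scores$image_id))
  sess <- split(scores$score, as.character(scores$image_id))[ids]
  P <- lengths(sess)
  if (length(unique(P)) != 1L) {
    stop("all images must share the same session count")
  }
  sbar <- vapply(sess, mean_session_score, numeric(1))
  seeds <- if (is.null(seed)) rep(list(NULL), length(ids)) else
    as.list(seed + seq_along(ids))
  assigned <- lapply(seq_along(ids), function(i) {
    assign_orientation_scores(sess[[i]], L, seed = seeds[[i]])
  })
  manifest <- data.frame(
    image_id = rep(ids, each = L),
    orientation = rep(seq_len(L), times = length(ids)),
    assigned_score = unlist(assigned),
    mean_score = rep(unname(sbar), each = L),
    stringsAsFactors = FALSE
  )
  structure(list(subject = subject, L = as.integer(L), images = ids,
                 session_scores = sess, mean_scores = sbar,
                 manifest = manifest),
            class = "scored_dataset")
}

#' @export
print.scored_dataset <- function(x, ...) {
  cat(sprintf("<scored_dataset> subject %s: %d images x %d orientations, %d sessions/image\n",
              x$subject, length(x$images), x$L,
              length(x$session_scores[[1]])))
  cat(sprintf("  mean score range %.2f .. %.2f\n",
              min(x$mean_scores), max(x$mean_scores)))
  invisible(x)
}

#' Split image ids into training and test sets
#'
#' The split is at the image level — all orientations of an image land on
#' the same side — so no photograph leaks between training and test via
#' its rotated copies.  The training side receives `round(train_fraction *
#' K)` images.
#'
#' @param ids character vector of image ids (or a `scored_dataset`, whose
#'   ids are used).
#' @param train_fraction fraction of images assigned to training
#'   (default 0.85, the standard 85:15 split).
#' @param seed integer seed; the split is deterministic given it.
#' @return A list with character vectors `train` and `test`.
#' @export
split_dataset <- function(ids, train_fraction = 0.85, seed = NULL) {
  if (inherits(ids, "scored_dataset")) ids <- ids$images
  K <- length(ids)
  if (K < 2L) stop("cannot split: need at least 2 images")
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- as.integer(round(train_fraction * K))
  if (n_train == 0L || n_train == K) {
    stop("cannot split: rounding leaves one side empty")
  }
  with_seed(seed, {
    tr <- sample(ids, n_train)
    list(train = tr, test = setdiff(ids, tr))
  })
}

#' Equalize sample counts across score bins
#'
#' Training scores cluster in the middle of the 1-10 scale; to keep the
#' model from collapsing its estimates toward the middle, samples in
#' under-populated score intervals are duplicated (picked uniformly at
#' random) until every non-empty interval holds as many samples as the
#' largest one held before balancing.  Nothing is ever deleted.
#'
#' @param samples data frame with at least a `score` column; rows are
#'   duplicated whole.
#' @param bin_edges breakpoints of the score intervals.  Defaults to the
#'   nine unit intervals covering \[1, 10\].  Intervals are half-open
#'   `[a, b)` with the last closed, so every score falls in exactly one bin.
#' @param seed integer seed for the duplication draws.
#' @return A data frame: the input rows followed by the duplicated rows.
#' @export
balance_by_score_bins <- function(samples, bin_edges = 1:10, seed = NULL) {
  stopifnot(is.data.frame(samples), "score" %in% names(samples))
  if (nrow(samples) == 0L) stop("no samples")
  bin <- findInterval(samples$score, bin_edges, rightmost.closed = TRUE)
  if (any(bin == 0L | bin >= length(bin_edges))) {
    stop("scores fall outside the binning range")
  }
  counts <- table(bin)
  target <- max(counts)
  extra_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(b) {
      members <- which(bin == as.integer(b))
      need <- target - length(members)
      if (need > 0L) {
        members[sample.int(length(members), need, replace = TRUE)]
      } else {
        integer(0)
      }
    }))
  })
  rbind(samples, samples[extra_idx, , drop = FALSE])
}
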