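# Synthetic food-matrix / air-cell image generator.
#
# Each synthetic image shows an orange "food matrix" region — a large
# circle (LC), box (BO), ellipse (EL) or small circle (SC) — on a black
# background, containing darker elliptical "air cells" of controllable
# count, size and elongation.  A rule-based granularity oracle scores
# each specification from its geometry (coverage, count, elongation),
# standing in for human raters when probing what image features drive
# the network's estimates.

MATRIX_COLOR <- c(230L, 140L, 40L)   # orange food matrix
CELL_COLOR   <- c(90L, 50L, 30L)     # dark brown air cells
BG_COLOR     <- c(0L, 0L, 0L)

# granularity oracle constants: caps normalizing each term to [0, 1]
ORACLE_WEIGHTS <- c(cov = 0.4, cnt = 0.3, el = 0.3)
ORACLE_COV_CAP <- 0.25   # cell-area coverage fraction mapping to 1
ORACLE_CNT_CAP <- 12     # cell count mapping to 1
ORACLE_EL_CAP  <- 8      # summed elongation excess (1 - b/a) mapping to 1

#' Air-cell specification
#'
#' An elliptical cell with semi-major axis `a`, semi-minor axis `b`
#' (`a >= b > 0`; a circle when `a == b`) centered at `center` (row,
#' col, pixels) with the major axis at `angle` degrees from the column
#' axis.
#'
#' @param center numeric `c(row, col)` in pixels.
#' @param a,b semi-axes in pixels.
#' @param angle major-axis direction in degrees.
#' @return A list of class `synth_cell`.
#' @export
synth_cell <- function(center, a, b, angle = 0) {
  stopifnot(length(center) == 2L, a >= b, b > 0)
  structure(list(center = as.numeric(center), a = as.numeric(a),
                 b = as.numeric(b), angle = as.numeric(angle)),
            class = "synth_cell")
}

#' Synthetic image specification
#'
#' A renderable, oracle-scorable description: matrix shape and color,
#' background, air cells and canvas size.  Validity requires every cell
#' to lie entirely inside the matrix and no two cells to overlap (both
#' checked conservatively via each cell's bounding circle of radius `a`).
#'
#' @param index image index (1-30 in the catalog).
#' @param category one of `"LC"`, `"BO"`, `"EL"`, `"SC"`.
#' @param matrix_shape a list: `list(type = "circle", radius = )`,
#'   `list(type = "box", half = c(hr, hc))` or
#'   `list(type = "ellipse", semi = c(sr, sc))`; all sizes in pixels,
#'   the matrix is centered on the canvas.
#' @param cells list of [synth_cell()]s.
#' @param canvas canvas side length in pixels.
#' @return A list of class `synth_spec`.
#' @export
synthetic_spec <- function(index, category, matrix_shape, cells = list(),
                           canvas = 1024L) {
  stopifnot(category %in% c("LC", "BO", "EL", "SC"),
            matrix_shape$type %in% c("circle", "box", "ellipse"))
  sp <- structure(list(index = as.integer(index), category = category,
                       matrix_shape = matrix_shape, cells = cells,
                       canvas = as.integer(canvas),
                       matrix_color = MATRIX_COLOR, cell_color = CELL_COLOR,
                       background = BG_COLOR),
                  class = "synth_spec")
  validate_spec(sp)
  sp
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> #%d %s: %s matrix, %d cells, canvas %d px, oracle %.2f\n",
              x$index, x$category, x$matrix_shape$type, length(x$cells),
              x$canvas, oracle_score(x)))
  invisible(x)
}

# conservative containment: the cell's bounding circle (radius a) must
# fit inside the matrix region; conservative overlap: bounding circles
# of two cells must not intersect
validate_spec <- function(sp) {
  ctr <- (sp$canvas + 1) / 2
  ms <- sp$matrix_shape
  for (cl in sp$cells) {
    d <- cl$center - ctr
    ok <- switch(ms$type,
      circle  = sqrt(sum(d^2)) + cl$a <= ms$radius,
      box     = abs(d[1]) + cl$a <= ms$half[1] && abs(d[2]) + cl$a <= ms$half[2],
      ellipse = {
        sh <- ms$semi - cl$a
        all(sh > 0) && (d[1] / sh[1])^2 + (d[2] / sh[2])^2 <= 1
      })
    if (!ok) stop("invalid spec: cell not contained in matrix")
  }
  n <- length(sp$cells)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dd <- sqrt(sum((sp$cells[[i]]$center - sp$cells[[j]]$center)^2))
        if (dd <= sp$cells[[i]]$a + sp$cells[[j]]$a) {
          stop("invalid spec: cells overlap")
        }
      }
    }
  }
  invisible(sp)
}

matrix_area <- function(sp) {
  ms <- sp$matrix_shape
  switch(ms$type,
         circle  = pi * ms$radius^2,
         box     = 4 * ms$half[1] * ms$half[2],
         ellipse = pi * ms$semi[1] * ms$semi[2])
}

#' Rule-based granularity oracle
#'
#' Scores a specification from its geometry alone, emulating what drives
#' perceived fibrosity: the coverage the air cells give the food matrix,
#' how many there are, and how elongated they are.  Each term is
#' normalized to \[0, 1\] by a fixed cap (coverage fraction 0.25, count
#' 12, summed elongation excess 8) and combined with weights
#' (0.4, 0.3, 0.3):
#' `score = 1 + 9 * clip01(0.4 * cov + 0.3 * cnt + 0.3 * el)`.
#' A cell-free matrix scores exactly 1; all terms at their caps score 10.
#' The score is monotone non-decreasing in cell count, total cell area
#' and elongation — in particular, adding a cell never lowers it.
#'
#' @param sp a [synthetic_spec()].
#' @return A score in \[1, 10\].
#' @export
oracle_score <- function(sp) {
  stopifnot(inherits(sp, "synth_spec"))
  if (length(sp$cells) == 0L) return(1)
  area <- sum(vapply(sp$cells, function(cl) pi * cl$a * cl$b, numeric(1)))
  elx <- sum(vapply(sp$cells, function(cl) 1 - cl$b / cl$a, numeric(1)))
  terms <- c(cov = clip01(area / matrix_area(sp) / ORACLE_COV_CAP),
             cnt = clip01(length(sp$cells) / ORACLE_CNT_CAP),
             el  = clip01(elx / ORACLE_EL_CAP))
  1 + 9 * clip01(sum(ORACLE_WEIGHTS * terms))
}

#' Render a synthetic specification to an image
#'
#' Hard-edged (no anti-aliasing) rasterization at pixel centers, so the
#' image contains exactly the background, matrix and cell colors and
#' cells remain countable by connected-component labeling.  Rendering is
#' deterministic: the same spec always yields the bit-identical image.
#'
#' @param sp a [synthetic_spec()].
#' @return A [raster_image()] of size `canvas x canvas`.
#' @export
render_spec <- function(sp) {
  stopifnot(inherits(sp, "synth_spec"))
  validate_spec(sp)
  n <- sp$canvas
  ctr <- (n + 1) / 2
  dr <- matrix(rep(seq_len(n) - ctr, n), n)        # row offsets
  dc <- matrix(rep(seq_len(n) - ctr, each = n), n) # col offsets
  ms <- sp$matrix_shape
  in_matrix <- switch(ms$type,
    circle  = dr^2 + dc^2 <= ms$radius^2,
    box     = abs(dr) <= ms$half[1] & abs(dc) <= ms$half[2],
    ellipse = (dr / ms$semi[1])^2 + (dc / ms$semi[2])^2 <= 1)
  in_cell <- matrix(FALSE, n, n)
  for (cl in sp$cells) {
    th <- cl$angle * pi / 180
    u <- (dc - (cl$center[2] - ctr)) * cos(th) +
         (dr - (cl$center[1] - ctr)) * sin(th)
    v <- -(dc - (cl$center[2] - ctr)) * sin(th) +
         (dr - (cl$center[1] - ctr)) * cos(th)
    in_cell <- in_cell | (u / cl$a)^2 + (v / cl$b)^2 <= 1
  }
  px <- array(0L, c(n, n, 3L))
  for (k in 1:3) {
    ch <- matrix(sp$background[k], n, n)
    ch[in_matrix] <- sp$matrix_color[k]
    ch[in_cell] <- sp$cell_color[k]
    px[, , k] <- ch
  }
  raster_image(px, id = sprintf("synth%02d", sp$index))
}

# deterministic ring placement: k cells at equal angles (offset by a
# per-index phase) on a ring inside the matrix, oriented radially
ring_cells <- function(k, category, canvas, b_frac, elong, phase = 0) {
  if (k == 0L) return(list())
  n <- canvas
  ctr <- (n + 1) / 2
  b <- b_frac * n
  a <- elong * b
  ring <- switch(category,
                 LC = c(0.24, 0.24), BO = c(0.20, 0.20),
                 EL = c(0.165, 0.242), SC = c(0.15, 0.15)) * n
  th <- 2 * pi * (seq_len(k) - 1) / k + phase * pi / 180
  lapply(seq_len(k), function(i) {
    cy <- ctr + ring[1] * sin(th[i])
    cx <- ctr + ring[2] * cos(th[i])
    synth_cell(c(cy, cx), a, b, angle = th[i] * 180 / pi)
  })
}

matrix_shape_for <- function(category, canvas) {
  n <- canvas
  switch(category,
         LC = list(type = "circle", radius = 0.42 * n),
         BO = list(type = "box", half = c(0.33, 0.38) * n),
         EL = list(type = "ellipse", semi = c(0.30, 0.44) * n),
         SC = list(type = "circle", radius = 0.26 * n))
}

# per-image catalog geometry: index order within each row runs from the
# most to the least granular; rightmost images have only circular cells
catalog_params <- function() {
  rows <- list(
    LC = list(idx = c(19, 1, 20, 8, 21, 7, 3, 2),
              n  = c(7, 8, 8, 7, 6, 5, 4, 7),
              el = c(5.0, 3.2, 2.8, 2.4, 2.0, 2.0, 2.6, 1.0),
              b  = c(0.018, 0.014, 0.013, 0.012, 0.012, 0.013, 0.016, 0.004)),
    BO = list(idx = c(15, 14, 12, 22, 13, 9, 11, 10),
              n  = c(8, 8, 8, 7, 6, 6, 5, 5),
              el = c(4.0, 3.6, 3.2, 3.0, 2.6, 2.1, 1.6, 1.0),
              b  = c(0.016, 0.015, 0.014, 0.014, 0.013, 0.012, 0.012, 0.012)),
    EL = list(idx = c(27, 30, 29, 26, 28, 23, 24, 25),
              n  = c(8, 8, 8, 8, 8, 7, 6, 5),
              el = c(4.0, 3.9, 3.8, 3.7, 2.8, 2.2, 1.6, 1.0),
              b  = c(0.014, 0.0138, 0.0136, 0.0134, 0.013, 0.012, 0.011, 0.011)),
    SC = list(idx = c(18, 17, 5, 6, 4, 16),
              n  = c(8, 5, 5, 4, 4, 3),
              el = c(3.5, 2.5, 2.0, 1.8, 1.4, 1.0),
              b  = c(0.010, 0.012, 0.011, 0.011, 0.010, 0.010)))
  do.call(rbind, lapply(names(rows), function(cat) {
    r <- rows[[cat]]
    data.frame(index = r$idx, category = cat, pos = seq_along(r$idx),
               n_cells = r$n, elong = r$el, b_frac = r$b,
               stringsAsFactors = FALSE)
  }))
}

#' The 30-image synthetic catalog
#'
#' Deterministically constructs the full synthetic stimulus set: 8 large
#' circles (LC), 8 boxes (BO), 8 ellipses (EL) and 6 small circles (SC),
#' 30 images in all.  Within each category the fixed index order runs
#' from many, strongly elongated cells down to few, circular cells, so
#' oracle scores decrease strictly along each row; each category's last
#' image contains only circular cells.  The exact geometries are this
#' package's own design — chosen to reproduce the category membership
#' and qualitative granularity gradient of the stimulus set, not any
#' pixel-level original.
#'
#' @param canvas canvas side length in pixels (default 1024; use 6032
#'   for acquisition-scale runs).
#' @return A list of 30 [synthetic_spec()]s, ordered by image index.
#' @export
catalog30 <- function(canvas = 1024L) {
  pars <- catalog_params()
  specs <- lapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    synthetic_spec(p$index, p$category, matrix_shape_for(p$category, canvas),
                   ring_cells(p$n_cells, p$category, canvas, p$b_frac,
                              p$elong, phase = 37 * p$index),
                   canvas = canvas)
  })
  specs[order(pars$index)]
}

#' Catalog manifest
#'
#' Summary table of a list of specifications: geometry descriptors and
#' oracle scores, one row per image.
#'
#' @param specs list of [synthetic_spec()]s, e.g. from [catalog30()].
#' @return Data frame with columns `index`, `category`, `n_cells`,
#'   `mean_elongation`, `coverage`, `oracle_score`.
#' @export
catalog_manifest <- function(specs) {
  do.call(rbind, lapply(specs, function(sp) {
    nc <- length(sp$cells)
    area <- if (nc) sum(vapply(sp$cells, function(cl) pi * cl$a * cl$b,
                               numeric(1))) else 0
    mel <- if (nc) mean(vapply(sp$cells, function(cl) cl$a / cl$b,
                               numeric(1))) else NA_real_
    data.frame(index = sp$index, category = sp$category, n_cells = nc,
               mean_elongation = mel, coverage = area / matrix_area(sp),
               oracle_score = oracle_score(sp), stringsAsFactors = FALSE)
  }))
}

#' Random synthetic specification
#'
#' Draws a random category, cell count, cell sizes and elongations, and
#' places the cells by rejection sampling (fresh random centers until
#' the containment and non-overlap checks pass; after 10000 failed
#' attempts a "cannot place cell" error is raised).  Used to produce
#' arbitrarily many oracle-scorable training images.
#'
#' @param canvas canvas side length in pixels.
#' @param seed integer seed; the spec is deterministic given it.
#' @param index index stored in the spec.
#' @param max_cells upper bound for the uniform cell-count draw.
#' @return A [synthetic_spec()].
#' @export
random_synthetic_spec <- function(canvas = 128L, seed = NULL, index = 0L,
                                  max_cells = 12L) {
  with_seed(seed, {
    category <- sample(c("LC", "BO", "EL", "SC"), 1L)
    ms <- matrix_shape_for(category, canvas)
    k <- sample(0:max_cells, 1L)
    ctr <- (canvas + 1) / 2
    inner <- switch(category, LC = 0.42, BO = 0.33, EL = 0.30, SC = 0.26)
    cells <- list()
    attempts <- 0L
    while (length(cells) < k) {
      b <- stats::runif(1, 0.008, 0.016) * canvas
      a <- b * stats::runif(1, 1, 4)
      rad <- stats::runif(1, 0, inner * canvas - a - 2)
      th <- stats::runif(1, 0, 2 * pi)
      cand <- synth_cell(ctr + rad * c(sin(th), cos(th)), a, b,
                         angle = stats::runif(1, 0, 180))
      trial <- structure(list(canvas = canvas, matrix_shape = ms,
                              cells = c(cells, list(cand))),
                         class = "synth_spec")
      ok <- !inherits(try(validate_spec(trial), silent = TRUE), "try-error")
      if (ok) {
        cells <- c(cells, list(cand))
      } else {
        attempts <- attempts + 1L
        if (attempts > 10000L) stop("cannot place cell")
      }
    }
    synthetic_spec(index, category, ms, cells, canvas = canvas)
  })
}
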