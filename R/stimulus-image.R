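#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# package-level cache for rasterization lookup tables
.magbee_cache <- new.env(parent = emptyenv())

#' Stimulus image objects
#'
#' A `stim_image` is a binary raster of one display: a `width` x `height`
#' 0/1 matrix (1 = black ink) plus generation metadata. The default canvas is
#' 120 x 120 px, i.e. a 6 x 6 cm display sampled at 20 px/cm. Pixel
#' coordinates in `elements` are 0-based, origin at the top-left corner,
#' x = column, y = row.
#'
#' @param pixels integer 0/1 matrix (rows = y, columns = x).
#' @param n_elements number of elements the display was built with.
#' @param shape_kind `"square"`, `"diamond"` or `"circle"` (mixed displays
#'   record `"mixed"`).
#' @param elements tibble of per-element records (`shape`, `cx`, `cy`,
#'   `size_param`, `aspect`, `area_px`).
#' @param seed RNG seed the display was generated from (or `NA`).
#' @param cue_bias `"none"`, `"high"` or `"low"` cue-bias construction.
#' @return An object of class `stim_image`.
#' @export
new_stim_image <- function(pixels, n_elements, shape_kind, elements,
                           seed = NA_integer_, cue_bias = "none") {
  stopifnot(is.matrix(pixels), all(pixels %in% c(0L, 1L)))
  structure(
    list(
      pixels = pixels,
      width = ncol(pixels),
      height = nrow(pixels),
      n_elements = as.integer(n_elements),
      shape_kind = shape_kind,
      elements = elements,
      seed = seed,
      cue_bias = cue_bias
    ),
    class = "stim_image"
  )
}

#' @export
print.stim_image <- function(x, ...) {
  cat(sprintf(
    "<stim_image> %dx%d px, %d element(s) [%s], %d black px, cue_bias=%s\n",
    x$width, x$height, x$n_elements, x$shape_kind, sum(x$pixels), x$cue_bias
  ))
  invisible(x)
}

#' @export
as.matrix.stim_image <- function(x, ...) x$pixels

is_stim_image <- function(x) inherits(x, "stim_image")

# coerce either a stim_image or a plain 0/1 matrix to a matrix, validating
as_binary_matrix <- function(image, arg = "image") {
  m <- if (is_stim_image(image)) image$pixels else image
  if (!is.matrix(m)) {
    abort(sprintf("`%s` must be a stim_image or a matrix.", arg))
  }
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1).", arg))
  }
  storage.mode(m) <- "integer"
  m
}

# ---- shape size tables -------------------------------------------------------

# sorted generalized squared norms for ellipse rasterization at a given
# aspect ratio; aspect = rx/ry with rx*ry = r^2, so membership is
# dx^2/aspect + dy^2*aspect <= r^2
ellipse_norms <- function(aspect, rmax = 40) {
  key <- sprintf("ellipse_%.4f", aspect)
  if (!is.null(.magbee_cache[[key]])) {
    return(.magbee_cache[[key]])
  }
  lim <- ceiling(rmax * sqrt(aspect))
  dx <- seq(-lim, lim)
  n2 <- outer(dx^2 / aspect, dx^2 * aspect, "+")
  out <- sort(as.vector(n2))
  .magbee_cache[[key]] <- out
  out
}

# best ellipse "radius^2" achieving a pixel count close to target
ellipse_size_for_area <- function(target, aspect = 1) {
  norms <- ellipse_norms(aspect)
  target <- max(1L, round(target))
  if (target > length(norms)) abort("target element area too large for rasterizer table")
  # counts achievable are the boundaries of tie blocks; take block containing
  # the target-th smallest norm, then compare block edges
  r2 <- norms[target]
  n_hi <- sum(norms <= r2)              # count if we include the whole block
  n_lo <- sum(norms < r2)               # count if we exclude it
  if (abs(n_hi - target) <= abs(n_lo - target) || n_lo == 0) {
    list(r2 = r2, count = n_hi)
  } else {
    list(r2 = max(norms[norms < r2]), count = n_lo)
  }
}

# pixel count of a diamond (L1 ball of radius t) centered at fractional
# offset (ox, oy) relative to the integer lattice
diamond_count <- function(t, ox = 0, oy = 0) {
  ys <- seq(ceiling(oy - t), floor(oy + t))
  h <- t - abs(ys - oy)
  sum(pmax(0, floor(ox + h) - ceiling(ox - h) + 1))
}

# best (radius, sub-pixel offset) for a diamond hitting a target pixel
# count; half-pixel center offsets give much finer count granularity than
# integer-centered diamonds
diamond_size_for_area <- function(target) {
  t0 <- sqrt(target / 2)
  best <- NULL
  for (ox in c(0, 0.5)) {
    for (oy in c(0, 0.5)) {
      for (t in t0 + seq(-1, 1, by = 0.1)) {
        if (t <= 0.4) next
        cnt <- diamond_count(t, ox, oy)
        if (is.null(best) || abs(cnt - target) < abs(best$count - target)) {
          best <- list(t = t, ox = ox, oy = oy, count = cnt)
        }
      }
    }
  }
  best
}

# rectangle dims (w, h) with w/h ~ aspect and w*h close to target
rect_size_for_area <- function(target, aspect = 1) {
  w0 <- sqrt(target * aspect)
  cand_w <- unique(pmax(1L, c(floor(w0), ceiling(w0))))
  best <- NULL
  for (w in cand_w) {
    for (h in unique(pmax(1L, c(floor(target / w), ceiling(target / w))))) {
      if (is.null(best) || abs(w * h - target) < abs(best$w * best$h - target)) {
        best <- list(w = as.integer(w), h = as.integer(h))
      }
    }
  }
  best$count <- best$w * best$h
  best
}

# ---- rasterization -----------------------------------------------------------

#' Rasterize a single element
#'
#' Draws one filled element on an otherwise white canvas. Squares are
#' axis-aligned, diamonds are squares rotated by 45 degrees (an L1 ball),
#' circles are filled discs. `size_param` is the side length for squares
#' and diamonds (so equal `size_param` means equal nominal area under
#' rotation) and the radius for circles (pixels).
#'
#' Diamond centers may be fractional: sub-pixel (half-offset) placement
#' changes which lattice pixels fall inside the rotated square and lets a
#' diamond match a square's pixel count within ~2%.
#'
#' @param shape_kind `"square"`, `"diamond"` or `"circle"`.
#' @param size_param positive size (px, see above).
#' @param center numeric `c(x, y)` center, 0-based pixel coordinates.
#' @param width,height canvas size in pixels.
#' @param aspect width/height aspect ratio (>= 1 elongates horizontally,
#'   < 1 vertically); area is preserved.
#' @return 0/1 integer matrix of dimension `height` x `width`.
#' @export
#' @examples
#' m <- rasterize_element("square", 20, center = c(60, 60))
#' sum(m) # 400
rasterize_element <- function(shape_kind, size_param, center,
                              width = 120, height = 120, aspect = 1) {
  shape_kind <- match.arg(shape_kind, c("square", "diamond", "circle"))
  if (size_param <= 0) abort("`size_param` must be positive.")
  cx <- center[1]
  cy <- center[2]
  m <- matrix(0L, nrow = height, ncol = width)
  if (shape_kind == "square") {
    w <- max(1L, round(size_param * sqrt(aspect)))
    h <- max(1L, round(size_param / sqrt(aspect)))
    x0 <- round(cx - (w - 1) / 2)
    y0 <- round(cy - (h - 1) / 2)
    if (x0 < 0 || y0 < 0 || x0 + w > width || y0 + h > height) {
      abort("element does not fit inside the display", class = "magbee_placement_error")
    }
    m[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- 1L
  } else if (shape_kind == "diamond") {
    t <- size_param / sqrt(2)
    ys <- seq(ceiling(cy - t), floor(cy + t))
    px <- integer(0)
    py <- integer(0)
    for (y in ys) {
      h <- t - abs(y - cy)
      if (h < 0) next
      xs <- seq(ceiling(cx - h), floor(cx + h))
      px <- c(px, xs)
      py <- c(py, rep(y, length(xs)))
    }
    if (length(px) == 0 ||
        any(px < 0) || any(py < 0) || any(px >= width) || any(py >= height)) {
      abort("element does not fit inside the display", class = "magbee_placement_error")
    }
    m[cbind(py + 1, px + 1)] <- 1L
  } else {
    cx <- round(cx)
    cy <- round(cy)
    rx <- size_param * sqrt(aspect)
    ry <- size_param / sqrt(aspect)
    r <- ceiling(max(rx, ry))
    dx <- seq(-r, r)
    inside <- outer((dx / ry)^2, (dx / rx)^2, "+") <= 1 # rows = dy, cols = dx
    ys <- cy + dx
    xs <- cx + dx
    keep <- which(inside, arr.ind = TRUE)
    px <- xs[keep[, 2]]
    py <- ys[keep[, 1]]
    if (any(px < 0) || any(py < 0) || any(px >= width) || any(py >= height)) {
      abort("element does not fit inside the display", class = "magbee_placement_error")
    }
    m[cbind(py + 1, px + 1)] <- 1L
  }
  m
}

# ---- stimulus generation -----------------------------------------------------

# partition total area into n element areas; lambda = heterogeneity in [0,1],
# alpha = Dirichlet concentration of the heterogeneous part
partition_areas <- function(n, total, lambda, alpha, floor_frac = 0.25) {
  if (n == 1) {
    return(total)
  }
  d <- stats::rgamma(n, shape = alpha)
  d <- d / sum(d)
  w <- (1 - lambda) / n + lambda * d
  # floor each share at a fraction of the equal share so no element vanishes
  f <- floor_frac / n
  w <- f + (1 - n * f) * w / sum(w)
  total * w
}

# choose discrete size params for each element so the running total tracks
# the target area (greedy remainder compensation)
choose_element_sizes <- function(areas, shape, aspect = 1) {
  n <- length(areas)
  total_target <- sum(areas)
  out <- vector("list", n)
  placed <- 0
  for (i in seq_len(n)) {
    remaining_target <- total_target - placed
    remaining_n <- n - i + 1
    tgt <- areas[i] * remaining_target / sum(areas[i:n])
    if (shape == "square") {
      s <- rect_size_for_area(tgt, aspect)
      out[[i]] <- list(shape = shape, w = s$w, h = s$h, count = s$count,
                       size_param = sqrt(s$w * s$h), aspect = aspect,
                       hw = (s$w - 1) / 2, hh = (s$h - 1) / 2)
    } else if (shape == "diamond") {
      s <- diamond_size_for_area(tgt)
      out[[i]] <- list(shape = shape, t = s$t, ox = s$ox, oy = s$oy,
                       count = s$count, size_param = s$t * sqrt(2), aspect = 1,
                       hw = ceiling(s$t), hh = ceiling(s$t))
    } else {
      s <- ellipse_size_for_area(tgt, aspect)
      rr <- sqrt(s$r2)
      out[[i]] <- list(shape = shape, r2 = s$r2, count = s$count,
                       size_param = rr, aspect = aspect,
                       hw = ceiling(rr * sqrt(aspect)), hh = ceiling(rr / sqrt(aspect)))
    }
    placed <- placed + out[[i]]$count
  }
  out
}

# sample non-overlapping centers by rejection; boxes are inflated by `gap`
# px on each side. `spread_min` forces a minimum pairwise center distance,
# `cluster` confines centers to a window around a cluster center.
place_elements <- function(sizes, width, height, margin = 2, gap = 2,
                           spread_min = 0, cluster_r = Inf,
                           max_attempts = 1000) {
  n <- length(sizes)
  centers <- matrix(NA_real_, n, 2)
  boxes <- matrix(NA_real_, n, 4) # x0, x1, y0, y1
  ccenter <- c(
    stats::runif(1, width * 0.3, width * 0.7),
    stats::runif(1, height * 0.3, height * 0.7)
  )
  for (i in seq_len(n)) {
    hw <- sizes[[i]]$hw
    hh <- sizes[[i]]$hh
    lo_x <- margin + hw
    hi_x <- width - 1 - margin - hw
    lo_y <- margin + hh
    hi_y <- height - 1 - margin - hh
    if (hi_x < lo_x || hi_y < lo_y) {
      abort("element too large for the display margins",
            class = "magbee_placement_error")
    }
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      # widen the cluster window gradually if placement is tight
      cr <- if (is.finite(cluster_r)) cluster_r * (1 + att / 200) else Inf
      cx <- stats::runif(1, max(lo_x, ccenter[1] - cr), min(hi_x, ccenter[1] + cr))
      cy <- stats::runif(1, max(lo_y, ccenter[2] - cr), min(hi_y, ccenter[2] + cr))
      box <- c(cx - hw, cx + hw, cy - hh, cy + hh)
      clash <- FALSE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          sep_x <- box[1] > boxes[j, 2] + gap || box[2] < boxes[j, 1] - gap
          sep_y <- box[3] > boxes[j, 4] + gap || box[4] < boxes[j, 3] - gap
          if (!(sep_x || sep_y)) {
            clash <- TRUE
            break
          }
          if (spread_min > 0 &&
              sqrt((cx - centers[j, 1])^2 + (cy - centers[j, 2])^2) < spread_min) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        centers[i, ] <- c(cx, cy)
        boxes[i, ] <- box
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place element %d of %d after %d attempts (margin/gap/spread constraints)",
        i, n, max_attempts
      ), class = "magbee_placement_error")
    }
  }
  centers
}

#' Generate one constant-area stimulus display
#'
#' Places `n_elements` black elements of one shape on a white canvas by
#' rejection sampling, keeping the total black area at `target_area` pixels
#' (within 2%) regardless of the element count. Element sizes within a
#' display are heterogeneous (a floored Dirichlet partition of the total
#' area), emulating the size variability of printed numerosity stimulus
#' sets; `size_lambda = 0` gives equal-sized elements.
#'
#' @param n_elements integer 0..6.
#' @param shape_kind `"square"`, `"diamond"` or `"circle"`.
#' @param target_area total black area in px^2 (default 1024, ~7% of the
#'   default 120 x 120 canvas).
#' @param seed RNG seed; the same seed reproduces the display bit for bit.
#' @param width,height canvas size (px).
#' @param cue_bias `"none"` for the standard construction; `"high"` uses
#'   elongated elements spread far apart (raises edge length, convex hull
#'   and spatial-frequency power at fixed count and area); `"low"` uses
#'   compact, tightly clustered elements with a skewed size partition
#'   (lowers all three).
#' @param size_lambda,size_alpha heterogeneity of the within-display element
#'   size partition (mixing weight and Dirichlet concentration). The
#'   defaults emulate the element-size variability of printed numerosity
#'   stimulus sets, whose cue-count covariation the generator reproduces.
#' @param max_attempts rejection-sampling budget per element.
#' @return A [new_stim_image()] object.
#' @export
generate_stimulus <- function(n_elements, shape_kind, target_area = 1024,
                              seed = NULL, width = 120, height = 120,
                              cue_bias = c("none", "high", "low"),
                              size_lambda = 1, size_alpha = 0.4,
                              max_attempts = 1000) {
  cue_bias <- match.arg(cue_bias)
  shape_kind <- match.arg(shape_kind, c("square", "diamond", "circle"))
  stopifnot(n_elements >= 0, n_elements <= 6)
  if (target_area > 0.25 * width * height) {
    abort("`target_area` must not exceed 25% of the display area.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  empty_elements <- tibble(
    shape = character(), cx = numeric(), cy = numeric(),
    size_param = numeric(), aspect = numeric(), area_px = integer()
  )
  if (n_elements == 0) {
    return(new_stim_image(matrix(0L, height, width), 0L, shape_kind,
                          empty_elements, seed %||% NA_integer_, cue_bias))
  }

  aspect <- 1
  spread_min <- 0
  cluster_r <- Inf
  lambda <- size_lambda
  alpha <- size_alpha
  if (cue_bias == "high") {
    # elongated elements, forced apart: raises edge length, hull and SF power
    aspect <- 3
    lambda <- 0       # equal areas keep every element elongated
    spread_min <- min(width, height) * 0.9 / max(2, n_elements)
  } else if (cue_bias == "low") {
    # compact skewed sizes, tight cluster: one dominant element lowers total
    # edge length; clustering shrinks the hull and softens the spectrum
    lambda <- 1
    alpha <- 0.55
    cluster_r <- min(width, height) * 0.16 + 2.2 * sqrt(target_area / max(1, n_elements))
  }
  bias_shape <- if (cue_bias == "high" && shape_kind == "diamond") "square" else shape_kind

  for (round in 1:10) {
    areas <- partition_areas(n_elements, target_area, lambda, alpha)
    sizes <- choose_element_sizes(areas, bias_shape, aspect)
    total <- sum(vapply(sizes, `[[`, numeric(1), "count"))
    if (abs(total - target_area) / target_area > 0.02) next
    centers <- tryCatch(
      place_elements(sizes, width, height,
                     spread_min = spread_min, cluster_r = cluster_r,
                     max_attempts = max_attempts),
      magbee_placement_error = function(e) NULL
    )
    if (is.null(centers)) next
    m <- matrix(0L, height, width)
    recs <- vector("list", n_elements)
    for (i in seq_len(n_elements)) {
      s <- sizes[[i]]
      cx <- centers[i, 1]
      cy <- centers[i, 2]
      if (s$shape == "square") {
        # integer dims chosen by rect_size_for_area; draw the exact block
        x0 <- round(cx - (s$w - 1) / 2)
        y0 <- round(cy - (s$h - 1) / 2)
        el <- matrix(0L, height, width)
        el[(y0 + 1):(y0 + s$h), (x0 + 1):(x0 + s$w)] <- 1L
      } else if (s$shape == "diamond") {
        el <- rasterize_element("diamond", s$size_param,
                                c(round(cx) + s$ox, round(cy) + s$oy),
                                width, height)
      } else {
        el <- rasterize_element("circle", s$size_param, c(cx, cy), width, height,
                                aspect = s$aspect)
      }
      m <- m | el
      recs[[i]] <- tibble(
        shape = s$shape, cx = round(cx, 2), cy = round(cy, 2),
        size_param = s$size_param, aspect = s$aspect, area_px = as.integer(s$count)
      )
    }
    m <- matrix(as.integer(m), height, width)
    if (abs(sum(m) - target_area) / target_area > 0.02) next
    return(new_stim_image(m, n_elements, shape_kind,
                          dplyr::bind_rows(recs), seed %||% NA_integer_, cue_bias))
  }
  abort("failed to generate a stimulus meeting the area/placement constraints",
        class = "magbee_generation_error")
}

#' Generate a cue-biased pair of same-count displays
#'
#' Builds two displays with identical element count and total black area,
#' where the `high` member measurably exceeds the `low` member in all three
#' covarying continuous cues: total edge length, convex hull area, and
#' spatial-frequency power. The construction (elongation + spacing vs
#' compact clustering) is verified by measuring the cues and regenerated
#' with fresh sub-seeds until the joint ordering holds.
#'
#' @inheritParams generate_stimulus
#' @param max_pair_attempts number of regeneration rounds before giving up.
#' @return Named list with `stim_image` members `high` and `low`.
#' @export
generate_cue_biased_pair <- function(n_elements, target_area = 1024,
                                     seed = NULL, shape_kind = "square",
                                     width = 120, height = 120,
                                     max_pair_attempts = 50) {
  stopifnot(n_elements >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  for (k in seq_len(max_pair_attempts)) {
    s1 <- sample.int(.Machine$integer.max, 1)
    s2 <- sample.int(.Machine$integer.max, 1)
    high <- generate_stimulus(n_elements, shape_kind, target_area, seed = s1,
                              width = width, height = height, cue_bias = "high")
    low <- generate_stimulus(n_elements, shape_kind, target_area, seed = s2,
                             width = width, height = height, cue_bias = "low")
    ch <- cue_vector(high)
    cl <- cue_vector(low)
    # any single convex element has hull == area, so at n = 1 the hulls of
    # the two members tie by construction; strictness applies from n = 2
    hull_ok <- if (n_elements >= 2) {
      ch$convex_hull_area > cl$convex_hull_area
    } else {
      ch$convex_hull_area >= 0.98 * cl$convex_hull_area
    }
    if (ch$edge_length > cl$edge_length && hull_ok &&
        ch$sf_power > cl$sf_power) {
      return(list(high = high, low = low))
    }
  }
  abort("could not construct a pair with the required joint cue ordering",
        class = "magbee_generation_error")
}
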