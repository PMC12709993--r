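#' Extract the phenotype vector from a front-view RGB image
#'
#' Pipeline: excess-green foreground segmentation (Otsu threshold),
#' contour/convex-hull extraction, centroid localization, Hough-transform
#' detection of straight leaf segments, and Campbell-function fitting of
#' the segment inclination histogram. Produces the 5-dimensional
#' phenotype vector appended to the reflectance input at fine-tuning:
#' relative height of the plant centroid (RHC), fitted Campbell parameter,
#' mean and standard deviation of the leaf inclination angles, and the
#' convex-hull fill ratio.
#'
#' Coordinate convention: image row 1 is the top; heights are measured in
#' pixels above the pot-rim row, so RHC = (rim - centroid row) / (rim -
#' top row) is scale-free and lies in \[0, 1\].
#'
#' @param image RGB array (rows x cols x 3, values in \[0, 1\]) or path to
#'   a PNG file.
#' @param pot_rim_row Pixel row of the pot rim; defaults to the lowest
#'   plant pixel.
#' @param min_votes Minimum Hough votes for a line segment.
#' @param max_lines Maximum number of extracted segments.
#' @return One-row tibble: `rhc`, `cam_alpha_fit`, `mean_leaf_angle`,
#'   `leaf_angle_sd`, `hull_fill_ratio`, plus `n_segments` and
#'   `low_confidence` (TRUE when fewer than 3 segments were found).
#' @export
extract_front_view_phenotype <- function(image, pot_rim_row = NULL,
                                         min_votes = 20L, max_lines = 300L) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be an RGB array or PNG path", call. = FALSE)
  }
  mask <- segment_green_foreground(image)
  if (!any(mask)) stop("no green foreground found in the image", call. = FALSE)

  px <- which(mask, arr.ind = TRUE)  # (row, col)
  centroid_row <- mean(px[, 1])
  top_row <- min(px[, 1])
  if (is.null(pot_rim_row)) pot_rim_row <- max(px[, 1])
  height <- pot_rim_row - top_row
  rhc <- if (height > 0) (pot_rim_row - centroid_row) / height else 0.5
  rhc <- min(max(rhc, 0), 1)

  hull <- grDevices::chull(px[, 2], px[, 1])
  hull_area <- polygon_area(px[hull, 2], px[hull, 1])
  hull_fill <- min(nrow(px) / max(hull_area, 1), 1)

  edges <- mask_edges(mask)
  segs <- hough_segments(edges, min_votes = min_votes, max_lines = max_lines)
  low_conf <- nrow(segs) < 3L
  if (nrow(segs) == 0L) {
    angles <- 45
    wts <- 1
  } else {
    angles <- segs$angle_deg
    # weight segments by their supporting pixel count (~ segment length):
    # the leaf-angle distribution is an area-weighted density
    wts <- segs$votes
  }
  fit <- if (length(angles) >= 10L) fit_campbell(angles, weights = wts) else
    list(alpha = min(max(stats::weighted.mean(angles, wts), 6), 88),
         gof = NA_real_)

  mu <- stats::weighted.mean(angles, wts)
  tibble::tibble(
    rhc = rhc,
    cam_alpha_fit = fit$alpha,
    mean_leaf_angle = mu,
    leaf_angle_sd = sqrt(stats::weighted.mean((angles - mu)^2, wts)),
    hull_fill_ratio = hull_fill,
    n_segments = nrow(segs),
    low_confidence = low_conf
  )
}

# Excess-green index 2G - R - B with Otsu threshold; falls back to a
# fixed cut when EBImage is unavailable.
segment_green_foreground <- function(image) {
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  exg01 <- (exg + 2) / 4
  thr <- if (requireNamespace("EBImage", quietly = TRUE)) {
    EBImage::otsu(exg01, range = c(0, 1))
  } else {
    0.55
  }
  # foreground must also be green-dominant in absolute terms
  (exg01 > thr) & (exg > 0)
}

# Boundary pixels of a binary mask (4-neighbour erosion complement).
mask_edges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !core
}

# Shoelace polygon area.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Hough-transform extraction of straight segments and their inclinations
#'
#' Standard (rho, theta) accumulator over edge pixels with iterative peak
#' extraction: the strongest line is recorded, its supporting pixels
#' (within 1.5 px of the line) are removed, and the process repeats until
#' no line reaches `min_votes`. The returned inclination is the angle of
#' the line to the horizontal, folded to \[0, 90\] degrees.
#'
#' @param edges Logical matrix of edge pixels (row 1 = image top).
#' @param theta_step Angular resolution (degrees).
#' @param min_votes Minimum supporting pixels per line.
#' @param max_lines Cap on the number of extracted lines.
#' @return Tibble with `angle_deg` (inclination), `votes`, `rho`, `theta`.
#' @export
hough_segments <- function(edges, theta_step = 1, min_votes = 20L,
                           max_lines = 300L) {
  px <- which(edges, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    return(tibble::tibble(angle_deg = numeric(), votes = integer(),
                          rho = numeric(), theta = numeric()))
  }
  # x to the right, y upward so inclination is vs. the horizontal
  x <- px[, 2]
  y <- nrow(edges) - px[, 1] + 1
  thetas <- seq(0, 180 - theta_step, by = theta_step) * pi / 180
  ct <- cos(thetas); st <- sin(thetas)
  rho_max <- ceiling(sqrt(nrow(edges)^2 + ncol(edges)^2))
  nbin <- 2L * rho_max + 2L
  # full accumulator built once; removed pixels' votes are subtracted
  # incrementally instead of rebuilding per extracted line
  rbin_all <- matrix(0L, length(x), length(thetas))
  for (j in seq_along(thetas)) {
    rbin_all[, j] <- as.integer(round(x * ct[j] + y * st[j])) + rho_max + 1L
  }
  acc <- matrix(0L, nbin, length(thetas))
  for (j in seq_along(thetas)) {
    acc[, j] <- tabulate(rbin_all[, j], nbins = nbin)
  }
  subtract_votes <- function(acc, rows) {
    for (j in seq_along(thetas)) {
      tab <- tabulate(rbin_all[rows, j], nbins = nbin)
      acc[, j] <- acc[, j] - tab
    }
    acc
  }
  out <- list()
  alive <- rep(TRUE, length(x))
  for (iter in seq_len(max_lines)) {
    if (sum(alive) < min_votes) break
    best <- arrayInd(which.max(acc), dim(acc))
    votes <- acc[best]
    if (votes < min_votes) break
    theta_b <- thetas[best[2]]
    rho_b <- best[1] - rho_max - 1L
    idx <- which(alive)
    d <- abs(x[idx] * cos(theta_b) + y[idx] * sin(theta_b) - rho_b)
    support <- idx[d <= 1.5]
    if (length(support) < min_votes) { # peak built from rounding spread
      rm <- idx[d <= 0.6]
      if (!length(rm)) rm <- idx[which.min(d)]
      alive[rm] <- FALSE
      acc <- subtract_votes(acc, rm)
      next
    }
    # segment validation: keep the longest contiguous run of support
    # pixels along the line direction, rejecting collinear-by-chance
    # pixel sets spread across the image
    tproj <- -x[support] * sin(theta_b) + y[support] * cos(theta_b)
    ord_t <- order(tproj)
    gaps <- which(diff(tproj[ord_t]) > 3)
    starts <- c(1L, gaps + 1L)
    ends <- c(gaps, length(tproj))
    runs <- ends - starts + 1L
    kbest <- which.max(runs)
    run_idx <- ord_t[starts[kbest]:ends[kbest]]
    chunk <- support[run_idx]
    alive[chunk] <- FALSE
    acc <- subtract_votes(acc, chunk)
    if (length(chunk) < min_votes) next
    support <- chunk
    # refine the quantized accumulator angle by the principal direction
    # of the support pixels (sub-degree accuracy)
    xs <- x[support]; ys <- y[support]
    cv <- stats::cov(cbind(xs, ys))
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    incl <- atan2(abs(ev[2]), abs(ev[1])) * 180 / pi
    out[[length(out) + 1L]] <- tibble::tibble(
      angle_deg = incl, votes = length(support),
      rho = rho_b, theta = theta_b * 180 / pi)
  }
  if (!length(out)) {
    return(tibble::tibble(angle_deg = numeric(), votes = integer(),
                          rho = numeric(), theta = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Continuous Campbell ellipsoidal leaf-angle density
#'
#' @param theta_deg Leaf inclination angles (degrees, 0-90).
#' @param alpha Mean leaf angle parameter (degrees).
#' @return Density values (per radian), normalized over \[0, pi/2\].
#' @export
campbell_density <- function(theta_deg, alpha) {
  x <- exp(-1.6184e-5 * alpha^3 + 2.1145e-3 * alpha^2 -
             1.2390e-1 * alpha + 3.2491)
  th <- theta_deg * pi / 180
  g <- function(t) 2 * x^3 * sin(t) / (cos(t)^2 + x^2 * sin(t)^2)^2
  grid <- seq(0, pi / 2, length.out = 2001L)
  norm <- sum(g(grid)) * (grid[2] - grid[1])
  g(th) / norm
}

#' Fit the Campbell parameter to observed leaf angles
#'
#' Maximum-likelihood (default) or least-squares-on-binned-density fit of
#' the one-parameter ellipsoidal leaf-angle distribution.
#'
#' @param angles_deg Leaf inclination angles in degrees (>= 10 values).
#' @param method `"mle"` or `"ls"`.
#' @param weights Optional non-negative observation weights (e.g. segment
#'   lengths, approximating leaf area); default equal weights.
#' @return List with `alpha` (degrees), `gof` (mean absolute deviation
#'   between empirical and fitted 10-degree bin frequencies) and
#'   `boundary` (TRUE when the optimum hit the search boundary).
#' @export
fit_campbell <- function(angles_deg, method = c("mle", "ls"), weights = NULL) {
  method <- match.arg(method)
  keep <- is.finite(angles_deg)
  a <- angles_deg[keep]
  if (length(a) < 10L) stop("need at least 10 angles", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(a)) else weights[keep]
  w <- w / sum(w)
  a <- pmin(pmax(a, 0.25), 89.75)
  if (stats::sd(a) < 1e-9) {
    warning("degenerate all-equal angles; returning boundary fit", call. = FALSE)
    return(list(alpha = min(max(a[1], 6), 88), gof = NA_real_, boundary = TRUE))
  }
  lo <- 6; hi <- 88
  emp_bins <- function() {
    brk <- seq(0, 90, by = 10)
    bins <- cut(a, brk)
    as.numeric(tapply(w, bins, sum, default = 0))
  }
  if (method == "mle") {
    nll <- function(alpha) -sum(w * log(pmax(campbell_density(a, alpha), 1e-12)))
    opt <- stats::optimize(nll, c(lo, hi))
  } else {
    emp <- emp_bins()
    obj <- function(alpha) {
      centers <- seq(5, 85, by = 10)
      mod <- campbell_density(centers, alpha) * (10 * pi / 180)
      sum((emp - mod)^2)
    }
    opt <- stats::optimize(obj, c(lo, hi))
  }
  alpha <- opt$minimum
  emp <- emp_bins()
  mod <- campbell_density(seq(5, 85, by = 10), alpha) * (10 * pi / 180)
  list(alpha = alpha, gof = mean(abs(emp - mod)),
       boundary = alpha < lo + 0.51 || alpha > hi - 0.51)
}

#' Draw random leaf angles from the Campbell distribution
#'
#' Inverse-CDF sampling on a fine grid.
#'
#' @param n Number of angles.
#' @param alpha Campbell mean leaf angle parameter (degrees).
#' @param seed Optional integer seed.
#' @return Numeric vector of angles in degrees (0-90).
#' @export
sample_campbell_angles <- function(n, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 90, length.out = 4001L)
  dens <- campbell_density(grid, alpha)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  grid[findInterval(u, cdf) + 1L]
}
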