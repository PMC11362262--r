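#' Convert 8-bit sRGB to CIELAB
#'
#' Standard pipeline: inverse sRGB gamma, linear RGB to XYZ (D65 white, 2
#' degree observer), XYZ to CIELAB.
#'
#' @param rgb numeric vector of length 3 or n x 3 matrix, components in
#'   0..255.
#' @return n x 3 matrix with columns `L`, `a`, `b` (`L` in 0..100).
#' @export
srgb_to_lab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 1)
  if (ncol(m) != 3 || any(m < 0) || any(m > 255)) {
    stop("rgb must have 3 components in 0..255", call. = FALSE)
  }
  cs <- m / 255
  lin <- ifelse(cs <= 0.04045, cs / 12.92, ((cs + 0.055) / 1.055)^2.4)
  # sRGB (IEC 61966-2-1) linear RGB -> XYZ, D65
  M <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.00000, 1.08883) # D65, 2 degree observer
  t_ <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(t_ > delta^3, t_^(1 / 3), t_ / (3 * delta^2) + 4 / 29)
  lab <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  lab
}

#' CIEDE2000 color difference
#'
#' Full CIEDE2000 formula (kL = kC = kH = 1) including the lightness,
#' chroma and hue weighting functions and the blue-region hue-rotation
#' term. Vectorized over rows.
#'
#' @param lab1,lab2 length-3 CIELAB triples or n x 3 matrices.
#' @return non-negative numeric vector of color differences (Delta E 2000).
#' @export
ciede2000 <- function(lab1, lab2) {
  a1m <- if (is.matrix(lab1)) lab1 else matrix(lab1, nrow = 1)
  a2m <- if (is.matrix(lab2)) lab2 else matrix(lab2, nrow = 1)
  stopifnot(ncol(a1m) == 3, ncol(a2m) == 3, nrow(a1m) == nrow(a2m))
  L1 <- a1m[, 1]; a1 <- a1m[, 2]; b1 <- a1m[, 3]
  L2 <- a2m[, 1]; a2 <- a2m[, 2]; b2 <- a2m[, 3]
  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- ifelse(C1p * C2p == 0, 0,
    ifelse(abs(h2p - h1p) <= 180, h2p - h1p,
      ifelse(h2p - h1p > 180, h2p - h1p - 360, h2p - h1p + 360)
    )
  )
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
    ifelse(abs(h1p - h2p) <= 180, hsum / 2,
      ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)
    )
  )
  T_ <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  d_theta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * d_theta * pi / 180) * RC
  unname(sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
    RT * (dCp / SC) * (dHp / SH)))
}

# overlap-weight matrix mapping `src` source pixels onto `dst` target cells
# (area-average / box resampling along one axis); rows sum to 1
area_weights <- function(src, dst) {
  W <- matrix(0, dst, src)
  step <- src / dst
  for (t in seq_len(dst)) {
    lo <- (t - 1) * step
    hi <- t * step
    for (s in seq(floor(lo) + 1, ceiling(hi))) {
      overlap <- min(hi, s) - max(lo, s - 1)
      if (overlap > 0) W[t, s] <- overlap / step
    }
  }
  W
}

#' Downsample an object image and keep non-background pixels
#'
#' Area-average (box) resampling of an RGBA image to a low-resolution grid
#' (default 20 x 20), treating the alpha channel as the background mask:
#' RGB is alpha-weighted during averaging and resampled cells with alpha
#' below 0.5 are dropped. Remaining sRGB colors are converted to CIELAB.
#'
#' @param image path to a PNG with an alpha channel, or an H x W x 4 array
#'   with values in \[0, 1\] (as returned by `png::readPNG`).
#' @param target edge length of the downsampled grid (pixels).
#' @param object_id optional id carried along in the result.
#' @return object of class `pixel_set`: list with `object_id`, `lab`
#'   (m x 3 CIELAB matrix of retained pixels, 1 <= m <= target^2), `alpha`
#'   (retained alpha values), `target`.
#' @export
downsample_and_mask <- function(image, target = 20L, object_id = NA) {
  arr <- if (is.character(image)) png::readPNG(image) else image
  if (length(dim(arr)) != 3 || dim(arr)[3] < 4) {
    stop("image must have an alpha channel (H x W x 4)", call. = FALSE)
  }
  h <- dim(arr)[1]
  w <- dim(arr)[2]
  Wr <- area_weights(h, target)
  Wc <- t(area_weights(w, target))
  alpha <- Wr %*% arr[, , 4] %*% Wc
  # premultiplied averaging: color of a cell is the alpha-weighted mean
  chan <- lapply(1:3, function(c) Wr %*% (arr[, , c] * arr[, , 4]) %*% Wc)
  keep <- alpha >= 0.5
  if (!any(keep)) stop("empty pixel set: image is fully transparent", call. = FALSE)
  rgb255 <- sapply(chan, function(m) m[keep] / alpha[keep]) * 255
  rgb255 <- pmin(pmax(rgb255, 0), 255)
  if (!is.matrix(rgb255)) rgb255 <- matrix(rgb255, ncol = 3)
  structure(
    list(
      object_id = object_id, lab = srgb_to_lab(rgb255),
      alpha = alpha[keep], target = as.integer(target)
    ),
    class = "pixel_set"
  )
}

#' Mean color difference between two objects
#'
#' Averages CIEDE2000 over the full cross product of the two objects'
#' retained pixels: every pixel of `a` against every pixel of `b`. Despite
#' the study's "similarity" wording this is a dissimilarity — larger means
#' more different in color.
#'
#' @param a,b `pixel_set` objects (see [downsample_and_mask()]), or bare
#'   m x 3 CIELAB matrices.
#' @return list with `pair` (the two object ids) and `mean_delta_e`.
#' @export
pair_color_score <- function(a, b) {
  la <- if (inherits(a, "pixel_set")) a$lab else as.matrix(a)
  lb <- if (inherits(b, "pixel_set")) b$lab else as.matrix(b)
  if (nrow(la) == 0 || nrow(lb) == 0) {
    stop("empty pixel set", call. = FALSE)
  }
  idx <- expand.grid(ia = seq_len(nrow(la)), ib = seq_len(nrow(lb)))
  de <- ciede2000(la[idx$ia, , drop = FALSE], lb[idx$ib, , drop = FALSE])
  list(
    pair = c(
      if (inherits(a, "pixel_set")) a$object_id else NA,
      if (inherits(b, "pixel_set")) b$object_id else NA
    ),
    mean_delta_e = mean(de)
  )
}

#' All pairwise mean color differences
#'
#' @param pixel_sets list of `pixel_set` objects in object-id order.
#' @return data.frame with columns `i`, `j`, `mean_delta_e` in lexical pair
#'   order.
#' @export
color_score_table <- function(pixel_sets) {
  n <- length(pixel_sets)
  ij <- pair_index(n)
  de <- vapply(seq_len(nrow(ij)), function(r) {
    pair_color_score(pixel_sets[[ij[r, 1]]], pixel_sets[[ij[r, 2]]])$mean_delta_e
  }, numeric(1))
  data.frame(i = ij[, 1], j = ij[, 2], mean_delta_e = de)
}

#' Correlation between color differences and arrangement-derived distances
#'
#' Pearson correlation between per-pair mean CIEDE2000 color differences
#' and per-pair MDS distances, with the two-tailed t-based p value — the
#' confound check that similarity judgments were driven by shape, not
#' color. Both inputs are dissimilarities, so a positive r would indicate a
#' color influence.
#'
#' @param color_scores numeric vector of per-pair mean Delta E values.
#' @param mds_distances numeric vector of per-pair MDS distances, same pair
#'   ordering.
#' @return list with `r`, `df` (`n_pairs - 2`), `p`.
#' @export
color_shape_correlation <- function(color_scores, mds_distances) {
  if (length(color_scores) != length(mds_distances) || length(color_scores) < 3) {
    stop("inputs must be equal-length vectors of length >= 3", call. = FALSE)
  }
  if (sd(color_scores) == 0 || sd(mds_distances) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  ct <- cor.test(color_scores, mds_distances, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}
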