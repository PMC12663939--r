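#' FRET-efficiency calibration curve
#'
#' Strictly monotone map between water potential and FRET efficiency
#' (zeta), either a parameterised logistic or tabulated pairs with
#' monotone spline interpolation. The shipped default is a placeholder
#' logistic spanning [-20, 0] MPa and is not a physiological calibration:
#' real analyses must inject the instrument's own curve.
#'
#' @param type `"logistic"` or `"table"`.
#' @param zeta_range FRET efficiency at the dry and wet asymptotes
#'   (logistic).
#' @param psi_mid Midpoint, MPa (logistic).
#' @param width Transition width, MPa (logistic).
#' @param table Data.frame with columns `psi`, `zeta` (type = "table"),
#'   strictly monotone in zeta.
#' @param psi_range Valid water-potential range, MPa.
#' @return Object of class `calibration_curve`.
#' @examples
#' cal <- calibration_curve()
#' cal_invert(cal, cal_apply(cal, -6)) # -6
#' @export
calibration_curve <- function(type = c("logistic", "table"),
                              zeta_range = c(0.2, 0.8), psi_mid = -8,
                              width = 3, table = NULL,
                              psi_range = c(-20, 0)) {
  type <- match.arg(type)
  stopifnot(psi_range[1] < psi_range[2])
  if (type == "logistic") {
    stopifnot(zeta_range[1] < zeta_range[2], width > 0)
    obj <- list(
      type = type, zeta_range = zeta_range, psi_mid = psi_mid,
      width = width, psi_range = psi_range
    )
  } else {
    stopifnot(
      !is.null(table), all(c("psi", "zeta") %in% names(table)),
      nrow(table) >= 3
    )
    table <- table[order(table$psi), ]
    dz <- diff(table$zeta)
    if (!(all(dz > 0) || all(dz < 0))) {
      stop("tabulated calibration must be strictly monotone")
    }
    obj <- list(
      type = type, table = table,
      psi_range = range(table$psi)
    )
  }
  structure(obj, class = "calibration_curve")
}

#' @rdname calibration_curve
#' @param cal A `calibration_curve`.
#' @param psi Water potential, MPa (matrix or vector).
#' @return `cal_apply`: FRET efficiency zeta with the shape of `psi`.
#' @export
cal_apply <- function(cal, psi) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$type == "logistic") {
    out <- cal$zeta_range[1] + diff(cal$zeta_range) /
      (1 + exp(-(psi - cal$psi_mid) / cal$width))
  } else {
    f <- stats::splinefun(cal$table$psi, cal$table$zeta, method = "hyman")
    out <- f(psi)
    dim(out) <- dim(psi)
  }
  out
}

#' @rdname calibration_curve
#' @param zeta FRET efficiency (matrix or vector).
#' @return `cal_invert`: water potential, MPa; `NA` outside the
#'   invertible range.
#' @export
cal_invert <- function(cal, zeta) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$type == "logistic") {
    zlo <- cal_apply(cal, cal$psi_range[1])
    zhi <- cal_apply(cal, cal$psi_range[2])
    ok <- is.finite(zeta) & zeta > zlo & zeta < zhi
    out <- rep(NA_real_, length(zeta))
    z <- zeta[ok]
    out[ok] <- cal$psi_mid + cal$width *
      log((z - cal$zeta_range[1]) / (cal$zeta_range[2] - z))
    dim(out) <- dim(zeta)
  } else {
    inc <- diff(cal$table$zeta)[1] > 0
    zs <- if (inc) cal$table$zeta else rev(cal$table$zeta)
    ps <- if (inc) cal$table$psi else rev(cal$table$psi)
    f <- stats::splinefun(zs, ps, method = "hyman")
    ok <- is.finite(zeta) & zeta >= min(zs) & zeta <= max(zs)
    out <- rep(NA_real_, length(zeta))
    out[ok] <- f(zeta[ok])
    dim(out) <- dim(zeta)
  }
  out
}

#' Pixel-wise water-potential map from a FRET image
#'
#' Inverts the calibration curve at every pixel. Pixels whose efficiency
#' falls outside the invertible range become `NA`; their count is
#' reported via the `n_out_of_range` attribute and a message.
#'
#' @param img A `fret_image` (see [generate_fret_image()] /
#'   [read_fret_image()]).
#' @param cal A [calibration_curve()].
#' @return Numeric matrix of water potentials (MPa) with attribute
#'   `n_out_of_range`.
#' @export
zeta_to_psi_map <- function(img, cal = calibration_curve()) {
  stopifnot(inherits(img, "fret_image"))
  psi <- cal_invert(cal, img$zeta_map)
  n_bad <- sum(is.na(psi) & !is.na(img$zeta_map))
  if (n_bad > 0) {
    message(sprintf("%d pixel(s) outside the calibration range set to NA", n_bad))
  }
  attr(psi, "n_out_of_range") <- n_bad
  psi
}

#' Histogram and mode of a water-potential map
#'
#' Fixed-width histogram (default 0.25 MPa bins anchored at multiples of
#' the bin width) over the valid pixels of a potential map; the mode is
#' the centre of the tallest bin, with ties resolved toward the less
#' negative bin. A fixed-width histogram rather than a density estimate
#' keeps the mode reproducible.
#'
#' @param psi_map Numeric matrix of water potentials, MPa.
#' @param bin_width Bin width, MPa.
#' @param mask Optional logical matrix selecting pixels to include.
#' @return List with `histogram` (data.frame `bin_center`, `count`),
#'   `mode` (MPa) and `n_pixels`.
#' @export
psi_histogram <- function(psi_map, bin_width = 0.25, mask = NULL) {
  vals <- if (is.null(mask)) psi_map else psi_map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 100) {
    stop("need at least 100 valid pixels for a histogram")
  }
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.vector(table(cut(vals, breaks,
    include.lowest = TRUE,
    right = FALSE
  )))
  centers <- breaks[-length(breaks)] + bin_width / 2
  best <- which(counts == max(counts))
  mode <- max(centers[best]) # tie -> less negative bin
  list(
    histogram = data.frame(bin_center = centers, count = counts),
    mode = mode,
    n_pixels = length(vals)
  )
}

# Sub-pixel contour length of a binary mask: arc length of the level-0.5
# iso-contour (marching squares with linear interpolation), lightly
# smoothed with a 3-point circular moving average of the polygon vertices
# to remove the half-pixel staircase bias. A digitised disk comes out
# within ~2% of 2*pi*r; a square keeps its corners to within ~3%.
mask_perimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  cl <- grDevices::contourLines(
    x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m, levels = 0.5
  )
  sum(vapply(cl, function(cc) {
    x <- cc$x
    y <- cc$y
    n <- length(x)
    if (n < 5) {
      return(sum(sqrt(diff(x)^2 + diff(y)^2)))
    }
    if (x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]
      y <- y[-n]
      n <- n - 1L
    }
    prv <- c(n, seq_len(n - 1L))
    nxt <- c(seq_len(n)[-1], 1L)
    xs <- (x[prv] + x + x[nxt]) / 3
    ys <- (y[prv] + y + y[nxt]) / 3
    sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  }, numeric(1)))
}

#' Cell morphometrics from an autofluorescence channel
#'
#' Segments mesophyll cells (Otsu threshold, hole filling, watershed
#' split of touching cells) or accepts pre-made label masks, then
#' measures area, perimeter and circularity (4*pi*A/P^2, capped at 1)
#' per cell. Perimeter uses the sub-pixel iso-contour of the cell mask at
#' level one half, so a disk scores circularity near 1 and an
#' axis-aligned square near pi/4. Cells touching the image border are
#' excluded.
#'
#' @param autofluorescence Numeric matrix in [0, 1], or a `fret_image`.
#' @param masks Optional integer label matrix bypassing segmentation.
#' @param pixel_size Pixel edge, micrometres.
#' @param min_area_px Minimum object area in pixels (speckle filter).
#' @return Data.frame `label`, `area_um2`, `perimeter_um`, `circularity`.
#' @examples
#' img <- generate_fret_image(seed = 3)
#' morph <- cell_morphometrics(img)
#' @export
cell_morphometrics <- function(autofluorescence, masks = NULL,
                               pixel_size = 1, min_area_px = 30) {
  if (inherits(autofluorescence, "fret_image")) {
    if (missing(pixel_size)) pixel_size <- autofluorescence$pixel_size
    autofluorescence <- autofluorescence$autofluorescence
  }
  if (is.null(masks)) {
    im <- EBImage::Image(autofluorescence)
    thr <- EBImage::otsu(im)
    bin <- EBImage::fillHull(im > thr)
    labels <- EBImage::imageData(EBImage::watershed(EBImage::distmap(bin), tolerance = 2))
  } else {
    labels <- masks
  }
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  border <- unique(c(
    labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)]
  ))
  ids <- setdiff(sort(unique(as.vector(labels))), c(0L, border))
  rows <- lapply(ids, function(id) {
    mask <- labels == id
    area_px <- sum(mask)
    if (area_px < min_area_px) {
      return(NULL)
    }
    per_px <- mask_perimeter(mask)
    circ <- min(1, 4 * pi * area_px / per_px^2)
    data.frame(
      label = id,
      area_um2 = area_px * pixel_size^2,
      perimeter_um = per_px * pixel_size,
      circularity = circ
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    warning("no segmentable cells found")
    return(data.frame(
      label = integer(0), area_um2 = numeric(0),
      perimeter_um = numeric(0), circularity = numeric(0)
    ))
  }
  do.call(rbind, rows)
}

# compact-letter display by insert-absorb on the significant-pair set
cld_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  for (p in sig_pairs) {
    k <- 1
    while (k <= length(sets)) {
      s <- sets[[k]]
      if (all(p %in% s)) {
        sets[[k]] <- setdiff(s, p[1])
        sets[[length(sets) + 1]] <- setdiff(s, p[2])
      }
      k <- k + 1
    }
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- sets[keep]
  }
  letters_out <- stats::setNames(rep("", length(group_names)), group_names)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out
}

#' Group comparison of cell morphometrics
#'
#' One-way ANOVA with Tukey HSD post-hoc per metric, plus a
#' compact-letter display (groups sharing no letter differ at the given
#' level). Degenerate within-group variance is flagged rather than
#' tested.
#'
#' @param morphologies Data.frame with a `condition` column and one or
#'   more numeric metric columns (e.g. the output of
#'   [cell_morphometrics()] per condition, row-bound with a `condition`
#'   label).
#' @param metrics Character vector of metric columns to test.
#' @param alpha Significance level.
#' @return Object of class `group_comparison`: per metric a list with
#'   `pairs` (Tukey table: `pair`, `diff`, `p_adj`, `significant`),
#'   `letters`, and `degenerate` flag.
#' @examples
#' m1 <- data.frame(condition = "turgid", area_um2 = rnorm(25, 100, 5))
#' m2 <- data.frame(condition = "cut", area_um2 = rnorm(25, 60, 5))
#' group_compare(rbind(m1, m2), metrics = "area_um2")
#' @export
group_compare <- function(morphologies,
                          metrics = c("area_um2", "circularity"),
                          alpha = 0.05) {
  stopifnot("condition" %in% names(morphologies))
  grp <- factor(morphologies$condition)
  if (nlevels(grp) < 2) stop("need at least two conditions")
  if (any(table(grp) < 3)) stop("each condition needs n >= 3")
  out <- list()
  for (v in metrics) {
    y <- morphologies[[v]]
    if (is.null(y)) stop("metric column not found: ", v)
    degenerate <- any(tapply(y, grp, stats::sd) < .Machine$double.eps^0.5)
    if (degenerate) {
      out[[v]] <- list(pairs = NULL, letters = NULL, degenerate = TRUE)
      next
    }
    fit <- stats::aov(y ~ grp)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
    pairs_df <- data.frame(
      pair = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      row.names = NULL
    )
    sig_pairs <- lapply(
      pairs_df$pair[pairs_df$significant],
      function(s) strsplit(s, "-", fixed = TRUE)[[1]]
    )
    out[[v]] <- list(
      pairs = pairs_df,
      letters = cld_letters(levels(grp), sig_pairs),
      degenerate = FALSE
    )
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (v in names(x)) {
    cat(sprintf("== %s ==\n", v))
    if (isTRUE(x[[v]]$degenerate)) {
      cat("  degenerate within-group variance; not tested\n")
      next
    }
    print(x[[v]]$pairs, row.names = FALSE)
    cat("  letters:", paste(
      names(x[[v]]$letters), x[[v]]$letters,
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}
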