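# Picrosirius-red collagen quantification: segment tissue from background,
# classify collagen-red pixels in HSV space, report the fibrotic-area
# percentage (collagen pixels / tissue pixels * 100).

#' Read an RGB image from a PNG file
#' @param path PNG path.
#' @return height x width x 3 numeric array in \[0, 1\] (alpha dropped,
#'   greyscale replicated).
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to a PNG file
#' @param img height x width x 3 array in \[0, 1\].
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# run-based two-pass connected-component labelling (4-connectivity) of a
# logical matrix; returns an integer matrix of labels (0 = background)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_row <- list()
  nrun <- 0L
  run_row <- run_lo <- run_hi <- integer(0)
  for (r in seq_len(h)) {
    v <- mask[r, ]
    d <- diff(c(FALSE, v, FALSE))
    lo <- which(d == 1L); hi <- which(d == -1L) - 1L
    if (length(lo)) {
      run_row <- c(run_row, rep.int(r, length(lo)))
      run_lo <- c(run_lo, lo); run_hi <- c(run_hi, hi)
    }
  }
  nrun <- length(run_lo)
  if (!nrun) return(matrix(0L, h, w))
  parent <- seq_len(nrun)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  row_start <- match(seq_len(h), run_row)
  for (i in seq_len(nrun)) {
    r <- run_row[i]
    if (r == 1L) next
    j <- row_start[r - 1L]
    if (is.na(j)) next
    while (!is.na(j) && j <= nrun && run_row[j] == r - 1L) {
      if (run_lo[j] <= run_hi[i] && run_hi[j] >= run_lo[i]) union_(i, j)
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(nrun), find, 0L)
  labels <- match(roots, unique(roots))
  out <- matrix(0L, h, w)
  for (i in seq_len(nrun))
    out[run_row[i], run_lo[i]:run_hi[i]] <- labels[i]
  out
}

img_hsv <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

#' Stain-classification thresholds
#'
#' HSV thresholds for "picrosirius red collagen" and "near-white
#' background". The red hue window wraps around 0; defaults were chosen on
#' the synthetic stain distributions and are deliberately wide (the original
#' study's macro is unpublished, so only relative behaviour is meaningful on
#' real slides).
#'
#' @param hue_lo,hue_hi red hue window in \[0, 1\], wrap-around when
#'   `hue_lo > hue_hi` (default 0.90 .. 0.08).
#' @param sat_min minimum saturation for a collagen pixel.
#' @param val_lo,val_hi value (brightness) bounds for a collagen pixel.
#' @param bg_val_min,bg_sat_max background = value above / saturation below
#'   these (near-white by lightness).
#' @return list of thresholds, class `"stain_thresholds"`.
#' @export
stain_thresholds <- function(hue_lo = 0.90, hue_hi = 0.08, sat_min = 0.3,
                             val_lo = 0.1, val_hi = 0.95,
                             bg_val_min = 0.92, bg_sat_max = 0.15) {
  stopifnot(hue_lo >= 0, hue_lo <= 1, hue_hi >= 0, hue_hi <= 1,
            sat_min >= 0, sat_min <= 1, val_lo < val_hi)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_lo = val_lo, val_hi = val_hi, bg_val_min = bg_val_min,
                 bg_sat_max = bg_sat_max),
            class = "stain_thresholds")
}

#' Segment tissue from background
#'
#' Background is near-white (value above `bg_val_min` and saturation below
#' `bg_sat_max`); the tissue mask keeps the connected components comparable
#' in size to the largest one and fills enclosed holes smaller than
#' `fill_holes_px`.
#'
#' @param img height x width x 3 RGB array in \[0, 1\].
#' @param thresholds a [stain_thresholds()].
#' @param min_component_frac keep components at least this fraction of the
#'   largest component's size (default 0.05).
#' @param fill_holes_px fill enclosed background holes smaller than this
#'   (default 100 px).
#' @return logical tissue mask (height x width).
#' @export
segment_tissue <- function(img, thresholds = stain_thresholds(),
                           min_component_frac = 0.05, fill_holes_px = 100) {
  hsv <- img_hsv(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  bg <- hsv[3, ] >= thresholds$bg_val_min & hsv[2, ] <= thresholds$bg_sat_max
  tissue <- matrix(!bg, h, w)
  if (!any(tissue)) stop("no tissue detected (image is entirely background)")
  if (all(tissue)) return(tissue)
  lab <- label_components(tissue)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_frac * max(sizes))
  tissue <- matrix(lab %in% keep, h, w)
  # fill small enclosed holes: background components not touching the border
  hol <- label_components(!tissue)
  if (max(hol) > 0L) {
    border_labs <- unique(c(hol[1, ], hol[h, ], hol[, 1], hol[, w]))
    hsizes <- tabulate(hol[hol > 0L])
    fill <- setdiff(which(hsizes < fill_holes_px), border_labs)
    if (length(fill)) tissue[hol %in% fill] <- TRUE
  }
  tissue
}

#' Quantify collagen-stained (fibrotic) area
#'
#' Counts tissue pixels whose HSV colour falls inside the red collagen
#' window and reports the fibrotic-area percentage
#' `100 * collagen_px / tissue_px`. By default the denominator is the
#' tissue mask ("total tissue area"); set `denominator = "frame"` to divide
#' by the full image area instead.
#'
#' @param img height x width x 3 RGB array in \[0, 1\].
#' @param tissue_mask logical mask from [segment_tissue()] (computed on the
#'   fly when `NULL`).
#' @param thresholds a [stain_thresholds()].
#' @param denominator `"tissue"` (default) or `"frame"`.
#' @return An object of class `"collagen_quantification"`: list with
#'   `tissue_px`, `collagen_px`, `fibrotic_pct`.
#' @export
quantify_collagen <- function(img, tissue_mask = NULL,
                              thresholds = stain_thresholds(),
                              denominator = c("tissue", "frame")) {
  denominator <- match.arg(denominator)
  if (is.null(tissue_mask)) tissue_mask <- segment_tissue(img, thresholds)
  stopifnot(is.logical(tissue_mask),
            all(dim(tissue_mask) == dim(img)[1:2]))
  if (!any(tissue_mask)) stop("tissue mask is empty")
  hsv <- img_hsv(img)
  hh <- hsv[1, ]; ss <- hsv[2, ]; vv <- hsv[3, ]
  in_hue <- if (thresholds$hue_lo > thresholds$hue_hi)
    hh >= thresholds$hue_lo | hh <= thresholds$hue_hi
  else hh >= thresholds$hue_lo & hh <= thresholds$hue_hi
  red <- in_hue & ss >= thresholds$sat_min &
    vv >= thresholds$val_lo & vv <= thresholds$val_hi
  red <- matrix(red, dim(img)[1], dim(img)[2]) & tissue_mask
  tissue_px <- sum(tissue_mask)
  collagen_px <- sum(red)
  denom <- if (denominator == "tissue") tissue_px else length(tissue_mask)
  structure(list(tissue_px = tissue_px, collagen_px = collagen_px,
                 fibrotic_pct = 100 * collagen_px / denom),
            class = "collagen_quantification")
}

#' @export
print.collagen_quantification <- function(x, ...) {
  cat(sprintf("<collagen> %d / %d tissue px red: fibrotic area %.2f%%\n",
              x$collagen_px, x$tissue_px, x$fibrotic_pct))
  invisible(x)
}

#' Batch collagen quantification over a directory of PNG images
#' @param dir directory containing `.png` files.
#' @param thresholds a [stain_thresholds()].
#' @return data frame `(file, tissue_px, collagen_px, fibrotic_pct)`.
#' @export
quantify_collagen_dir <- function(dir, thresholds = stain_thresholds()) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) stop("no PNG files in ", dir)
  rows <- lapply(files, function(f) {
    q <- quantify_collagen(read_image_png(f), thresholds = thresholds)
    data.frame(file = basename(f), tissue_px = q$tissue_px,
               collagen_px = q$collagen_px, fibrotic_pct = q$fibrotic_pct)
  })
  do.call(rbind, rows)
}

#' Downscale an RGB image by integer block averaging
#' @param img height x width x 3 array.
#' @param factor integer downscale factor.
#' @export
downscale_image <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  h <- dim(img)[1] %/% factor * factor
  w <- dim(img)[2] %/% factor * factor
  out <- array(0, dim = c(h %/% factor, w %/% factor, 3))
  for (k in 1:3) {
    m <- img[seq_len(h), seq_len(w), k]
    m <- (m[seq(1, h, 2), ] + m[seq(2, h, 2), ]) / 2
    m <- (m[, seq(1, w, 2)] + m[, seq(2, w, 2)]) / 2
    if (factor == 2L) out[, , k] <- m
    else stop("only factor 2 supported")
  }
  out
}
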