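#' Otsu threshold of an 8-bit gray histogram
#'
#' Picks the threshold t in 0..254 maximizing the between-class
#' variance of the two classes {v <= t} and {v > t}, computed from the
#' 256-bin histogram by the cumulative-moment recurrence. Foreground is
#' taken as the class above the threshold.
#'
#' @param v numeric/integer vector or matrix of gray values in 0..255.
#' @return The threshold t (integer in 0..254); pixels with value > t
#'   are foreground under the default bright-grain polarity.
#' @export
otsu_threshold <- function(v) {
  v <- as.integer(round(v))
  if (length(v) == 0L) stop("empty input")
  if (min(v) < 0L || max(v) > 255L) stop("gray values must be in 0..255")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                 # class sizes at t = 0..255
  m0 <- cumsum(h * lev)           # class first moments
  mt <- m0[256]
  t_all <- 0:254
  w0t <- w0[t_all + 1L]
  w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  if (!any(valid)) return(0L)     # constant image: degenerate, return 0
  mu0 <- m0[t_all + 1L] / w0t
  mu1 <- (mt - m0[t_all + 1L]) / w1t
  bcv <- ifelse(valid, w0t * w1t * (mu0 - mu1)^2, -Inf)
  t_all[which.max(bcv)]
}

#' Binarize a calibrated image into a grain mask
#'
#' Thresholds an 8-bit grayscale image. Under coaxial illumination the
#' grain section is bright on a dark background, so the default
#' polarity takes pixels above the threshold as foreground; set
#' `invert = TRUE` for dark-on-bright material.
#'
#' @param img a [calibrated_image()].
#' @param method `"otsu"` (automatic, [otsu_threshold()]) or `"fixed"`.
#' @param threshold gray level in 0..255; required for
#'   `method = "fixed"`. Foreground is `value >= threshold` (fixed) or
#'   `value > t_otsu` (otsu).
#' @param invert flip the foreground polarity.
#' @return A [grain_mask()]; its provenance records the method,
#'   effective threshold and polarity. The mask may contain several
#'   components; use [extract_roi()] to isolate the grain.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     invert = FALSE) {
  stopifnot(inherits(img, "calibrated_image"))
  method <- match.arg(method)
  v <- img$pixels
  if (method == "otsu") {
    t_eff <- otsu_threshold(v)
    fg <- v > t_eff
  } else {
    if (is.null(threshold) || !is.numeric(threshold) ||
        length(threshold) != 1L || threshold < 0 || threshold > 255)
      stop("`threshold` must be a gray level in 0..255 for method = \"fixed\"")
    t_eff <- threshold
    fg <- v >= t_eff
  }
  if (isTRUE(invert)) fg <- !fg
  if (!any(fg))
    stop(sprintf(
      "binarize: empty foreground (method = %s, threshold = %s, invert = %s)",
      method, format(t_eff), invert))
  grain_mask(fg, img$scale_mm_per_px, img$source_id,
             provenance = list(method = method, threshold = t_eff,
                               invert = isTRUE(invert)))
}

#' Label connected components of a binary matrix
#'
#' Labels foreground components of a 0/1 matrix using 8- (default) or
#' 4-connectivity. Implemented as connected components of the pixel
#' adjacency graph.
#'
#' @param m 0/1 (or logical) matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in order of their smallest column-major pixel index.
#' @export
label_components <- function(m, connectivity = 8) {
  if (is.logical(m)) m <- m + 0L
  stopifnot(is.matrix(m), connectivity %in% c(4, 8))
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m != 0)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  inside <- logical(length(idx))
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    idx2 <- (c2 - 1L) * nr + r2
    ok[ok] <- m[idx2[ok]] != 0
    from <- c(from, idx[ok]); to <- c(to, idx2[ok])
  }
  vmap <- match(c(from, to), idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(vmap[seq_along(from)],
                                    vmap[length(from) + seq_along(to)]))
  memb <- igraph::components(g)$membership
  # renumber so component 1 contains the smallest column-major index
  first <- tapply(seq_along(idx), memb, min)
  ord <- order(idx[first])
  renum <- integer(length(first)); renum[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[idx] <- renum[memb]
  lab
}

#' Fill interior holes of a binary matrix
#'
#' Background regions (4-connected) that do not touch the image border
#' are converted to foreground. A transverse endosperm section is
#' simply connected, so interior cracks and voids are artifacts of
#' thresholding.
#'
#' @param m 0/1 (or logical) matrix.
#' @return 0/1 integer matrix with holes filled.
#' @export
fill_holes <- function(m) {
  if (is.logical(m)) m <- m + 0L
  stopifnot(is.matrix(m))
  bg <- 1L - m
  lab <- label_components(bg, connectivity = 4)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs != 0L]
  hole <- lab != 0L & !(lab %in% border_labs)
  out <- m
  out[hole] <- 1L
  storage.mode(out) <- "integer"
  out
}

#' Extract the grain region of interest from a segmented mask
#'
#' Keeps the largest 8-connected foreground component (the grain
#' cross-section) and, by default, fills its interior holes. When two
#' components tie on area, the one whose foreground pixel has the
#' lexicographically smallest (row, column) coordinate wins; the choice
#' is recorded in the provenance.
#'
#' @param mask a [grain_mask()] (possibly multi-component).
#' @param fill_holes fill interior holes of the kept component
#'   (default TRUE).
#' @param crop optional crop box `c(row_min, row_max, col_min, col_max)`
#'   applied before component extraction.
#' @return A [grain_mask()] with exactly one 8-connected component;
#'   provenance gains `components_dropped` and, on a tie,
#'   `tie_break = "topleft"`.
#' @export
extract_roi <- function(mask, fill_holes = TRUE, crop = NULL) {
  stopifnot(inherits(mask, "grain_mask"))
  m <- mask$pixels
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4L)
    keep <- matrix(0L, nrow(m), ncol(m))
    keep[crop[1]:crop[2], crop[3]:crop[4]] <- 1L
    m <- m * keep
    if (sum(m) == 0L) stop("crop box contains no foreground")
  }
  lab <- label_components(m, connectivity = 8)
  ncomp <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  big <- which(sizes == max(sizes))
  tie <- length(big) > 1L
  if (tie) {
    # smallest (row, col) lexicographic foreground coordinate wins
    firstpos <- vapply(big, function(k) {
      idx <- which(lab == k)
      r <- ((idx - 1L) %% nrow(lab)) + 1L
      cc <- ((idx - 1L) %/% nrow(lab)) + 1L
      min(r * (ncol(lab) + 1) + cc)  # row-major order key
    }, 0)
    winner <- big[which.min(firstpos)]
  } else {
    winner <- big
  }
  out <- (lab == winner) + 0L
  if (isTRUE(fill_holes)) out <- fill_holes(out)
  prov <- mask$provenance
  prov$components_dropped <- ncomp - 1L
  prov$holes_filled <- isTRUE(fill_holes)
  if (tie) prov$tie_break <- "topleft"
  grain_mask(out, mask$scale_mm_per_px, mask$source_id, provenance = prov)
}
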