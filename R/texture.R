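#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels co-occurring at a fixed pixel offset
#' over all valid positions of an 8-bit patch, after uniform binning of
#' 0..255 into `Ng` levels (level = floor(value * Ng / 256)). With
#' `symmetric = TRUE` each pair is counted in both directions, so the
#' matrix equals the average of the one-directional count matrix and
#' its transpose. The result is normalized to sum 1.
#'
#' @param patch matrix of gray values in 0..255, at least 2x2.
#' @param Ng number of gray levels after binning, 2..256 (default 8).
#' @param offset integer pair `c(dx, dy)`: dx = column displacement
#'   (positive right), dy = row displacement (positive down). Default
#'   `c(1, 0)`, i.e. distance 1 at 0 degrees.
#' @param symmetric count both directions (default TRUE).
#' @return An object of class `glcm`: list with `matrix` (Ng x Ng
#'   probabilities), `Ng`, `offset`, `symmetric`.
#' @export
glcm <- function(patch, Ng = 8, offset = c(1, 0), symmetric = TRUE) {
  stopifnot(is.matrix(patch), nrow(patch) >= 2L || ncol(patch) >= 2L)
  if (nrow(patch) < 2L && ncol(patch) < 2L) stop("patch must be >= 2x2")
  Ng <- as.integer(Ng)
  if (Ng < 2L || Ng > 256L) stop("Ng must be in 2..256")
  v <- round(patch)
  if (min(v) < 0 || max(v) > 255) stop("gray values must be in 0..255")
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  nr <- nrow(v); nc <- ncol(v)
  if (abs(dx) >= nc || abs(dy) >= nr)
    stop("offset larger than patch")
  if (dx == 0L && dy == 0L) stop("offset must be nonzero")
  lev <- matrix(pmin(Ng - 1L, v %/% (256 / Ng)), nr, nc)
  rows1 <- max(1L, 1L - dy):min(nr, nr - dy)
  cols1 <- max(1L, 1L - dx):min(nc, nc - dx)
  a <- lev[rows1, cols1, drop = FALSE]
  b <- lev[rows1 + dy, cols1 + dx, drop = FALSE]
  counts <- matrix(tabulate(a * Ng + b + 1L, nbins = Ng * Ng),
                   Ng, Ng, byrow = TRUE)
  if (isTRUE(symmetric)) counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(list(matrix = p, Ng = Ng, offset = c(dx, dy),
                 symmetric = isTRUE(symmetric)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> Ng = %d, offset = (%d, %d), symmetric = %s\n",
              x$Ng, x$offset[1], x$offset[2], x$symmetric))
  invisible(x)
}

#' GLCM entropy
#'
#' E = -sum p(i,j) * log p(i,j) over nonzero entries; high for randomly
#' organized (disordered) pixel neighborhoods, 0 for a constant patch.
#'
#' @param g a [glcm()].
#' @param base log base: `"nat"` (natural log, default; nats) or
#'   `"2"` (bits).
#' @return Entropy (nats by default).
#' @export
glcm_entropy <- function(g, base = c("nat", "2")) {
  stopifnot(inherits(g, "glcm"))
  base <- match.arg(base)
  p <- g$matrix[g$matrix > 0]
  e <- -sum(p * log(p))
  if (base == "2") e <- e / log(2)
  e
}

#' GLCM angular second moment
#'
#' ASM = sum p(i,j)^2; a homogeneity/organization measure, 1 for a
#' constant patch and 1/Ng^2 at the uniform co-occurrence limit.
#'
#' @param g a [glcm()].
#' @return ASM in (0, 1].
#' @export
glcm_asm <- function(g) {
  stopifnot(inherits(g, "glcm"))
  sum(g$matrix^2)
}

#' Texture record of one endosperm patch
#'
#' @param patch matrix of gray values 0..255.
#' @param patch_id identifier.
#' @param region `"dorsal"`, `"ventral"` or `"synthetic"`.
#' @param Ng,offset,symmetric GLCM settings, see [glcm()].
#' @return One-row data frame: patch_id, region, E (nats), ASM, and the
#'   GLCM settings used.
#' @export
texture_record <- function(patch, patch_id = "patch",
                           region = c("synthetic", "dorsal", "ventral"),
                           Ng = 8, offset = c(1, 0), symmetric = TRUE) {
  region <- match.arg(region)
  g <- glcm(patch, Ng = Ng, offset = offset, symmetric = symmetric)
  data.frame(patch_id = patch_id, region = region,
             E = glcm_entropy(g), ASM = glcm_asm(g),
             Ng = g$Ng, dx = g$offset[1], dy = g$offset[2],
             symmetric = g$symmetric, stringsAsFactors = FALSE)
}
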