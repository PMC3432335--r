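#' Joint intensity histogram of two images
#'
#' Bins paired intensities of two volumes (or arrays) on the same grid into a
#' `bins x bins` count matrix, the discrete estimate of the joint intensity
#' distribution from which entropies and mutual information are computed.
#' Bin edges span each image's intensity range uniformly; the range defaults
#' to the observed min-max of the contributing voxels but can be pinned with
#' `range_a`/`range_b` (registration fixes the edges once per run so that MI
#' values are comparable across candidate transforms).
#'
#' @param a,b Two [volume3d()] objects or numeric arrays with identical
#'   dimensions.
#' @param bins Number of bins per image (default 64).
#' @param mask Optional logical array selecting the voxels that contribute;
#'   defaults to the intersection of the volumes' own validity masks (all
#'   voxels when none is set).
#' @param range_a,range_b Optional length-2 intensity ranges fixing the bin
#'   edges.
#' @return A `joint_histogram`: `counts` (`bins x bins`, image `a` on rows),
#'   `edges_a`, `edges_b`, `bins`, and `n`, the number of paired samples.
#' @examples
#' x <- array(rep(c(0, 1), 32), c(4, 4, 4))
#' joint_histogram(x, x, bins = 2)$counts
#' @export
joint_histogram <- function(a, b, bins = 64L, mask = NULL,
                            range_a = NULL, range_b = NULL) {
  va <- if (inherits(a, "volume3d")) a else NULL
  vb <- if (inherits(b, "volume3d")) b else NULL
  da <- if (is.null(va)) a else va$data
  db <- if (is.null(vb)) b else vb$data
  if (!identical(dim(da), dim(db))) {
    stop("Both images must live on the same grid.", call. = FALSE)
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop("Need at least 2 bins.", call. = FALSE)
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(da))
    if (!is.null(va) && !is.null(va$mask)) mask <- mask & va$mask
    if (!is.null(vb) && !is.null(vb$mask)) mask <- mask & vb$mask
  }
  xa <- da[mask]
  xb <- db[mask]
  n <- length(xa)
  if (n == 0L) {
    stop("No overlapping voxels to histogram; the mask is empty.",
         call. = FALSE)
  }
  if (is.null(range_a)) range_a <- range(xa)
  if (is.null(range_b)) range_b <- range(xb)
  ia <- bin_index(xa, range_a, bins)
  ib <- bin_index(xb, range_b, bins)
  counts <- matrix(tabulate(ia + bins * (ib - 1L), nbins = bins * bins),
                   bins, bins)
  structure(
    list(counts = counts, bins = bins,
         edges_a = seq(range_a[1], range_a[2], length.out = bins + 1L),
         edges_b = seq(range_b[1], range_b[2], length.out = bins + 1L),
         n = n),
    class = "joint_histogram"
  )
}

# Uniform binning of values into 1..bins over `rng`; out-of-range values are
# clamped into the boundary bins (they only arise when a caller pins ranges).
bin_index <- function(x, rng, bins) {
  w <- rng[2] - rng[1]
  if (w <= 0) {
    return(rep(1L, length(x)))  # constant image: everything in bin 1
  }
  i <- floor((x - rng[1]) / w * bins) + 1
  pmin(pmax(as.integer(i), 1L), bins)
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat("<joint_histogram> ", x$bins, "x", x$bins, " bins, n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log 0 = 0`. Accepts a
#' probability vector or matrix (joint distribution); it must be non-negative
#' and sum to 1 within `1e-9`.
#'
#' @param pdf Non-negative numeric vector or matrix summing to 1.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))       # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
shannon_entropy <- function(pdf) {
  p <- as.numeric(pdf)
  if (any(p < 0)) stop("Probabilities must be non-negative.", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("Probabilities must sum to 1 (within 1e-9).", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information from a joint histogram, in bits
#'
#' The plug-in estimate `MI = H(A) + H(B) - H(A, B)` computed from the
#' normalized joint counts and their marginals. As a Kullback-Leibler
#' divergence it is non-negative; tiny negative floating-point residue is
#' floored at zero.
#'
#' @param x A `joint_histogram`, or a volume/array (in which case `y` must be
#'   the paired image and the histogram is built via [joint_histogram()]).
#' @param y,bins,mask Passed to [joint_histogram()] when `x` is not already a
#'   histogram.
#' @return Mutual information in bits.
#' @examples
#' h <- list(counts = matrix(c(2, 0, 0, 2), 2), n = 4)
#' class(h) <- "joint_histogram"
#' mutual_information(h)  # 1 bit
#' @export
mutual_information <- function(x, y = NULL, bins = 64L, mask = NULL) {
  h <- if (inherits(x, "joint_histogram")) {
    x
  } else {
    joint_histogram(x, y, bins = bins, mask = mask)
  }
  if (h$n <= 0) stop("Histogram has no samples.", call. = FALSE)
  p <- h$counts / h$n
  h_joint <- shannon_entropy(p)
  h_a <- shannon_entropy(rowSums(p))
  h_b <- shannon_entropy(colSums(p))
  max(h_a + h_b - h_joint, 0)
}

#' Write a joint histogram as CSV (debug aid)
#'
#' @param h A `joint_histogram`.
#' @param path Output CSV path; cells written as `bin_a`, `bin_b`, `count`.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "joint_histogram"))
  df <- data.frame(bin_a = rep(seq_len(h$bins), times = h$bins),
                   bin_b = rep(seq_len(h$bins), each = h$bins),
                   count = as.vector(h$counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
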