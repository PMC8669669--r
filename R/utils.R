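## Internal helpers shared across modules.

cm_error <- function(msg, class) {
  stop(structure(class = c(class, "cammesh_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

cm_input_error <- function(msg) cm_error(msg, "cammesh_input_error")
cm_validation_error <- function(msg) cm_error(msg, "cammesh_validation_error")
cm_registration_error <- function(msg) cm_error(msg, "cammesh_registration_error")
cm_io_error <- function(msg) cm_error(msg, "cammesh_io_error")

## Evaluate expr with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Coefficient of variation; NA when undefined (fewer than 2 values).
cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

## Label connected components (8- or 4-connectivity), returning an integer
## matrix with attribute "n" = number of components.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  .label_cpp(mask_logical(mask), as.integer(connectivity))
}

mask_logical <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  storage.mode(mask) <- "logical"
  mask
}

#' Euler number of a binary image
#'
#' Components minus holes under the package convention: 8-connected
#' foreground, 4-connected background. Holes are background components that
#' do not touch the image border.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer Euler number.
#' @export
euler_number <- function(mask) {
  mask <- mask_logical(mask)
  ncomp <- attr(label_components(mask, 8), "n")
  ncomp - count_holes(mask)
}

## Number of enclosed holes (4-connected background components not touching
## the border).
count_holes <- function(mask) {
  mask <- mask_logical(mask)
  bg <- label_components(!mask, 4)
  nb <- attr(bg, "n")
  if (nb == 0) return(0L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  sum(!(seq_len(nb) %in% border))
}

## Separable convolution with reflective (mirror) boundary handling.
## k is a 1-D kernel applied along rows then columns.
sep_convolve <- function(img, k) {
  conv1 <- function(m, k) {
    # convolve each column of m with k, reflective padding
    r <- (length(k) - 1L) %/% 2L
    n <- nrow(m)
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    idx <- pmin(pmax(idx, 1L), n)  # degenerate small images: clamp reflection
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[seq_len(n) + (i - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img, k)), k))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Local mean over an odd square window, reflective boundaries.
local_mean <- function(img, window) {
  k <- rep(1 / window, window)
  sep_convolve(img, k)
}
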