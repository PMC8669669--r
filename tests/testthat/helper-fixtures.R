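## Shared fixtures and independent oracles.

## Smooth random-texture stack with a scripted integer drift, for
## registration tests: a static world viewed through a moving window.
make_drift_stack <- function(seed, n_frames = 20, size = 64, max_drift = 4,
                             noise_sd = 0, drift = NULL) {
  set.seed(seed)
  m <- max_drift
  world <- cammesh:::sep_convolve(matrix(rnorm((size + 2 * m)^2), size + 2 * m),
                                  cammesh:::gaussian_kernel_1d(2))
  world <- 120 + world * (25 / sd(world))
  if (is.null(drift)) {
    steps <- matrix(sample(c(-1L, 0L, 1L), 2 * n_frames, TRUE), ncol = 2)
    steps[1, ] <- 0L
    drift <- pmin(pmax(apply(steps, 2, cumsum), -m), m)
  }
  storage.mode(drift) <- "integer"
  frames <- array(0, dim = c(size, size, n_frames))
  for (t in seq_len(n_frames)) {
    frames[, , t] <- world[m - drift[t, 1] + seq_len(size),
                           m - drift[t, 2] + seq_len(size)]
    if (noise_sd > 0)
      frames[, , t] <- frames[, , t] + rnorm(size^2, 0, noise_sd)
  }
  list(stack = frame_stack(pmax(frames, 0)), drift = drift)
}

## Independent connected-component labeling by plain BFS flood fill
## (no shared code with the package's Rcpp labeler).
flood_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); nl <- 0L
  offs <- if (connectivity == 8) {
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  } else cbind(c(-1,1,0,0), c(0,0,-1,1))
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nl <- nl + 1L
    queue <- list(c(i, j)); lab[i, j] <- nl
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r < 1 || r > H || c < 1 || c > W) next
        if (mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nl
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  attr(lab, "n") <- nl
  lab
}

## Independent Euler number: 8-connected foreground components minus
## enclosed 4-connected background holes, both via flood_label.
euler_oracle <- function(mask) {
  ncomp <- attr(flood_label(mask, 8), "n")
  bg <- flood_label(!mask, 4)
  nb <- attr(bg, "n")
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- sum(!(seq_len(nb) %in% border[border > 0]))
  ncomp - holes
}

## Random smooth blob mask (possibly with holes).
random_blob_mask <- function(seed, size = 24, p = 0.4) {
  set.seed(seed)
  m <- matrix(runif(size^2) < p, size, size)
  EBImage::dilate(m * 1, EBImage::makeBrush(3, "disc")) > 0
}

## Ring (annulus) mask: one component, one hole.
ring_mask <- function(size = 15, r_in = 2, r_out = 5) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  d >= r_in & d <= r_out
}

## Cached small phase-I render shared by several test files.
.fixture_env <- new.env(parent = emptyenv())
phase1_fixture <- function() {
  if (is.null(.fixture_env$p1)) {
    scene <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 42)
    rv <- render_video(scene, render_params(n_frames = 60, seed = 43))
    .fixture_env$p1 <- list(scene = scene, rv = rv,
                            res = run_pipeline(rv$stack, analysis_config()))
  }
  .fixture_env$p1
}
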