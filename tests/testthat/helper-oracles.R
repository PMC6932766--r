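# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# per-pixel bilinear interpolation with corner-aligned sampling
oracle_bilinear <- function(px, target) {
  H <- nrow(px); W <- ncol(px)
  out <- matrix(NA_real_, target, target)
  for (i in seq_len(target)) {
    for (j in seq_len(target)) {
      r <- if (target == 1) (H - 1) / 2 else (i - 1) * (H - 1) / (target - 1)
      c <- if (target == 1) (W - 1) / 2 else (j - 1) * (W - 1) / (target - 1)
      r0 <- min(floor(r), H - 2); c0 <- min(floor(c), W - 2)
      if (H == 1) r0 <- 0
      if (W == 1) c0 <- 0
      fr <- r - r0; fc <- c - c0
      p <- function(a, b) px[min(a, H - 1) + 1, min(b, W - 1) + 1]
      out[i, j] <- (1 - fr) * (1 - fc) * p(r0, c0) +
        (1 - fr) * fc * p(r0, c0 + 1) +
        fr * (1 - fc) * p(r0 + 1, c0) +
        fr * fc * p(r0 + 1, c0 + 1)
    }
  }
  out
}

# double-loop block means in row-major block order, without normalization
oracle_block_means <- function(px, s) {
  nb <- nrow(px) / s
  out <- numeric(nb * nb)
  k <- 0
  for (bi in seq_len(nb)) {
    for (bj in seq_len(nb)) {
      k <- k + 1
      acc <- 0
      for (i in seq_len(s)) {
        for (j in seq_len(s)) {
          acc <- acc + px[(bi - 1) * s + i, (bj - 1) * s + j]
        }
      }
      out[k] <- acc / (s * s)
    }
  }
  out
}

# exhaustive bounding box of pixels > thr * max
oracle_bbox <- function(px, thr = 0) {
  keep <- which(px > thr * max(px), arr.ind = TRUE)
  list(r = range(keep[, 1]), c = range(keep[, 2]))
}

# total squared-error loss 0.5 * sum (t - o)^2 evaluated via nn_forward,
# used for central-difference gradient checks
oracle_loss <- function(state, x, target, activation = "logistic_sigmoid") {
  o <- nn_forward(state, x, activation)$output
  0.5 * sum((target - o)^2)
}

oracle_numeric_grad <- function(state, x, target, eps = 1e-6,
                                activation = "logistic_sigmoid") {
  gr <- list(W_ih = array(0, dim(state$W_ih)),
             W_ho = array(0, dim(state$W_ho)))
  for (nm in names(gr)) {
    for (i in seq_along(state[[nm]])) {
      sp <- state; sm <- state
      sp[[nm]][i] <- sp[[nm]][i] + eps
      sm[[nm]][i] <- sm[[nm]][i] - eps
      gr[[nm]][i] <- (oracle_loss(sp, x, target, activation) -
                        oracle_loss(sm, x, target, activation)) / (2 * eps)
    }
  }
  gr
}

random_small_image <- function(h, w, maxv = 255) {
  raw_image(matrix(sample(0:maxv, h * w, replace = TRUE), h, w),
            max_intensity = maxv)
}

# run a python snippet; the sandbox image ships numpy/nibabel/tifffile
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}
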