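# shared internal helpers

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# named sub-seeds derived from one root seed; kept well below 2^31
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(phantom = 101L, degrade = 211L, sample = 307L, train = 401L,
               split = 503L, augment = 601L, predict = 701L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(arg, " contains non-finite values", call. = FALSE)
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must share the same shape", call. = FALSE)
  invisible(NULL)
}

# reflective padding (edge duplicated) of a matrix
pad_reflect <- function(m, top, bottom = top, left = top, right = left) {
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(min(top, h))), seq_len(h),
            h + 1 - rev(seq_len(min(bottom, h))))
  ridx <- ridx[c(rep(1, max(0, top - h)), seq_along(ridx),
                 rep(length(ridx), max(0, bottom - h)))]
  cidx <- c(rev(seq_len(min(left, w))), seq_len(w),
            w + 1 - rev(seq_len(min(right, w))))
  m[ridx, cidx, drop = FALSE]
}

# single-pass 3x3 binary median filter (majority of the 9-neighbourhood),
# reflective borders
binary_median3 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- pad_reflect(mask * 1, 1)
  h <- nrow(mask); w <- ncol(mask)
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + m[dr + seq_len(h), dc + seq_len(w)]
  acc >= 5
}

rotate90 <- function(m) {
  # counter-clockwise quarter turn
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_vertical <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
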