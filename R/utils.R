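# Shared helpers. Rounding is half-up everywhere an intensity or coordinate
# is remapped, applied exactly once per stage.

# Half-up rounding; the epsilon absorbs binary representation error of
# decimal scale factors (e.g. 50 * 2.55 = 127.4999...97) so that exact
# halves computed in decimal arithmetic round up as intended.
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_grey_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix (grey image)", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` has zero extent", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` must hold intensities in [0, 255] with no NAs", arg),
         call. = FALSE)
  invisible(img)
}

assert_binary_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric 0/1 matrix (binary image)", arg),
         call. = FALSE)
  if (!all(img == 0 | img == 1))
    stop(sprintf("`%s` must contain only 0 and 1", arg), call. = FALSE)
  invisible(img)
}

# Reflect-101 index folding: mirror about the first/last sample without
# repeating the border sample (period 2(n-1)). Valid for any pad width.
reflect101_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

pad_reflect101 <- function(m, r) {
  ri <- reflect101_index(seq.int(1L - r, nrow(m) + r), nrow(m))
  ci <- reflect101_index(seq.int(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Neighbour value matrix: value of the pixel at offset (dr, dc), zeros
# beyond the border.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Count of 1-valued 8-neighbours at every pixel.
neighbour_counts <- function(bi) {
  acc <- matrix(0, nrow(bi), ncol(bi))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shift_matrix(bi, dr, dc)
  }
  acc
}
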