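# Independent reference implementations used as oracles. These are kept
# deliberately naive (per-pixel loops, direct definitions) and share no code
# with the package internals they check.

# Direct 2D convolution with reflect-101 padding, double loop.
ref_convolve <- function(img, K) {
  r <- (nrow(K) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (a in seq_len(nr)) for (b in seq_len(nc)) {
    s <- 0
    for (i in -r:r) for (j in -r:r) {
      s <- s + K[i + r + 1L, j + r + 1L] *
        img[refl(a + i, nr), refl(b + j, nc)]
    }
    out[a, b] <- s
  }
  out
}

# Integer error-accumulation midpoint line: step the minor axis when the
# accumulated error reaches the half step (ties stepped), mirrored by sign.
ref_bresenham <- function(p, q) {
  dr <- q[1] - p[1]; dc <- q[2] - p[2]
  adr <- abs(dr); adc <- abs(dc)
  sr <- sign(dr); sc <- sign(dc)
  n <- max(adr, adc)
  if (n == 0L) return(matrix(p, 1, 2))
  amaj <- max(adr, adc); amin <- min(adr, adc)
  sr <- as.integer(sr); sc <- as.integer(sc)
  err <- 0L; minor <- 0L
  out <- matrix(NA_integer_, n + 1L, 2L)
  for (k in 0:n) {
    if (adc >= adr) out[k + 1L, ] <- c(p[1] + sr * minor, p[2] + sc * k)
    else out[k + 1L, ] <- c(p[1] + sr * k, p[2] + sc * minor)
    err <- err + amin
    if (2L * err >= amaj) {
      minor <- minor + 1L
      err <- err - amaj
    }
  }
  storage.mode(out) <- "integer"
  out
}

# Stack-based flood fill, 8-connectivity; returns list of pixel matrices.
ref_flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    px <- NULL
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      px <- rbind(px, cur)
      for (di in -1:1) for (dj in -1:1) {
        a <- cur[1] + di; b <- cur[2] + dj
        if (a < 1 || a > nr || b < 1 || b > nc) next
        if (mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
    comps[[length(comps) + 1L]] <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  }
  comps
}

# Hysteresis by iterated dilation from the strong pixels through non-zero
# pixels (pure definition of reachability).
ref_hysteresis <- function(supp, z1, z2) {
  nz <- supp > 0
  reach <- supp > z2
  dil <- function(m) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (di in -1:1) for (dj in -1:1) {
      if (!di && !dj) next
      rs <- max(1, 1 - di):min(nr, nr - di)
      cs <- max(1, 1 - dj):min(nc, nc - dj)
      out[rs, cs] <- out[rs, cs] | m[rs + di, cs + dj]
    }
    out
  }
  repeat {
    nxt <- dil(reach) & nz
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- matrix(0, nrow(supp), ncol(supp))
  out[(supp > z2) | (supp >= z1 & supp <= z2 & reach)] <- 1
  out
}

# Textbook Zhang-Suen with explicit per-pixel loops.
ref_zhang_suen <- function(img) {
  a <- img
  nr <- nrow(a); nc <- ncol(a)
  at <- function(r, c) if (r < 1 || r > nr || c < 1 || c > nc) 0 else a[r, c]
  repeat {
    any_change <- FALSE
    for (step in 0:1) {
      kill <- NULL
      for (c in seq_len(nc)) for (r in seq_len(nr)) {
        if (!a[r, c]) next
        p <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
               at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
        B <- sum(p)
        if (B < 2 || B > 6) next
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        if (A != 1) next
        if (step == 0) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        kill <- rbind(kill, c(r, c))
      }
      if (!is.null(kill)) {
        a[kill] <- 0
        any_change <- TRUE
      }
    }
    if (!any_change) break
  }
  a
}

# Random binary blob: union of a few discs on a small grid.
random_blob <- function(nr = 32, nc = 32, n_discs = 3) {
  out <- matrix(0, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(n_discs)) {
    cy <- stats::runif(1, 5, nr - 4); cx <- stats::runif(1, 5, nc - 4)
    rad <- stats::runif(1, 3, 8)
    out[(rr - cy)^2 + (cc - cx)^2 <= rad^2] <- 1
  }
  out
}

# Column-run boundary table of a silhouette: first/last foreground row per
# column (NA when empty).
column_bounds <- function(sil) {
  apply(sil, 2, function(v) {
    w <- which(v > 0)
    if (!length(w)) c(NA_real_, NA_real_) else c(w[1], w[length(w)])
  })
}

# Synthetic centreline object from a point matrix.
as_centreline <- function(pts) {
  colnames(pts) <- c("row", "col")
  structure(list(points = pts, n = nrow(pts), closed = FALSE),
            class = "tube_centreline")
}

default_run <- local({
  cache <- new.env()
  function(which = "A") {
    key <- paste0("run_", which)
    if (is.null(cache[[key]]))
      cache[[key]] <- run_pipeline(control_image(which), tube_config(),
                                   keep_stages = TRUE)
    cache[[key]]
  }
})
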