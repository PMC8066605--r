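# Centreline extraction: Zhang-Suen thinning, a secondary neighbour-count
# reduction down to a strictly 1-pixel-wide path, ordering of the path into
# an indexed coordinate list, and a concentricity diagnostic.

#' Zhang-Suen thinning
#'
#' Iteratively peels contour pixels off a binary silhouette with the
#' classic two-subiteration scheme until no pixel changes, leaving an
#' (approximately centred) skeleton. The skeleton is a subset of the
#' input's 1-pixels and each input component stays connected.
#'
#' @param silhouette Binary image.
#' @return Binary image of the skeleton.
#' @export
zhang_suen_thin <- function(silhouette) {
  assert_binary_image(silhouette, "silhouette")
  if (!any(silhouette > 0)) return(silhouette)
  out <- cpp_zhang_suen(matrix(as.integer(silhouette > 0), nrow(silhouette)))
  storage.mode(out) <- "double"
  out
}

# TRUE when the 1-valued 8-neighbours of (r, c) form a single 8-connected
# component among themselves (adjacency within the punctured 3x3
# neighbourhood, diagonal contacts included). Deleting the centre of such
# a pixel cannot disconnect its neighbourhood.
punctured_connected <- function(bi, r, c) {
  nr <- nrow(bi); nc <- ncol(bi)
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  rr <- r + off[, 1]; cc <- c + off[, 2]
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  ok[ok] <- bi[cbind(rr[ok], cc[ok])] > 0
  pts <- off[ok, , drop = FALSE]
  m <- nrow(pts)
  if (m <= 1L) return(TRUE)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m - 1L)) for (b in seq.int(a + 1L, m)) {
      if (comp[a] != comp[b] &&
          max(abs(pts[a, ] - pts[b, ])) <= 1L) {
        comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp)) == 1L
}

#' Secondary thinning to a strict 1-pixel-wide path
#'
#' The Zhang-Suen skeleton can keep pixels with three or more neighbours
#' (diagonal-redundant corner pixels and short spurs), which prevents
#' representing the line as a simple indexed list. This pass first deletes,
#' scanning row-major until stable, every pixel with more than two
#' neighbours whose 1-valued neighbours remain a single 8-connected cluster
#' without it (this covers the corner case where a diagonal pixel
#' duplicates its two cardinal neighbours, and its thick-staircase
#' generalisations); if branch junctions remain, the shortest spur branch
#' is pruned and the sweep repeats.
#' The result has at most 2 neighbours at every pixel and preserves the
#' connectivity of the longest path.
#'
#' @param skeleton Binary skeleton image, normally from [zhang_suen_thin()].
#' @return Binary image whose 1-pixels all have `<= 2` 8-neighbours.
#' @export
secondary_thin <- function(skeleton) {
  assert_binary_image(skeleton, "skeleton")
  bi <- skeleton
  local_neighbours <- function(bi, r, c) {
    rr <- max(1, r - 1):min(nrow(bi), r + 1)
    cc <- max(1, c - 1):min(ncol(bi), c + 1)
    nb <- which(bi[rr, cc, drop = FALSE] > 0, arr.ind = TRUE)
    nb <- cbind(rr[nb[, 1]], cc[nb[, 2]])
    nb[!(nb[, 1] == r & nb[, 2] == c), , drop = FALSE]
  }
  redundancy_pass <- function(bi) {
    repeat {
      counts <- neighbour_counts(bi)
      # pixels with >2 neighbours whose deletion keeps the local cluster
      # connected, plus corner pixels of "triangles" (two mutually adjacent
      # neighbours, at least one of them overcrowded): both are redundant
      cand <- which(bi > 0 & counts >= 2, arr.ind = TRUE)
      if (!nrow(cand)) break
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      changed <- FALSE
      for (k in seq_len(nrow(cand))) {
        r <- cand[k, 1]; c <- cand[k, 2]
        if (bi[r, c] == 0) next
        nb <- local_neighbours(bi, r, c)
        ncnt <- nrow(nb)
        del <- FALSE
        if (ncnt > 2) {
          del <- punctured_connected(bi, r, c)
        } else if (ncnt == 2 && max(abs(nb[1, ] - nb[2, ])) <= 1) {
          cnt1 <- nrow(local_neighbours(bi, nb[1, 1], nb[1, 2]))
          cnt2 <- nrow(local_neighbours(bi, nb[2, 1], nb[2, 2]))
          del <- max(cnt1, cnt2) > 2
        }
        if (del) {
          bi[r, c] <- 0
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    bi
  }
  bi <- redundancy_pass(bi)
  guard <- 0L
  repeat {
    counts <- neighbour_counts(bi)
    if (!any(bi > 0 & counts > 2) || guard > 1000L) break
    guard <- guard + 1L
    ends <- which(bi > 0 & counts == 1, arr.ind = TRUE)
    if (nrow(ends)) {
      # walk each spur from its endpoint to the first junction; prune the
      # shortest spur (ties: first endpoint in row-major order)
      best <- NULL
      ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
      for (k in seq_len(nrow(ends))) {
        path <- list(c(ends[k, 1], ends[k, 2]))
        prev <- c(NA_integer_, NA_integer_)
        repeat {
          cur <- path[[length(path)]]
          rr <- max(1, cur[1] - 1):min(nrow(bi), cur[1] + 1)
          cc <- max(1, cur[2] - 1):min(ncol(bi), cur[2] + 1)
          nb <- which(bi[rr, cc, drop = FALSE] > 0, arr.ind = TRUE)
          nb <- cbind(rr[nb[, 1]], cc[nb[, 2]])
          nb <- nb[!(nb[, 1] == cur[1] & nb[, 2] == cur[2]), , drop = FALSE]
          if (!is.na(prev[1]))
            nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
          if (nrow(nb) != 1L) break           # junction (or dead end) reached
          if (counts[nb[1, 1], nb[1, 2]] > 2) break
          prev <- cur
          path[[length(path) + 1L]] <- c(nb[1, 1], nb[1, 2])
        }
        if (is.null(best) || length(path) < length(best)) best <- path
      }
      for (p in best) bi[p[1], p[2]] <- 0
    } else {
      # no endpoints (looped junction): delete the first removable junction
      jn <- which(bi > 0 & counts > 2, arr.ind = TRUE)
      jn <- jn[order(jn[, 1], jn[, 2]), , drop = FALSE]
      bi[jn[1, 1], jn[1, 2]] <- 0
    }
    bi <- redundancy_pass(bi)
  }
  bi
}

#' Order a 1-pixel-wide skeleton into an indexed centreline
#'
#' Walks the skeleton from one endpoint (a pixel with exactly one
#' neighbour) to the other, assigning consecutive indices; the endpoint
#' with the smaller row-major coordinate becomes index 1. Closed loops
#' start at their smallest row-major pixel and walk toward the smaller of
#' its two neighbours. If several components survive thinning, only the
#' largest is kept (the rest are reported via a message).
#'
#' @param skeleton Binary image whose pixels all have `<= 2` neighbours
#'   (see [secondary_thin()]).
#' @return Object of class `tube_centreline`: list with `points` (n x 2
#'   matrix of `(row, col)` in walk order), `n`, and `closed`.
#' @export
order_centreline <- function(skeleton) {
  assert_binary_image(skeleton, "skeleton")
  if (!any(skeleton > 0)) stop("empty skeleton", call. = FALSE)
  lab <- cpp_label_components(skeleton > 0)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) > 1L) {
    message(length(sizes) - 1L,
            " minor skeleton component(s) dropped; keeping the largest")
  }
  main <- which.max(sizes)
  bi <- matrix(0, nrow(skeleton), ncol(skeleton))
  bi[lab == main] <- 1
  counts <- neighbour_counts(bi)
  bad <- which(bi > 0 & counts > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("branch pixel with >2 neighbours at (%d, %d); run secondary_thin() first",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  px <- which(bi > 0, arr.ind = TRUE)
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  n <- nrow(px)
  if (n == 1L) {
    return(structure(list(points = matrix(c(px[1, 1], px[1, 2]), 1, 2,
                                          dimnames = list(NULL, c("row", "col"))),
                          n = 1L, closed = FALSE),
                     class = "tube_centreline"))
  }
  ends <- which(bi > 0 & counts == 1, arr.ind = TRUE)
  closed <- nrow(ends) == 0L
  if (!closed) {
    ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
    start <- c(ends[1, 1], ends[1, 2])
  } else {
    start <- c(px[1, 1], px[1, 2])
  }
  pts <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("row", "col")))
  pts[1, ] <- start
  visited <- matrix(FALSE, nrow(bi), ncol(bi))
  visited[start[1], start[2]] <- TRUE
  cur <- start
  for (i in seq_len(n - 1L)) {
    rr <- max(1, cur[1] - 1):min(nrow(bi), cur[1] + 1)
    cc <- max(1, cur[2] - 1):min(ncol(bi), cur[2] + 1)
    nb <- which(bi[rr, cc, drop = FALSE] > 0 & !visited[rr, cc, drop = FALSE],
                arr.ind = TRUE)
    if (!nrow(nb)) break
    nb <- cbind(rr[nb[, 1]], cc[nb[, 2]])
    nb <- nb[order(nb[, 1], nb[, 2]), , drop = FALSE]
    cur <- c(nb[1, 1], nb[1, 2])
    pts[i + 1L, ] <- cur
    visited[cur[1], cur[2]] <- TRUE
  }
  if (anyNA(pts)) pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
  structure(list(points = pts, n = nrow(pts), closed = closed),
            class = "tube_centreline")
}

#' @export
print.tube_centreline <- function(x, ...) {
  cat(sprintf("<tube_centreline> %d points%s, from (%d, %d) to (%d, %d)\n",
              x$n, if (x$closed) " (closed loop)" else "",
              x$points[1, 1], x$points[1, 2],
              x$points[x$n, 1], x$points[x$n, 2]))
  invisible(x)
}

#' Concentricity diagnostic of a centreline inside its silhouette
#'
#' For each centreline index, casts the two opposite normal rays (as the
#' width measurement does) and reports half the difference of their
#' lengths: 0 means the point is equidistant from the two walls, a positive
#' value means the line sits closer to the wall hit by the second
#' (negative-direction) ray. Indices whose rays cannot be computed are
#' `NA`. Diagnostic only; it does not feed back into the pipeline.
#'
#' @param line A `tube_centreline`.
#' @param silhouette The filled binary silhouette the line was thinned from.
#' @param offset Finite-difference half-distance for the local slope
#'   (default 4, as in the width measurement).
#' @return Numeric vector of signed deviations (pixels), one per index.
#' @export
concentricity_check <- function(line, silhouette, offset = 4L) {
  stopifnot(inherits(line, "tube_centreline"))
  assert_binary_image(silhouette, "silhouette")
  n <- line$n
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    o <- min(offset, i - 1L, n - i)
    if (o < 1L) next
    dev <- tryCatch({
      s <- local_gradient(line, i, o)
      org <- line$points[i, ]
      e1 <- cast_normal_ray(silhouette, org, s, 1L)
      e2 <- cast_normal_ray(silhouette, org, s, -1L)
      (sqrt(sum((e1 - org)^2)) - sqrt(sum((e2 - org)^2))) / 2
    }, error = function(e) NA_real_)
    out[i] <- dev
  }
  out
}
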