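# Silhouette filling: turn the two-edge binary map into the solid binary
# "shadow" of the tube by scan-line filling with continuity checks and
# Bresenham interpolation across missing-edge gaps.

#' Integer Bresenham rasterisation of a segment
#'
#' Returns the 8-connected chain of pixels from `p` to `q` inclusive, each
#' endpoint exactly once. Along the driving axis (the one with the larger
#' absolute delta) every coordinate appears exactly once, so the chain has
#' `max(|drow|, |dcol|) + 1` pixels. Ties of the minor coordinate are
#' rounded half-up in the driving frame (away from `p`'s minor coordinate
#' when stepping forward).
#'
#' @param p,q Length-2 integer `(row, col)` coordinates.
#' @return An `n x 2` integer matrix of `(row, col)` pixels, `p` first.
#' @export
bresenham_line <- function(p, q) {
  p <- as.integer(p); q <- as.integer(q)
  dr <- q[1] - p[1]; dc <- q[2] - p[2]
  adr <- abs(dr); adc <- abs(dc)
  sr <- sign(dr); sc <- sign(dc)
  if (adr == 0L && adc == 0L)
    return(matrix(p, 1L, 2L, dimnames = list(NULL, c("row", "col"))))
  if (adc >= adr) {
    k <- 0:adc
    col <- p[2] + sc * k
    row <- p[1] + sr * ((2L * k * adr + adc) %/% (2L * adc))
  } else {
    k <- 0:adr
    row <- p[1] + sr * k
    col <- p[2] + sc * ((2L * k * adc + adr) %/% (2L * adr))
  }
  cbind(row = as.integer(row), col = as.integer(col))
}

# Interpolate the NA stretches of an edge trace (one y value per scan line)
# with one Bresenham segment per gap between the flanking detections.
# Leading/trailing NAs (no flanking detection on one side) are left NA.
interp_trace <- function(v) {
  known <- which(!is.na(v))
  if (length(known) < 2L) return(v)
  gaps <- which(diff(known) > 1L)
  for (g in gaps) {
    j0 <- known[g]; j1 <- known[g + 1L]
    pts <- bresenham_line(c(v[j0], j0), c(v[j1], j1))
    for (j in seq.int(j0 + 1L, j1 - 1L)) {
      ys <- pts[pts[, 2] == j, 1]
      if (length(ys)) v[j] <- ys[1]
    }
  }
  v
}

# Resolve the leading/trailing NA stretches of an edge trace after
# interior gaps have been interpolated. Within the span of scan lines
# where the tube was seen at all, a missing leading/trailing edge means
# either (a) the edge has left the image scope -- its nearest detection
# sits against the border, and the border index stands in for it -- or
# (b) a plain detection gap, in which case the nearest known value is
# carried across. `border` is 1 for the top trace, nrow for the bottom.
resolve_trace_ends <- function(v, span, border) {
  known <- which(!is.na(v))
  if (!length(known)) return(v)
  k0 <- known[1]; k1 <- known[length(known)]
  near_border <- function(y) abs(y - border) <= 3
  if (k0 > span[1]) {
    fillv <- if (near_border(v[k0])) border else v[k0]
    v[span[1]:(k0 - 1L)] <- fillv
  }
  if (k1 < span[2]) {
    fillv <- if (near_border(v[k1])) border else v[k1]
    v[(k1 + 1L):span[2]] <- fillv
  }
  v
}

# One directional pass of the scan-line fill. Per scan line, detections are
# clustered (clusters separated by gaps > 3 px); two or more clusters mean
# both edges are present (y1 = first, y2 = last); a single cluster is
# assigned to the top or bottom edge trace by continuity with the previous
# scan lines, leaving the other edge missing. Missing edges are then
# recovered by Bresenham interpolation across interior gaps and by the
# border/carry rule at the ends, and each scan line is filled y1..y2.
scan_fill_pass <- function(bi) {
  nr <- nrow(bi); nc <- ncol(bi)
  top <- bot <- rep(NA_real_, nc)
  lo <- hi <- cen1 <- cenK <- rep(NA_real_, nc)
  nclust <- integer(nc)
  sep <- rep(0, nc)
  for (j in seq_len(nc)) {
    ys <- which(bi[, j] > 0)
    if (!length(ys)) next
    lo[j] <- ys[1L]; hi[j] <- ys[length(ys)]
    br <- which(diff(ys) > 3)
    nclust[j] <- length(br) + 1L
    if (length(br)) {
      cen1[j] <- mean(ys[seq_len(br[1])])
      cenK[j] <- mean(ys[seq.int(br[length(br)] + 1L, length(ys))])
      sep[j] <- ys[br[length(br)] + 1L] - ys[br[1]]
    } else {
      cen1[j] <- cenK[j] <- mean(ys)
    }
  }
  # A scan line with two well-separated detection clusters carries both
  # edges; a single cluster (or clusters fragmented by a short detection
  # gap) carries one edge, identified by continuity with the neighbouring
  # scan lines. A trace that has not been updated for several scan lines
  # (its edge left the image scope, or a long detection gap) is "stale":
  # an actively tracked trace claims a nearby cluster in preference to a
  # stale one, so that an edge sweeping past the other edge's old position
  # is not mis-assigned. The sweep starts from an unambiguous two-edge
  # anchor line and proceeds outward in both directions.
  claim_tol <- 12   # max plausible per-scan-line drift of an edge crossing
  anchor <- which(nclust >= 2L & sep > 10)[1]
  dirs <- if (is.na(anchor)) list(seq_len(nc)) else
    list(seq.int(anchor, nc), rev(seq_len(anchor)))
  for (ord in dirs) {
    prev_t <- prev_b <- NA_real_
    age_t <- age_b <- Inf
    decide <- function(cen) {
      dt <- abs(cen - prev_t); db <- abs(cen - prev_b)
      if (age_b <= 2 && age_t > 5 && db <= claim_tol * age_b) return("bot")
      if (age_t <= 2 && age_b > 5 && dt <= claim_tol * age_t) return("top")
      if (dt <= db) "top" else "bot"
    }
    for (j in ord) {
      age_t <- age_t + 1; age_b <- age_b + 1
      if (is.na(lo[j])) next
      if (is.na(prev_t)) {
        top[j] <- lo[j]; bot[j] <- hi[j]
      } else if (nclust[j] == 1L) {
        if (decide(cen1[j]) == "top") top[j] <- lo[j] else bot[j] <- hi[j]
      } else {
        a1 <- decide(cen1[j]); aK <- decide(cenK[j])
        if (a1 == "top" && aK == "bot") {
          top[j] <- lo[j]; bot[j] <- hi[j]
        } else if (a1 == "top" && aK == "top") {
          top[j] <- lo[j]
        } else if (a1 == "bot" && aK == "bot") {
          bot[j] <- hi[j]
        } else {
          top[j] <- lo[j]; bot[j] <- hi[j]
        }
      }
      if (!is.na(top[j])) { prev_t <- top[j]; age_t <- 0 }
      if (!is.na(bot[j])) { prev_b <- bot[j]; age_b <- 0 }
    }
  }
  seen <- which(!is.na(top) | !is.na(bot))
  out <- matrix(0, nr, nc)
  if (!length(seen)) return(out)
  span <- c(seen[1], seen[length(seen)])
  top <- resolve_trace_ends(interp_trace(top), span, 1L)
  bot <- resolve_trace_ends(interp_trace(bot), span, nr)
  for (j in span[1]:span[2]) {
    y1 <- top[j]; y2 <- bot[j]
    if (is.na(y1) && is.na(y2)) next
    if (is.na(y1)) y1 <- y2
    if (is.na(y2)) y2 <- y1
    out[max(1, min(y1, y2)):min(nr, max(y1, y2)), j] <- 1
  }
  out
}

#' Fill the two-edge map into a solid tube silhouette
#'
#' Runs the scan-line fill once over columns and once over rows, and
#' combines the two passes. Each pass fills, per scan line, the interval
#' between the first and last detected edge pixel; a scan line where one
#' edge is undetected keeps the detected edge and recovers the other by the
#' continuity rule (the new edge index must lie within one pixel of the
#' previous scan line's) or, across longer runs, by a Bresenham segment
#' between the flanking detections.
#'
#' A single pass overshoots on oblique or curved tubes (it fills the
#' scan-line convex hull); the default combination is therefore the
#' intersection of the two passes. `combine = "union"` is available for
#' replication experiments.
#'
#' @param edges Binary image holding the tube's two bounding edges
#'   (normally the output of [keep_longest_two()]).
#' @param combine `"intersection"` (default) or `"union"` of the column and
#'   row passes.
#' @return Binary image of the filled silhouette.
#' @export
fill_silhouette <- function(edges, combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  assert_binary_image(edges, "edges")
  if (!any(edges > 0))
    stop("empty edge image: nothing to fill", call. = FALSE)
  cols <- scan_fill_pass(edges)
  rows <- t(scan_fill_pass(t(edges)))
  if (combine == "intersection") cols * rows else pmax(cols, rows)
}
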