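#' Circumcentre of three annotated points
#'
#' Centre of the circle through three planar points, via
#' x = B/(2A), y = -C/(2A) with
#' A = x1(y2 - y3) + x2(y3 - y1) + x3(y1 - y2),
#' B = (x1^2 + y1^2)(y2 - y3) + (x2^2 + y2^2)(y3 - y1) + (x3^2 + y3^2)(y1 - y2),
#' C = (x1^2 + y1^2)(x2 - x3) + (x2^2 + y2^2)(x3 - x1) + (x3^2 + y3^2)(x1 - x2).
#'
#' @param p1,p2,p3 numeric length-2 coordinates
#' @return numeric c(x, y) of the centre
#' @export
circumcentre <- function(p1, p2, p3) {
  x1 <- p1[1]; y1 <- p1[2]; x2 <- p2[1]; y2 <- p2[2]; x3 <- p3[1]; y3 <- p3[2]
  A <- x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2)
  scale <- max(abs(c(x1, y1, x2, y2, x3, y3, 1)))
  if (abs(A) < 1e-12 * scale^2)
    stop("degenerate input: the three points are collinear", call. = FALSE)
  s1 <- x1^2 + y1^2; s2 <- x2^2 + y2^2; s3 <- x3^2 + y3^2
  B <- s1 * (y2 - y3) + s2 * (y3 - y1) + s3 * (y1 - y2)
  C <- s1 * (x2 - x3) + s2 * (x3 - x1) + s3 * (x1 - x2)
  c(x = B / (2 * A), y = -C / (2 * A))
}

#' Tissue opening angle from a three-point annotation
#'
#' For two boundary points and one middle (apex) point on the midplane of
#' a spherical-cap tissue region,
#' theta = pi - arccos(<p1 - c, p2 - c> / (|p1 - c| |p2 - c|)),
#' where c is the circumcentre, p1 a boundary point and p2 the middle
#' point. Exact for noise-free points on a circular arc; invariant under
#' rigid motions and uniform scaling.
#'
#' @param p1 a boundary point (crypt/villus interface)
#' @param p2 the middle point of the region
#' @param p3 the other boundary point
#' @return opening angle in radians, in [0, pi]
#' @export
opening_angle <- function(p1, p2, p3) {
  ctr <- circumcentre(p1, p2, p3)
  u <- c(p1[1] - ctr[1], p1[2] - ctr[2])
  w <- c(p2[1] - ctr[1], p2[2] - ctr[2])
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  pi - acos(pmin(1, pmax(-1, cosang)))
}

#' Degree of crypt opening
#'
#' theta_c / (pi - theta_v): 0 for a budded (fully closed) crypt, 1 for a
#' spherical organoid. Ratios slightly above 1 (annotation noise near the
#' spherical limit) are clipped with a warning; larger inconsistencies
#' warn and return NA.
#'
#' @param theta_c crypt opening angle in [0, pi]
#' @param theta_v villus opening angle in [0, pi)
#' @param tol clipping tolerance for slightly inconsistent annotations
#' @return ratio in [0, 1]
#' @export
degree_of_opening <- function(theta_c, theta_v, tol = 0.02) {
  stopifnot(all(theta_c >= 0 & theta_c <= pi), all(theta_v >= 0 &
                                                     theta_v < pi))
  r <- theta_c / (pi - theta_v)
  high <- r > 1
  if (any(high)) {
    fixable <- r <= 1 + tol
    if (any(high & fixable)) {
      warning(sprintf("%d opening ratio(s) slightly above 1 clipped",
                      sum(high & fixable)))
      r[high & fixable] <- 1
    }
    if (any(high & !fixable)) {
      warning(sprintf("%d inconsistent annotation(s): ratio > 1 + tol",
                      sum(high & !fixable)))
      r[high & !fixable] <- NA_real_
    }
  }
  r
}

#' Tension asymmetry from an apical-to-basal intensity ratio
#'
#' Myosin intensity ratios proxy tension ratios, so
#' epsilon = (r - 1)/(r + 1) estimates
#' (Gamma_a - Gamma_b)/(Gamma_a + Gamma_b). Monotone in r, with range
#' (-1, 1).
#'
#' @param r apical-to-basal intensity ratio (> 0), vectorized
#' @return epsilon
#' @export
asymmetry_from_intensity <- function(r) {
  if (any(r <= 0)) stop("intensity ratio must be positive", call. = FALSE)
  (r - 1) / (r + 1)
}

#' Normalized lumen state from pre/post-ablation volumes
#'
#' The mechanical state of the lumen is inferred from its volume before
#' and after epithelial breakage: v_hat = v_pre / v_post. Values above 1
#' indicate a swollen lumen, below 1 a shrunk one. With vectors, summary
#' statistics across samples are attached.
#'
#' @param v_pre lumen volume(s) before breakage (> 0)
#' @param v_post lumen volume(s) after breakage (> 0)
#' @return data.frame with v_pre, v_post, v_hat; attributes `mean` and `sd`
#' @export
infer_v <- function(v_pre, v_post) {
  if (any(v_pre <= 0) || any(v_post <= 0))
    stop("volumes must be positive", call. = FALSE)
  stopifnot(length(v_pre) == length(v_post))
  out <- data.frame(v_pre = v_pre, v_post = v_post,
                    v_hat = v_pre / v_post)
  attr(out, "mean") <- mean(out$v_hat)
  attr(out, "sd") <- stats::sd(out$v_hat)
  out
}

#' Read a three-point annotation table
#'
#' CSV schema: columns `sample_id`, `region` (crypt/villus), `role`
#' (boundary1/middle/boundary2), `x`, `y` — one row per point.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_point_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "role", "x", "y")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Opening angles and degree of opening per sample
#'
#' Applies [opening_angle()] to each (sample, region) triplet and combines
#' crypt and villus angles into the degree of crypt opening.
#'
#' @param annotations data.frame in the [read_point_annotations()] schema
#' @return data.frame: sample_id, theta_c, theta_v, opening
#' @export
angles_from_annotations <- function(annotations) {
  ang_one <- function(df) {
    g <- function(role) {
      r <- df[df$role == role, c("x", "y")]
      if (nrow(r) != 1) stop("each (sample, region) needs exactly one '",
                             role, "' point", call. = FALSE)
      as.numeric(r)
    }
    opening_angle(g("boundary1"), g("middle"), g("boundary2"))
  }
  out <- NULL
  for (sid in unique(annotations$sample_id)) {
    sub <- annotations[annotations$sample_id == sid, ]
    th_c <- ang_one(sub[sub$region == "crypt", ])
    th_v <- ang_one(sub[sub$region == "villus", ])
    out <- rbind(out, data.frame(sample_id = sid, theta_c = th_c,
                                 theta_v = th_v,
                                 opening = degree_of_opening(th_c, th_v)))
  }
  out
}
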