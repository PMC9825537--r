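# Small shared primitives: union-find single linkage, Kabsch superposition,
# rotation decomposition.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-linkage grouping from a pairwise relation
#'
#' Union-find closure over an n x n logical matrix (or a 2-column index matrix
#' of linked pairs). Returns an integer membership vector with deterministic
#' labels: components are numbered by their smallest member index.
#'
#' @param n number of items.
#' @param pairs 2-column integer matrix of linked item pairs (may have 0 rows).
#' @return integer vector of length n; `membership[i] == membership[j]` iff i
#'   and j are in one single-linkage component.
#' @keywords internal
single_linkage <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # relabel roots 1..k in order of first appearance (= smallest member index)
  match(roots, sort(unique(roots)))
}

#' Optimal rotation superposing one point set onto another (Kabsch)
#'
#' Least-squares rotation (proper, det = +1) and translation mapping `from`
#' onto `to`. With `center = FALSE` the translation is fixed at zero and only
#' the orthogonal-Procrustes rotation about the origin is fitted, which is the
#' form needed when testing point-group operations about a common origin.
#'
#' @param from,to n x 3 coordinate matrices, matched row for row.
#' @param center fit the translation (default) or force it to zero.
#' @return list with `rot` (3 x 3), `trans` (length-3), `rmsd`.
#' @keywords internal
kabsch <- function(from, to, center = TRUE) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3L, ncol(to) == 3L)
  if (center) {
    cf <- colMeans(from); ct <- colMeans(to)
    A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  } else {
    A <- from; B <- to
  }
  s <- svd(crossprod(A, B))            # A^T B = U D V^T ; R = V S U^T
  d <- sign(det(s$v %*% t(s$u)))
  S <- diag(c(1, 1, d))
  rot <- s$v %*% S %*% t(s$u)
  trans <- if (center) as.numeric(ct - rot %*% cf) else c(0, 0, 0)
  fitted <- sweep(from %*% t(rot), 2, trans, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - to)^2)))
  list(rot = rot, trans = trans, rmsd = rmsd)
}

# Angle (degrees, in [0, 180]) and unit axis of a proper rotation matrix.
# For the identity the axis is undefined; c(0,0,1) is returned by convention.
rotation_angle_axis <- function(rot) {
  tr <- sum(diag(rot))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  if (ang < 1e-6) return(list(angle = 0, axis = c(0, 0, 1)))
  if (ang > 175) {
    # near-180 rotation: the skew part vanishes, take the +1 eigenvector
    ev <- eigen(rot, symmetric = FALSE)
    k <- which.min(abs(Re(ev$values) - 1))
    ax <- Re(ev$vectors[, k])
  } else {
    ax <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1], rot[2, 1] - rot[1, 2])
  }
  list(angle = ang, axis = ax / sqrt(sum(ax^2)))
}

# Acute angle (degrees) between two axes, ignoring direction.
axis_angle_deg <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, cosang)) * 180 / pi
}

# Rotation matrices about coordinate axes (degrees).
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}

# Random proper rotation (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

is_orthonormal <- function(rot, tol = 1e-6) {
  is.matrix(rot) && all(dim(rot) == c(3L, 3L)) &&
    max(abs(crossprod(rot) - diag(3))) <= tol && abs(det(rot) - 1) <= 1e-4
}

# stop() with a classed condition so callers can test error categories.
qc_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "quatclust_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
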