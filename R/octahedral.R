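# Tolerances used throughout the combinatorial/geometric symmetry code.
.MAT_TOL <- 1e-9   # elementwise, rotation matrices
.VEC_TOL <- 1e-6   # unit vectors / axis identification

#' Rotation about an arbitrary axis
#'
#' @param axis numeric length-3; need not be normalised.
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c_ * diag(3) + s_ * ux + (1 - c_) * (u %o% u)
}

.canonical_axis <- function(v) {
  # unit axis with a sign convention: first component of largest magnitude
  # (ties broken by position) is made positive, so +v and -v collapse.
  v <- v / sqrt(sum(v^2))
  i <- which.max(abs(v) - 1e-12 * seq_along(v))
  if (v[i] < 0) v <- -v
  v
}

.rot_axis <- function(m) {
  # axis = eigenvector of eigenvalue +1 (real rotation matrix)
  e <- eigen(m)
  i <- which.min(abs(e$values - 1))
  .canonical_axis(Re(e$vectors[, i]))
}

.classify_rotation <- function(m) {
  tr <- sum(diag(m))
  if (abs(tr - 3) < 1e-6) {
    return(list(order = 1L, axis = c(0, 0, 0), axis_class = "identity"))
  }
  axis <- .rot_axis(m)
  if (abs(tr - 1) < 1e-6) {                      # +/- 90 degrees
    list(order = 4L, axis = axis, axis_class = "fourfold_axis")
  } else if (abs(tr) < 1e-6) {                   # +/- 120 degrees
    list(order = 3L, axis = axis, axis_class = "threefold_axis")
  } else if (abs(tr + 1) < 1e-6) {               # 180 degrees
    # face-type twofold = axis along a fourfold (coordinate-type) direction;
    # edge-type twofold = axis along a (1,1,0)-type direction.
    srt <- sort(abs(axis), decreasing = TRUE)
    if (srt[2] < .VEC_TOL) {
      list(order = 2L, axis = axis, axis_class = "twofold_face")
    } else {
      list(order = 2L, axis = axis, axis_class = "twofold_edge")
    }
  } else {
    stop("matrix is not an octahedral rotation (trace = ", tr, ")")
  }
}

new_rotation_operator <- function(matrix) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  if (max(abs(matrix %*% t(matrix) - diag(3))) > 1e-7)
    stop("matrix is not orthonormal")
  if (abs(det(matrix) - 1) > 1e-7)
    stop("matrix is not a proper rotation (det != +1)")
  cls <- .classify_rotation(matrix)
  structure(list(matrix = matrix, order = cls$order, axis = cls$axis,
                 axis_class = cls$axis_class),
            class = "RotationOperator")
}

#' @export
print.RotationOperator <- function(x, ...) {
  cat("<RotationOperator>", x$axis_class, "order", x$order, "\n")
  invisible(x)
}

#' The chiral octahedral rotation group (432)
#'
#' Generates the 24 proper rotations of octahedral symmetry by closure from a
#' 90-degree rotation about z and a 120-degree rotation about (1,1,1). Each
#' operator is classified by order and axis class: the identity, six
#' four-fold (+/-90 degree) rotations, three face-type two-folds (180 degrees
#' about a four-fold axis), eight three-folds, and six edge-type two-folds.
#'
#' @return a list of 24 `RotationOperator` objects, the identity first.
#' @examples
#' rots <- build_octahedral_rotations()
#' table(vapply(rots, `[[`, "", "axis_class"))
.rot_group_cache <- new.env(parent = emptyenv())

#' @export
build_octahedral_rotations <- function() {
  if (!is.null(.rot_group_cache$group)) return(.rot_group_cache$group)
  gen <- list(rotation_about(c(0, 0, 1), pi / 2),
              rotation_about(c(1, 1, 1), 2 * pi / 3))
  mats <- list(diag(3))
  key <- function(m) {
    x <- round(m, 6)
    x[x == 0] <- 0  # collapse -0
    paste(sprintf("%.6f", x), collapse = ",")
  }
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- mats
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in gen) {
      p <- g %*% m
      k <- key(p)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        mats <- c(mats, list(p))
        queue <- c(queue, list(p))
      }
    }
  }
  if (length(mats) != 24)
    stop("closure produced ", length(mats), " rotations, expected 24")
  .rot_group_cache$group <- lapply(mats, new_rotation_operator)
  .rot_group_cache$group
}

#' Index of the rotation closest to a given matrix
#' @keywords internal
match_rotation <- function(m, rotations, tol = .MAT_TOL) {
  devs <- vapply(rotations, function(r) max(abs(r$matrix - m)), 0)
  i <- which.min(devs)
  if (devs[i] > max(tol, 1e-7)) return(NA_integer_)
  i
}

#' Verify closure of a rotation set
#' @keywords internal
rotations_closed <- function(rotations, tol = 1e-7) {
  for (a in rotations) for (b in rotations) {
    if (is.na(match_rotation(a$matrix %*% b$matrix, rotations, tol)))
      return(FALSE)
  }
  TRUE
}
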