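# Recovering the cage's dimer pairing, octahedral frame and point group from
# coordinates, and mapping chains onto the abstract cage graph.

#' Detect antiparallel dimers by interface contacts
#'
#' Builds a chain-pair graph weighted by the number of heavy-atom contacts
#' (atom pairs within `contact_cutoff`), drops edges below `min_contacts`,
#' and extracts the maximum-weight perfect matching (exact branch-and-bound;
#' the contact graph of a closed cage is sparse). Each pair is annotated with
#' its contact count, the cosine between the two oriented principal axes
#' (antiparallel packing gives values near -1) and, when subunit types are
#' assigned, a homotypic flag.
#'
#' @param assembly an `Assembly`.
#' @param contact_cutoff heavy-atom contact distance, Angstrom.
#' @param min_contacts minimum contacts for an admissible dimer edge.
#' @param override allow non-24-chain assemblies.
#' @return a `DimerPairing`: data frame with columns `chain_1`, `chain_2`,
#'   `contacts`, `antiparallel_cos`, `homotypic`.
#' @export
detect_dimers <- function(assembly, contact_cutoff = 5.0, min_contacts = 50,
                          override = FALSE) {
  .assert_cage(assembly, override)
  ids <- names(assembly$chains)
  n <- length(ids)
  if (n %% 2 == 1) stop("odd chain count cannot form a dimer pairing")
  xyz <- lapply(assembly$chains, .chain_xyz)
  cen <- t(vapply(xyz, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(i)
    sqrt(max(rowSums((xyz[[i]] - rep(cen[i, ], each = nrow(xyz[[i]])))^2))),
    0)
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((cen[i, ] - cen[j, ])^2)) >
        rad[i] + rad[j] + contact_cutoff) next
    d2 <- outer(rowSums(xyz[[i]]^2), rowSums(xyz[[j]]^2), "+") -
      2 * xyz[[i]] %*% t(xyz[[j]])
    W[i, j] <- W[j, i] <- sum(d2 < contact_cutoff^2)
  }
  A <- W >= min_contacts
  match_idx <- .max_weight_perfect_matching(W, A)
  if (is.null(match_idx))
    stop("not a closed cage: no perfect dimer matching with >= ",
         min_contacts, " contacts per pair")

  axes <- t(vapply(assembly$chains, .oriented_principal_axis, numeric(3)))
  types <- .chain_types(assembly)
  pairs <- which(match_idx > seq_len(n))
  out <- data.frame(
    chain_1 = ids[pairs],
    chain_2 = ids[match_idx[pairs]],
    contacts = W[cbind(pairs, match_idx[pairs])],
    antiparallel_cos = vapply(pairs, function(i)
      sum(axes[i, ] * axes[match_idx[i], ]), 0),
    homotypic = if (all(types %in% c("A", "B")))
      types[pairs] == types[match_idx[pairs]] else NA)
  rownames(out) <- NULL
  class(out) <- c("DimerPairing", "data.frame")
  out
}

.oriented_principal_axis <- function(chain) {
  a <- chain$atoms
  ca <- a[a$atom == "CA", , drop = FALSE]
  if (nrow(ca) < 3) ca <- a
  m <- as.matrix(ca[, c("x", "y", "z")])
  v <- eigen(stats::cov(m), symmetric = TRUE)$vectors[, 1]
  # orient N-terminal -> C-terminal so antiparallel packing shows as cos ~ -1
  nc <- as.numeric(m[nrow(m), ] - m[1, ])
  if (sum(v * nc) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# exact maximum-weight perfect matching on a small sparse graph
.max_weight_perfect_matching <- function(W, A) {
  n <- nrow(W)
  best <- list(weight = -Inf, match = NULL)
  nb <- lapply(seq_len(n), function(i) which(A[i, ]))
  rec <- function(match, weight) {
    free <- which(match == 0L)
    if (!length(free)) {
      if (weight > best$weight) best <<- list(weight = weight, match = match)
      return()
    }
    # optimistic bound: every free vertex matched at its best edge
    ub <- weight + sum(vapply(free, function(v) {
      cand <- nb[[v]][match[nb[[v]]] == 0L]
      if (length(cand)) max(W[v, cand]) else -Inf
    }, 0)) / 2
    if (!is.finite(ub) || ub <= best$weight) return()
    v <- free[1]
    cand <- nb[[v]][match[nb[[v]]] == 0L]
    if (!length(cand)) return()
    for (u in cand[order(-W[v, cand])]) {
      match[c(v, u)] <- c(u, v)
      rec(match, weight + W[v, u])
      match[c(v, u)] <- 0L
    }
  }
  rec(integer(n), 0)
  if (is.null(best$match)) NULL else best$match
}

#' Fit the octahedral symmetry frame of a cage
#'
#' Estimates the cage centre and the three mutually orthogonal four-fold
#' axes from the geometry of the 12 dimer axes (sums of perpendicular
#' dimer-direction pairs), refines the frame by minimising the RMS
#' self-coincidence of the 24 chain centroids under the 432 group action,
#' and derives the three-fold and edge-type two-fold axes from the fitted
#' four-folds.
#'
#' @param assembly an `Assembly` (24 chains).
#' @param pairing optional precomputed [detect_dimers()] result.
#' @param max_residual residual (Angstrom) above which the assembly is
#'   rejected as non-octahedral.
#' @return an `OctahedralFrame`: list with `center`, `rotation` (3x3, maps
#'   canonical frame axes onto fitted axes), `fourfold_axes` (3x3 rows),
#'   `threefold_axes` (4x3), `twofold_edge_axes` (6x3), `fit_residual`.
#' @export
fit_octahedral_frame <- function(assembly, pairing = NULL,
                                 max_residual = 3.0) {
  .assert_cage(assembly)
  if (is.null(pairing)) pairing <- detect_dimers(assembly)
  cen <- chain_centroids(assembly)
  center <- colMeans(cen)
  X <- sweep(cen, 2, center)

  i1 <- match(pairing$chain_1, names(assembly$chains))
  i2 <- match(pairing$chain_2, names(assembly$chains))
  M <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / 2
  M <- M / sqrt(rowSums(M^2))

  # perpendicular dimer-axis pairs bisect to four-fold axes
  cand <- list()
  for (i in seq_len(nrow(M) - 1)) for (j in (i + 1):nrow(M)) {
    if (abs(sum(M[i, ] * M[j, ])) > 0.3) next
    cand <- c(cand, list(.canonical_axis(M[i, ] + M[j, ])),
              list(.canonical_axis(M[i, ] - M[j, ])))
  }
  if (length(cand) < 3) stop("assembly not octahedral: too few axis candidates")
  C <- do.call(rbind, cand)
  # greedy angular clustering
  used <- rep(FALSE, nrow(C))
  clusters <- list()
  for (i in seq_len(nrow(C))) {
    if (used[i]) next
    memb <- which(!used & abs(C %*% C[i, ]) > cos(10 * pi / 180))
    used[memb] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      list(axis = .canonical_axis(colSums(C[memb, , drop = FALSE] *
                                            sign(C[memb, , drop = FALSE] %*% C[i, ])[, 1])),
           size = length(memb))
  }
  clusters <- clusters[order(-vapply(clusters, `[[`, 0, "size"))]
  axes <- matrix(NA_real_, 0, 3)
  for (cl in clusters) {
    if (nrow(axes) == 3) break
    if (nrow(axes) == 0 || all(abs(axes %*% cl$axis) < 0.3))
      axes <- rbind(axes, cl$axis)
  }
  if (nrow(axes) < 3) stop("assembly not octahedral: no orthogonal axis trio")
  # snap to the nearest orthonormal right-handed trio
  sv <- svd(t(axes))
  Q <- sv$u %*% t(sv$v)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]

  canon_rots <- lapply(build_octahedral_rotations(), `[[`, "matrix")
  resid_fn <- function(Q) {
    r <- 0
    for (Rm in canon_rots) {
      S <- Q %*% Rm %*% t(Q)
      Y <- X %*% t(S)
      d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
      r <- r + sum(pmax(apply(d2, 1, min), 0))
    }
    sqrt(r / (length(canon_rots) * nrow(X)))
  }
  r0 <- resid_fn(Q)
  if (r0 > 0.05) {
    opt <- stats::optim(c(0, 0, 0), function(p) {
      ang <- sqrt(sum(p^2))
      Rp <- if (ang < 1e-12) diag(3) else rotation_about(p, ang)
      resid_fn(Rp %*% Q)
    }, method = "Nelder-Mead", control = list(maxit = 200, reltol = 1e-8))
    ang <- sqrt(sum(opt$par^2))
    if (ang >= 1e-12) Q <- rotation_about(opt$par, ang) %*% Q
    r0 <- resid_fn(Q)
  }
  if (r0 > max_residual)
    stop(sprintf("assembly not octahedral (fit residual %.2f A)", r0))

  four <- t(Q)            # rows = fitted four-fold axes
  signs <- as.matrix(expand.grid(c(1, 1), c(1, -1), c(1, -1)))[1:4, ]
  three <- t(apply(signs, 1, function(s)
    .unit(s[1] * four[1, ] + s[2] * four[2, ] + s[3] * four[3, ])))
  pairs2 <- rbind(c(1, 2, 1), c(1, 2, -1), c(1, 3, 1), c(1, 3, -1),
                  c(2, 3, 1), c(2, 3, -1))
  two <- t(apply(pairs2, 1, function(s)
    .unit(four[s[1], ] + s[3] * four[s[2], ])))

  structure(list(center = center, rotation = Q, fourfold_axes = four,
                 threefold_axes = three, twofold_edge_axes = two,
                 fit_residual = r0),
            class = "OctahedralFrame")
}

#' @export
print.OctahedralFrame <- function(x, ...) {
  cat(sprintf("<OctahedralFrame> residual %.3f A, centre (%.1f, %.1f, %.1f)\n",
              x$fit_residual, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Label-preserving point group of a typed assembly
#'
#' Among the 24 rotations of the fitted frame, returns those mapping the
#' typed chain-centroid set onto itself with subunit types preserved
#' (bijection within `tol` Angstrom). The hetero-cage arrangement retains a
#' single two-fold; a homogeneous cage retains all 24 rotations.
#'
#' @param assembly a typed `Assembly`.
#' @param frame an `OctahedralFrame`.
#' @param pairing unused placeholder for interface symmetry (`NULL` ok).
#' @param tol centroid coincidence tolerance, Angstrom.
#' @return list with `order`, `axis_classes` of all elements, and
#'   `generator_axis_class` (axis class of the non-identity element of an
#'   order-2 group, else `NA`).
#' @export
assembly_point_group <- function(assembly, frame, pairing = NULL, tol = 2.0) {
  types <- .chain_types(assembly)
  if (!all(types %in% c("A", "B")))
    stop("assign subunit types before point-group detection")
  cen <- chain_centroids(assembly)
  X <- sweep(cen, 2, frame$center)
  rots <- build_octahedral_rotations()
  Q <- frame$rotation
  kept <- vapply(rots, function(r) {
    Y <- X %*% t(Q %*% r$matrix %*% t(Q))
    d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
    j <- apply(d2, 1, which.min)
    dmin <- sqrt(pmax(d2[cbind(seq_along(j), j)], 0))
    all(dmin < tol) && !anyDuplicated(j) && all(types[j] == types)
  }, TRUE)
  classes <- vapply(rots[kept], `[[`, "", "axis_class")
  gen <- if (sum(kept) == 2) setdiff(classes, "identity") else NA_character_
  list(order = sum(kept), axis_classes = classes,
       generator_axis_class = gen, indices = which(kept))
}

#' Map a typed assembly onto the cage graph
#'
#' Assigns every detected dimer to the nearest dimer-slot direction of the
#' abstract cage (unique within `max_angle`), distributes each dimer's two
#' chains over the slot's two subunit slots by angular proximity, and
#' returns the induced dimer labeling for cross-validation against the
#' combinatorial model.
#'
#' @param assembly a typed `Assembly`.
#' @param frame an `OctahedralFrame`.
#' @param pairing a `DimerPairing`.
#' @param graph a `CageGraph`.
#' @param max_angle maximum slot-assignment angle, degrees.
#' @return list with `dimer_slot` (named: dimer index in `pairing` ->
#'   slot), `chain_slot` (named: chain id -> subunit slot), and `labeling`
#'   (induced `DimerLabeling`).
#' @export
map_assembly_to_graph <- function(assembly, frame, pairing,
                                  graph = build_cage_graph(),
                                  max_angle = 15) {
  types <- .chain_types(assembly)
  if (!all(types %in% c("A", "B")))
    stop("assign subunit types before mapping to the cage graph")
  cen <- chain_centroids(assembly)
  X <- sweep(cen, 2, frame$center)
  Xc <- X %*% frame$rotation      # canonical-frame coordinates
  dirs <- Xc / sqrt(rowSums(Xc^2))

  i1 <- match(pairing$chain_1, names(assembly$chains))
  i2 <- match(pairing$chain_2, names(assembly$chains))
  M <- (Xc[i1, , drop = FALSE] + Xc[i2, , drop = FALSE])
  M <- M / sqrt(rowSums(M^2))
  cosd <- M %*% t(graph$dimer_dirs)
  slot <- apply(cosd, 1, which.max)
  ang <- acos(pmin(1, cosd[cbind(seq_along(slot), slot)])) * 180 / pi
  bad <- ang > max_angle
  if (any(bad))
    stop("dimer(s) ", paste(which(bad), collapse = ", "),
         " have no dimer slot within ", max_angle, " degrees")
  if (anyDuplicated(slot)) {
    dup <- slot[duplicated(slot)]
    stop("ambiguous slot assignment: slot(s) ",
         paste(unique(dup), collapse = ", "), " claimed by multiple dimers")
  }

  chain_slot <- integer(length(assembly$chains))
  names(chain_slot) <- names(assembly$chains)
  lab <- character(12)
  for (k in seq_along(slot)) {
    subs <- which(graph$sub_dimer == slot[k])
    ci <- c(i1[k], i2[k])
    cost_direct <- acos(pmin(1, sum(dirs[ci[1], ] * graph$sub_dirs[subs[1], ]))) +
      acos(pmin(1, sum(dirs[ci[2], ] * graph$sub_dirs[subs[2], ])))
    cost_swap <- acos(pmin(1, sum(dirs[ci[1], ] * graph$sub_dirs[subs[2], ]))) +
      acos(pmin(1, sum(dirs[ci[2], ] * graph$sub_dirs[subs[1], ])))
    if (cost_swap < cost_direct) subs <- rev(subs)
    chain_slot[ci] <- subs
    tt <- types[ci]
    if (tt[1] != tt[2])
      warning("heterotypic dimer at slot ", slot[k],
              "; labeling by first chain")
    lab[slot[k]] <- tt[1]
  }
  list(dimer_slot = slot, chain_slot = chain_slot,
       labeling = dimer_labeling(lab, strict = FALSE))
}
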