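# Canonical cage geometry constants. The cage is modelled on the rhombic
# dodecahedron dual of the cuboctahedron: 12 faces (= antiparallel homodimers)
# centred on the edge-type two-fold axes, 6 four-coordinate vertices on the
# four-fold axes and 8 three-coordinate vertices on the three-fold axes.
# A subunit slot is a generic direction inside one face quadrant; the full
# orbit under the 24 rotations gives the 24 subunit slots.
.CAGE_A0 <- c(1, 1, 0) / sqrt(2)     # reference dimer (face) axis
.CAGE_P0 <- c(1, -1, 0) / sqrt(2)    # in-face axis towards the 4-fold vertices
.CAGE_Q0 <- c(0, 0, 1)               # in-face axis towards the 3-fold vertices
# offsets of the reference subunit direction from the face axis; the subunit
# leans towards its own four-fold vertex (+x) and three-fold vertex (1,1,1)
.CAGE_OFF_P <- 0.10
.CAGE_OFF_Q <- 0.16

.unit <- function(v) v / sqrt(sum(v^2))

#' Canonical direction of the reference subunit slot
#' @keywords internal
reference_subunit_dir <- function() {
  .unit(.CAGE_A0 + .CAGE_OFF_P * .CAGE_P0 + .CAGE_OFF_Q * .CAGE_Q0)
}

.match_dir <- function(v, dirs, tol = 1e-6) {
  # index of the row of `dirs` equal to unit vector v (within tol)
  d <- dirs %*% v
  i <- which.max(d)
  if (d[i] < 1 - tol) NA_integer_ else i
}

.dir_key <- function(v) {
  x <- round(v, 6)
  x[x == 0] <- 0  # collapse -0
  paste(sprintf("%+.6f", x), collapse = " ")
}

#' Build the incidence graph of the 432-symmetric 24-mer cage
#'
#' Constructs the abstract cage used for all combinatorial work: 12 dimer
#' slots (one per edge-type two-fold piercing direction), 24 subunit slots
#' (two per dimer, the orbit of a generic reference direction), six four-fold
#' pore nodes, eight three-fold pore nodes and 24 B-pore nodes, for a total
#' of 38 channels. Each subunit slot belongs to exactly one four-fold node,
#' one three-fold node, and three B-pore nodes (twice through its own dimer's
#' whole-dimer donations and once as the single donor to a neighbouring
#' dimer's pore).
#'
#' The B-pore incidence (which dimer donates its whole dimer to which pore)
#' cannot be read off the symmetry axes alone; it is derived once from the
#' canonical geometric realisation: the single donor of the reference dimer's
#' pore is the neighbouring-face subunit closest to the reference face axis
#' (lexicographic tie-break between the two mirror-equivalent choices), and
#' the remaining 23 B-pores are the group orbit of that reference incidence.
#' All incidence invariants are checked and violations are an error.
#'
#' @param rotations the 24-element rotation group from
#'   [build_octahedral_rotations()].
#' @return an object of class `CageGraph`.
#' @examples
#' g <- build_cage_graph(build_octahedral_rotations())
#' g$n_pores   # 38
.graph_cache <- new.env(parent = emptyenv())

#' @export
build_cage_graph <- function(rotations = build_octahedral_rotations()) {
  use_cache <- missing(rotations)
  if (use_cache && !is.null(.graph_cache$graph)) return(.graph_cache$graph)
  if (length(rotations) != 24 ||
      !all(vapply(rotations, inherits, TRUE, "RotationOperator")))
    stop("`rotations` must be the full 24-element octahedral group")

  # dimer slots: the 12 signed edge-axis directions
  perm2 <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
                 c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
                 c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  dimer_dirs <- perm2 / sqrt(2)
  rownames(dimer_dirs) <- sprintf("D%02d", seq_len(12))

  # pore axis poles
  four_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rownames(four_dirs) <- sprintf("F%d", seq_len(6))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  three_dirs <- unname(signs) / sqrt(3)
  rownames(three_dirs) <- sprintf("T%d", seq_len(8))

  # subunit slots: orbit of the reference direction; bookkeeping of each
  # slot's dimer, four-fold vertex and three-fold vertex travels with the
  # group element that generated it.
  u0 <- reference_subunit_dir()
  v4_0 <- c(1, 0, 0)
  v3_0 <- c(1, 1, 1) / sqrt(3)
  sub_dirs <- matrix(NA_real_, 24, 3)
  sub_dimer <- integer(24)
  sub_four <- integer(24)
  sub_three <- integer(24)
  sub_gen <- integer(24)   # rotation index that generates the slot from u0
  seen <- character(0)
  k <- 0L
  for (ri in seq_along(rotations)) {
    r <- rotations[[ri]]
    v <- drop(r$matrix %*% u0)
    key <- .dir_key(v)
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    sub_dirs[k, ] <- v
    sub_gen[k] <- ri
    sub_dimer[k] <- .match_dir(drop(r$matrix %*% .CAGE_A0), dimer_dirs)
    sub_four[k] <- .match_dir(drop(r$matrix %*% v4_0), four_dirs)
    sub_three[k] <- .match_dir(drop(r$matrix %*% v3_0), three_dirs)
  }
  if (k != 24 || anyNA(sub_dimer) || anyNA(sub_four) || anyNA(sub_three))
    stop("subunit orbit construction failed (wrong geometric seed)")
  rownames(sub_dirs) <- sprintf("S%02d", seq_len(24))

  if (!all(tabulate(sub_dimer, 12) == 2L))
    stop("each dimer slot must carry exactly 2 subunit slots")
  if (!all(tabulate(sub_four, 6) == 4L) || !all(tabulate(sub_three, 8) == 3L))
    stop("pore-vertex incidence violated")

  # --- B-pore incidence ------------------------------------------------
  # reference: dimer slot of the reference subunit acts as the whole-dimer
  # donor; the single donor is the outside subunit closest to the face axis.
  d0 <- sub_dimer[1]
  a0 <- dimer_dirs[d0, ]
  outside <- which(sub_dimer != d0)
  ang <- sub_dirs[outside, , drop = FALSE] %*% a0
  best <- outside[ang > max(ang) - 1e-9]
  # the mirror pair ties by construction; fix the handedness lexicographically
  keys <- apply(sub_dirs[best, , drop = FALSE], 1, .dir_key)
  s_ref <- best[order(keys)][1]

  b_whole <- integer(24)
  b_single <- integer(24)
  seen_b <- character(0)
  kb <- 0L
  for (r in rotations) {
    w <- .match_dir(drop(r$matrix %*% dimer_dirs[d0, ]), dimer_dirs)
    s <- .match_dir(drop(r$matrix %*% sub_dirs[s_ref, ]), sub_dirs)
    key <- paste(w, s)
    if (key %in% seen_b) next
    seen_b <- c(seen_b, key)
    kb <- kb + 1L
    b_whole[kb] <- w
    b_single[kb] <- s
  }
  if (kb != 24)
    stop("B-pore orbit has size ", kb, ", expected 24 (wrong geometric seed)")
  if (!all(tabulate(b_whole, 12) == 2L))
    stop("each dimer slot must whole-donate to exactly 2 B-pores")
  if (!all(tabulate(b_single, 24) == 1L))
    stop("each subunit slot must single-donate to exactly 1 B-pore")

  # per-B-node contributing subunit slots (2 from the whole dimer + single)
  b_subunits <- lapply(seq_len(24), function(i)
    c(which(sub_dimer == b_whole[i]), b_single[i]))
  # each subunit slot must appear in exactly 3 B-pores
  if (!all(tabulate(unlist(b_subunits), 24) == 3L))
    stop("subunit slots must each appear in exactly 3 B-pores")

  # induced permutations of the dimer slots under each rotation (used for
  # automorphism groups and orbit computations)
  dimer_perm <- t(vapply(rotations, function(r) {
    vapply(seq_len(12), function(j)
      .match_dir(drop(r$matrix %*% dimer_dirs[j, ]), dimer_dirs), 1L)
  }, integer(12)))
  sub_perm <- t(vapply(rotations, function(r) {
    vapply(seq_len(24), function(j)
      .match_dir(drop(r$matrix %*% sub_dirs[j, ]), sub_dirs), 1L)
  }, integer(24)))
  if (anyNA(dimer_perm) || anyNA(sub_perm))
    stop("rotation group does not act on the slot set")

  out <- structure(list(
    rotations = rotations,
    dimer_dirs = dimer_dirs,
    sub_dirs = sub_dirs,
    sub_dimer = sub_dimer,
    sub_four = sub_four,
    sub_three = sub_three,
    sub_gen = sub_gen,
    four_dirs = four_dirs,
    three_dirs = three_dirs,
    b_whole = b_whole,
    b_single = b_single,
    b_subunits = b_subunits,
    dimer_perm = dimer_perm,
    sub_perm = sub_perm,
    n_pores = 6L + 8L + 24L
  ), class = "CageGraph")
  if (use_cache) .graph_cache$graph <- out
  out
}

#' @export
print.CageGraph <- function(x, ...) {
  cat("<CageGraph> 12 dimer slots, 24 subunit slots,",
      x$n_pores, "pore nodes (24 B + 6 four-fold + 8 three-fold)\n")
  invisible(x)
}

#' Ideal (unit-sphere) direction of each pore node
#'
#' Four-fold and three-fold pores sit on their symmetry-axis poles; a B-pore
#' direction is the normalised mean of its three contributing subunit-slot
#' directions.
#'
#' @param graph a `CageGraph`.
#' @return a list with matrices `fourfold` (6 x 3), `threefold` (8 x 3) and
#'   `b_pore` (24 x 3).
#' @export
pore_node_directions <- function(graph) {
  b <- t(vapply(graph$b_subunits, function(s)
    .unit(colSums(graph$sub_dirs[s, , drop = FALSE])), numeric(3)))
  rownames(b) <- sprintf("B%02d", seq_len(24))
  list(fourfold = graph$four_dirs, threefold = graph$three_dirs, b_pore = b)
}
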