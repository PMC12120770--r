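# Dimer-type labelings of the cage and their pore-composition spectra.
#
# A labeling assigns each of the 12 dimer slots to subunit type A (heme-free)
# or B (heme-binding). The strict case (6 A + 6 B) models a hetero-cage with
# equal stoichiometry; relaxed labelings (any split) are allowed for
# degenerate/homogeneous cages.

#' Construct a dimer labeling
#'
#' @param labels character vector of length 12 with values "A"/"B", in dimer
#'   slot order (optionally named by slot id).
#' @param strict if `TRUE` (default), require exactly 6 A and 6 B.
#' @return a `DimerLabeling` (character vector with class attribute).
#' @export
dimer_labeling <- function(labels, strict = TRUE) {
  labels <- as.character(labels)
  if (length(labels) != 12 || !all(labels %in% c("A", "B")))
    stop("a labeling is 12 values from {A, B}")
  if (strict && sum(labels == "A") != 6)
    stop("strict labelings have exactly 6 A and 6 B dimers; ",
         "use strict = FALSE for degenerate cages")
  names(labels) <- sprintf("D%02d", seq_len(12))
  structure(labels, class = "DimerLabeling")
}

#' Enumerate dimer-type labelings
#'
#' In strict mode yields all choose(12, 6) = 924 assignments of six type-A
#' and six type-B dimers to the 12 slots; in relaxed mode, all 2^12 = 4096
#' assignments.
#'
#' @param graph a `CageGraph` (present for interface symmetry; the slot count
#'   is fixed at 12).
#' @param strict logical, default `TRUE`.
#' @return a logical matrix with one row per labeling and 12 columns,
#'   `TRUE` = type A. Use [dimer_labeling()] / [labeling_from_row()] to lift
#'   a row to a `DimerLabeling`.
#' @export
enumerate_labelings <- function(graph, strict = TRUE) {
  if (strict) {
    sets <- utils::combn(12, 6)
    m <- matrix(FALSE, ncol(sets), 12)
    for (i in seq_len(ncol(sets))) m[i, sets[, i]] <- TRUE
  } else {
    m <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 12)))
    dimnames(m) <- NULL
  }
  colnames(m) <- sprintf("D%02d", seq_len(12))
  m
}

#' @rdname enumerate_labelings
#' @param row a logical vector of length 12 (`TRUE` = type A).
#' @export
labeling_from_row <- function(row) {
  dimer_labeling(ifelse(row, "A", "B"), strict = sum(row) == 6)
}

.labeling_logical <- function(labeling) {
  if (is.logical(labeling)) {
    stopifnot(length(labeling) == 12)
    return(labeling)
  }
  unname(unclass(labeling) == "A")
}

#' Pore-composition spectrum of a labeling
#'
#' Assigns every pore node its composition (number of type-A and type-B
#' contributing subunits; 4 subunits for a four-fold pore, 3 for three-fold
#' and B-pores) and aggregates counts per (kind, composition) class.
#'
#' @param graph a `CageGraph`.
#' @param labeling a `DimerLabeling` or logical vector (`TRUE` = A).
#' @return a `SubtypeSpectrum`: data frame with columns `kind`, `n_A`, `n_B`,
#'   `count`, ordered by kind and decreasing `n_A`.
#' @examples
#' g <- build_cage_graph()
#' composition_spectrum(g, dimer_labeling(rep(c("A", "B"), 6)))
#' @export
composition_spectrum <- function(graph, labeling) {
  lab <- .labeling_logical(labeling)
  comp <- pore_compositions(graph, lab)
  agg <- function(kind, nA, total) {
    tab <- table(factor(nA, levels = 0:total))
    d <- data.frame(kind = kind, n_A = as.integer(names(tab)),
                    n_B = total - as.integer(names(tab)),
                    count = as.integer(tab))
    d[d$count > 0, , drop = FALSE]
  }
  out <- rbind(agg("b_pore", comp$b_pore, 3L),
               agg("fourfold", comp$fourfold, 4L),
               agg("threefold", comp$threefold, 3L))
  out <- out[order(out$kind, -out$n_A), ]
  rownames(out) <- NULL
  class(out) <- c("SubtypeSpectrum", "data.frame")
  out
}

#' Per-pore type-A counts for a labeling
#'
#' @return list of integer vectors `fourfold` (6), `threefold` (8),
#'   `b_pore` (24): number of type-A subunits at each pore node.
#' @keywords internal
pore_compositions <- function(graph, labeling) {
  lab <- .labeling_logical(labeling)
  sub_is_a <- lab[graph$sub_dimer]
  four <- vapply(seq_len(6), function(f)
    sum(sub_is_a[graph$sub_four == f]), 0L)
  three <- vapply(seq_len(8), function(t)
    sum(sub_is_a[graph$sub_three == t]), 0L)
  b <- 2L * lab[graph$b_whole] + lab[graph$sub_dimer[graph$b_single]]
  list(fourfold = four, threefold = three, b_pore = as.integer(b))
}

#' Vectorised type-A pore counts for many labelings
#'
#' @param graph a `CageGraph`.
#' @param labmat logical matrix, one labeling per row (from
#'   [enumerate_labelings()]).
#' @return list of integer matrices `fourfold` (n x 6), `threefold` (n x 8),
#'   `b_pore` (n x 24) of per-pore type-A counts.
#' @export
pore_compositions_all <- function(graph, labmat) {
  L <- labmat * 1L
  M4 <- matrix(0L, 12, 6)
  M3 <- matrix(0L, 12, 8)
  for (s in seq_len(24)) {
    d <- graph$sub_dimer[s]
    M4[d, graph$sub_four[s]] <- M4[d, graph$sub_four[s]] + 1L
    M3[d, graph$sub_three[s]] <- M3[d, graph$sub_three[s]] + 1L
  }
  b <- 2L * L[, graph$b_whole, drop = FALSE] +
    L[, graph$sub_dimer[graph$b_single], drop = FALSE]
  list(fourfold = L %*% M4, threefold = L %*% M3, b_pore = b)
}

#' Label-preserving rotation subgroup of a labeling
#'
#' Returns the rotations whose induced permutation of the dimer slots
#' preserves the labels; always contains the identity, and its order divides
#' 24 (Lagrange).
#'
#' @inheritParams composition_spectrum
#' @return list with `indices` (into `graph$rotations`), `rotations`, and
#'   `order`.
#' @export
labeling_automorphisms <- function(graph, labeling) {
  lab <- .labeling_logical(labeling)
  keep <- vapply(seq_len(nrow(graph$dimer_perm)), function(i) {
    p <- graph$dimer_perm[i, ]
    all(lab[p] == lab)
  }, TRUE)
  idx <- which(keep)
  list(indices = idx, rotations = graph$rotations[idx], order = length(idx))
}

.comp_key <- function(nA, total) paste0(nA, ":", total - nA)

#' Search labelings by composition and symmetry constraints
#'
#' Exhaustively filters the strict labelings by (i) the exact set of
#' compositions present per pore kind, (ii) the order of the label-preserving
#' rotation subgroup, and (iii) optionally the compositions of the two
#' four-fold pores pierced by the C2 generator axis. Matches are grouped into
#' equivalence classes under the rotation group.
#'
#' @param graph a `CageGraph`.
#' @param fourfold_comps,threefold_comps,b_comps optional character vectors
#'   of composition strings `"nA:nB"`; when given, the set of compositions
#'   present for that kind must match exactly.
#' @param automorphism_order optional required subgroup order.
#' @param axis_pore_comps optional length-2 character vector: the required
#'   (unordered) compositions of the two four-fold pores on the axis of the
#'   order-2 generator; implies the generator is a 180-degree rotation about
#'   a four-fold axis.
#' @param labmat optional precomputed labeling matrix.
#' @return list with `matches` (logical matrix of surviving labelings, one
#'   per row), `classes` (integer vector mapping each match to a
#'   rotation-equivalence class), and `n_classes`.
#' @export
find_arrangements <- function(graph,
                              fourfold_comps = NULL,
                              threefold_comps = NULL,
                              b_comps = NULL,
                              automorphism_order = NULL,
                              axis_pore_comps = NULL,
                              labmat = enumerate_labelings(graph)) {
  comps <- pore_compositions_all(graph, labmat)
  keep <- rep(TRUE, nrow(labmat))

  set_ok <- function(mat, total, want) {
    if (is.null(want)) return(rep(TRUE, nrow(mat)))
    want <- sort(want)
    apply(mat, 1, function(nA)
      identical(sort(unique(.comp_key(nA, total))), want))
  }
  keep <- keep & set_ok(comps$fourfold, 4L, fourfold_comps)
  keep <- keep & set_ok(comps$threefold, 3L, threefold_comps)
  keep <- keep & set_ok(comps$b_pore, 3L, b_comps)

  if (!is.null(automorphism_order) || !is.null(axis_pore_comps)) {
    for (i in which(keep)) {
      aut <- labeling_automorphisms(graph, labmat[i, ])
      if (!is.null(automorphism_order) && aut$order != automorphism_order) {
        keep[i] <- FALSE
        next
      }
      if (!is.null(axis_pore_comps)) {
        gens <- aut$rotations[vapply(aut$rotations, `[[`, "", "axis_class")
                              == "twofold_face"]
        ok <- FALSE
        for (gen in gens) {
          # the two four-fold pores pierced by the generator axis
          poles <- which(abs(graph$four_dirs %*% gen$axis) > 1 - 1e-6)
          pc <- sort(.comp_key(comps$fourfold[i, poles], 4L))
          if (identical(pc, sort(axis_pore_comps))) ok <- TRUE
        }
        if (!ok) keep[i] <- FALSE
      }
    }
  }

  matches <- labmat[keep, , drop = FALSE]
  # rotation-equivalence classes among the matches
  n <- nrow(matches)
  classes <- integer(n)
  if (n > 0) {
    key <- apply(matches, 1, paste, collapse = "")
    cls <- 0L
    for (i in seq_len(n)) {
      if (classes[i] != 0L) next
      cls <- cls + 1L
      orbit_keys <- apply(graph$dimer_perm, 1, function(p)
        paste(matches[i, ][p], collapse = ""))
      classes[key %in% orbit_keys] <- cls
    }
  }
  list(matches = matches, classes = classes, n_classes = max(classes, 0L))
}

# listing order of compositions per kind; subtype I, II, ... follow it
.SUBTYPE_ORDER <- list(
  b_pore = c("3:0", "0:3", "1:2", "2:1"),
  fourfold = c("4:0", "1:3", "2:2", "0:4", "3:1"),
  threefold = c("2:1", "1:2", "3:0", "0:3")
)

#' Subtype table of a spectrum
#'
#' Names the composition classes of each pore kind subtype I, II, ... in the
#' conventional listing order (B-pores: 3:0, 0:3, 1:2, 2:1; four-fold: 4:0,
#' 1:3, 2:2; three-fold: 2:1, 1:2; compositions outside the listing order are
#' appended after it).
#'
#' @param spectrum a `SubtypeSpectrum` from [composition_spectrum()].
#' @return data frame with columns `kind`, `subtype` (roman numeral),
#'   `composition`, `count`.
#' @export
subtype_table <- function(spectrum) {
  out <- do.call(rbind, lapply(names(.SUBTYPE_ORDER), function(kind) {
    d <- spectrum[spectrum$kind == kind, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    comp <- .comp_key(d$n_A, d$n_A + d$n_B)
    ord <- match(comp, .SUBTYPE_ORDER[[kind]])
    ord[is.na(ord)] <- length(.SUBTYPE_ORDER[[kind]]) + rank(comp[is.na(ord)])
    d <- d[order(ord), , drop = FALSE]
    data.frame(kind = kind,
               subtype = as.character(utils::as.roman(seq_len(nrow(d)))),
               composition = .comp_key(d$n_A, d$n_A + d$n_B),
               count = d$count)
  }))
  rownames(out) <- NULL
  out
}
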