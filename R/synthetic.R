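# Deterministic synthetic cage generator.
#
# Builds idealised 24-subunit cage coordinate sets from any dimer labeling so
# that every geometric stage (typing, dimer detection, frame fitting, pore
# classification) can be validated against the combinatorial oracle without
# any external structure. Subunits are rigid pseudo-atom templates: a
# four-rod CA trace standing in for the four-helix bundle, plus labelled
# marker residues for the C-terminal (four-fold) pore lining, the
# helix-loop-helix (three-fold) lining, the B-pore lining, the ferroxidase
# centre, and the heme-ligand position that distinguishes the two types
# (Lys52 in the heme-free type A, Met52 in the heme-binding type B).

.TEMPLATE_RADIUS <- 50   # Angstrom, subunit-shell scale of a Bfr cage

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Pseudo-atom template of one subunit
#'
#' Returns the reference-position template (canonical frame, reference dimer
#' slot) for a subunit of the given type. Types A and B share identical body
#' coordinates and differ in residue naming: the heme-ligand slot (Lys vs
#' Met), the marker residue numbering of the C-terminal helix (148/151 vs
#' 149/152), and the residue identities read by the role map.
#'
#' @param type `"A"` (heme-free) or `"B"` (heme-binding).
#' @param graph a `CageGraph` (used to locate the template's B-pore marker).
#' @return data frame of atoms (`resno`, `insert`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occ`) with a `role` column.
#' @export
.template_cache <- new.env(parent = emptyenv())

make_subunit_template <- function(type = c("A", "B"),
                                  graph = build_cage_graph()) {
  type <- match.arg(type)
  # the template depends only on the type and the graph's B-node seed;
  # memoise on that key (rebuilding it is pure data.frame overhead)
  bnode0 <- which(graph$b_single == 1L)
  cache_key <- paste(type, .dir_key(.unit(colSums(
    graph$sub_dirs[graph$b_subunits[[bnode0]], ]))))
  if (!is.null(.template_cache[[cache_key]]))
    return(.template_cache[[cache_key]])
  R <- .TEMPLATE_RADIUS
  a <- .CAGE_A0                       # face (dimer two-fold) axis
  n <- reference_subunit_dir()        # subunit direction
  e <- .unit(.cross3(a, n))           # bundle long axis (perp. to both)
  l <- .cross3(n, e)                  # completing the local frame
  Fc <- R * a                         # face centre
  w <- .unit(.CAGE_OFF_P * .CAGE_P0 + .CAGE_OFF_Q * .CAGE_Q0)  # to subunit
  v4 <- c(1, 0, 0)                    # own four-fold pole
  v3 <- c(1, 1, 1) / sqrt(3)          # own three-fold pole

  # B-pore the reference subunit single-donates to (slot 1 by construction)
  bnode <- which(graph$b_single == 1L)
  bdir <- .unit(colSums(graph$sub_dirs[graph$b_subunits[[bnode]], ]))

  rows <- list()
  add <- function(resno, resname, role, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, insert = "", resname = resname, atom = "CA",
      element = "C", x = pos[1], y = pos[2], z = pos[3], occ = 1,
      role = role)
  }

  # body: four antiparallel-packable rods spanning the dimer interface side
  body_res <- if (type == "A") "ALA" else "GLY"
  rod_off <- rbind(c(1.5, 2.2), c(1.5, -2.2), c(4.5, 2.2), c(4.5, -2.2))
  resno <- 200L
  for (k in seq_len(nrow(rod_off))) {
    for (t in seq(-15, 15, by = 2.5)) {
      add(resno, body_res, "body",
          Fc + rod_off[k, 1] * w + rod_off[k, 2] * a + t * e)
      resno <- resno + 1L
    }
  }

  # ferroxidase centre: tight cluster at a fixed interior offset
  fc_pos <- (R - 8) * n
  fcs <- if (type == "A") {
    list(c(18L, "GLU"), c(51L, "GLU"), c(94L, "GLU"), c(54L, "HIS"))
  } else {
    list(c(18L, "GLU"), c(51L, "ASP"), c(127L, "GLU"), c(54L, "HIS"))
  }
  off <- list(0.5 * e, -0.5 * e, 0.5 * l, -0.5 * l)
  for (i in seq_along(fcs))
    add(as.integer(fcs[[i]][1]), fcs[[i]][2], "fc", fc_pos + off[[i]])

  # heme-ligand slot at the dimer interface (the type discriminator)
  add(52L, if (type == "A") "LYS" else "MET", "heme", Fc + 1.2 * w + 2.5 * a)

  # short C-terminal helix running from the bundle to the four-fold pole,
  # its tip carrying the conserved pore-lining pair
  p4 <- R * .unit(3 * v4 + n)
  body_ctr <- Fc + 3.0 * w
  for (i in seq_len(7)) {
    add(resno, body_res, "body",
        body_ctr + (0.25 + 0.12 * (i - 1)) * (p4 - body_ctr))
    resno <- resno + 1L
  }
  cterm <- if (type == "A") c(148L, 151L) else c(149L, 152L)
  add(cterm[1], "ASN", "fourfold", p4 + 0.8 * l)
  add(cterm[2], "GLN", "fourfold", p4 - 0.8 * l)

  # helix-loop-helix proxy at the three-fold pole
  p3 <- R * .unit(3 * v3 + n)
  add(118L, if (type == "A") "GLU" else "ASN", "threefold", p3 + 0.8 * e)
  add(121L, "GLU", "threefold", p3 - 0.8 * e)

  # B-pore lining cluster at the pore this subunit single-donates to
  pb <- R * .unit(0.85 * bdir + 0.15 * n)
  bl <- if (type == "A") {
    list(c(34L, "ASP"), c(66L, "GLU"), c(132L, "ASP"), c(135L, "GLU"))
  } else {
    list(c(34L, "HIS"), c(66L, "GLU"), c(132L, "ASP"), c(136L, "GLU"))
  }
  for (i in seq_along(bl))
    add(as.integer(bl[[i]][1]), bl[[i]][2], "bpore", pb + 0.6 * off[[i]])

  # interior iron-handling site; type B carries plain body atoms at the same
  # coordinates so both templates have identical geometry (only naming
  # differs), which keeps the typed cage's centroid set exactly symmetric
  if (type == "A") {
    add(46L, "HIS", "interior", (R - 10) * n + 0.5 * e)
    add(50L, "ASP", "interior", (R - 10) * n - 0.5 * e)
  } else {
    add(46L, body_res, "body", (R - 10) * n + 0.5 * e)
    add(50L, body_res, "body", (R - 10) * n - 0.5 * e)
  }

  out <- do.call(rbind, rows)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  .template_cache[[cache_key]] <- out
  out
}

.random_rotation <- function() {
  # uniform-ish random rotation from the session RNG stream
  ax <- stats::rnorm(3)
  rotation_about(ax, stats::runif(1, 0, 2 * pi))
}

#' Build a synthetic cage assembly from a dimer labeling
#'
#' Places the type-appropriate subunit template on each of the 24 subunit
#' slots by the slot's group rotation, optionally applies isotropic Gaussian
#' coordinate noise, a global rotation, and a uniform scale, and shuffles
#' chain identifiers deterministically from the seed. With the same
#' parameters and seed the output is bit-identical.
#'
#' @param labeling a `DimerLabeling` or logical vector (`TRUE` = A).
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (must be < 2;
#'   beyond that the geometric detection guarantees are void).
#' @param seed integer seed driving noise, chain shuffling and the random
#'   global rotation.
#' @param global_rotation `NULL` (none), `"random"`, or a 3x3 rotation
#'   matrix.
#' @param radius_scale uniform scale factor (> 0) applied to all coordinates.
#' @param graph a `CageGraph`.
#' @param path optional output PDB path (written via [write_assembly()]).
#' @return an `Assembly` (24 chains, subunit types unassigned); the
#'   generating labeling and chain -> slot map are attached as attributes
#'   `"true_labeling"` and `"slot_of_chain"` for validation work.
#' @export
build_synthetic_cage <- function(labeling, noise_sd = 0, seed = 1,
                                 global_rotation = NULL, radius_scale = 1,
                                 graph = build_cage_graph(), path = NULL) {
  stopifnot(noise_sd >= 0, radius_scale > 0)
  if (noise_sd >= 2)
    stop("noise_sd must be < 2 Angstrom")
  lab <- .labeling_logical(labeling)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  tmplA <- make_subunit_template("A", graph)
  tmplB <- make_subunit_template("B", graph)
  G <- if (is.null(global_rotation)) diag(3)
  else if (is.matrix(global_rotation)) global_rotation
  else if (identical(global_rotation, "random")) .random_rotation()
  else stop("global_rotation must be NULL, 'random', or a 3x3 matrix")

  chain_ids <- sample(c(LETTERS[1:24]))
  chains <- vector("list", 24)
  for (s in seq_len(24)) {
    is_a <- lab[graph$sub_dimer[s]]
    tmpl <- if (is_a) tmplA else tmplB
    Rm <- graph$rotations[[graph$sub_gen[s]]]$matrix
    xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(Rm)
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd), ncol = 3)
    xyz <- (xyz %*% t(G)) * radius_scale
    at <- tmpl[, c("resno", "insert", "resname", "atom", "element")]
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at$occ <- 1
    chains[[s]] <- new_subunit_model(chain_ids[s], at)
  }
  ord <- order(chain_ids)
  asm <- new_assembly(chains[ord], source_id = "synthetic-cage")
  attr(asm, "true_labeling") <- labeling_from_row(lab)
  attr(asm, "slot_of_chain") <- stats::setNames(seq_len(24)[ord],
                                                chain_ids[ord])
  if (!is.null(path)) write_assembly(asm, path)
  asm
}

#' The hetero-cage reference arrangement
#'
#' Runs the constrained exhaustive search (four-fold compositions exactly
#' {4:0, 1:3, 2:2}, three-fold exactly {2:1, 1:2}, label-preserving subgroup
#' of order 2 about a four-fold axis piercing one 4:0 and one 2:2 pore) and
#' returns its unique arrangement class as a canonical representative (the
#' lexicographically smallest matching labeling).
#'
#' @param graph a `CageGraph`.
#' @return a `DimerLabeling`.
#' @export
reference_arrangement <- function(graph = build_cage_graph()) {
  res <- find_arrangements(graph,
                           fourfold_comps = c("4:0", "1:3", "2:2"),
                           threefold_comps = c("2:1", "1:2"),
                           automorphism_order = 2,
                           axis_pore_comps = c("4:0", "2:2"))
  if (nrow(res$matches) == 0 || res$n_classes != 1)
    stop("reference arrangement search did not yield a unique class")
  key <- apply(res$matches, 1, paste, collapse = "")
  labeling_from_row(res$matches[order(key)[1], ])
}

#' Two-chain dimer fixture with charged and aromatic markers
#'
#' A synthetic antiparallel homodimer carrying full side-chain pseudo-atoms:
#' two symmetric Asp23-Arg74 carboxylate/guanidinium pairs at 3.0 Angstrom
#' and two symmetric Phe26 ring / Lys52 ammonium pairs at 4.0 Angstrom above
#' the ring plane, for exercising the interface-contact detectors.
#'
#' @param path optional output PDB path.
#' @return an `Assembly` with 2 chains.
#' @export
make_interface_dimer <- function(path = NULL) {
  rows <- list()
  add <- function(resno, resname, atom, element, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, insert = "", resname = resname, atom = atom,
      element = element, x = pos[1], y = pos[2], z = pos[3], occ = 1)
  }
  # spacer backbone giving the chain an oriented principal axis (+x)
  for (i in 1:10) add(i, "GLY", "CA", "C", c(-9 + 2 * (i - 1), 8, 0))
  # Asp23 side chain (carboxylate)
  add(23L, "ASP", "CA", "C", c(3.2, 6.5, -0.5))
  add(23L, "ASP", "CB", "C", c(2.4, 5.9, 0.2))
  add(23L, "ASP", "CG", "C", c(1.9, 5.3, 0.0))
  add(23L, "ASP", "OD1", "O", c(1.5, 5.0, 0.0))
  add(23L, "ASP", "OD2", "O", c(2.0, 5.9, -0.6))
  # Phe26 ring in the xy-plane, centre (4, 0, 2)
  add(26L, "PHE", "CA", "C", c(5.5, 1.8, 2.4))
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  angs <- c(90, 150, 30, 210, 330, 270) * pi / 180
  for (i in seq_along(ring))
    add(26L, "PHE", ring[i], "C",
        c(4 + 1.39 * cos(angs[i]), 1.39 * sin(angs[i]), 2))
  # Lys52: NZ sits 4.0 A above the partner's ring centre after the flip
  add(52L, "LYS", "CA", "C", c(-5.5, -1.2, 5.6))
  add(52L, "LYS", "CE", "C", c(-4.6, -0.6, 6.3))
  add(52L, "LYS", "NZ", "N", c(-4.0, 0.0, 6.0))
  # Arg74 guanidinium opposing the partner's Asp23
  add(74L, "ARG", "CA", "C", c(-3.0, -6.6, -5.2))
  add(74L, "ARG", "CD", "C", c(-2.4, -6.2, -4.6))
  add(74L, "ARG", "NE", "N", c(-1.9, -5.8, -4.2))
  add(74L, "ARG", "CZ", "C", c(-1.8, -4.7, -3.2))
  add(74L, "ARG", "NH1", "N", c(-1.5, -5.0, -3.0))
  add(74L, "ARG", "NH2", "N", c(-2.1, -4.4, -3.4))
  atomsA <- do.call(rbind, rows)
  flip <- function(d) { d$x <- -d$x; d$y <- -d$y; d }
  atomsB <- flip(atomsA)
  asm <- new_assembly(list(new_subunit_model("A", atomsA, "A"),
                           new_subunit_model("B", atomsB, "A")),
                      source_id = "synthetic-dimer")
  if (!is.null(path)) write_assembly(asm, path)
  asm
}

#' Write the canonical synthetic fixture set
#'
#' Writes the fixtures used across the test-suite: the hetero-cage reference
#' arrangement, a homogeneous all-A cage, a mixed labeling with no rotational
#' symmetry, noisy variants of the reference arrangement (0.5 Angstrom,
#' seeds 1-5), and the two-chain interface dimer.
#'
#' @param output_dir directory (created if missing).
#' @param graph a `CageGraph`.
#' @return named character vector of file paths.
#' @export
fixture_suite <- function(output_dir, graph = build_cage_graph()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  ref <- reference_arrangement(graph)
  out <- c(cage_reference = p("cage_reference.pdb"),
           cage_homogeneous_A = p("cage_homogeneous_A.pdb"),
           cage_asymmetric = p("cage_asymmetric.pdb"),
           stats::setNames(p(sprintf("cage_noisy_s%d.pdb", 1:5)),
                           sprintf("cage_noisy_s%d", 1:5)),
           dimer_interface = p("dimer_interface.pdb"))
  build_synthetic_cage(ref, graph = graph, path = out[["cage_reference"]])
  build_synthetic_cage(rep(TRUE, 12), graph = graph,
                       path = out[["cage_homogeneous_A"]])
  asym <- .first_asymmetric_labeling(graph)
  build_synthetic_cage(asym, graph = graph, path = out[["cage_asymmetric"]])
  for (s in 1:5)
    build_synthetic_cage(ref, noise_sd = 0.5, seed = s, graph = graph,
                         path = out[[sprintf("cage_noisy_s%d", s)]])
  make_interface_dimer(out[["dimer_interface"]])
  out
}

.first_asymmetric_labeling <- function(graph) {
  lm <- enumerate_labelings(graph)
  for (i in seq_len(nrow(lm))) {
    if (labeling_automorphisms(graph, lm[i, ])$order == 1L)
      return(labeling_from_row(lm[i, ]))
  }
  stop("no asymmetric strict labeling found")  # cannot happen
}
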