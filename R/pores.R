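# Geometric detection and characterisation of the 38 cage channels.
#
# Pore centres follow a documented convention: the centroid of the
# designated lining-role residues' CA atoms of the contributing chains
# (four-fold: the Asn/Gln pair per chain; three-fold: the 118/121 pair;
# B-pore: the acidic lining cluster), falling back to the CA centroid near
# the ideal graph position when role residues are absent ("degraded
# centering").

.FORMAL_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0)

.role_ca <- function(chain, role_map, role) {
  hit <- suppressWarnings(resolve_role_residues(chain, role_map, role))
  ca <- hit[hit$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0) ca <- hit
  ca
}

#' Detect the 38 pores of a typed cage assembly
#'
#' Localises the six four-fold pores (at the +/- piercings of the three
#' fitted four-fold axes), the eight three-fold pores, and the 24 B-pores
#' (one per (whole dimer, adjacent single subunit) incidence of the mapped
#' cage graph). Contributing chains and compositions come from the graph
#' mapping; centres from the lining-role residues with a geometric fallback.
#'
#' @param assembly a typed `Assembly`.
#' @param frame an `OctahedralFrame`.
#' @param pairing a `DimerPairing`.
#' @param role_map a `ResidueRoleMap`.
#' @param graph a `CageGraph`.
#' @param mapping optional precomputed [map_assembly_to_graph()] result.
#' @return a `PoreSet`: list of `GeometricPore` objects (fields `id`,
#'   `kind`, `center`, `axis`, `chains`, `types`, `n_A`, `n_B`, `degraded`),
#'   with the slot mapping and induced labeling attached as attributes.
#' @export
detect_pores <- function(assembly, frame, pairing,
                         role_map = default_role_map(),
                         graph = build_cage_graph(), mapping = NULL) {
  if (is.null(mapping))
    mapping <- map_assembly_to_graph(assembly, frame, pairing, graph)
  Q <- frame$rotation
  cen <- chain_centroids(assembly)
  rbar <- mean(sqrt(rowSums(sweep(cen, 2, frame$center)^2)))
  types <- .chain_types(assembly)
  chain_of_slot <- match(seq_len(24), mapping$chain_slot)
  ndirs <- pore_node_directions(graph)

  ca_cache <- lapply(assembly$chains, function(ch) {
    a <- ch$atoms[ch$atoms$atom == "CA", , drop = FALSE]
    if (nrow(a) == 0) a <- ch$atoms
    a
  })

  mk_pore <- function(id, kind, slots, ideal_dir, role, axis = NULL) {
    ci <- chain_of_slot[slots]
    chains <- names(assembly$chains)[ci]
    ideal <- frame$center + drop(Q %*% ideal_dir) * rbar
    pts <- do.call(rbind, lapply(ci, function(i) {
      d <- .role_ca(assembly$chains[[i]], role_map, role)
      if (nrow(d)) cbind(d$x, d$y, d$z) else NULL
    }))
    degraded <- FALSE
    if (!is.null(pts) && nrow(pts)) {
      keep <- sqrt(rowSums(sweep(pts, 2, ideal)^2)) < 10
      pts <- pts[keep, , drop = FALSE]
    }
    if (is.null(pts) || nrow(pts) == 0) {
      degraded <- TRUE
      all_ca <- do.call(rbind, lapply(ci, function(i)
        as.matrix(ca_cache[[i]][, c("x", "y", "z")])))
      keep <- sqrt(rowSums(sweep(all_ca, 2, ideal)^2)) < 10
      pts <- if (any(keep)) all_ca[keep, , drop = FALSE] else
        matrix(ideal, 1, 3)
    }
    tt <- types[ci]
    structure(list(id = id, kind = kind, center = colMeans(pts),
                   axis = axis, chains = chains, types = tt,
                   n_A = sum(tt == "A"), n_B = sum(tt == "B"),
                   degraded = degraded),
              class = "GeometricPore")
  }

  pores <- list()
  for (f in seq_len(6)) {
    pole <- graph$four_dirs[f, ]
    slots <- which(graph$sub_four == f)
    pores[[length(pores) + 1L]] <- mk_pore(
      sprintf("F%d", f), "fourfold", slots, pole, "fourfold_lining",
      axis = drop(Q %*% pole))
  }
  for (t in seq_len(8)) {
    pole <- graph$three_dirs[t, ]
    slots <- which(graph$sub_three == t)
    pores[[length(pores) + 1L]] <- mk_pore(
      sprintf("T%d", t), "threefold", slots, pole, "threefold_lining",
      axis = drop(Q %*% pole))
  }
  for (b in seq_len(24)) {
    slots <- graph$b_subunits[[b]]
    pores[[length(pores) + 1L]] <- mk_pore(
      sprintf("B%02d", b), "b_pore", slots, ndirs$b_pore[b, ], "bpore_lining")
  }
  structure(pores, class = "PoreSet", mapping = mapping,
            labeling = mapping$labeling, frame = frame)
}

#' @export
print.PoreSet <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat("<PoreSet>", length(x), "pores:",
      paste(names(table(kinds)), table(kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Residues lining a pore
#'
#' Residues of the contributing chains with any heavy atom within `radius`
#' of the pore centre, sorted by closest-atom distance.
#'
#' @param pore a `GeometricPore`.
#' @param assembly the `Assembly` it came from.
#' @param radius search radius, Angstrom.
#' @return data frame `chain`, `resno`, `resname`, `min_dist`.
#' @export
lining_residues <- function(pore, assembly, radius = 8.0) {
  out <- do.call(rbind, lapply(pore$chains, function(chid) {
    a <- assembly$chains[[chid]]$atoms
    a <- a[a$element != "H", , drop = FALSE]
    d <- sqrt((a$x - pore$center[1])^2 + (a$y - pore$center[2])^2 +
                (a$z - pore$center[3])^2)
    keep <- d <= radius
    if (!any(keep)) return(NULL)
    a <- a[keep, , drop = FALSE]
    agg <- stats::aggregate(d[keep],
                            by = list(resno = a$resno, resname = a$resname),
                            FUN = min)
    data.frame(chain = chid, resno = agg$resno, resname = agg$resname,
               min_dist = agg$x)
  }))
  if (is.null(out))
    return(data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), min_dist = numeric(0)))
  out <- out[order(out$min_dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Net formal charge of a pore's lining
#'
#' Sum of side-chain formal charges over the lining residues (Asp/Glu -1,
#' Lys/Arg +1, His 0 at neutral pH; termini ignored).
#'
#' @inheritParams lining_residues
#' @return integer net charge.
#' @export
charge_profile <- function(pore, assembly, radius = 8.0) {
  lin <- lining_residues(pore, assembly, radius)
  q <- .FORMAL_CHARGE[lin$resname]
  as.integer(sum(q, na.rm = TRUE))
}

.fc_terminal_atoms <- c(
  GLU = "OE1|OE2", ASP = "OD1|OD2", HIS = "ND1|NE2", GLN = "OE1|NE2",
  ASN = "OD1|ND2", LYS = "NZ", ARG = "NH1|NH2")

#' Ferroxidase-centre centroids of one subunit type
#'
#' Centroid per chain of the side-chain terminal heavy atoms of the
#' ferroxidase-centre role residues (CA used where side chains are absent,
#' as in pseudo-atom models).
#'
#' @param assembly a typed `Assembly`.
#' @param role_map a `ResidueRoleMap`.
#' @param target_type `"A"` or `"B"`.
#' @return matrix (one row per target-type chain) of FC centroids.
#' @export
fc_centroids <- function(assembly, role_map, target_type = "A") {
  idx <- which(.chain_types(assembly) == target_type)
  if (!length(idx)) stop("no chains of type ", target_type)
  out <- t(vapply(idx, function(i) {
    ch <- assembly$chains[[i]]
    hit <- suppressWarnings(resolve_role_residues(ch, role_map, "fc_residues",
                                                  type = target_type))
    if (nrow(hit) == 0) return(c(NA_real_, NA_real_, NA_real_))
    pat <- .fc_terminal_atoms[hit$resname]
    term <- hit[!is.na(pat) & mapply(grepl, paste0("^(", pat, ")$"),
                                     hit$atom), , drop = FALSE]
    if (nrow(term) == 0) term <- hit
    c(mean(term$x), mean(term$y), mean(term$z))
  }, numeric(3)))
  rownames(out) <- names(assembly$chains)[idx]
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Distance from a pore centre to the nearest ferroxidase centre
#'
#' @inheritParams lining_residues
#' @param role_map a `ResidueRoleMap`.
#' @param target_type subunit type whose FCs are measured (default the
#'   heme-free type A, which carries the catalytic centre).
#' @return the minimum distance (Angstrom); all per-chain distances are
#'   attached as attribute `"distances"`.
#' @export
pore_fc_distance <- function(pore, assembly, role_map = default_role_map(),
                             target_type = "A") {
  fcs <- fc_centroids(assembly, role_map, target_type)
  if (nrow(fcs) == 0) stop("no resolvable FC residues on type ", target_type)
  d <- sqrt(rowSums(sweep(fcs, 2, pore$center)^2))
  structure(min(d), distances = d)
}

#' Pore-to-FC distance summary per pore kind
#'
#' @param pores a `PoreSet`.
#' @param assembly,role_map,target_type as in [pore_fc_distance()].
#' @return data frame `kind`, `n`, `min`, `mean`, `sd` of the nearest-FC
#'   distance across pores of each kind.
#' @export
pore_fc_summary <- function(pores, assembly, role_map = default_role_map(),
                            target_type = "A") {
  d <- vapply(pores, function(p)
    as.numeric(pore_fc_distance(p, assembly, role_map, target_type)), 0)
  kinds <- vapply(pores, `[[`, "", "kind")
  out <- do.call(rbind, lapply(split(d, kinds), function(x)
    data.frame(n = length(x), min = min(x), mean = mean(x),
               sd = stats::sd(x))))
  out <- cbind(kind = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' External and internal cage diameters
#'
#' Shoots a quasi-uniform grid of directions from the cage centre; within
#' each angular cone the maximum (external) and minimum (internal) radial
#' heavy-atom distances are recorded, and the diameters are twice the means
#' over all cones that pierce protein.
#'
#' @param assembly an `Assembly`.
#' @param n_dirs number of grid directions.
#' @param cone half-angle of each cone, degrees.
#' @return an `AssemblyMetrics` list: `external_diameter`,
#'   `internal_diameter` (Angstrom), `n_directions_hit`.
#' @export
cage_diameters <- function(assembly, n_dirs = 500, cone = 8) {
  xyz <- do.call(rbind, lapply(assembly$chains, .chain_xyz))
  center <- colMeans(xyz)
  X <- sweep(xyz, 2, center)
  r <- sqrt(rowSums(X^2))
  U <- X / r
  # Fibonacci sphere
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  zc <- 1 - 2 * i / n_dirs
  s <- sqrt(pmax(1 - zc^2, 0))
  D <- cbind(s * cos(phi), s * sin(phi), zc)
  ct <- cos(cone * pi / 180)
  ext <- int <- numeric(0)
  step <- 100
  for (k in seq(1, n_dirs, by = step)) {
    kk <- k:min(k + step - 1, n_dirs)
    Cc <- U %*% t(D[kk, , drop = FALSE])   # n_atoms x |kk|
    for (j in seq_along(kk)) {
      hit <- Cc[, j] > ct
      if (any(hit)) {
        ext <- c(ext, max(r[hit]))
        int <- c(int, min(r[hit]))
      }
    }
  }
  if (!length(ext)) stop("no direction pierces the assembly")
  structure(list(external_diameter = 2 * mean(ext),
                 internal_diameter = 2 * mean(int),
                 n_directions_hit = length(ext)),
            class = "AssemblyMetrics")
}

#' Subtype classification of detected pores
#'
#' Groups the detected pores into (kind, composition) classes, names the
#' classes in the conventional listing order, and cross-checks the counts
#' against the combinatorial spectrum of the induced labeling - a mismatch
#' signals a geometry or typing bug and is an error.
#'
#' @param pores a `PoreSet` from [detect_pores()].
#' @param graph the `CageGraph` used for detection.
#' @return data frame `kind`, `subtype`, `composition`, `count`, `pores`
#'   (comma-separated member ids).
#' @export
classify_subtypes <- function(pores, graph = build_cage_graph()) {
  if (length(pores) != 38)
    stop("expected 38 pores, got ", length(pores))
  kinds <- vapply(pores, `[[`, "", "kind")
  nA <- vapply(pores, `[[`, 0L, "n_A")
  nB <- vapply(pores, `[[`, 0L, "n_B")
  ids <- vapply(pores, `[[`, "", "id")
  spec <- data.frame(kind = kinds, n_A = nA, n_B = nB)
  agg <- stats::aggregate(list(count = rep(1L, nrow(spec))),
                          by = spec, FUN = sum)
  agg <- agg[order(agg$kind, -agg$n_A), ]
  class(agg) <- c("SubtypeSpectrum", "data.frame")

  lab <- attr(pores, "labeling")
  if (!is.null(lab)) {
    oracle <- composition_spectrum(graph, lab)
    rownames(agg) <- NULL
    if (!isTRUE(all.equal(as.data.frame(agg), as.data.frame(oracle),
                          check.attributes = FALSE)))
      stop("geometric subtype spectrum disagrees with the combinatorial ",
           "spectrum of the induced labeling")
  }
  tab <- subtype_table(agg)
  tab$pores <- vapply(seq_len(nrow(tab)), function(i) {
    comp <- as.integer(strsplit(tab$composition[i], ":")[[1]])
    paste(ids[kinds == tab$kind[i] & nA == comp[1]], collapse = ",")
  }, "")
  tab
}
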