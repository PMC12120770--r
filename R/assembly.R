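# Atomic cage models: reading, writing, and subunit typing.
#
# An Assembly holds the protein chains of one (putative) cage model with
# auth residue numbering, so residue labels line up with the literature
# (Met52, Glu94, ...). Heteroatoms (heme, waters, ions) are kept in a side
# table and excluded from the subunit models.

#' Construct a subunit model
#' @keywords internal
new_subunit_model <- function(chain_id, atoms, subunit_type = "unassigned") {
  # atoms: data.frame resno, insert, resname, atom, element, x, y, z, occ
  res <- atoms[!duplicated(paste(atoms$resno, atoms$insert)), , drop = FALSE]
  if (is.unsorted(res$resno, strictly = FALSE))
    atoms <- atoms[order(atoms$resno), , drop = FALSE]
  seq1 <- paste(bio3d::aa321(res$resname[order(res$resno)]), collapse = "")
  structure(list(chain_id = chain_id, atoms = atoms, sequence = seq1,
                 subunit_type = subunit_type),
            class = "SubunitModel")
}

#' @export
print.SubunitModel <- function(x, ...) {
  cat("<SubunitModel>", x$chain_id, "type", x$subunit_type,
      nchar(x$sequence), "residues,", nrow(x$atoms), "atoms\n")
  invisible(x)
}

new_assembly <- function(chains, source_id = "", het = NULL) {
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  structure(list(chains = chains, source_id = source_id, het = het),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  types <- vapply(x$chains, `[[`, "", "subunit_type")
  cat("<Assembly>", x$source_id, "-", length(x$chains), "chains (",
      paste(names(table(types)), table(types), collapse = ", "), ")\n")
  invisible(x)
}

#' Read an atomic cage model
#'
#' Reads a PDB or mmCIF file (first model), extracts the protein chains into
#' subunit models with auth residue numbering and keeps heteroatoms (heme,
#' ions, waters) in a side table. Alternate locations are reduced to the
#' highest-occupancy conformer.
#'
#' A closed ferritin-family cage has exactly 24 protein chains; other chain
#' counts trigger a warning, and downstream cage operations refuse such
#' assemblies unless their `override` flag is set (a 2-chain dimer file is
#' still perfectly usable for interface analysis).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return an `Assembly`.
#' @export
read_assembly <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path) else
      bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms in '", path, "'")
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  # highest-occupancy alternate conformer per atom site
  if (!is.null(at$alt)) {
    o <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
    idx <- seq_len(nrow(at))
    ord <- order(-o)   # prefer the highest-occupancy conformer
    keep <- ord[!duplicated(paste(at$chain, at$resno, at$insert,
                                  at$elety)[ord])]
    at <- at[sort(keep), , drop = FALSE]
  }
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type != "ATOM", , drop = FALSE]
  mk <- function(d) data.frame(
    resno = d$resno,
    insert = ifelse(is.na(d$insert) | d$insert == "", "", d$insert),
    resname = toupper(d$resid),
    atom = d$elety,
    element = toupper(ifelse(is.na(d$elesy) | d$elesy == "",
                             substr(gsub("[0-9]", "", d$elety), 1, 1),
                             d$elesy)),
    x = d$x, y = d$y, z = d$z,
    occ = if (is.null(d$o)) rep(1, nrow(d)) else d$o)
  chains <- lapply(split(seq_len(nrow(prot)), prot$chain), function(i) {
    ch <- prot$chain[i[1]]
    a <- mk(prot[i, , drop = FALSE])
    a <- a[order(a$resno), , drop = FALSE]
    new_subunit_model(ch, a)
  })
  if (length(chains) != 24)
    warning("assembly has ", length(chains),
            " protein chains; a closed cage has 24 - cage operations will ",
            "refuse this assembly unless override = TRUE")
  new_assembly(chains, source_id = basename(path),
               het = if (nrow(het)) mk(het) else NULL)
}

.assert_cage <- function(assembly, override = FALSE) {
  if (length(assembly$chains) != 24 && !override)
    stop("assembly has ", length(assembly$chains),
         " chains, not a 24-mer cage (set override = TRUE to force)")
  invisible(assembly)
}

#' Write an assembly as a PDB file
#'
#' Coordinates are written at standard PDB precision (1e-3 Angstrom), one
#' chain per subunit model; output is byte-deterministic for a given
#' assembly.
#'
#' @param assembly an `Assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  rows <- do.call(rbind, lapply(assembly$chains, function(ch)
    cbind(chain = ch$chain_id, ch$atoms)))
  xyz <- as.vector(t(as.matrix(rows[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = rows$resno, resid = rows$resname,
                   chain = rows$chain, elety = rows$atom,
                   o = rows$occ, b = rep(0, nrow(rows)),
                   elesy = rows$element)
  invisible(path)
}

.pid_cache <- new.env(parent = emptyenv())

.pairwise_identity <- function(seqs) {
  n <- length(seqs)
  pid <- matrix(100, n, n)
  if (n < 2) return(pid)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- paste(sort(c(seqs[i], seqs[j])), collapse = "|")
    if (!is.null(.pid_cache[[key]])) {
      pid[i, j] <- pid[j, i] <- .pid_cache[[key]]
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    p <- Biostrings::pid(aln, type = "PID1")
    .pid_cache[[key]] <- p
    pid[i, j] <- pid[j, i] <- p
  }
  pid
}

#' Assign a subunit type to every chain
#'
#' Either applies an explicit chain -> type map, or partitions chains into at
#' most two types by single-linkage clustering of pairwise global sequence
#' identity (two hetero-cage subunit types share well under the default 90%
#' threshold, so separation is unambiguous). The cluster whose chains carry a
#' Met at the heme-ligand role position is labelled B (heme-binding); without
#' that signal, the larger cluster is labelled A and the choice is reported.
#'
#' @param assembly an `Assembly`.
#' @param mode `"cluster"` or `"map"`.
#' @param chain_map named character vector chain id -> "A"/"B" (map mode).
#' @param identity_threshold percent identity above which chains are the
#'   same type (default 90).
#' @param role_map `ResidueRoleMap` used to locate the heme-ligand position.
#' @return the `Assembly` with `subunit_type` set on every chain.
#' @export
assign_subunit_types <- function(assembly, mode = c("cluster", "map"),
                                 chain_map = NULL, identity_threshold = 90,
                                 role_map = default_role_map()) {
  mode <- match.arg(mode)
  if (mode == "map") {
    if (is.null(chain_map) || !all(names(assembly$chains) %in% names(chain_map)))
      stop("map mode needs a chain_map covering every chain")
    for (ch in names(assembly$chains)) {
      if (!chain_map[[ch]] %in% c("A", "B"))
        stop("chain_map values must be 'A' or 'B'")
      assembly$chains[[ch]]$subunit_type <- chain_map[[ch]]
    }
    return(assembly)
  }
  if (length(assembly$chains) < 2)
    stop("clustering mode requires at least 2 chains")
  seqs <- vapply(assembly$chains, `[[`, "", "sequence")
  uniq <- unique(seqs)
  pid <- .pairwise_identity(uniq)
  if (length(uniq) == 1) {
    cl_u <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(100 - pid), method = "single")
    cl_u <- stats::cutree(hc, h = 100 - identity_threshold)
  }
  cl <- cl_u[match(seqs, uniq)]
  k <- length(unique(cl))
  if (k > 2)
    stop("chains form ", k, " sequence clusters at ", identity_threshold,
         "% identity: ",
         paste(vapply(split(names(assembly$chains), cl), paste,
                      "", collapse = "+"), collapse = " | "),
         "; a hetero-cage has at most 2 subunit types")
  if (k == 1) {
    for (ch in names(assembly$chains)) assembly$chains[[ch]]$subunit_type <- "A"
    message("all chains equivalent at ", identity_threshold,
            "% identity; homogeneous cage labelled type A")
    return(assembly)
  }
  # which cluster is heme-binding (Met at the heme-ligand position)?
  heme_pos <- role_map$B$heme_ligand$resno
  has_met <- vapply(split(names(assembly$chains), cl), function(chs) {
    any(vapply(chs, function(ch) {
      a <- assembly$chains[[ch]]$atoms
      any(a$resname[a$resno %in% heme_pos] == "MET")
    }, TRUE))
  }, TRUE)
  if (sum(has_met) == 1) {
    b_cluster <- as.integer(names(has_met)[has_met])
  } else {
    sizes <- table(cl)
    b_cluster <- as.integer(names(sizes)[which.min(sizes)])
    message("no unambiguous heme-ligand Met; labelling the smaller cluster B")
  }
  for (i in seq_along(assembly$chains))
    assembly$chains[[i]]$subunit_type <- if (cl[i] == b_cluster) "B" else "A"
  assembly
}

#' Chain centroids (heavy atoms)
#' @keywords internal
chain_centroids <- function(assembly) {
  t(vapply(assembly$chains, function(ch) {
    a <- ch$atoms[ch$atoms$element != "H", , drop = FALSE]
    c(mean(a$x), mean(a$y), mean(a$z))
  }, numeric(3)))
}

.chain_types <- function(assembly)
  vapply(assembly$chains, `[[`, "", "subunit_type")

.chain_xyz <- function(chain, heavy = TRUE) {
  a <- chain$atoms
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
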