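# Residue-role configuration: which residues (auth numbering) mark the
# ferroxidase centre, heme ligand, and pore linings of each subunit type.
# Defaults follow the SoBfr12 assignments: the heme-free type A subunit
# (SoBfr1-like, Lys at position 52) and the heme-binding type B subunit
# (SoBfr2-like, Met52); type B's C-terminal numbering is shifted by one.

.role_df <- function(resno, resname) {
  data.frame(resno = as.integer(resno), resname = toupper(resname))
}

#' Default residue-role map
#'
#' @return a `ResidueRoleMap`: list with elements `A` and `B`, each a list of
#'   data frames (`resno`, `resname`) for roles `fc_residues`, `heme_ligand`,
#'   `fourfold_lining`, `threefold_lining`, `bpore_lining`, `interior_site`.
#' @export
default_role_map <- function() {
  structure(list(
    A = list(
      fc_residues      = .role_df(c(18, 51, 94, 54), c("GLU", "GLU", "GLU", "HIS")),
      heme_ligand      = .role_df(integer(0), character(0)),
      fourfold_lining  = .role_df(c(148, 151), c("ASN", "GLN")),
      threefold_lining = .role_df(c(118, 121), c("GLU", "GLU")),
      bpore_lining     = .role_df(c(34, 66, 132, 135), c("ASP", "GLU", "ASP", "GLU")),
      interior_site    = .role_df(c(46, 50), c("HIS", "ASP"))
    ),
    B = list(
      fc_residues      = .role_df(c(18, 51, 127, 54), c("GLU", "ASP", "GLU", "HIS")),
      heme_ligand      = .role_df(52, "MET"),
      fourfold_lining  = .role_df(c(149, 152), c("ASN", "GLN")),
      threefold_lining = .role_df(c(118, 121), c("ASN", "GLU")),
      bpore_lining     = .role_df(c(34, 66, 132, 136), c("HIS", "GLU", "ASP", "GLU")),
      interior_site    = .role_df(integer(0), character(0))
    )
  ), class = "ResidueRoleMap")
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.parse_role_entry <- function(x) {
  # accepts "Glu18" tokens or list(resno=, resname=)
  if (is.list(x) && !is.null(x$resno)) {
    rn <- toupper(as.character(x$resname))
    if (!rn %in% .AA3) stop("unknown residue name: ", rn)
    return(.role_df(x$resno, rn))
  }
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-Za-z]{3})([0-9]+)$", x))[[1]]
  if (length(m) != 3) stop("malformed residue spec: '", x, "'")
  rn <- toupper(m[2])
  if (!rn %in% .AA3) stop("unknown residue name token: '", m[2], "'")
  .role_df(as.integer(m[3]), rn)
}

#' Load a residue-role map from a YAML config
#'
#' The config may override any role of either subunit type; omitted fields
#' keep their defaults. Roles are lists of residue tokens such as `Glu18`.
#' An empty or missing file yields the full default map.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `ResidueRoleMap`.
#' @examples
#' rm <- load_role_map(NULL)
#' rm$B$heme_ligand
#' @export
load_role_map <- function(path = NULL) {
  map <- default_role_map()
  if (is.null(path)) return(map)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(map)
  for (type in intersect(names(cfg), c("A", "B"))) {
    for (role in names(cfg[[type]])) {
      if (!role %in% names(map[[type]]))
        stop("unknown role '", role, "' for type ", type)
      entries <- cfg[[type]][[role]]
      if (is.null(entries) || length(entries) == 0) {
        map[[type]][[role]] <- .role_df(integer(0), character(0))
      } else {
        if (!is.list(entries)) entries <- as.list(entries)
        map[[type]][[role]] <- do.call(rbind, lapply(entries, .parse_role_entry))
      }
    }
  }
  map
}

#' Resolve a role's residues on one chain
#'
#' Looks up the role residues (by auth number) on a chain; residues whose
#' number is absent from the chain are skipped with a warning, matching the
#' tolerant behaviour needed for truncated or engineered constructs.
#'
#' @param chain a `SubunitModel`.
#' @param role_map a `ResidueRoleMap`.
#' @param role role name, e.g. `"fc_residues"`.
#' @param type subunit type override; defaults to the chain's assigned type.
#' @return data frame of matching atoms (subset of `chain$atoms`).
#' @export
resolve_role_residues <- function(chain, role_map, role,
                                  type = chain$subunit_type) {
  if (is.null(type) || !type %in% c("A", "B"))
    stop("chain has no subunit type assigned")
  want <- role_map[[type]][[role]]
  if (is.null(want)) stop("unknown role: ", role)
  atoms <- chain$atoms
  hit <- atoms[atoms$resno %in% want$resno, , drop = FALSE]
  missing <- setdiff(want$resno, atoms$resno)
  if (length(missing))
    warning("chain ", chain$chain_id, ": role ", role, " residue(s) ",
            paste(missing, collapse = ", "), " not present; skipped")
  hit
}
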