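# Typed cross-subunit interactions within a dimer: salt bridges between
# acidic carboxylates and Arg/Lys side-chain nitrogens, and pi-cation pairs
# between aromatic ring faces and cationic groups.

.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
.CATION_ATOM <- list(LYS = "NZ", ARG = "CZ")   # CZ = guanidinium proxy

.side_atoms <- function(chain, table) {
  a <- chain$atoms
  keep <- mapply(function(rn, at) {
    !is.null(table[[rn]]) && at %in% table[[rn]]
  }, a$resname, a$atom)
  a[keep, , drop = FALSE]
}

#' Salt bridges across a chain pair
#'
#' One contact per (acidic, basic) residue pair with any side-chain
#' carboxylate oxygen within `cutoff` of any Arg/Lys side-chain nitrogen
#' (His is excluded from the basic set). A residue pair with several
#' qualifying atom pairs counts once, at its minimum distance.
#'
#' @param assembly an `Assembly`.
#' @param chain_pair character vector of two chain ids.
#' @param cutoff distance cutoff, Angstrom.
#' @return data frame of `InterfaceContact` rows: `kind`, `chain_1`,
#'   `resno_1`, `resname_1`, `chain_2`, `resno_2`, `resname_2`, `distance`.
#' @export
find_salt_bridges <- function(assembly, chain_pair, cutoff = 4.0) {
  stopifnot(length(chain_pair) == 2)
  out <- list()
  for (ord in list(chain_pair, rev(chain_pair))) {
    acid <- .side_atoms(assembly$chains[[ord[1]]], .ACIDIC_O)
    base <- .side_atoms(assembly$chains[[ord[2]]], .BASIC_N)
    if (!nrow(acid) || !nrow(base)) next
    d <- sqrt(outer(acid$x, base$x, "-")^2 + outer(acid$y, base$y, "-")^2 +
                outer(acid$z, base$z, "-")^2)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    df <- data.frame(kind = "salt_bridge",
                     chain_1 = ord[1], resno_1 = acid$resno[hit[, 1]],
                     resname_1 = acid$resname[hit[, 1]],
                     chain_2 = ord[2], resno_2 = base$resno[hit[, 2]],
                     resname_2 = base$resname[hit[, 2]],
                     distance = d[hit])
    df <- df[order(df$distance), , drop = FALSE]
    df <- df[!duplicated(df[, c("chain_1", "resno_1", "chain_2", "resno_2")]),
             , drop = FALSE]
    out[[length(out) + 1L]] <- df
  }
  .contact_table(out)
}

#' Pi-cation pairs across a chain pair
#'
#' Contacts between an aromatic ring (Phe/Tyr six-ring, Trp six-ring) and a
#' cationic centre (Lys NZ, Arg CZ as guanidinium proxy) with ring-centroid
#' distance within `centroid_cutoff` and the centroid-to-cation vector
#' within `max_angle` of the ring normal.
#'
#' @inheritParams find_salt_bridges
#' @param centroid_cutoff ring-centroid to cation distance cutoff, Angstrom.
#' @param max_angle maximum angle between ring normal and centroid-to-cation
#'   vector, degrees.
#' @export
find_pi_cation <- function(assembly, chain_pair, centroid_cutoff = 6.0,
                           max_angle = 45) {
  stopifnot(length(chain_pair) == 2)
  rings_of <- function(chid) {
    a <- assembly$chains[[chid]]$atoms
    out <- list()
    for (rn in names(.RING_ATOMS)) {
      res <- unique(a$resno[a$resname == rn])
      for (r in res) {
        m <- a[a$resno == r & a$resname == rn &
                 a$atom %in% .RING_ATOMS[[rn]], c("x", "y", "z"),
               drop = FALSE]
        if (nrow(m) < 5) next
        m <- as.matrix(m)
        ctr <- colMeans(m)
        normal <- svd(sweep(m, 2, ctr))$v[, 3]
        out[[length(out) + 1L]] <- list(resno = r, resname = rn,
                                        center = ctr, normal = normal)
      }
    }
    out
  }
  cations_of <- function(chid) {
    a <- .side_atoms(assembly$chains[[chid]],
                     lapply(.CATION_ATOM, identity))
    a
  }
  out <- list()
  for (ord in list(chain_pair, rev(chain_pair))) {
    rings <- rings_of(ord[1])
    cats <- cations_of(ord[2])
    if (!length(rings) || !nrow(cats)) next
    rows <- list()
    for (rg in rings) {
      v <- cbind(cats$x - rg$center[1], cats$y - rg$center[2],
                 cats$z - rg$center[3])
      d <- sqrt(rowSums(v^2))
      cosang <- abs((v %*% rg$normal) / d)
      ok <- d <= centroid_cutoff & cosang >= cos(max_angle * pi / 180)
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "pi_cation",
        chain_1 = ord[1], resno_1 = rg$resno, resname_1 = rg$resname,
        chain_2 = ord[2], resno_2 = cats$resno[ok],
        resname_2 = cats$resname[ok], distance = d[ok])
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df <- df[order(df$distance), , drop = FALSE]
    df <- df[!duplicated(df[, c("chain_1", "resno_1", "chain_2", "resno_2")]),
             , drop = FALSE]
    out[[length(out) + 1L]] <- df
  }
  .contact_table(out)
}

.contact_table <- function(pieces) {
  empty <- data.frame(kind = character(0), chain_1 = character(0),
                      resno_1 = integer(0), resname_1 = character(0),
                      chain_2 = character(0), resno_2 = integer(0),
                      resname_2 = character(0), distance = numeric(0))
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  if (!nrow(out)) return(empty)
  out <- out[order(out$chain_1, out$resno_1, out$resno_2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface-contact inventory per dimer
#'
#' Runs salt-bridge and pi-cation detection across every detected dimer and
#' aggregates counts per dimer and per dimer type.
#'
#' @param assembly an `Assembly`.
#' @param pairing a `DimerPairing` from [detect_dimers()].
#' @param sb_cutoff,pc_cutoff detection cutoffs, Angstrom.
#' @return list with `per_dimer` (data frame: chains, type, salt bridges,
#'   pi-cation counts), `by_type` (aggregate), and `contacts` (full contact
#'   table).
#' @export
interface_summary <- function(assembly, pairing, sb_cutoff = 4.0,
                              pc_cutoff = 6.0) {
  types <- .chain_types(assembly)
  rows <- list()
  contacts <- list()
  for (k in seq_len(nrow(pairing))) {
    cp <- c(pairing$chain_1[k], pairing$chain_2[k])
    sb <- find_salt_bridges(assembly, cp, cutoff = sb_cutoff)
    pc <- find_pi_cation(assembly, cp, centroid_cutoff = pc_cutoff)
    contacts[[k]] <- rbind(sb, pc)
    ty <- types[match(cp, names(assembly$chains))]
    rows[[k]] <- data.frame(
      chain_1 = cp[1], chain_2 = cp[2],
      dimer_type = if (all(ty %in% c("A", "B")) && ty[1] == ty[2])
        ty[1] else "mixed",
      salt_bridges = nrow(sb), pi_cation = nrow(pc))
  }
  per_dimer <- do.call(rbind, rows)
  by_type <- stats::aggregate(per_dimer[, c("salt_bridges", "pi_cation")],
                              by = list(dimer_type = per_dimer$dimer_type),
                              FUN = mean)
  list(per_dimer = per_dimer, by_type = by_type,
       contacts = do.call(rbind, contacts))
}
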