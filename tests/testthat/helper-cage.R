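# Shared fixtures, built once per test run (all in code, no stored data).

.fixture_env <- new.env(parent = emptyenv())

cage_graph_fx <- function() build_cage_graph()

reference_labeling_fx <- function() {
  if (is.null(.fixture_env$ref_lab))
    .fixture_env$ref_lab <- reference_arrangement(cage_graph_fx())
  .fixture_env$ref_lab
}

# typed reference-arrangement cage with its derived geometry, computed once
reference_cage_fx <- function() {
  if (is.null(.fixture_env$ref_cage)) {
    g <- cage_graph_fx()
    asm <- assign_subunit_types(
      build_synthetic_cage(reference_labeling_fx(), graph = g))
    pairing <- detect_dimers(asm)
    frame <- fit_octahedral_frame(asm, pairing)
    mapping <- map_assembly_to_graph(asm, frame, pairing, g)
    pores <- detect_pores(asm, frame, pairing, graph = g, mapping = mapping)
    .fixture_env$ref_cage <- list(assembly = asm, pairing = pairing,
                                  frame = frame, mapping = mapping,
                                  pores = pores)
  }
  .fixture_env$ref_cage
}

homogeneous_cage_fx <- function() {
  if (is.null(.fixture_env$homo_cage)) {
    g <- cage_graph_fx()
    asm <- suppressMessages(
      assign_subunit_types(build_synthetic_cage(rep(TRUE, 12), graph = g)))
    .fixture_env$homo_cage <- asm
  }
  .fixture_env$homo_cage
}

# minimal assembly from a coordinate matrix (one pseudo-chain)
point_cloud_assembly <- function(xyz, chain_id = "A") {
  atoms <- data.frame(resno = seq_len(nrow(xyz)), insert = "",
                      resname = "GLY", atom = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1)
  bfrcage:::new_assembly(list(bfrcage:::new_subunit_model(chain_id, atoms)),
                         source_id = "point-cloud")
}

# dense two-layer spherical shell (exact inner/outer radii)
shell_assembly <- function(r_in, r_out, n = 1500) {
  fib <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n
    s <- sqrt(pmax(1 - z^2, 0))
    cbind(s * cos(phi), s * sin(phi), z)
  }
  point_cloud_assembly(rbind(fib(n) * r_in, fib(n) * r_out))
}

# path where optional real deposited structures would live; the files are
# multi-megabyte and cannot ship with the package sources
real_structure_path <- function(file) {
  file.path(test_path("structures"), file)
}
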