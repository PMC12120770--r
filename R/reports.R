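# Pipeline orchestration and report writing.

#' Resolved run configuration
#'
#' Collects every tunable of the analysis pipeline with its default; the
#' resolved configuration is embedded in all reports for provenance.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    format = "auto",
    role_map_path = NULL,
    chain_map = NULL,
    identity_threshold = 90,
    contact_cutoff = 5.0,
    min_contacts = 50,
    salt_bridge_cutoff = 4.0,
    pi_cation_cutoff = 6.0,
    lining_radius = 8.0,
    max_frame_residual = 3.0,
    override = FALSE,
    seed = 1L,
    verbosity = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("contact_cutoff", "salt_bridge_cutoff", "pi_cation_cutoff",
              "lining_radius"))
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  structure(cfg, class = "RunConfig")
}

.log_msg <- function(cfg, ...) {
  if (isTRUE(cfg$verbosity >= 1)) message("[bfrcage] ", ...)
}

#' Run the full cage analysis pipeline on an assembly
#'
#' Typing -> dimer detection -> octahedral frame -> graph mapping -> pore
#' detection and subtype classification -> metrics -> interface inventory.
#'
#' @param assembly an `Assembly` (or a file path, which is read first).
#' @param config a [run_config()].
#' @param graph a `CageGraph`.
#' @return list with the typed `assembly`, `pairing`, `frame`, `mapping`,
#'   `pores`, `subtypes`, `point_group`, `metrics`, `fc_summary`,
#'   `interfaces`, and the resolved `config`.
#' @export
analyze_cage <- function(assembly, config = run_config(),
                         graph = build_cage_graph()) {
  if (is.character(assembly))
    assembly <- read_assembly(assembly, format = config$format)
  role_map <- load_role_map(config$role_map_path)
  .log_msg(config, "typing ", length(assembly$chains), " chains")
  assembly <- if (!is.null(config$chain_map))
    assign_subunit_types(assembly, "map", chain_map = config$chain_map)
  else assign_subunit_types(assembly,
                            identity_threshold = config$identity_threshold,
                            role_map = role_map)
  .assert_cage(assembly, config$override)
  pairing <- detect_dimers(assembly, contact_cutoff = config$contact_cutoff,
                           min_contacts = config$min_contacts,
                           override = config$override)
  .log_msg(config, "detected ", nrow(pairing), " dimers")
  frame <- fit_octahedral_frame(assembly, pairing,
                                max_residual = config$max_frame_residual)
  .log_msg(config, sprintf("frame residual %.3f A", frame$fit_residual))
  mapping <- map_assembly_to_graph(assembly, frame, pairing, graph)
  pores <- detect_pores(assembly, frame, pairing, role_map, graph, mapping)
  subtypes <- classify_subtypes(pores, graph)
  pg <- assembly_point_group(assembly, frame, pairing)
  metrics <- cage_diameters(assembly)
  fc <- pore_fc_summary(pores, assembly, role_map)
  interfaces <- interface_summary(assembly, pairing,
                                  sb_cutoff = config$salt_bridge_cutoff,
                                  pc_cutoff = config$pi_cation_cutoff)
  list(assembly = assembly, pairing = pairing, frame = frame,
       mapping = mapping, pores = pores, subtypes = subtypes,
       point_group = pg, metrics = metrics, fc_summary = fc,
       interfaces = interfaces, config = config)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.report_meta <- function(config) {
  list(package = "bfrcage",
       version = as.character(utils::packageVersion("bfrcage")),
       config = unclass(config))
}

#' Enumerate labelings and write subtype reports
#'
#' Writes the constrained arrangement search results (or all 924 spectra
#' with `all = TRUE`) as TSV plus a JSON report embedding the resolved
#' configuration.
#'
#' @param output_dir output directory.
#' @param constraints list passed to [find_arrangements()] (fields
#'   `fourfold_comps`, `threefold_comps`, `b_comps`, `automorphism_order`,
#'   `axis_pore_comps`); `NULL` applies the hetero-cage reference
#'   constraints.
#' @param all if `TRUE`, also write the spectrum of every strict labeling.
#' @param config a [run_config()].
#' @param graph a `CageGraph`.
#' @return named vector of written file paths, invisibly.
#' @export
cmd_enumerate <- function(output_dir, constraints = NULL, all = FALSE,
                          config = run_config(),
                          graph = build_cage_graph()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(constraints))
    constraints <- list(fourfold_comps = c("4:0", "1:3", "2:2"),
                        threefold_comps = c("2:1", "1:2"),
                        automorphism_order = 2,
                        axis_pore_comps = c("4:0", "2:2"))
  res <- do.call(find_arrangements, c(list(graph = graph), constraints))
  files <- c()
  if (nrow(res$matches) == 0) {
    warning("no labeling satisfies the constraints")
    tab <- NULL
  } else {
    lab <- labeling_from_row(res$matches[1, ])
    tab <- subtype_table(composition_spectrum(graph, lab))
    files["subtypes"] <- .write_tsv(tab, file.path(output_dir, "subtypes.tsv"))
  }
  mt <- data.frame(labeling = apply(res$matches, 1,
                                    function(r) paste(ifelse(r, "A", "B"),
                                                      collapse = "")),
                   class = res$classes,
                   automorphism_order = apply(res$matches, 1, function(r)
                     labeling_automorphisms(graph, r)$order))
  files["arrangements"] <- .write_tsv(mt, file.path(output_dir,
                                                    "arrangements.tsv"))
  if (all) {
    lm <- enumerate_labelings(graph)
    co <- pore_compositions_all(graph, lm)
    sp <- data.frame(
      labeling = apply(lm, 1, function(r) paste(ifelse(r, "A", "B"),
                                                collapse = "")),
      b_30 = rowSums(co$b_pore == 3), b_03 = rowSums(co$b_pore == 0),
      b_12 = rowSums(co$b_pore == 1), b_21 = rowSums(co$b_pore == 2),
      f_40 = rowSums(co$fourfold == 4), f_31 = rowSums(co$fourfold == 3),
      f_22 = rowSums(co$fourfold == 2), f_13 = rowSums(co$fourfold == 1),
      f_04 = rowSums(co$fourfold == 0),
      t_30 = rowSums(co$threefold == 3), t_21 = rowSums(co$threefold == 2),
      t_12 = rowSums(co$threefold == 1), t_03 = rowSums(co$threefold == 0))
    files["spectra"] <- .write_tsv(sp, file.path(output_dir,
                                                 "all_spectra.tsv"))
  }
  rep <- c(.report_meta(config),
           list(constraints = constraints, n_matches = nrow(res$matches),
                n_classes = res$n_classes,
                subtype_table = tab))
  files["report"] <- file.path(output_dir, "enumerate.json")
  jsonlite::write_json(rep, files["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' Analyze a structure file and write the full report set
#'
#' @param path structure file (PDB/mmCIF).
#' @param output_dir output directory.
#' @param config a [run_config()].
#' @param graph a `CageGraph`.
#' @return named vector of written file paths, invisibly.
#' @export
cmd_analyze <- function(path, output_dir, config = run_config(),
                        graph = build_cage_graph()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_cage(path, config, graph)
  files <- c(
    subtypes = .write_tsv(res$subtypes, file.path(output_dir, "subtypes.tsv")),
    pores = .write_tsv(.pore_table(res), file.path(output_dir, "pores.tsv")),
    dimers = .write_tsv(res$pairing, file.path(output_dir, "dimers.tsv")),
    interfaces = .write_tsv(res$interfaces$per_dimer,
                            file.path(output_dir, "interfaces.tsv")))
  rep <- c(.report_meta(res$config), list(
    source = res$assembly$source_id,
    n_chains = length(res$assembly$chains),
    chain_types = as.list(table(.chain_types(res$assembly))),
    frame = list(residual = res$frame$fit_residual,
                 center = res$frame$center,
                 fourfold_axes = res$frame$fourfold_axes),
    point_group = list(order = res$point_group$order,
                       generator = res$point_group$generator_axis_class),
    labeling = paste(unclass(res$mapping$labeling), collapse = ""),
    metrics = unclass(res$metrics),
    fc_summary = res$fc_summary,
    interfaces_by_type = res$interfaces$by_type))
  files["report"] <- file.path(output_dir, "analysis.json")
  jsonlite::write_json(rep, files["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

.pore_table <- function(res) {
  do.call(rbind, lapply(res$pores, function(p) data.frame(
    id = p$id, kind = p$kind,
    composition = paste0(p$n_A, ":", p$n_B),
    x = p$center[1], y = p$center[2], z = p$center[3],
    net_charge = charge_profile(p, res$assembly,
                                radius = res$config$lining_radius),
    chains = paste(p$chains, collapse = ","),
    degraded = p$degraded)))
}

#' Write the canonical synthetic fixture set (CLI backend)
#'
#' @param output_dir output directory.
#' @param config a [run_config()] (its `seed` drives any randomised
#'   fixtures).
#' @param graph a `CageGraph`.
#' @return named vector of file paths, invisibly.
#' @export
cmd_simulate <- function(output_dir, config = run_config(),
                         graph = build_cage_graph()) {
  files <- fixture_suite(output_dir, graph)
  rep <- c(.report_meta(config), list(files = as.list(files)))
  jsonlite::write_json(rep, file.path(output_dir, "simulate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
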