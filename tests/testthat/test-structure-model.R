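test_that("writing and re-reading a cage preserves atoms and coordinates", {
  asm <- reference_cage_fx()$assembly
  f <- withr::local_tempfile(fileext = ".pdb")
  write_assembly(asm, f)
  back <- read_assembly(f)
  expect_length(back$chains, 24)
  expect_equal(names(back$chains), names(asm$chains))
  for (ch in names(asm$chains)) {
    a <- asm$chains[[ch]]$atoms
    b <- back$chains[[ch]]$atoms
    expect_equal(nrow(b), nrow(a))
    expect_equal(as.matrix(b[, c("x", "y", "z")]),
                 as.matrix(a[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(b$resname, a$resname)
  }
})

test_that("sequence clustering splits the two subunit types 12 + 12", {
  asm <- reference_cage_fx()$assembly
  types <- vapply(asm$chains, `[[`, "", "subunit_type")
  expect_equal(unname(table(types)[c("A", "B")]), c(12L, 12L),
               ignore_attr = TRUE)
  # the B chains carry the heme-ligand methionine, A chains a lysine
  for (ch in asm$chains) {
    at52 <- ch$atoms$resname[ch$atoms$resno == 52]
    expect_equal(unique(at52), if (ch$subunit_type == "B") "MET" else "LYS")
  }
})

test_that("subunit typing is invariant to chain order", {
  asm <- reference_cage_fx()$assembly
  perm <- rev(seq_along(asm$chains))
  shuffled <- bfrcage:::new_assembly(asm$chains[perm], asm$source_id)
  retyped <- assign_subunit_types(shuffled)
  expect_equal(vapply(retyped$chains, `[[`, "", "subunit_type"),
               vapply(asm$chains, `[[`, "", "subunit_type")[perm])
})

test_that("explicit chain maps and homogeneous cages are handled", {
  asm <- reference_cage_fx()$assembly
  cm <- stats::setNames(rep(c("A", "B"), 12), names(asm$chains))
  mapped <- assign_subunit_types(asm, "map", chain_map = cm)
  expect_equal(vapply(mapped$chains, `[[`, "", "subunit_type"),
               cm)
  expect_error(assign_subunit_types(asm, "map",
                                    chain_map = cm[1:3]), "every chain")
  homo <- homogeneous_cage_fx()
  expect_true(all(vapply(homo$chains, `[[`, "", "subunit_type") == "A"))
})

test_that("a 2-chain dimer file is readable with a cage warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_interface_dimer(f)
  expect_warning(di <- read_assembly(f), "24")
  expect_length(di$chains, 2)
  # cage operations refuse it without the override
  expect_error(detect_dimers(di), "24")
  expect_s3_class(detect_dimers(di, min_contacts = 1, override = TRUE),
                  "DimerPairing")
})

test_that("the role map defaults match the subunit-type chemistry", {
  rm <- load_role_map(NULL)
  expect_equal(rm$B$heme_ligand$resno, 52L)
  expect_equal(rm$B$heme_ligand$resname, "MET")
  expect_equal(nrow(rm$A$heme_ligand), 0L)
  expect_equal(rm$A$fc_residues$resno, c(18L, 51L, 94L, 54L))
  expect_equal(rm$B$fc_residues$resno, c(18L, 51L, 127L, 54L))
  expect_equal(rm$A$fourfold_lining$resno, c(148L, 151L))
  expect_equal(rm$B$fourfold_lining$resno, c(149L, 152L))
  expect_equal(rm$A$threefold_lining$resname, c("GLU", "GLU"))
  expect_equal(rm$B$threefold_lining$resname, c("ASN", "GLU"))
})

test_that("role map YAML overrides are respected and validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("A:", "  fc_residues: [Glu10, His20]"), f)
  rm <- load_role_map(f)
  expect_equal(rm$A$fc_residues$resno, c(10L, 20L))
  expect_equal(rm$A$fc_residues$resname, c("GLU", "HIS"))
  # untouched roles keep defaults
  expect_equal(rm$B$heme_ligand$resname, "MET")
  writeLines(c("A:", "  fc_residues: [Zzz10]"), f)
  expect_error(load_role_map(f), "unknown residue")
  writeLines(c("A:", "  fc_residues: [Glu]"), f)
  expect_error(load_role_map(f), "malformed")
  writeLines(c("A:", "  not_a_role: [Glu10]"), f)
  expect_error(load_role_map(f), "unknown role")
})

test_that("missing role residues are skipped with a warning", {
  asm <- reference_cage_fx()$assembly
  rm <- default_role_map()
  rm$A$fc_residues <- rbind(rm$A$fc_residues,
                            data.frame(resno = 999L, resname = "GLU"))
  ch <- asm$chains[[which(vapply(asm$chains, `[[`, "",
                                 "subunit_type") == "A")[1]]]
  expect_warning(hit <- resolve_role_residues(ch, rm, "fc_residues"), "999")
  expect_setequal(unique(hit$resno), c(18L, 51L, 94L, 54L))
})

test_that("unparseable structure files raise clean errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(read_assembly(f), "parse|atoms")
})
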