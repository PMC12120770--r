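test_that("all 38 pores are detected with graph-consistent compositions", {
  fx <- reference_cage_fx()
  po <- fx$pores
  kinds <- vapply(po, `[[`, "", "kind")
  expect_equal(unname(table(kinds)[c("b_pore", "fourfold", "threefold")]),
               c(24L, 6L, 8L), ignore_attr = TRUE)
  # compositions are consistent with the contributing subunit types
  for (p in po) {
    expect_equal(p$n_A + p$n_B, if (p$kind == "fourfold") 4L else 3L)
    expect_equal(p$n_A, sum(p$types == "A"))
    expect_length(p$chains, if (p$kind == "fourfold") 4L else 3L)
  }
  expect_false(any(vapply(po, `[[`, TRUE, "degraded")))
})

test_that("geometric subtypes reproduce the nine-class inventory", {
  fx <- reference_cage_fx()
  tab <- classify_subtypes(fx$pores, cage_graph_fx())
  expect_equal(nrow(tab), 9L)
  f <- tab[tab$kind == "fourfold", ]
  expect_equal(f$count[match(c("4:0", "1:3", "2:2"), f$composition)],
               c(1L, 2L, 3L))
  b <- tab[tab$kind == "b_pore", ]
  expect_equal(b$count[match(c("3:0", "0:3", "1:2", "2:1"), b$composition)],
               c(4L, 4L, 8L, 8L))
  # member lists are complete
  expect_equal(sum(lengths(strsplit(tab$pores, ","))), 38L)
})

test_that("a homogeneous cage yields three pure subtype classes", {
  homo <- homogeneous_cage_fx()
  pr <- detect_dimers(homo)
  fr <- fit_octahedral_frame(homo, pr)
  po <- detect_pores(homo, fr, pr, graph = cage_graph_fx())
  tab <- classify_subtypes(po, cage_graph_fx())
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$composition, c("3:0", "4:0"))
})

test_that("a composition corrupted after detection is caught", {
  fx <- reference_cage_fx()
  po <- fx$pores
  po[[1]]$n_A <- po[[1]]$n_A + 1L
  po[[1]]$n_B <- po[[1]]$n_B - 1L
  expect_error(classify_subtypes(po, cage_graph_fx()), "disagrees")
})

test_that("the C2 axis connects an all-A and an equal-composition 4-fold pore", {
  fx <- reference_cage_fx()
  pg <- assembly_point_group(fx$assembly, fx$frame)
  gen <- build_octahedral_rotations()[pg$indices]
  gen <- gen[[which(vapply(gen, `[[`, "", "axis_class") == "twofold_face")]]
  g <- cage_graph_fx()
  poles <- which(abs(g$four_dirs %*% gen$axis) > 1 - 1e-6)
  four <- fx$pores[vapply(fx$pores, `[[`, "", "kind") == "fourfold"]
  comps <- vapply(poles, function(f) {
    p <- four[[f]]
    paste0(p$n_A, ":", p$n_B)
  }, "")
  expect_setequal(comps, c("4:0", "2:2"))
})

test_that("lining residues are radius-monotone and distance-sorted", {
  fx <- reference_cage_fx()
  p <- fx$pores[[1]]
  expect_equal(nrow(lining_residues(p, fx$assembly, radius = 0)), 0L)
  l6 <- lining_residues(p, fx$assembly, radius = 6)
  l8 <- lining_residues(p, fx$assembly, radius = 8)
  key <- function(d) paste(d$chain, d$resno)
  expect_true(all(key(l6) %in% key(l8)))
  expect_false(is.unsorted(l8$min_dist))
  expect_true(all(l8$min_dist <= 8))
})

test_that("formal-charge profiles follow the lining chemistry", {
  fx <- reference_cage_fx()
  po <- fx$pores
  kinds <- vapply(po, `[[`, "", "kind")
  nA <- vapply(po, `[[`, 0L, "n_A")
  # all-A B-pore lining: Asp34, Glu66, Asp132, Glu135 -> net -4
  bI <- po[[which(kinds == "b_pore" & nA == 3L)[1]]]
  expect_equal(charge_profile(bI, fx$assembly), -4L)
  # all-B B-pore lining: His34 counts 0 -> net -3
  bII <- po[[which(kinds == "b_pore" & nA == 0L)[1]]]
  expect_equal(charge_profile(bII, fx$assembly), -3L)
  # every B-pore is negative (uptake path for Fe2+)
  expect_true(all(vapply(po[kinds == "b_pore"], charge_profile, 0L,
                         assembly = fx$assembly) < 0))
})

test_that("pore-to-FC distances match the closed-form template geometry", {
  g <- cage_graph_fx()
  fx <- reference_cage_fx()
  R <- bfrcage:::.TEMPLATE_RADIUS
  # independent oracle: compute marker and FC positions from the template
  # placement rule directly (single-donor B-pore cluster, FC at (R-8)*n)
  slot_of <- attr(fx$assembly, "slot_of_chain")
  types <- vapply(fx$assembly$chains, `[[`, "", "subunit_type")
  fc_exp <- R - 8
  nd <- pore_node_directions(g)
  a_slots <- slot_of[types == "A"]
  fc_pos <- g$sub_dirs[a_slots, , drop = FALSE] * fc_exp
  node_key <- vapply(g$b_subunits, function(s) paste(sort(s), collapse = "-"),
                     "")
  po <- fx$pores
  for (p in po[vapply(po, `[[`, "", "kind") == "b_pore"][1:6]) {
    # the pore's true graph node, independent of the frame gauge
    b <- match(paste(sort(unname(slot_of[p$chains])), collapse = "-"),
               node_key)
    single <- g$b_single[b]
    center_exp <- R * bfrcage:::.unit(
      0.85 * nd$b_pore[b, ] + 0.15 * g$sub_dirs[single, ])
    expect_equal(p$center, center_exp, tolerance = 1e-6,
                 ignore_attr = TRUE)
    d_exp <- min(sqrt(rowSums(sweep(fc_pos, 2, center_exp)^2)))
    expect_equal(as.numeric(pore_fc_distance(p, fx$assembly)), d_exp,
                 tolerance = 1e-6)
  }
  # per-kind summary covers every pore kind once
  s <- pore_fc_summary(fx$pores, fx$assembly)
  expect_setequal(s$kind, c("b_pore", "fourfold", "threefold"))
  expect_equal(s$n[match(c("b_pore", "fourfold", "threefold"), s$kind)],
               c(24L, 6L, 8L))
})

test_that("cage diameters recover an exact hollow shell", {
  sh <- shell_assembly(39.4, 61.4)
  dm <- cage_diameters(sh)
  expect_equal(dm$external_diameter, 122.8, tolerance = 0.01)
  expect_equal(dm$internal_diameter, 78.8, tolerance = 0.01)
  expect_gt(dm$external_diameter, dm$internal_diameter)
})

test_that("diameters are rigid-motion invariant and scale-equivariant", {
  g <- cage_graph_fx()
  asm1 <- build_synthetic_cage(reference_labeling_fx(), graph = g)
  dm1 <- cage_diameters(asm1)
  asm2 <- build_synthetic_cage(reference_labeling_fx(), graph = g,
                               radius_scale = 2)
  dm2 <- cage_diameters(asm2)
  expect_equal(dm2$external_diameter, 2 * dm1$external_diameter,
               tolerance = 1e-6)
  expect_equal(dm2$internal_diameter, 2 * dm1$internal_diameter,
               tolerance = 1e-6)
  moved <- asm1
  Rm <- bfrcage:::rotation_about(c(0, 1, 1), 0.7)
  for (ch in names(moved$chains)) {
    a <- moved$chains[[ch]]$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(Rm)
    a$x <- xyz[, 1] - 30; a$y <- xyz[, 2]; a$z <- xyz[, 3] + 12
    moved$chains[[ch]]$atoms <- a
  }
  # invariance holds to the angular resolution of the direction grid
  dm3 <- cage_diameters(moved)
  expect_equal(dm3$external_diameter, dm1$external_diameter,
               tolerance = 0.01)
  expect_equal(dm3$internal_diameter, dm1$internal_diameter,
               tolerance = 0.01)
})
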