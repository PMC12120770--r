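test_that("labeling enumeration is exhaustive and unique", {
  g <- cage_graph_fx()
  lm <- enumerate_labelings(g)
  expect_equal(nrow(lm), choose(12, 6))
  expect_equal(anyDuplicated(apply(lm, 1, paste, collapse = "")), 0L)
  expect_true(all(rowSums(lm) == 6))
  expect_equal(nrow(enumerate_labelings(g, strict = FALSE)), 2^12)
  # degenerate labelings need the relaxation flag
  expect_error(dimer_labeling(rep("A", 12)), "strict")
  expect_s3_class(dimer_labeling(rep("A", 12), strict = FALSE),
                  "DimerLabeling")
})

test_that("a homogeneous cage has one subtype per pore kind", {
  g <- cage_graph_fx()
  sp <- composition_spectrum(g, dimer_labeling(rep("A", 12), strict = FALSE))
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$count[sp$kind == "b_pore"], 24L)
  expect_equal(sp$count[sp$kind == "fourfold"], 6L)
  expect_equal(sp$count[sp$kind == "threefold"], 8L)
  expect_true(all(sp$n_B == 0))
  tab <- subtype_table(sp)
  expect_equal(tab$subtype, rep("I", 3))
})

test_that("conservation laws hold across all strict labelings", {
  g <- cage_graph_fx()
  lm <- enumerate_labelings(g)
  co <- pore_compositions_all(g, lm)
  # each subunit sits in one four-fold, one three-fold and three B-pores
  expect_true(all(rowSums(co$fourfold) == 12))
  expect_true(all(rowSums(co$threefold) == 12))
  expect_true(all(rowSums(co$b_pore) == 36))
  # B-pores: pure and mixed compositions balance for every labeling
  expect_equal(rowSums(co$b_pore == 3), rowSums(co$b_pore == 0))
  expect_equal(rowSums(co$b_pore == 2), rowSums(co$b_pore == 1))
  # three-fold pores: the sharp law ties the mixed imbalance to the pure
  # imbalance (equality holds exactly when no pure three-fold is present)
  t30 <- rowSums(co$threefold == 3); t03 <- rowSums(co$threefold == 0)
  t21 <- rowSums(co$threefold == 2); t12 <- rowSums(co$threefold == 1)
  expect_equal(t12 - t21, 3L * (t30 - t03))
  pure_absent <- t30 == 0 & t03 == 0
  expect_true(all(t21[pure_absent] == t12[pure_absent]))
  # and the balance is genuinely conditional: some labelings break it
  expect_gt(sum(t21 != t12), 0)
})

test_that("swapping A and B mirrors every spectrum", {
  g <- cage_graph_fx()
  lm <- enumerate_labelings(g)
  set.seed(42)
  for (i in sample(nrow(lm), 25)) {
    sp <- composition_spectrum(g, lm[i, ])
    sw <- composition_spectrum(g, !lm[i, ])
    sw2 <- sw[, c("kind", "n_B", "n_A", "count")]
    names(sw2) <- c("kind", "n_A", "n_B", "count")
    sw2 <- sw2[order(sw2$kind, -sw2$n_A), ]
    rownames(sw2) <- NULL
    expect_equal(as.data.frame(sp), as.data.frame(sw2),
                 ignore_attr = TRUE)
  }
})

test_that("automorphism groups obey Lagrange and the known extremes", {
  g <- cage_graph_fx()
  expect_equal(labeling_automorphisms(
    g, dimer_labeling(rep("A", 12), strict = FALSE))$order, 24L)
  lm <- enumerate_labelings(g)
  orders <- vapply(seq_len(nrow(lm)), function(i)
    labeling_automorphisms(g, lm[i, ])$order, 0L)
  expect_true(all(24L %% orders == 0L))
  aut <- labeling_automorphisms(g, reference_labeling_fx())
  expect_equal(aut$order, 2L)
  gen <- aut$rotations[[which(vapply(aut$rotations, `[[`, "", "axis_class")
                              != "identity")]]
  expect_equal(gen$axis_class, "twofold_face")
})

test_that("the constrained search isolates the hetero-cage arrangement", {
  g <- cage_graph_fx()
  res <- find_arrangements(g,
                           fourfold_comps = c("4:0", "1:3", "2:2"),
                           threefold_comps = c("2:1", "1:2"),
                           automorphism_order = 2,
                           axis_pore_comps = c("4:0", "2:2"))
  expect_gt(nrow(res$matches), 0)
  expect_equal(res$n_classes, 1L)
  sp <- composition_spectrum(g, res$matches[1, ])
  expect_equal(nrow(sp), 9L)
  tab <- subtype_table(sp)
  b <- tab[tab$kind == "b_pore", ]
  expect_equal(b$count[b$composition %in% c("1:2", "2:1")], c(8L, 8L))
  expect_equal(b$count[b$composition %in% c("3:0", "0:3")], c(4L, 4L))
  f <- tab[tab$kind == "fourfold", ]
  expect_equal(f$count[match(c("4:0", "1:3", "2:2"), f$composition)],
               c(1L, 2L, 3L))
  expect_equal(tab$count[tab$kind == "threefold"], c(4L, 4L))
  # subtype numbering follows the listing order
  expect_equal(b$subtype, c("I", "II", "III", "IV"))
})

test_that("impossible and empty constraint sets behave sanely", {
  g <- cage_graph_fx()
  # strict labelings can never have only pure three-fold pores
  res <- find_arrangements(g, threefold_comps = c("3:0", "0:3"))
  expect_equal(nrow(res$matches), 0L)
  expect_equal(res$n_classes, 0L)
  # no constraints returns everything
  expect_equal(nrow(find_arrangements(g)$matches), 924L)
})
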