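test_that("L0 register arithmetic: d is +1, g is position -4", {
  # hinge chosen so positions -4..-1 are V,K,A,E
  s <- paste0("N", "AAAAAAA", "R", "AAAAA", "VKAE",
              "LEQKAAA", "LAAAAAA")
  d <- find_bzip_domains(s, "t")[[1]]
  z <- register_heptads(d)
  expect_equal(z$heptads[[1]][["d"]], "L")
  expect_equal(z$heptads[[1]][["g"]], "V")       # residue at -4
  expect_equal(unname(d$residue_at["-4"]), "V")
  expect_equal(z$heptads[[1]][["e"]], "E")       # +2
  # register cycle property: register r of heptad k sits at g0 + 7k + offset
  g0 <- d$zipper_start - 4L
  regs <- c("g", "a", "b", "c", "d", "e", "f")
  sch <- strsplit(s, "")[[1]]
  for (k in seq_along(z$heptads)) {
    h <- z$heptads[[k]]
    for (j in seq_along(regs)) {
      if (regs[j] %in% names(h))
        expect_equal(h[[regs[j]]], sch[g0 + 7 * (k - 1) + j - 1])
    }
  }
})

test_that("zipper termination records the boundary cause", {
  hp <- c("LAAAAAA", "LAAAAAA", "LAAAAAA", "LAAAAAA", "LAAAAAA")
  # proline right after 5 heptads
  s_pro <- planted_sequence(heptads = hp, flank_c = "PGGGGGG")
  z <- register_heptads(find_bzip_domains(s_pro, "p")[[1]])
  expect_equal(z$n_heptads, 5)
  expect_equal(z$end_reason, "helix_break")
  # 12 heptads, cap at 9
  s_12 <- planted_sequence(heptads = rep("LAAAAAA", 12))
  z12 <- register_heptads(find_bzip_domains(s_12, "c")[[1]], max_heptads = 9)
  expect_equal(z12$n_heptads, 9)
  expect_equal(z12$end_reason, "max_heptads")
  # sequence simply ends
  z_end <- register_heptads(find_bzip_domains(planted_sequence(), "e")[[1]])
  expect_equal(z_end$end_reason, "sequence_end")
  expect_true(z_end$accepted)
  # a non-hydrophobic d register ends the zipper and is excluded
  s_d <- planted_sequence(heptads = c("LAAAAAA", "LAAAAAA", "QAAAAAA"),
                          flank_c = "GGGG")
  zd <- register_heptads(find_bzip_domains(s_d, "d")[[1]])
  expect_equal(zd$n_heptads, 2)
  expect_equal(zd$end_reason, "d_register_failure")
})

test_that("g-e' classification matches the legend on all 400 ordered pairs", {
  for (g in bzipr:::AA_STANDARD) {
    for (e in bzipr:::AA_STANDARD) {
      expect_equal(classify_ge_pair(g, e), oracle_ge_category(g, e),
                   info = paste(g, e))
    }
  }
  # the lookup is ordered/asymmetric
  expect_equal(classify_ge_pair("R", "E"), "attractive_basic_acidic")
  expect_equal(classify_ge_pair("E", "R"), "attractive_acidic_basic")
  expect_equal(classify_ge_pair("K", "K"), "repulsive_basic")
  expect_equal(classify_ge_pair("A", "A"), "none")
  expect_equal(classify_ge_pair("D", "R"), "complete_unlisted")
})

test_that("pair enumeration honours the register rule and boundaries", {
  # one complete heptad plus a bare +1 leucine: same_heptad pairs only L0
  s1 <- paste0("N", "AAAAAAA", "R", "AAAAA", "EKAA", "LEAAAAA", "GGGG")
  z1 <- register_heptads(find_bzip_domains(s1, "b", min_heptads = 1)[[1]])
  expect_equal(nrow(ge_pairs(z1, "same_heptad")),
               sum(vapply(z1$heptads, function(h)
                 all(c("g", "e") %in% names(h)), TRUE)))
  # planted E/K at g/e of every heptad -> all pairs attractive_acidic_basic
  s2 <- paste0("N", "AAAAAAA", "R", "AAAAA", "EAAA",
               "LKA", "EAAA", "LKA", "EAAA", "LKA")
  z2 <- register_heptads(find_bzip_domains(s2, "ek")[[1]])
  p2 <- ge_pairs(z2, "same_heptad")
  expect_true(all(p2$category == "attractive_acidic_basic"))
  # next_heptad yields one fewer pair and shifts attribution to e's heptad
  pn <- ge_pairs(z2, "next_heptad")
  expect_equal(nrow(pn), nrow(p2) - 1)
  expect_true(all(pn$heptad_index >= 1))
})

test_that("pair enumeration equals brute force over registers", {
  set.seed(21)
  spec <- synthetic_spec(n_proteins = 1,
                         intron_pattern_counts = c(a = 1))
  for (i in 1:20) {
    p <- make_protein(spec, id = paste0("z", i))
    z <- register_heptads(find_bzip_domains(p$record$sequence, "z")[[1]])
    got <- ge_pairs(z, "same_heptad")
    for (k in seq_along(z$heptads)) {
      h <- z$heptads[[k]]
      if (all(c("g", "e") %in% names(h))) {
        row <- got[got$heptad_index == k - 1, ]
        expect_equal(nrow(row), 1)
        expect_equal(row$category, oracle_ge_category(h[["g"]], h[["e"]]))
      }
    }
  }
})

test_that("composition stats pool occupied registers and sum to one", {
  s1 <- planted_sequence(heptads = rep("LAAAAAA", 3))
  s2 <- planted_sequence(heptads = c("LAAAAAA", "IAAAAAA"))
  zs <- lapply(list(c(s1, "a"), c(s2, "b")), function(x)
    register_heptads(find_bzip_domains(x[1], x[2])[[1]]))
  comp <- composition_stats(zs)
  dtab <- comp$table[comp$table$register == "d", ]
  expect_equal(dtab$freq[dtab$residue == "L"], 0.8)  # 4 of 5 d registers
  expect_equal(dtab$freq[dtab$residue == "I"], 0.2)
  for (r in unique(comp$table$register))
    expect_equal(sum(comp$table$freq[comp$table$register == r]), 1,
                 tolerance = 1e-9)
  expect_error(composition_stats(list()), "no zipper")
  # register rule never changes composition
  expect_identical(comp, composition_stats(zs))
})

test_that("asn histogram uses per-heptad denominators", {
  # N at the a register of L2 only (a of L2 = position +10)
  s <- paste0("N", "AAAAAAA", "R", "AAAAAAAAA",
              "LAA", "AAAA", "LAA", "ANAA", "LAA", "AAAA")
  z <- register_heptads(find_bzip_domains(s, "n")[[1]])
  h <- asn_per_heptad(list(z))
  expect_equal(h$asn_fraction[h$heptad_index == 2], 1)
  expect_true(all(h$asn_fraction[h$heptad_index != 2] == 0))
  # no Asn anywhere -> all-zero histogram
  z0 <- register_heptads(find_bzip_domains(planted_sequence(), "0")[[1]])
  expect_true(all(asn_per_heptad(list(z0))$asn_fraction == 0))
})

test_that("dimerization types key on both heptad count and pair string", {
  sig <- data.frame(protein_id = c("a", "b", "c", "d"),
                    n_heptads = c(4, 4, 5, 4),
                    pair_string = c("GGRR", "GGRR", "GGRR", "BBRR"),
                    stringsAsFactors = FALSE)
  typed <- dimerization_types(sig)
  expect_equal(typed$type_id, c(1, 1, 2, 3))
  expect_equal(attr(typed, "n_types"), 3)
})
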