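small_spec <- function(n = 6, counts = c(a = 1, b = 1, c = 1, d = 1,
                                         e = 1, intronless = 1), ...) {
  synthetic_spec(n_proteins = n, intron_pattern_counts = counts, ...)
}

test_that("planted cores are recovered exactly by the scanner", {
  set.seed(51)
  spec <- small_spec()
  for (i in 1:30) {
    p <- make_protein(spec, id = paste0("s", i))
    doms <- find_bzip_domains(p$record$sequence, p$record$id)
    expect_length(doms, 1)
    expect_equal(doms[[1]]$core_start, p$truth$core_start)
    expect_equal(doms[[1]]$zipper_start, p$truth$zipper_start)
    expect_equal(doms[[1]]$n_qualifying_heptads, p$truth$n_heptads)
  }
})

test_that("planted registers and pair categories round-trip through registration", {
  set.seed(52)
  spec <- small_spec()
  for (i in 1:20) {
    p <- make_protein(spec, id = paste0("r", i))
    z <- register_heptads(find_bzip_domains(p$record$sequence, "r")[[1]])
    expect_equal(z$n_heptads, p$truth$n_heptads)
    for (k in seq_len(p$truth$n_heptads))
      expect_equal(z$heptads[[k]][c("g", "a", "d", "e")],
                   p$truth$registers[[k]][c("g", "a", "d", "e")])
    got <- ge_pairs(z, "same_heptad")
    expect_equal(got$category[seq_len(p$truth$n_heptads)],
                 unname(p$truth$pair_categories))
  }
})

test_that("forced register distributions appear verbatim", {
  set.seed(53)
  spec <- small_spec(reg_a = c(N = 1.0))
  p <- make_protein(spec, "alln")
  a_res <- vapply(p$truth$registers, `[[`, "", "a")
  expect_true(all(a_res == "N"))
  z <- register_heptads(find_bzip_domains(p$record$sequence, "alln")[[1]])
  expect_true(all(vapply(z$heptads[seq_len(z$n_heptads)], `[[`, "", "a") == "N"))
})

test_that("pair-category targets are realized per heptad", {
  set.seed(54)
  spec <- small_spec(pair_targets = c(repulsive_basic = 1.0))
  p <- make_protein(spec, "rb")
  expect_true(all(p$truth$pair_categories == "repulsive_basic"))
  spec2 <- small_spec(pair_targets = c(incomplete_acidic = 0.5,
                                       none = 0.5))
  p2 <- make_protein(spec2, "mix")
  expect_true(all(p2$truth$pair_categories %in% c("incomplete_acidic", "none")))
})

test_that("the generator is deterministic under a seed", {
  spec <- small_spec()
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(spec, seed = 99, out_dir = d1)
  c2 <- generate_cohort(spec, seed = 99, out_dir = d2)
  expect_identical(c1$truth_table, c2$truth_table)
  expect_identical(readLines(c1$paths$proteins), readLines(c2$paths$proteins))
  expect_identical(readLines(c1$paths$gff3), readLines(c2$paths$gff3))
  c3 <- generate_cohort(spec, seed = 100)
  expect_false(identical(c1$truth_table$core_start, c3$truth_table$core_start))
})

test_that("emitted gene models re-derive the planted intron truth", {
  set.seed(55)
  spec <- small_spec()
  co <- generate_cohort(spec, seed = 7, out_dir = tempfile())
  seqs <- read_protein_fasta(co$paths$proteins)
  models <- read_gene_models(co$paths$gff3)
  genome <- Biostrings::readDNAStringSet(co$paths$genome)
  for (i in seq_len(nrow(co$truth_table))) {
    id <- co$truth_table$protein_id[i]
    m <- normalize_stop_codon(models[[id]], nchar(seqs[[id]]))
    intr <- derive_introns(m)
    truth_bp <- co$truth_table$introns[i]
    got <- paste(sprintf("%d:P%d", intr$cds_offset, intr$phase), collapse = ";")
    expect_equal(got, truth_bp, info = id)
    # CDS conservation: segment lengths total 3 x protein length
    expect_equal(bzipr:::cds_length(m), 3L * nchar(seqs[[id]]))
    # the spliced CDS actually translates back to the protein
    seg <- m$cds_segments
    pieces <- vapply(seq_len(nrow(seg)), function(j) {
      sub <- Biostrings::subseq(genome[[id]], min(seg[j, ]), max(seg[j, ]))
      if (m$strand == "-") sub <- Biostrings::reverseComplement(sub)
      as.character(sub)
    }, "")
    cds <- Biostrings::DNAString(paste(pieces, collapse = ""))
    aa <- as.character(Biostrings::translate(cds))
    expect_equal(aa, seqs[[id]], info = id)
  }
})

test_that("infeasible specs and missing seeds are rejected", {
  expect_error(synthetic_spec(reg_a = c(N = 0.5)), "sum to 1")
  expect_error(synthetic_spec(intron_pattern_counts = c(a = 3)),
               "sum to n_proteins")
  expect_error(synthetic_spec(flank_n_range = c(2, 10)), ">= 8")
  expect_error(synthetic_spec(reg_d = c(L = 0.5, A = 0.5)), "d-register")
  expect_error(generate_cohort(small_spec()), "seed")
})

test_that("an empty cohort still writes schema-valid outputs", {
  co <- generate_cohort(small_spec(n = 0, counts = integer(0)), seed = 1,
                        out_dir = tempfile())
  expect_equal(nrow(co$truth_table), 0)
  expect_true(file.exists(co$paths$gff3))
  expect_equal(nrow(read_pipeline_table(co$paths$truth)), 0)
})

test_that("config files drive the generator", {
  f <- tempfile()
  writeLines(c("seed: 5", "n_proteins: 4",
               "pattern_counts: a=2,e=1,intronless=1",
               "flank_n_min: 10", "flank_n_max: 20"), f)
  conf <- read_synthetic_config(f)
  expect_equal(conf$seed, 5L)
  expect_equal(conf$spec$n_proteins, 4L)
  expect_equal(unname(conf$spec$intron_pattern_counts["a"]), 2L)
  expect_error(read_synthetic_config({
    g <- tempfile(); writeLines("n_proteins: 3", g); g
  }), "seed")
})
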