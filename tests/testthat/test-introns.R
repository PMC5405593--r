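test_that("splice phase is the coding offset modulo three", {
  m0 <- gene_model("g0", "+", rbind(c(1, 9), c(100, 399)))
  i0 <- derive_introns(m0)
  expect_equal(i0$cds_offset, 9L)
  expect_equal(i0$phase, 0L)
  m1 <- gene_model("g1", "+", rbind(c(1, 10), c(100, 398)))
  expect_equal(derive_introns(m1)$phase, 1L)
  m2 <- gene_model("g2", "+", rbind(c(1, 11), c(100, 397)))
  expect_equal(derive_introns(m2)$phase, 2L)
  expect_error(derive_introns(gene_model("g3", "+", rbind(c(1, 10)))),
               "divisible by 3")
})

test_that("phase arithmetic holds over random multi-exon models", {
  set.seed(31)
  for (i in 1:50) {
    nseg <- sample(2:6, 1)
    lens <- sample(3:200, nseg, replace = TRUE)
    lens[nseg] <- lens[nseg] + (3 - sum(lens) %% 3) %% 3
    gaps <- sample(60:300, nseg - 1, replace = TRUE)
    starts <- cumsum(c(1, lens[-nseg] + gaps))
    m <- gene_model("r", "+", cbind(starts, starts + lens - 1))
    intr <- derive_introns(m)
    expect_equal(intr$phase, intr$cds_offset %% 3)
    expect_equal(nrow(intr), nseg - 1)
  }
})

test_that("mirrored minus-strand models yield identical intron calls", {
  seg <- rbind(c(1, 9), c(100, 150), c(300, 362))
  plus <- gene_model("p", "+", seg)
  L <- 500
  # same transcription order: the first coding exon gets mirrored coords
  mseg <- cbind(L - seg[, 2] + 1, L - seg[, 1] + 1)
  minus <- gene_model("p", "-", mseg)
  ip <- derive_introns(plus); im <- derive_introns(minus)
  expect_equal(ip$cds_offset, im$cds_offset)
  expect_equal(ip$phase, im$phase)
})

test_that("intron-to-domain mapping follows the junction convention", {
  # domain with zipper at residue 28 (flank of 9 upstream of the core)
  s <- planted_sequence(flank_n = strrep("G", 9))
  dom <- find_bzip_domains(s, "m")[[1]]
  zs <- dom$zipper_start  # 28
  # phase-0 junction right after the codon of residue -6
  r6 <- zs - 6
  intr <- data.frame(gene_id = "m", intron_index = 1L,
                     cds_offset = 3L * r6, phase = 0L)
  mapped <- map_to_domain(intr, dom)
  expect_equal(mapped$domain_position, -6L)
  # phase-2 junction inside the codon after residue -22
  r22 <- zs - 22
  intr2 <- data.frame(gene_id = "m", intron_index = 1L,
                      cds_offset = 3L * r22 + 2L, phase = 2L)
  expect_equal(map_to_domain(intr2, dom)$domain_position, -22L)
  # junction 30 codons downstream of +1 is outside the window
  intr3 <- data.frame(gene_id = "m", intron_index = 1L,
                      cds_offset = 3L * (zs + 30L), phase = 0L)
  expect_true(is.na(map_to_domain(intr3, dom)$domain_position))
})

test_that("the five patterns and the unassigned fallback classify correctly", {
  ev <- function(pos, ph) data.frame(
    gene_id = rep("g", length(pos)), intron_index = seq_along(pos),
    cds_offset = rep(NA_integer_, length(pos)), phase = ph,
    domain_position = pos)
  expect_equal(classify_pattern(ev(-6L, 0L), "g")$pattern, "a")
  expect_equal(classify_pattern(ev(-22L, 0L), "g")$pattern, "b")
  expect_equal(classify_pattern(ev(-22L, 2L), "g")$pattern, "c")
  expect_equal(classify_pattern(ev(c(-26L, -5L), c(0L, 0L)), "g")$pattern, "d")
  # introns only outside the region: e, not intronless
  out <- classify_pattern(ev(c(NA, NA, NA), c(0L, 1L, 2L)), "g")
  expect_equal(out$pattern, "e")
  expect_false(out$intronless)
  # zero introns: e with the intronless flag
  none <- classify_pattern(ev(integer(0), integer(0)), "g")
  expect_equal(none$pattern, "e")
  expect_true(none$intronless)
  # region evidence matching no rule is never forced into a class
  expect_equal(classify_pattern(ev(-6L, 2L), "g")$pattern, "unassigned")
  expect_equal(classify_pattern(ev(c(-6L, -22L), c(0L, 0L)), "g")$pattern,
               "unassigned")
})

test_that("cohort summary tallies patterns and the intronless fraction", {
  calls <- data.frame(
    gene_id = paste0("g", 1:10),
    pattern = c(rep("a", 4), rep("e", 5), "c"),
    intronless = c(rep(FALSE, 8), TRUE, TRUE),
    n_introns = c(rep(2L, 8), 0L, 0L),
    evidence = "")
  cs <- cohort_summary(calls)
  expect_equal(unname(cs$pattern_counts["a"]), 4L)
  expect_equal(unname(cs$pattern_counts["e"]), 5L)
  expect_equal(cs$intronless_fraction, 0.2)
  clades <- data.frame(gene_id = calls$gene_id,
                       clade = rep(c("A", "S"), each = 5))
  cs2 <- cohort_summary(calls, clades)
  expect_equal(sum(cs2$by_clade), 10)
  expect_equal(unname(cs2$by_clade["A", "a"]), 4L)
})

test_that("stop-codon dialects are normalized on read", {
  # CDS including a stop codon: 3 * protein_length + 3
  m <- gene_model("s", "+", rbind(c(1, 30), c(101, 109)))
  norm <- normalize_stop_codon(m, 12)  # 39 = 3*12 + 3
  expect_equal(bzipr:::cds_length(norm), 36L)
  expect_equal(unname(norm$cds_segments[2, "end"]), 106L)
  # trim across a segment boundary (terminal segment shorter than 3)
  m2 <- gene_model("s2", "+", rbind(c(1, 34), c(101, 102)))
  norm2 <- normalize_stop_codon(m2, 11)
  expect_equal(bzipr:::cds_length(norm2), 33L)
  expect_equal(nrow(norm2$cds_segments), 1L)
  # exact CDS is untouched; disagreement errors
  expect_identical(normalize_stop_codon(m, 13), m)
  expect_error(normalize_stop_codon(m, 10), "does not match")
})

test_that("gene models survive a GFF3 write/read round trip on both strands", {
  m_plus <- gene_model("gp", "+", rbind(c(10, 30), c(101, 130), c(200, 238)))
  m_minus <- gene_model("gm", "-", rbind(c(200, 238), c(101, 130), c(10, 30)))
  f <- tempfile(fileext = ".gff3")
  write_gene_models(list(gp = m_plus, gm = m_minus), f)
  back <- read_gene_models(f)
  expect_setequal(names(back), c("gp", "gm"))
  expect_equal(back$gp$cds_segments, m_plus$cds_segments)
  expect_equal(back$gm$cds_segments, m_minus$cds_segments)
  expect_equal(back$gm$strand, "-")
  # splice phases identical either way
  expect_equal(derive_introns(back$gm)$phase, derive_introns(m_minus)$phase)
})

test_that("gene structure JSON export carries exons and phases", {
  m <- gene_model("j", "+", rbind(c(1, 9), c(100, 399)))
  js <- gene_structure_json(m)
  expect_equal(length(js$exons), 2)
  expect_equal(js$introns[[1]]$phase, 0)
  expect_silent(jsonlite::toJSON(js, auto_unbox = TRUE))
})
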