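# Synthetic cohorts with planted, fully known bZIP structure: an invariant
# N-X7-R/K core, a 9-residue hinge, 2-9 leucine heptads with controllable
# register residues and g-e' pair categories, and gene models realizing the
# five basic-hinge intron patterns on either strand.

# Alphabet for unconstrained positions: no Asn (cannot seed a spurious
# anchor), no L/I/V/M/F (cannot extend a d-register run), no Pro.
NEUTRAL_ALPHABET <- c("A", "G", "S", "T", "Q", "E", "D", "H", "W", "Y",
                      "C", "K", "R")
# Non-chargeable pool for realizing incomplete/none g-e' pairs.
NONCHARGEABLE_POOL <- c("A", "S", "T", "G", "H", "Y", "N", "M", "V")

#' Specification for a synthetic bZIP cohort
#'
#' Defaults emulate the structure reported for the strawberry bZIP family:
#' zippers of two to nine heptads; roughly 18% Asn at the a register;
#' Leu-dominated d registers; half-charged e and g registers; and the
#' intron-pattern mixture with 14 pattern-a genes, 14 pattern-e genes and
#' 10 intronless genes out of 50 (the unpublished b/c/d split is fixed at
#' 8/7/7).
#'
#' @param n_proteins Cohort size.
#' @param heptad_count_probs Named probabilities over heptad counts 2..9.
#' @param reg_a,reg_d,reg_e,reg_g Named residue probability vectors for
#'   the a, d, e and g registers. `reg_d` must be supported on L,I,V,M,F.
#' @param pair_targets Optional named probability vector over g-e' pair
#'   categories; when given it overrides `reg_g`/`reg_e` at every heptad.
#' @param intron_pattern_counts Named integer counts over
#'   a,b,c,d,e,intronless summing to `n_proteins`.
#' @param flank_n_range,flank_c_range Integer ranges for the N-/C-terminal
#'   flank lengths (N flank >= 8 keeps position -26 inside the sequence).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_proteins = 50,
    heptad_count_probs = c("2" = 0.05, "3" = 0.10, "4" = 0.20, "5" = 0.20,
                           "6" = 0.20, "7" = 0.10, "8" = 0.10, "9" = 0.05),
    reg_a = c(N = 0.18, V = 0.20, L = 0.15, I = 0.10, A = 0.12,
              K = 0.05, R = 0.05, E = 0.05, T = 0.05, S = 0.05),
    reg_d = c(L = 0.80, I = 0.08, V = 0.06, M = 0.04, F = 0.02),
    reg_e = c(E = 0.25, K = 0.12, R = 0.08, D = 0.05, Q = 0.10,
              A = 0.10, S = 0.10, T = 0.08, N = 0.06, M = 0.06),
    reg_g = c(E = 0.20, K = 0.15, R = 0.10, D = 0.05, Q = 0.10,
              A = 0.10, S = 0.10, T = 0.08, N = 0.06, M = 0.06),
    pair_targets = NULL,
    intron_pattern_counts = c(a = 14, b = 8, c = 7, d = 7, e = 4,
                              intronless = 10),
    flank_n_range = c(8, 40),
    flank_c_range = c(10, 60)) {
  for (p in list(heptad_count_probs, reg_a, reg_d, reg_e, reg_g)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("probability vectors must be non-negative and sum to 1")
  }
  if (!all(names(reg_d) %in% D_REGISTER_SET))
    stop("reg_d must be supported on the d-register set (L,I,V,M,F)")
  if (!is.null(pair_targets)) {
    if (any(pair_targets < 0) || abs(sum(pair_targets) - 1) > 1e-9)
      stop("pair_targets must be a probability vector")
    if (!all(names(pair_targets) %in% GE_CATEGORIES))
      stop("unknown pair category in pair_targets")
  }
  counts <- intron_pattern_counts
  if (sum(counts) != n_proteins)
    stop("intron_pattern_counts must sum to n_proteins")
  if (flank_n_range[1] < 8) stop("N flank must be >= 8 (position -26)")
  structure(list(n_proteins = n_proteins,
                 heptad_count_probs = heptad_count_probs,
                 reg_a = reg_a, reg_d = reg_d, reg_e = reg_e, reg_g = reg_g,
                 pair_targets = pair_targets,
                 intron_pattern_counts = counts,
                 flank_n_range = flank_n_range,
                 flank_c_range = flank_c_range),
            class = "synthetic_spec")
}

draw <- function(probs, n = 1L) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Realize a (g, e) residue pair of the requested category.
realize_ge_pair <- function(category) {
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  if (category %in% GE_PAIR_TABLE) {
    keys <- names(GE_PAIR_TABLE)[GE_PAIR_TABLE == category]
    strsplit(pick(keys), "|", fixed = TRUE)[[1]]
  } else if (category == "complete_unlisted") {
    all <- expand.grid(g = CHARGEABLE_SET, e = CHARGEABLE_SET,
                       stringsAsFactors = FALSE)
    keys <- paste(all$g, all$e, sep = "|")
    unlisted <- all[!(keys %in% names(GE_PAIR_TABLE)), ]
    i <- sample(nrow(unlisted), 1L)
    c(unlisted$g[i], unlisted$e[i])
  } else if (category == "incomplete_basic") {
    side <- pick(c("R", "K")); other <- pick(NONCHARGEABLE_POOL)
    if (sample(2L, 1L) == 1L) c(side, other) else c(other, side)
  } else if (category == "incomplete_acidic") {
    side <- pick(c("E", "D", "Q")); other <- pick(NONCHARGEABLE_POOL)
    if (sample(2L, 1L) == 1L) c(side, other) else c(other, side)
  } else if (category == "none") {
    c(pick(NONCHARGEABLE_POOL), pick(NONCHARGEABLE_POOL))
  } else stop("cannot realize category ", category)
}

build_planted_sequence <- function(spec, n_heptads) {
  neutral <- function(n) sample(NEUTRAL_ALPHABET, n, replace = TRUE)
  flank_n <- sample(spec$flank_n_range[1]:spec$flank_n_range[2], 1L)
  flank_c <- sample(spec$flank_c_range[1]:spec$flank_c_range[2], 1L)
  registers <- vector("list", n_heptads)
  for (k in seq_len(n_heptads)) {
    if (!is.null(spec$pair_targets)) {
      cat_k <- draw(spec$pair_targets)
      ge <- realize_ge_pair(cat_k)
      g <- ge[1]; e <- ge[2]
    } else {
      g <- draw(spec$reg_g); e <- draw(spec$reg_e)
    }
    registers[[k]] <- c(g = g, a = draw(spec$reg_a), b = neutral(1),
                        c = neutral(1),
                        d = if (k == 1L) "L" else draw(spec$reg_d),
                        e = e, f = neutral(1))
  }
  # core: N, X7, R/K; hinge: 5 neutral then g,a,b,c of L0 (positions -4..-1)
  core <- c("N", neutral(7), sample(c("R", "K"), 1L))
  hinge_free <- neutral(5)
  l0 <- registers[[1]]
  zipper <- unlist(lapply(registers[-1], unname))
  seq_chars <- c(neutral(flank_n), core, hinge_free,
                 l0[c("g", "a", "b", "c")],
                 l0[c("d", "e", "f")], zipper,
                 "P", neutral(flank_c))
  list(sequence = paste(seq_chars, collapse = ""),
       core_start = flank_n + 1L,
       zipper_start = flank_n + 19L,
       registers = registers)
}

#' Generate one protein with planted bZIP structure
#'
#' The emitted sequence contains exactly one basic-hinge core: flanks and
#' free positions are drawn from an alphabet that cannot seed anchors or
#' extend d-register runs, and the whole sequence is rejection-sampled
#' (up to `max_tries`) until the motif scanner recovers exactly the
#' planted core.
#'
#' @param spec A `synthetic_spec`.
#' @param id Protein identifier.
#' @param max_tries Rejection-sampling cap; exceeded caps raise an error
#'   rather than emit an ambiguous sequence.
#' @return List with `record` (`id`, `sequence`) and `truth` (`core_start`,
#'   `zipper_start`, `n_heptads`, per-heptad `registers`, and
#'   `pair_categories` implied by the planted g/e residues).
#' @export
make_protein <- function(spec, id = "syn1", max_tries = 1000L) {
  n_heptads <- as.integer(draw(spec$heptad_count_probs))
  for (try in seq_len(max_tries)) {
    built <- build_planted_sequence(spec, n_heptads)
    found <- find_bzip_domains(built$sequence, id = id, min_heptads = 2)
    if (length(found) == 1L &&
        found[[1]]$core_start == built$core_start &&
        found[[1]]$n_qualifying_heptads == n_heptads) {
      cats <- vapply(built$registers, function(h)
        classify_ge_pair(h[["g"]], h[["e"]]), "")
      return(list(
        record = list(id = id, sequence = built$sequence),
        truth = list(protein_id = id,
                     core_start = built$core_start,
                     zipper_start = built$zipper_start,
                     n_heptads = n_heptads,
                     registers = built$registers,
                     pair_categories = cats)))
    }
  }
  stop("could not generate an unambiguous planted sequence in ",
       max_tries, " tries")
}

# Intron breakpoints (cds_offset, phase) realizing a pattern for a protein
# whose +1 leucine is residue `zs` (1-based).
pattern_breakpoints <- function(pattern, zs, protein_length, n_decoys) {
  bp <- switch(pattern,
    a = data.frame(cds_offset = 3L * (zs - 6L), phase = 0L),
    b = data.frame(cds_offset = 3L * (zs - 22L), phase = 0L),
    c = data.frame(cds_offset = 3L * (zs - 22L) + 2L, phase = 2L),
    d = data.frame(cds_offset = 3L * c(zs - 26L, zs - 5L), phase = c(0L, 0L)),
    e = local({
      if (n_decoys == 0L)
        return(data.frame(cds_offset = integer(0), phase = integer(0)))
      # decoy residues strictly downstream of the domain window
      lo <- zs + 3L; hi <- protein_length - 2L
      if (hi - lo + 1L < n_decoys)
        stop("protein too short for ", n_decoys, " decoy introns")
      r <- sort(sample(lo:hi, n_decoys))
      ph <- sample(0:2, n_decoys, replace = TRUE)
      data.frame(cds_offset = 3L * r + ph, phase = ph)
    }),
    intronless = data.frame(cds_offset = integer(0), phase = integer(0)),
    stop("unknown pattern ", pattern))
  if (nrow(bp) > 0 && any(bp$cds_offset <= 0L | bp$cds_offset >= 3L * protein_length))
    stop("pattern ", pattern, " breakpoint outside CDS (domain truncated?)")
  bp
}

AA_TO_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

back_translate <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  codons <- vapply(s, function(a) {
    opts <- AA_TO_CODONS[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste(codons, collapse = "")
}

random_intron_body <- function() {
  len <- sample(60:500, 1L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate a gene model realizing a requested intron pattern
#'
#' Back-translates the protein with uniform synonymous codons, inserts
#' GT..AG introns (length 60-500) at the junctions realizing the
#' requested pattern's domain-relative positions and phases, pads both
#' ends with random genomic sequence, and (for minus-strand emission)
#' reverse-complements the whole locus with mirrored coordinates.
#'
#' @param protein List with `id` and `sequence` (as from [make_protein()]).
#' @param pattern One of `"a".."e"` or `"intronless"`.
#' @param zipper_start 1-based residue index of the +1 leucine.
#' @param strand `"+"` or `"-"`.
#' @param n_decoys Number of decoy introns outside the basic-hinge region
#'   for pattern e (0-3).
#' @return List with `model` (a `gene_model`), `genomic` (sequence string),
#'   and `truth` (`pattern`, breakpoints data frame).
#' @export
make_gene_model <- function(protein, pattern, zipper_start, strand = "+",
                            n_decoys = sample(1:3, 1L)) {
  L <- nchar(protein$sequence)
  if (pattern %in% c("b", "c") && zipper_start < 23L)
    stop("domain truncated above -22; cannot realize pattern ", pattern)
  if (pattern == "d" && zipper_start < 27L)
    stop("domain truncated above -26; cannot realize pattern d")
  bp <- pattern_breakpoints(pattern, zipper_start, L, n_decoys)
  cds <- back_translate(protein$sequence)
  pad5 <- sample(20:120, 1L)
  pad3 <- sample(20:120, 1L)
  cuts <- c(0L, bp$cds_offset, nchar(cds))
  pieces <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1])
  genomic <- paste(sample(c("A", "C", "G", "T"), pad5, replace = TRUE),
                   collapse = "")
  seg <- matrix(0L, nrow = length(pieces), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(pieces)) {
    seg[i, "start"] <- nchar(genomic) + 1L
    genomic <- paste0(genomic, pieces[i])
    seg[i, "end"] <- nchar(genomic)
    if (i < length(pieces)) genomic <- paste0(genomic, random_intron_body())
  }
  genomic <- paste0(genomic,
                    paste(sample(c("A", "C", "G", "T"), pad3, replace = TRUE),
                          collapse = ""))
  if (strand == "-") {
    glen <- nchar(genomic)
    genomic <- revcomp(genomic)
    seg <- cbind(start = glen - seg[, "end"] + 1L,
                 end = glen - seg[, "start"] + 1L)
  }
  model <- gene_model(gene_id = protein$id, strand = strand,
                      cds_segments = seg, protein_id = protein$id)
  list(model = model, genomic = genomic,
       truth = list(pattern = pattern, breakpoints = bp))
}

#' Generate a full synthetic cohort
#'
#' Emits a protein FASTA, a genomic FASTA (one locus per gene), a GFF3 of
#' CDS features, and a ground-truth TSV, all consistent by construction.
#' The seed fully determines every byte of output.
#'
#' @param spec A `synthetic_spec`.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory; created if missing. `NULL` keeps the
#'   cohort in memory only.
#' @return (Invisibly) list with `proteins`, `truths`, `models`,
#'   `genomic`, `truth_table`, and (when written) `paths`.
#' @export
generate_cohort <- function(spec, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  n <- spec$n_proteins
  patterns <- sample(rep(names(spec$intron_pattern_counts),
                         times = spec$intron_pattern_counts))
  ids <- sprintf("syn%03d", seq_len(n))
  proteins <- vector("list", n); truths <- vector("list", n)
  models <- vector("list", n); genomic <- character(n)
  gene_truths <- vector("list", n)
  strands <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0)
  for (i in seq_len(n)) {
    p <- make_protein(spec, id = ids[i])
    proteins[[i]] <- p$record
    truths[[i]] <- p$truth
    gm <- make_gene_model(p$record, patterns[i], p$truth$zipper_start,
                          strand = strands[i])
    models[[i]] <- gm$model
    genomic[i] <- gm$genomic
    gene_truths[[i]] <- gm$truth
  }
  names(models) <- ids
  truth_table <- if (n > 0) data.frame(
    protein_id = ids,
    core_start = vapply(truths, `[[`, 0L, "core_start"),
    zipper_start = vapply(truths, `[[`, 0L, "zipper_start"),
    n_heptads = vapply(truths, `[[`, 0L, "n_heptads"),
    registers = vapply(truths, function(t)
      paste(vapply(t$registers, paste, "", collapse = ""), collapse = ","), ""),
    pair_categories = vapply(truths, function(t)
      paste(unname(GE_SYMBOLS[t$pair_categories]), collapse = ""), ""),
    pattern = patterns,
    strand = strands,
    introns = vapply(gene_truths, function(t)
      paste(sprintf("%d:P%d", t$breakpoints$cds_offset, t$breakpoints$phase),
            collapse = ";"), ""),
    stringsAsFactors = FALSE
  ) else data.frame(protein_id = character(0), core_start = integer(0),
                    zipper_start = integer(0), n_heptads = integer(0),
                    registers = character(0), pair_categories = character(0),
                    pattern = character(0), strand = character(0),
                    introns = character(0))
  out <- list(proteins = proteins, truths = truths, models = models,
              genomic = genomic, truth_table = truth_table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(proteins = file.path(out_dir, "proteins.fa"),
                  genome = file.path(out_dir, "genome.fa"),
                  gff3 = file.path(out_dir, "models.gff3"),
                  truth = file.path(out_dir, "truth.tsv"))
    aa <- Biostrings::AAStringSet(
      stats::setNames(vapply(proteins, `[[`, "", "sequence"), ids))
    Biostrings::writeXStringSet(aa, paths$proteins)
    dna <- Biostrings::DNAStringSet(stats::setNames(genomic, ids))
    Biostrings::writeXStringSet(dna, paths$genome)
    if (n > 0) write_gene_models(models, paths$gff3)
    else writeLines("##gff-version 3", paths$gff3)
    utils::write.table(truth_table, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}

#' Read a synthetic-cohort configuration from a plain-text file
#'
#' Simple `key: value` format. Recognized keys: `n_proteins`, `seed`,
#' `flank_n_min/max`, `flank_c_min/max`, and `pattern_counts` (e.g.
#' `a=14,b=8,c=7,d=7,e=4,intronless=10`). `seed` is mandatory.
#'
#' @param path Config file.
#' @return List with `spec` (a `synthetic_spec`) and `seed`.
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  conf <- stats::setNames(as.list(vals), keys)
  if (is.null(conf$seed)) stop("config must set seed")
  args <- list()
  if (!is.null(conf$n_proteins)) args$n_proteins <- as.integer(conf$n_proteins)
  if (!is.null(conf$pattern_counts)) {
    parts <- strsplit(strsplit(conf$pattern_counts, ",")[[1]], "=")
    args$intron_pattern_counts <- stats::setNames(
      as.integer(vapply(parts, `[[`, "", 2L)),
      trimws(vapply(parts, `[[`, "", 1L)))
  }
  if (!is.null(conf$flank_n_min))
    args$flank_n_range <- c(as.integer(conf$flank_n_min),
                            as.integer(conf$flank_n_max))
  if (!is.null(conf$flank_c_min))
    args$flank_c_range <- c(as.integer(conf$flank_c_min),
                            as.integer(conf$flank_c_max))
  list(spec = do.call(synthetic_spec, args), seed = as.integer(conf$seed))
}
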