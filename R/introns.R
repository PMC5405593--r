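#' Construct a gene model
#'
#' CDS segments are 1-based inclusive genomic intervals given in
#' transcription order (first coding exon first; on the minus strand that
#' is the segment with the highest coordinates).
#'
#' @param gene_id Gene/transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments Two-column matrix or data frame of `start`, `end`.
#' @param protein_id Identifier of the encoded protein (defaults to
#'   `gene_id`).
#' @return A `gene_model`.
#' @export
gene_model <- function(gene_id, strand, cds_segments, protein_id = gene_id) {
  seg <- as.matrix(cds_segments)
  if (ncol(seg) != 2L) stop("cds_segments must have two columns (start, end)")
  storage.mode(seg) <- "integer"
  colnames(seg) <- c("start", "end")
  if (any(seg[, "end"] < seg[, "start"]))
    stop("segment end before start in ", gene_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  genomic_order <- if (strand == "+") seg[, "start"] else -seg[, "start"]
  if (is.unsorted(genomic_order, strictly = TRUE) && nrow(seg) > 1L)
    stop("cds_segments must be in transcription order for ", gene_id)
  structure(list(gene_id = gene_id, strand = strand,
                 cds_segments = seg, protein_id = protein_id),
            class = "gene_model")
}

cds_length <- function(model) {
  sum(model$cds_segments[, "end"] - model$cds_segments[, "start"] + 1L)
}

#' Trim an annotated stop codon from a gene model
#'
#' GFF3 dialects differ on whether the stop codon is part of the CDS.
#' When the CDS totals `3 * protein_length + 3`, the trailing three bases
#' (in transcription order) are trimmed; segments emptied by the trim are
#' dropped. A CDS of exactly `3 * protein_length` is returned unchanged.
#'
#' @param model A `gene_model`.
#' @param protein_length Length of the encoded protein in residues.
#' @return A normalized `gene_model`.
#' @export
normalize_stop_codon <- function(model, protein_length) {
  total <- cds_length(model)
  if (total == 3L * protein_length) return(model)
  if (total != 3L * protein_length + 3L)
    stop(sprintf("CDS length %d does not match protein length %d for %s",
                 total, protein_length, model$gene_id))
  seg <- model$cds_segments
  left <- 3L
  i <- nrow(seg)
  while (left > 0L && i >= 1L) {
    len <- seg[i, "end"] - seg[i, "start"] + 1L
    cut <- min(len, left)
    if (model$strand == "+") seg[i, "end"] <- seg[i, "end"] - cut
    else seg[i, "start"] <- seg[i, "start"] + cut
    left <- left - cut
    if (seg[i, "end"] < seg[i, "start"]) seg <- seg[-i, , drop = FALSE]
    i <- i - 1L
  }
  gene_model(model$gene_id, model$strand, seg, model$protein_id)
}

#' Derive introns and splice phases from a gene model
#'
#' Each junction between consecutive CDS segments is an intron. Its
#' `cds_offset` is the number of coding bases 5' of the junction
#' (transcription order) and its splice phase is `cds_offset mod 3`:
#' phase 0 falls between codons, phase 1 after the first base of a codon,
#' phase 2 after the second.
#'
#' @param model A `gene_model` whose CDS length is divisible by 3.
#' @return Data frame: `gene_id`, `intron_index`, `cds_offset`, `phase`.
#' @export
derive_introns <- function(model) {
  lens <- model$cds_segments[, "end"] - model$cds_segments[, "start"] + 1L
  if (sum(lens) %% 3L != 0L)
    stop("CDS length not divisible by 3 for ", model$gene_id)
  n <- length(lens)
  if (n == 1L)
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      cds_offset = integer(0), phase = integer(0)))
  off <- cumsum(lens)[-n]
  data.frame(gene_id = model$gene_id,
             intron_index = seq_len(n - 1L),
             cds_offset = as.integer(off),
             phase = as.integer(off %% 3L),
             stringsAsFactors = FALSE)
}

#' Map introns to domain-relative positions
#'
#' An intron "follows position p" when the junction lies after the last
#' base of p's codon (phase 0) or inside the codon of the residue after p
#' (phases 1 and 2). `domain_position` is set when that position falls in
#' the -26..+1 window of the basic-hinge numbering, `NA` otherwise.
#'
#' @param introns Data frame from [derive_introns()].
#' @param domain The protein's `bzip_domain`.
#' @return The input with `domain_position` (integer or NA) and
#'   `follows_rule` (text record of the junction convention applied).
#' @export
map_to_domain <- function(introns, domain) {
  if (nrow(introns) == 0L) {
    introns$domain_position <- integer(0)
    introns$follows_rule <- character(0)
    return(introns)
  }
  zs <- domain$zipper_start
  p_res <- introns$cds_offset %/% 3L  # 1-based index of the residue p
  # cds_offset %/% 3 full codons precede the junction; the last complete
  # codon is residue p (phase 0: junction right after it; phase 1/2: the
  # junction interrupts the codon of residue p + 1).
  pos <- ifelse(p_res < zs, p_res - zs, p_res - zs + 1L)
  pos[p_res == 0L] <- NA  # junction before the first complete codon
  in_window <- !is.na(pos) & pos >= -26L & pos <= 1L
  introns$domain_position <- ifelse(in_window, pos, NA_integer_)
  introns$follows_rule <- ifelse(
    introns$phase == 0L,
    "junction after last base of p's codon",
    "junction inside codon of residue following p")
  introns
}

#' Classify the basic-hinge intron pattern
#'
#' Patterns follow the five observed placement/phase classes:
#' * **a** — one intron in the region, phase 0, after position -6;
#' * **b** — one intron, phase 0, after -22;
#' * **c** — one intron, phase 2, after -22;
#' * **d** — exactly two introns, both phase 0, after -26 and at hinge
#'   position -5;
#' * **e** — no intron within the basic-hinge region (-26..-1); introns
#'   elsewhere are permitted, and an intron-free gene is pattern e with
#'   `intronless = TRUE`.
#'
#' Region evidence matching none of a-d is reported as `"unassigned"`.
#'
#' @param mapped Data frame from [map_to_domain()] for one gene.
#' @param gene_id Gene identifier (defaults to the one in `mapped`).
#' @return One-row data frame: `gene_id`, `pattern`, `intronless`,
#'   `n_introns`, `evidence` (text like `"-6:P0"`, `;`-separated).
#' @export
classify_pattern <- function(mapped, gene_id = NULL) {
  if (is.null(gene_id))
    gene_id <- if (nrow(mapped) > 0) mapped$gene_id[1] else NA_character_
  inreg <- mapped[!is.na(mapped$domain_position) &
                    mapped$domain_position >= -26L &
                    mapped$domain_position <= -1L, , drop = FALSE]
  ev <- if (nrow(inreg) == 0) "" else
    paste(sprintf("%d:P%d", inreg$domain_position, inreg$phase),
          collapse = ";")
  hits <- function(pos, ph)
    any(inreg$domain_position == pos & inreg$phase == ph)
  pattern <-
    if (nrow(inreg) == 0L) "e"
    else if (nrow(inreg) == 1L && hits(-6L, 0L)) "a"
    else if (nrow(inreg) == 1L && hits(-22L, 0L)) "b"
    else if (nrow(inreg) == 1L && hits(-22L, 2L)) "c"
    else if (nrow(inreg) == 2L && hits(-26L, 0L) && hits(-5L, 0L)) "d"
    else "unassigned"
  data.frame(gene_id = gene_id,
             pattern = pattern,
             intronless = nrow(mapped) == 0L,
             n_introns = nrow(mapped),
             evidence = ev,
             stringsAsFactors = FALSE)
}

#' Summarize intron-pattern calls across a cohort
#'
#' @param calls Data frame of [classify_pattern()] rows.
#' @param clade_labels Optional data frame with `protein_id` (or
#'   `gene_id`) and `clade` columns for a pattern-by-clade cross-tab.
#' @return List with `pattern_counts` (named integer over
#'   a,b,c,d,e,unassigned), `n_genes`, `intronless_count`,
#'   `intronless_fraction`, and optionally `by_clade` (table).
#' @export
cohort_summary <- function(calls, clade_labels = NULL) {
  lev <- c("a", "b", "c", "d", "e", "unassigned")
  counts <- table(factor(calls$pattern, levels = lev))
  out <- list(pattern_counts = stats::setNames(as.integer(counts), lev),
              n_genes = nrow(calls),
              intronless_count = sum(calls$intronless),
              intronless_fraction =
                if (nrow(calls)) sum(calls$intronless) / nrow(calls) else NA_real_)
  if (!is.null(clade_labels)) {
    key <- if ("gene_id" %in% names(clade_labels)) "gene_id" else "protein_id"
    clade <- clade_labels$clade[match(calls$gene_id, clade_labels[[key]])]
    out$by_clade <- table(clade = clade,
                          pattern = factor(calls$pattern, levels = lev))
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' CDS features are grouped by their `Parent` (falling back to `ID`) and
#' ordered in transcription order by strand. Splice phases are computed
#' from CDS arithmetic, never read from the GFF3 phase column (which
#' encodes reading-frame offset, a different quantity).
#'
#' @param path GFF3 file with CDS features.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0L) return(list())
  parent <- S4Vectors::mcols(gr)$Parent
  ids <- if (!is.null(parent) && any(lengths(parent) > 0)) {
    vapply(as.list(parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, "")
  } else NULL
  if (is.null(ids) || all(is.na(ids))) ids <- as.character(S4Vectors::mcols(gr)$ID)
  models <- lapply(split(seq_along(gr), ids), function(i) {
    sub <- gr[i]
    st <- as.character(BiocGenerics::strand(sub))[1]
    ord <- order(BiocGenerics::start(sub),
                 decreasing = identical(st, "-"))
    sub <- sub[ord]
    gene_model(gene_id = ids[i][1], strand = st,
               cds_segments = cbind(start = BiocGenerics::start(sub),
                                    end = BiocGenerics::end(sub)))
  })
  models
}

#' Write gene models to a GFF3 file
#'
#' @param models List of `gene_model` objects.
#' @param path Output file.
#' @param seqnames Named character vector mapping gene_id to the sequence
#'   name its coordinates refer to (defaults to the gene_id itself).
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, seqnames = NULL) {
  rows <- lapply(models, function(m) {
    seg <- m$cds_segments
    sq <- if (!is.null(seqnames)) seqnames[[m$gene_id]] else m$gene_id
    lens <- seg[, "end"] - seg[, "start"] + 1L
    before <- c(0L, cumsum(lens)[-length(lens)])
    data.frame(seqname = sq, start = unname(seg[, "start"]),
               end = unname(seg[, "end"]), strand = m$strand,
               ID = paste0(m$gene_id, ".cds", seq_len(nrow(seg))),
               Parent = m$gene_id,
               phase = (3L - before %% 3L) %% 3L,  # GFF3 frame, not splice phase
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqname,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand,
    type = "CDS", ID = tab$ID, Parent = tab$Parent, phase = tab$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Exon/intron block structure as plain JSON
#'
#' Gene-structure export (exon blocks, intron gaps, splice phases) that a
#' plotting notebook can render, in the spirit of gene structure display
#' servers.
#'
#' @param model A `gene_model`.
#' @return A list (JSON-ready) with `gene_id`, `strand`, `exons` and
#'   `introns` (each intron with `cds_offset` and `phase`).
#' @export
gene_structure_json <- function(model) {
  intr <- derive_introns(model)
  seg <- model$cds_segments
  list(gene_id = model$gene_id,
       strand = model$strand,
       exons = lapply(seq_len(nrow(seg)), function(i)
         list(start = unname(seg[i, "start"]), end = unname(seg[i, "end"]))),
       introns = lapply(seq_len(nrow(intr)), function(i)
         list(cds_offset = intr$cds_offset[i], phase = intr$phase[i])))
}
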