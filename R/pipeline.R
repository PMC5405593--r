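# Pipeline orchestration: scan / introns / summarize / simulate stages
# producing plain TSV + JSON outputs. Logging goes to stderr (via message),
# data only to files.

#' Read a protein FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("protein FASTA not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("invalid FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(aa) == 0L) stop("empty FASTA: ", path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  seqs
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(format(x), collapse = ","), ""),
                   sep = "="), f)
  unname(tools::md5sum(f))
}

write_table_with_header <- function(tab, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bzipr %s config=%s",
                     as.character(utils::packageVersion("bzipr")), hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table (skipping the provenance header)
#'
#' @param path TSV written by the pipeline stages.
#' @return Data frame.
#' @export
read_pipeline_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

read_domain_overrides <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "core_start", "zipper_start")
  if (!all(need %in% names(tab)))
    stop("domain override TSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Scan stage: domains, zippers, phospho sites, descriptors
#'
#' Runs the domain scanner (or applies externally supplied coordinates),
#' registers the leucine zippers, scans phosphorylation-site motifs, and
#' computes the protein descriptors; writes one TSV per table. Exported
#' coordinates are 1-based inclusive.
#'
#' @param fasta Protein FASTA path.
#' @param out_dir Output directory.
#' @param min_heptads,max_heptads Zipper length bounds.
#' @param register_rule Pair-attribution rule, see [ge_pairs()].
#' @param domain_tsv Optional TSV of externally determined domain
#'   coordinates (`protein_id`, 1-based `core_start`, `zipper_start`).
#' @return (Invisibly) list of written paths plus the in-memory tables.
#' @export
run_scan <- function(fasta, out_dir, min_heptads = 2, max_heptads = 9,
                     register_rule = "same_heptad", domain_tsv = NULL) {
  seqs <- read_protein_fasta(fasta)
  config <- list(stage = "scan", fasta = basename(fasta),
                 min_heptads = min_heptads, max_heptads = max_heptads,
                 register_rule = register_rule,
                 domain_tsv = if (is.null(domain_tsv)) "" else basename(domain_tsv))
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  overrides <- if (!is.null(domain_tsv)) read_domain_overrides(domain_tsv)
  domains <- list()
  for (id in names(seqs)) {
    if (!is.null(overrides) && id %in% overrides$protein_id) {
      row <- overrides[overrides$protein_id == id, ][1, ]
      domains[[length(domains) + 1L]] <-
        bzip_domain_at(seqs[[id]], core_start = row$core_start, id = id,
                       zipper_start = row$zipper_start)
    } else {
      found <- find_bzip_domains(seqs[[id]], id = id, min_heptads = min_heptads)
      domains <- c(domains, found)
    }
  }
  message(sprintf("scan: %d protein(s), %d domain(s)",
                  length(seqs), length(domains)))

  zippers <- lapply(domains, register_heptads, max_heptads = max_heptads)
  inv <- do.call(rbind, lapply(domains, check_invariants))
  domain_tab <- do.call(rbind, Map(function(d, z, iv) {
    sig <- dimer_signature(z, register_rule)
    data.frame(protein_id = d$protein_id,
               core_start = d$core_start,
               zipper_start = d$zipper_start,
               minus18_ok = iv$minus18_ok,
               minus10_ok = iv$minus10_ok,
               n_heptads = z$n_heptads,
               end_reason = z$end_reason,
               accepted = z$accepted,
               pair_string = sig$pair_string,
               stringsAsFactors = FALSE)
  }, domains, zippers, split(inv, seq_len(nrow(inv)))))
  if (is.null(domain_tab))
    domain_tab <- data.frame(protein_id = character(0), core_start = integer(0),
                             zipper_start = integer(0), minus18_ok = logical(0),
                             minus10_ok = logical(0), n_heptads = integer(0),
                             end_reason = character(0), accepted = logical(0),
                             pair_string = character(0))
  phospho <- do.call(rbind, Map(scan_phospho_sites, seqs, names(seqs)))
  props <- do.call(rbind, Map(protein_properties, seqs, names(seqs)))

  paths <- list(domains = file.path(out_dir, "domains.tsv"),
                phospho = file.path(out_dir, "phospho.tsv"),
                properties = file.path(out_dir, "properties.tsv"))
  write_table_with_header(domain_tab, paths$domains, hash)
  write_table_with_header(phospho, paths$phospho, hash)
  write_table_with_header(round_properties(props), paths$properties, hash)
  invisible(list(paths = paths, domains = domains, zippers = zippers,
                 domain_table = domain_tab, phospho = phospho,
                 properties = props))
}

#' Intron stage: splice phases and basic-hinge patterns
#'
#' Reads gene models from GFF3, pairs them with the scanned domains by
#' protein/gene id, normalizes annotated stop codons, derives introns and
#' classifies the basic-hinge intron pattern. Unmatched ids are reported
#' but not fatal; genes whose CDS disagrees with the protein length are
#' skipped with a warning.
#'
#' @param gff3 GFF3 with CDS features.
#' @param fasta Protein FASTA with ids matching the GFF3 transcripts.
#' @param out_dir Output directory.
#' @param min_heptads Passed to the domain scanner.
#' @return (Invisibly) list with written paths, the intron table and the
#'   pattern table.
#' @export
run_introns <- function(gff3, fasta, out_dir, min_heptads = 2) {
  seqs <- read_protein_fasta(fasta)
  models <- read_gene_models(gff3)
  config <- list(stage = "introns", gff3 = basename(gff3),
                 fasta = basename(fasta), min_heptads = min_heptads)
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  unmatched <- setdiff(names(models), names(seqs))
  if (length(unmatched) > 0)
    message("introns: no protein for gene(s): ",
            paste(unmatched, collapse = ", "))
  intron_rows <- list(); call_rows <- list()
  for (gid in intersect(names(models), names(seqs))) {
    model <- models[[gid]]
    plen <- nchar(seqs[[gid]])
    model <- tryCatch(normalize_stop_codon(model, plen), error = function(e) {
      warning("skipping ", gid, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(model)) next
    intr <- derive_introns(model)
    dom <- find_bzip_domains(seqs[[gid]], id = gid, min_heptads = min_heptads)
    if (length(dom) == 0) {
      message("introns: no bZIP domain in ", gid, "; pattern not called")
      next
    }
    mapped <- map_to_domain(intr, dom[[1]])
    intron_rows[[gid]] <- mapped
    call_rows[[gid]] <- classify_pattern(mapped, gene_id = gid)
  }
  intron_tab <- if (length(intron_rows)) do.call(rbind, intron_rows) else
    data.frame(gene_id = character(0), intron_index = integer(0),
               cds_offset = integer(0), phase = integer(0),
               domain_position = integer(0), follows_rule = character(0))
  pattern_tab <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(gene_id = character(0), pattern = character(0),
               intronless = logical(0), n_introns = integer(0),
               evidence = character(0))
  rownames(intron_tab) <- rownames(pattern_tab) <- NULL
  paths <- list(introns = file.path(out_dir, "introns.tsv"),
                patterns = file.path(out_dir, "patterns.tsv"))
  write_table_with_header(intron_tab, paths$introns, hash)
  write_table_with_header(pattern_tab, paths$patterns, hash)
  invisible(list(paths = paths, introns = intron_tab, patterns = pattern_tab))
}

#' Summary stage: cohort-level statistics
#'
#' Assembles register composition tables, per-heptad Asn and pair-category
#' histograms, dimerization types, intron-pattern counts and descriptor
#' summary statistics from the per-protein stages; writes TSVs and one
#' summary JSON.
#'
#' @param fasta Protein FASTA (rescanned for zipper-level statistics).
#' @param out_dir Output directory (also receives the TSVs/JSON).
#' @param pattern_tsv Optional pattern table from [run_introns()].
#' @param clade_tsv Optional TSV with `protein_id` and `clade` columns.
#' @param min_heptads,max_heptads,register_rule Scanner/zipper settings.
#' @return (Invisibly) the summary list (also written as JSON).
#' @export
run_summarize <- function(fasta, out_dir, pattern_tsv = NULL,
                          clade_tsv = NULL, min_heptads = 2, max_heptads = 9,
                          register_rule = "same_heptad") {
  scan <- run_scan(fasta, out_dir, min_heptads = min_heptads,
                   max_heptads = max_heptads, register_rule = register_rule)
  config <- list(stage = "summarize", fasta = basename(fasta),
                 register_rule = register_rule)
  hash <- config_hash(config)
  zippers <- Filter(function(z) z$accepted, scan$zippers)
  if (length(zippers) == 0) stop("no accepted zipper; nothing to summarize")

  comp <- composition_stats(zippers)
  asn <- asn_per_heptad(zippers)
  ph <- pair_histogram(zippers, register_rule)
  sigs <- dimerization_types(
    do.call(rbind, lapply(zippers, dimer_signature, register_rule)))
  props <- table1_report(scan$properties)

  write_table_with_header(comp$table,
                          file.path(out_dir, "composition.tsv"), hash)
  write_table_with_header(asn, file.path(out_dir, "asn_per_heptad.tsv"), hash)
  write_table_with_header(ph$by_category,
                          file.path(out_dir, "pair_histogram.tsv"), hash)
  write_table_with_header(sigs, file.path(out_dir, "dimer_types.tsv"), hash)

  summary <- list(
    n_proteins = nrow(scan$properties),
    n_domains = length(scan$domains),
    n_accepted_zippers = length(zippers),
    charged_fraction_e = unname(comp$charged_fraction["e"]),
    charged_fraction_g = unname(comp$charged_fraction["g"]),
    asn_fraction_a = with(
      comp$table,
      ifelse(any(register == "a" & residue == "N"),
             sum(freq[register == "a" & residue == "N"]), 0)),
    leu_fraction_d = with(
      comp$table,
      ifelse(any(register == "d" & residue == "L"),
             sum(freq[register == "d" & residue == "L"]), 0)),
    n_dimer_types = attr(sigs, "n_types"),
    properties = props$summary)
  if (!is.null(pattern_tsv)) {
    patterns <- read_pipeline_table(pattern_tsv)
    clades <- if (!is.null(clade_tsv))
      utils::read.delim(clade_tsv, stringsAsFactors = FALSE)
    cs <- cohort_summary(patterns, clades)
    summary$pattern_counts <- as.list(cs$pattern_counts)
    summary$intronless_count <- cs$intronless_count
    summary$intronless_fraction <- cs$intronless_fraction
    if (!is.null(cs$by_clade))
      summary$by_clade <- as.data.frame(cs$by_clade)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Simulate stage: write a synthetic cohort
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (mandatory).
#' @param spec A `synthetic_spec` (default [synthetic_spec()]).
#' @param config Optional plain-text config file (`key: value`); when
#'   given, it supplies the spec and seed (explicit arguments win).
#' @return (Invisibly) the cohort object from [generate_cohort()].
#' @export
run_simulate <- function(out_dir, seed = NULL, spec = NULL, config = NULL) {
  if (!is.null(config)) {
    conf <- read_synthetic_config(config)
    if (is.null(spec)) spec <- conf$spec
    if (is.null(seed)) seed <- conf$seed
  }
  if (is.null(seed)) stop("seed is mandatory")
  if (is.null(spec)) spec <- synthetic_spec()
  cohort <- generate_cohort(spec, seed = seed, out_dir = out_dir)
  manifest <- list(stage = "simulate", seed = as.integer(seed),
                   n_proteins = spec$n_proteins,
                   pattern_counts = as.list(spec$intron_pattern_counts),
                   version = as.character(utils::packageVersion("bzipr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("simulate: wrote %d gene(s) to %s", spec$n_proteins, out_dir))
  invisible(cohort)
}
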