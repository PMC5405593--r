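#' Locate bZIP basic-hinge domains in a protein sequence
#'
#' The bZIP basic-hinge core is the 18-residue block carrying the invariant
#' motif N-X7-R/K-X9: an asparagine anchor (domain position -18), seven
#' unconstrained residues, an arginine or lysine (-10), and a nine-residue
#' hinge (-9..-1). The leucine zipper starts immediately after the hinge:
#' its first leucine is domain position +1. A candidate core qualifies only
#' when the zipper that follows holds at least `min_heptads` heptads whose
#' d register (positions +1, +8, +15, ...) is a hydrophobic residue from
#' `d_set`. `X` never satisfies a constrained position (N, R/K, L, d).
#'
#' When several candidate cores overlap, the one supporting more qualifying
#' downstream heptads is kept; ties go to the leftmost. Non-overlapping
#' candidates are all returned, left to right.
#'
#' @param sequence Character scalar, uppercase one-letter amino acids
#'   (20 standard residues plus `X`).
#' @param id Protein identifier attached to the result.
#' @param min_heptads Minimum number of consecutive qualifying heptads
#'   required downstream of the hinge (default 2, matching the two-to-nine
#'   heptad range seen in plant bZIPs).
#' @param d_set Residues accepted at the d register.
#' @return A list of `bzip_domain` objects (possibly empty). Each carries
#'   `protein_id`, 1-based `core_start` (index of the anchor N) and
#'   `zipper_start` (index of the +1 leucine), the position-to-residue map
#'   `residue_at`, and the number of consecutive qualifying heptads
#'   `n_qualifying_heptads`.
#' @export
find_bzip_domains <- function(sequence, id = "protein",
                              min_heptads = 2, d_set = D_REGISTER_SET) {
  check_sequence(sequence, allow_x = TRUE)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  # a qualifying run of q d-registers needs core + hinge + (q-1) full
  # heptads + the final d itself
  if (n < 19 + 7 * (min_heptads - 1)) return(list())

  cand_start <- integer(0)
  cand_q <- integer(0)
  # anchor N at i, R/K at i+8, hinge i+9..i+17, first zipper L at i+18
  for (i in which(s == "N")) {
    if (i + 18 > n) break
    if (!(s[i + 8] %in% c("R", "K"))) next
    if (s[i + 18] != "L") next
    q <- count_qualifying_heptads(s, zipper_start = i + 18, d_set = d_set)
    if (q >= min_heptads) {
      cand_start <- c(cand_start, i)
      cand_q <- c(cand_q, q)
    }
  }
  if (length(cand_start) == 0L) return(list())

  keep <- resolve_core_overlaps(cand_start, cand_q)
  lapply(keep, function(k) {
    new_bzip_domain(id, sequence, core_start = cand_start[k],
                    n_qualifying = cand_q[k])
  })
}

# Consecutive heptads (from L0) whose d register is in d_set. d of heptad k
# sits at zipper_start + 7k.
count_qualifying_heptads <- function(s, zipper_start, d_set) {
  q <- 0L
  i <- zipper_start
  while (i <= length(s) && s[i] %in% d_set) {
    q <- q + 1L
    i <- i + 7L
  }
  q
}

# Cluster candidates whose 18-residue cores overlap; keep, per cluster, the
# candidate with most qualifying heptads (ties: leftmost).
resolve_core_overlaps <- function(starts, quality) {
  ord <- order(starts)
  starts <- starts[ord]; quality <- quality[ord]
  keep <- integer(0)
  i <- 1L
  while (i <= length(starts)) {
    j <- i
    while (j < length(starts) && starts[j + 1L] <= starts[j] + 17L) j <- j + 1L
    cluster <- i:j
    best <- cluster[which.max(quality[cluster])]  # which.max = leftmost tie
    keep <- c(keep, ord[best])
    i <- j + 1L
  }
  sort(keep)
}

new_bzip_domain <- function(protein_id, sequence, core_start,
                            n_qualifying = NA_integer_) {
  n <- nchar(sequence)
  if (core_start < 1 || core_start + 18 > n)
    stop("domain coordinates outside sequence for ", protein_id)
  zipper_start <- core_start + 18L
  d <- structure(
    list(protein_id = protein_id,
         sequence = sequence,
         core_start = as.integer(core_start),
         zipper_start = as.integer(zipper_start),
         n_qualifying_heptads = as.integer(n_qualifying)),
    class = "bzip_domain")
  d$residue_at <- number_positions(d)
  d
}

#' Build a bZIP domain from supplied coordinates
#'
#' Escape hatch for injecting externally determined domain coordinates
#' (e.g. published HMMER hits) instead of motif scanning; deviations from
#' the invariant anchors are then reported by [check_invariants()] rather
#' than rejected.
#'
#' @param sequence Protein sequence.
#' @param core_start 1-based index of domain position -18.
#' @param id Protein identifier.
#' @param zipper_start 1-based index of position +1; defaults to
#'   `core_start + 18`.
#' @return A `bzip_domain`.
#' @export
bzip_domain_at <- function(sequence, core_start, id = "protein",
                           zipper_start = core_start + 18L) {
  check_sequence(sequence, allow_x = TRUE)
  if (zipper_start != core_start + 18L)
    stop("hinge must be exactly 9 residues: zipper_start = core_start + 18")
  new_bzip_domain(id, sequence, core_start)
}

#' Number domain positions relative to the first zipper leucine
#'
#' The first leucine of the zipper is +1 and the C-terminal hinge residue
#' is -1; there is no position 0. The anchor N is -18 and the basic region
#' is covered down to -26 where the sequence extends that far upstream.
#' Positive positions run to the end of the sequence.
#'
#' @param domain A `bzip_domain`.
#' @return Named character vector mapping positions (e.g. `"-18"`, `"+1"`)
#'   to residues.
#' @export
number_positions <- function(domain) {
  s <- strsplit(domain$sequence, "")[[1]]
  zs <- domain$zipper_start
  if (zs < 19 || zs > length(s))
    stop("zipper start outside sequence")
  neg <- seq(from = max(-26L, 1L - zs), to = -1L)
  pos <- seq_len(length(s) - zs + 1L)
  map <- c(s[zs + neg], s[zs + pos - 1L])
  names(map) <- c(as.character(neg), paste0("+", pos))
  map
}

position_residue <- function(domain, position) {
  key <- if (position > 0) paste0("+", position) else as.character(position)
  unname(domain$residue_at[key])
}

#' Check the invariant sites of a basic-hinge region
#'
#' Position -18 must hold the anchor Asn and -10 an Arg or Lys; a
#' replacement at -10 (e.g. the hydrophobic Ile seen in one strawberry
#' clade-U protein) is flagged as a possible loss or alteration of
#' DNA-binding specificity.
#'
#' @param domain A `bzip_domain`.
#' @return One-row data frame: `protein_id`, residues at -18 and -10,
#'   logical flags `minus18_ok` / `minus10_ok`, and a `note`.
#' @export
check_invariants <- function(domain) {
  r18 <- position_residue(domain, -18)
  r10 <- position_residue(domain, -10)
  ok18 <- identical(r18, "N")
  ok10 <- r10 %in% c("R", "K")
  note <- ""
  if (!ok10)
    note <- sprintf(
      "non-basic residue '%s' at -10: possible loss/alteration of DNA-binding specificity",
      r10)
  if (!ok18)
    note <- paste(note, sprintf("anchor Asn replaced by '%s' at -18", r18))
  data.frame(protein_id = domain$protein_id,
             pos_minus18_residue = r18,
             pos_minus10_residue = r10,
             minus18_ok = ok18,
             minus10_ok = ok10,
             note = trimws(note),
             stringsAsFactors = FALSE)
}

#' Scan phosphorylation-site motifs
#'
#' Reports every 4-residue window matching the casein kinase II motif
#' S/TxxD/E (`CKII`) or the Ca2+-dependent protein kinase motif R/KxxS/T
#' (`CDPK`). Overlapping matches are all reported; `X` never matches a
#' constrained position.
#'
#' @param sequence Protein sequence.
#' @param id Protein identifier.
#' @return Data frame with `protein_id`, `kind`, 1-based `start`, and the
#'   matched 4-mer. Zero rows when nothing matches.
#' @export
scan_phospho_sites <- function(sequence, id = "protein") {
  check_sequence(sequence, allow_x = TRUE)
  n <- nchar(sequence)
  empty <- data.frame(protein_id = character(0), kind = character(0),
                      start = integer(0), matched = character(0),
                      stringsAsFactors = FALSE)
  if (n < 4) return(empty)
  starts <- seq_len(n - 3L)
  first <- substring(sequence, starts, starts)
  last <- substring(sequence, starts + 3L, starts + 3L)
  ckii <- first %in% c("S", "T") & last %in% c("D", "E")
  cdpk <- first %in% c("R", "K") & last %in% c("S", "T")
  hit_start <- c(starts[ckii], starts[cdpk])
  if (length(hit_start) == 0L) return(empty)
  hit_kind <- c(rep("CKII", sum(ckii)), rep("CDPK", sum(cdpk)))
  ord <- order(hit_start, hit_kind)
  data.frame(protein_id = rep(id, length(hit_start)),
             kind = hit_kind[ord],
             start = hit_start[ord],
             matched = substring(sequence, hit_start[ord], hit_start[ord] + 3L),
             stringsAsFactors = FALSE)
}

check_sequence <- function(sequence, allow_x = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  if (nchar(sequence) == 0L) stop("sequence is empty")
  alphabet <- if (allow_x) c(AA_STANDARD, "X") else AA_STANDARD
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), alphabet)
  if (length(bad) > 0)
    stop("sequence contains non-standard residue(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.bzip_domain <- function(x, ...) {
  cat(sprintf(
    "<bzip_domain> %s: core N at %d (-18), R/K site at %d (-10), zipper +1 at %d, %s qualifying heptads\n",
    x$protein_id, x$core_start, x$core_start + 8L, x$zipper_start,
    ifelse(is.na(x$n_qualifying_heptads), "?", x$n_qualifying_heptads)))
  invisible(x)
}
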