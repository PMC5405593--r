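#' Molecular weight of a protein (average isotopic, Da)
#'
#' Sum of average residue masses plus one water, as computed by the
#' ProtParam server. Ambiguity codes (B, Z, X) are rejected.
#'
#' @param sequence Protein sequence (standard 20 residues).
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(sequence) {
  check_sequence(sequence, allow_x = FALSE)
  s <- strsplit(sequence, "")[[1]]
  sum(AA_MASS_AVG[s]) + MASS_WATER_AVG
}

# Henderson-Hasselbalch net charge at a given pH with the Bjellqvist /
# ProtParam pK set (side chains D,E,C,Y negative; H,K,R positive; termini
# with residue-specific N-terminal pKs).
protein_net_charge <- function(counts, first_res, last_res, ph) {
  pos <- 1 / (1 + 10^(ph - c(
    nterm = unname(if (first_res %in% names(PK_NTERM)) PK_NTERM[first_res]
                   else PK_NTERM_DEFAULT),
    PK_SIDECHAIN_POS)))
  neg <- 1 / (1 + 10^(c(
    cterm = unname(if (last_res %in% names(PK_CTERM)) PK_CTERM[last_res]
                   else PK_CTERM_DEFAULT),
    PK_SIDECHAIN_NEG) - ph))
  npos <- c(1, counts[names(PK_SIDECHAIN_POS)])
  nneg <- c(1, counts[names(PK_SIDECHAIN_NEG)])
  sum(npos * pos) - sum(nneg * neg)
}

#' Theoretical isoelectric point
#'
#' The pH at which the modeled net charge of the protein is zero, found by
#' bisection of the Henderson-Hasselbalch net-charge function over the
#' ionizable groups (D, E, C, Y, H, K, R and the termini) with the
#' ExPASy/Bjellqvist pK set. Net charge is strictly decreasing in pH, so
#' the root is unique.
#'
#' @param sequence Protein sequence.
#' @param tol Bisection tolerance in pH units (default 0.005; two-decimal
#'   reporting).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 0.005) {
  check_sequence(sequence, allow_x = FALSE)
  s <- strsplit(sequence, "")[[1]]
  counts <- table(factor(s, levels = AA_STANDARD))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, s[1], s[length(s)], mid) > 0) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index (Guruprasad)
#'
#' `(10 / L) * sum` of the dipeptide instability weight values over all
#' consecutive residue pairs. Values above 40 predict an unstable protein
#' in vitro.
#'
#' @param sequence Protein sequence, length >= 2.
#' @return Instability index.
#' @export
instability_index <- function(sequence) {
  check_sequence(sequence, allow_x = FALSE)
  s <- strsplit(sequence, "")[[1]]
  if (length(s) < 2L) stop("instability index needs at least 2 residues")
  w <- DIWV[cbind(s[-length(s)], s[-1])]
  10 / length(s) * sum(w)
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole percent.
#'
#' @param sequence Protein sequence.
#' @return Aliphatic index.
#' @export
aliphatic_index <- function(sequence) {
  check_sequence(sequence, allow_x = FALSE)
  s <- strsplit(sequence, "")[[1]]
  x <- 100 * c(A = mean(s == "A"), V = mean(s == "V"),
               I = mean(s == "I"), L = mean(s == "L"))
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' GRAVY (grand average of hydropathicity)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values.
#'
#' @param sequence Protein sequence.
#' @return GRAVY score.
#' @export
gravy <- function(sequence) {
  check_sequence(sequence, allow_x = FALSE)
  s <- strsplit(sequence, "")[[1]]
  mean(KYTE_DOOLITTLE[s])
}

#' All five descriptors for one protein
#'
#' @param sequence Protein sequence.
#' @param id Protein identifier.
#' @return One-row data frame: `protein_id`, `length`, `mol_weight`, `pI`,
#'   `instability_index`, `aliphatic_index`, `gravy` (full precision).
#' @export
protein_properties <- function(sequence, id = "protein") {
  data.frame(protein_id = id,
             length = nchar(sequence),
             mol_weight = molecular_weight(sequence),
             pI = isoelectric_point(sequence),
             instability_index = instability_index(sequence),
             aliphatic_index = aliphatic_index(sequence),
             gravy = gravy(sequence),
             stringsAsFactors = FALSE)
}

#' Property table and cohort summary
#'
#' Computes the descriptor table for a set of proteins, or summarizes an
#' already-computed (or published) property table. Summary statistics are
#' exact arithmetic on the per-protein values.
#'
#' @param x Either a named character vector of sequences or a data frame
#'   with at least `length`, `mol_weight`, `pI` columns.
#' @return List with `table` (per-protein properties) and `summary`
#'   (mean/min/max of length, mol_weight, pI).
#' @export
table1_report <- function(x) {
  tab <- if (is.data.frame(x)) x else {
    if (is.null(names(x))) names(x) <- paste0("protein", seq_along(x))
    do.call(rbind, Map(protein_properties, x, names(x)))
  }
  summ <- list(
    n = nrow(tab),
    length_mean = mean(tab$length),
    length_min = min(tab$length),
    length_max = max(tab$length),
    mol_weight_mean = mean(tab$mol_weight),
    mol_weight_min = min(tab$mol_weight),
    mol_weight_max = max(tab$mol_weight),
    pI_mean = mean(tab$pI),
    pI_min = min(tab$pI),
    pI_max = max(tab$pI))
  list(table = tab, summary = summ)
}

#' Published descriptor table of the 50 strawberry bZIP proteins
#'
#' Loads the packaged copy of the published per-protein descriptor table
#' (id, NCBI accession, chromosome, length, molecular weight, theoretical
#' pI, instability index, aliphatic index, GRAVY) so summary statistics
#' can be reproduced without downloads.
#'
#' @return Data frame with 50 rows.
#' @export
load_fvbzip_table <- function() {
  path <- system.file("extdata", "fvbzip_table1.tsv", package = "bzipr")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Round descriptors to reporting precision
#'
#' Reporting follows the published table: MW 1 decimal, pI 2, instability
#' and aliphatic indices 2, GRAVY 3. Internal values keep full precision.
#'
#' @param tab Data frame from [protein_properties()] rows.
#' @return The table with rounded descriptor columns.
#' @export
round_properties <- function(tab) {
  tab$mol_weight <- round(tab$mol_weight, 1)
  tab$pI <- round(tab$pI, 2)
  tab$instability_index <- round(tab$instability_index, 2)
  tab$aliphatic_index <- round(tab$aliphatic_index, 2)
  tab$gravy <- round(tab$gravy, 3)
  tab
}
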