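# Shared builders for planted sequences and models.

# A minimal valid domain: N, 7 spacers, R/K, 9-residue hinge, then
# `n_heptads` heptads whose d registers are Leu; positions are controllable
# through the spacer/hinge/zipper arguments.
planted_sequence <- function(flank_n = "", spacer7 = "AAAAAAA", rk = "R",
                             hinge9 = "AAAAAAAAA", heptads = c("LAAAAAA",
                                                               "LAAAAAA"),
                             flank_c = "") {
  stopifnot(nchar(spacer7) == 7, nchar(hinge9) == 9,
            all(nchar(heptads) <= 7))
  paste0(flank_n, "N", spacer7, rk, hinge9,
         paste(heptads, collapse = ""), flank_c)
}

# Independent brute-force domain finder used as oracle: enumerate every
# window, then apply the documented overlap rule (most qualifying heptads,
# leftmost tie) by explicit pairwise comparison.
brute_force_domains <- function(sequence, min_heptads = 2) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  dset <- c("L", "I", "V", "M", "F")
  cand <- data.frame(start = integer(0), q = integer(0))
  for (i in seq_len(max(0, n - 18))) {
    if (s[i] != "N") next
    if (!(s[i + 8] %in% c("R", "K"))) next
    if (s[i + 18] != "L") next
    q <- 0L; j <- i + 18L
    while (j <= n && s[j] %in% dset) { q <- q + 1L; j <- j + 7L }
    if (q >= min_heptads) cand <- rbind(cand, data.frame(start = i, q = q))
  }
  if (nrow(cand) == 0) return(cand)
  # transitive overlap clusters of the 18-residue cores
  cl <- integer(nrow(cand)); cl[1] <- 1L
  for (i in seq_len(nrow(cand))[-1]) {
    cl[i] <- if (cand$start[i] <= cand$start[i - 1] + 17) cl[i - 1] else cl[i - 1] + 1L
  }
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cl), function(idx) {
    best <- idx[1]
    for (j in idx[-1]) if (cand$q[j] > cand$q[best]) best <- j
    best
  }))
  cand[sort(keep), , drop = FALSE]
}

# Independent reimplementation of the pair legend for the 400-pair check:
# plain set membership, no shared lookup table.
oracle_ge_category <- function(g, e) {
  in_pairs <- function(pairs) any(vapply(pairs, function(p)
    p[1] == g && p[2] == e, TRUE))
  if (in_pairs(list(c("R", "E"), c("K", "E")))) return("attractive_basic_acidic")
  if (in_pairs(list(c("E", "R"), c("E", "K"), c("D", "K"))))
    return("attractive_acidic_basic")
  if (in_pairs(list(c("K", "K"), c("R", "K"), c("R", "Q"), c("Q", "K"),
                    c("K", "Q")))) return("repulsive_basic")
  if (in_pairs(list(c("E", "E"), c("E", "D"), c("E", "Q"), c("Q", "E"))))
    return("repulsive_acidic")
  chargeable <- c("R", "K", "E", "D", "Q")
  gc <- g %in% chargeable; ec <- e %in% chargeable
  if (gc && ec) return("complete_unlisted")
  if (!gc && !ec) return("none")
  side <- if (gc) g else e
  if (side %in% c("R", "K")) "incomplete_basic" else "incomplete_acidic"
}

random_aa <- function(n, alphabet = bzipr:::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
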