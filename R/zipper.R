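#' Register leucine-zipper heptads
#'
#' Heptads are labelled g,a,b,c,d,e,f in sequence order. The first heptad
#' (L0) is anchored so that its d register is the first zipper leucine
#' (+1); its g register therefore sits four residues earlier, at hinge
#' position -4. Registration proceeds heptad by heptad and terminates at
#' the first of:
#'
#' * a proline at or after position +1 (`helix_break`; the proline and any
#'   later residues are excluded),
#' * a heptad whose d register holds none of `d_set`
#'   (`d_register_failure`; that heptad is excluded),
#' * the end of the sequence (`sequence_end`; a partial terminal heptad is
#'   retained with only its occupied registers),
#' * `max_heptads` complete heptads (`max_heptads`).
#'
#' A zipper is accepted when it holds at least two complete heptads.
#'
#' @param domain A `bzip_domain`.
#' @param max_heptads Cap on complete heptads (default 9; observed plant
#'   zippers range from two to nine heptads).
#' @param d_set Residues accepted at the d register.
#' @return A `leucine_zipper`: `protein_id`, list of heptads (named
#'   register vectors), `n_heptads` (complete), `end_reason`, `accepted`.
#' @export
register_heptads <- function(domain, max_heptads = 9,
                             d_set = D_REGISTER_SET) {
  s <- strsplit(domain$sequence, "")[[1]]
  zs <- domain$zipper_start
  g0 <- zs - 4L
  regs <- c("g", "a", "b", "c", "d", "e", "f")
  heptads <- list()
  end_reason <- NA_character_
  k <- 0L
  repeat {
    if (k >= max_heptads) { end_reason <- "max_heptads"; break }
    base <- g0 + 7L * k
    h <- character(0)
    for (j in seq_along(regs)) {
      idx <- base + j - 1L
      if (idx > length(s)) { end_reason <- "sequence_end"; break }
      res <- s[idx]
      if (res == "P" && idx >= zs) { end_reason <- "helix_break"; break }
      h[regs[j]] <- res
    }
    if (!is.na(end_reason)) {
      if (length(h) > 0) heptads[[length(heptads) + 1L]] <- h
      break
    }
    if (!(h[["d"]] %in% d_set)) { end_reason <- "d_register_failure"; break }
    heptads[[length(heptads) + 1L]] <- h
    k <- k + 1L
  }
  n_complete <- sum(vapply(heptads, length, 0L) == 7L)
  structure(
    list(protein_id = domain$protein_id,
         heptads = heptads,
         n_heptads = n_complete,
         end_reason = end_reason,
         accepted = n_complete >= 2L),
    class = "leucine_zipper")
}

#' @export
print.leucine_zipper <- function(x, ...) {
  cat(sprintf("<leucine_zipper> %s: %d complete heptads (%s), %s\n",
              x$protein_id, x$n_heptads, x$end_reason,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Render a zipper with registers aligned in gabcdef columns
#'
#' @param zipper A `leucine_zipper`.
#' @return Character vector, one line per heptad (L0, L1, ...).
#' @export
format_zipper <- function(zipper) {
  regs <- c("g", "a", "b", "c", "d", "e", "f")
  hdr <- paste0("     ", paste(regs, collapse = " "))
  rows <- vapply(seq_along(zipper$heptads), function(i) {
    h <- zipper$heptads[[i]]
    cells <- vapply(regs, function(r) if (r %in% names(h)) h[[r]] else ".", "")
    sprintf("L%-3d %s", i - 1L, paste(cells, collapse = " "))
  }, "")
  c(hdr, rows)
}

# g-e' pair lookup from complete-pair lists: attractive basic-acidic
# (R-E, K-E), attractive acidic-basic (E-R, E-K, D-K), repulsive basic
# (K-K, R-K, R-Q, Q-K, K-Q), repulsive acidic (E-E, E-D, E-Q, Q-E).
GE_PAIR_TABLE <- local({
  tab <- c("R|E" = "attractive_basic_acidic",
           "K|E" = "attractive_basic_acidic",
           "E|R" = "attractive_acidic_basic",
           "E|K" = "attractive_acidic_basic",
           "D|K" = "attractive_acidic_basic",
           "K|K" = "repulsive_basic",
           "R|K" = "repulsive_basic",
           "R|Q" = "repulsive_basic",
           "Q|K" = "repulsive_basic",
           "K|Q" = "repulsive_basic",
           "E|E" = "repulsive_acidic",
           "E|D" = "repulsive_acidic",
           "E|Q" = "repulsive_acidic",
           "Q|E" = "repulsive_acidic")
  tab
})

GE_CATEGORIES <- c("attractive_basic_acidic", "attractive_acidic_basic",
                   "repulsive_basic", "repulsive_acidic", "complete_unlisted",
                   "incomplete_basic", "incomplete_acidic", "none")

# one-letter symbols for pair strings
GE_SYMBOLS <- c(attractive_basic_acidic = "G",
                attractive_acidic_basic = "Y",
                repulsive_basic = "B",
                repulsive_acidic = "R",
                complete_unlisted = "C",
                incomplete_basic = "b",
                incomplete_acidic = "a",
                none = "-")

#' Classify a g-e' residue pair
#'
#' Exact, ordered lookup against the salt-bridge pair lists: attractive
#' basic-acidic (R-E, K-E), attractive acidic-basic (E-R, E-K, D-K),
#' repulsive basic (K-K, R-K, R-Q, Q-K, K-Q) and repulsive acidic (E-E,
#' E-D, E-Q, Q-E). A pair is *complete* when both residues are chargeable
#' (R, K, E, D or Q); complete pairs absent from the lists are
#' `complete_unlisted`. When exactly one residue is chargeable the pair is
#' `incomplete_basic` (R/K) or `incomplete_acidic` (E/D, and Q as the
#' amide of Glu). Otherwise `none`. The lookup is ordered: (R,E) and
#' (E,R) fall in different categories.
#'
#' @param g_res,e_res Single residue letters at the g and e positions.
#' @return One of the eight category labels.
#' @export
classify_ge_pair <- function(g_res, e_res) {
  key <- paste(g_res, e_res, sep = "|")
  hit <- GE_PAIR_TABLE[key]
  if (!is.na(hit)) return(unname(hit))
  g_ch <- g_res %in% CHARGEABLE_SET
  e_ch <- e_res %in% CHARGEABLE_SET
  if (g_ch && e_ch) return("complete_unlisted")
  if (!g_ch && !e_ch) return("none")
  side <- if (g_ch) g_res else e_res
  if (side %in% c("R", "K")) "incomplete_basic" else "incomplete_acidic"
}

#' Enumerate and classify the g-e' pairs of a zipper
#'
#' Under the default `same_heptad` rule a pair is formed by the g and the
#' following e of the same heptad (in gabcdef order e follows g within one
#' heptad). Under `next_heptad` the g of heptad k is paired with the e of
#' heptad k+1 and attributed to heptad k+1 (the heptad of the e residue).
#'
#' @param zipper A `leucine_zipper`.
#' @param register_rule `"same_heptad"` or `"next_heptad"`.
#' @return Data frame: `protein_id`, `heptad_index` (0-based, of the e
#'   residue), `g_residue`, `e_residue`, `category`.
#' @export
ge_pairs <- function(zipper, register_rule = c("same_heptad", "next_heptad")) {
  register_rule <- match.arg(register_rule)
  hs <- zipper$heptads
  out <- list()
  take <- function(h, r) if (r %in% names(h)) h[[r]] else NA_character_
  if (register_rule == "same_heptad") {
    for (k in seq_along(hs)) {
      g <- take(hs[[k]], "g"); e <- take(hs[[k]], "e")
      if (!is.na(g) && !is.na(e))
        out[[length(out) + 1L]] <- list(k - 1L, g, e)
    }
  } else {
    if (length(hs) >= 2) {
      for (k in seq_len(length(hs) - 1L)) {
        g <- take(hs[[k]], "g"); e <- take(hs[[k + 1L]], "e")
        if (!is.na(g) && !is.na(e))
          out[[length(out) + 1L]] <- list(k, g, e)  # attributed to e's heptad
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(0), heptad_index = integer(0),
                      g_residue = character(0), e_residue = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  data.frame(
    protein_id = zipper$protein_id,
    heptad_index = vapply(out, `[[`, 0L, 1L),
    g_residue = vapply(out, `[[`, "", 2L),
    e_residue = vapply(out, `[[`, "", 3L),
    category = mapply(function(p) classify_ge_pair(p[[2L]], p[[3L]]), out),
    stringsAsFactors = FALSE)
}

#' Dimerization signature of a zipper
#'
#' One symbol per heptad from the pair categories (`G` basic-acidic
#' attractive, `Y` acidic-basic attractive, `B` basic repulsive, `R`
#' acidic repulsive, `C` complete unlisted, `b`/`a` incomplete
#' basic/acidic, `-` none, `.` no pair at that heptad).
#'
#' @inheritParams ge_pairs
#' @return One-row data frame: `protein_id`, `n_heptads`, `pair_string`.
#' @export
dimer_signature <- function(zipper,
                            register_rule = c("same_heptad", "next_heptad")) {
  register_rule <- match.arg(register_rule)
  pairs <- ge_pairs(zipper, register_rule)
  sym <- rep(".", length(zipper$heptads))
  if (nrow(pairs) > 0)
    sym[pairs$heptad_index + 1L] <- unname(GE_SYMBOLS[pairs$category])
  data.frame(protein_id = zipper$protein_id,
             n_heptads = zipper$n_heptads,
             pair_string = paste(sym, collapse = ""),
             stringsAsFactors = FALSE)
}

#' Group dimerization signatures into types
#'
#' Proteins sharing both heptad count and pair string share a type;
#' type ids are assigned in order of first appearance.
#'
#' @param signatures Data frame from [dimer_signature()] rows.
#' @return The input with a `type_id` column; the number of distinct types
#'   is attached as attribute `n_types`.
#' @export
dimerization_types <- function(signatures) {
  key <- paste(signatures$n_heptads, signatures$pair_string, sep = ":")
  type_id <- match(key, unique(key))
  signatures$type_id <- type_id
  attr(signatures, "n_types") <- length(unique(key))
  signatures
}

#' Pooled residue composition of the a, d, e and g registers
#'
#' Frequencies are over all occupied positions of each register pooled
#' across proteins (partial terminal heptads contribute only their
#' occupied registers). Charged fractions at e and g use R, K, E, D.
#'
#' @param zippers List of `leucine_zipper` objects.
#' @return List with `table` (data frame: register, residue, count, freq)
#'   and `charged_fraction` (named numeric for e and g).
#' @export
composition_stats <- function(zippers) {
  if (length(zippers) == 0L) stop("no zippers supplied")
  regs <- c("a", "d", "e", "g")
  pooled <- lapply(regs, function(r) {
    unlist(lapply(zippers, function(z)
      vapply(z$heptads,
             function(h) if (r %in% names(h)) h[[r]] else NA_character_, "")),
      use.names = FALSE)
  })
  names(pooled) <- regs
  rows <- do.call(rbind, lapply(regs, function(r) {
    v <- pooled[[r]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    tab <- table(v)
    data.frame(register = r, residue = names(tab),
               count = as.integer(tab),
               freq = as.numeric(tab) / length(v),
               stringsAsFactors = FALSE)
  }))
  charged <- vapply(c(e = "e", g = "g"), function(r) {
    v <- pooled[[r]]; v <- v[!is.na(v)]
    mean(v %in% CHARGED_SET)
  }, 0)
  list(table = rows, charged_fraction = charged)
}

#' Fraction of a-register asparagines per heptad
#'
#' For each heptad index, the fraction of zippers (with that heptad's a
#' register occupied) carrying Asn there. Asn at the a position stabilises
#' a-a' contacts and favours homodimerization.
#'
#' @param zippers List of `leucine_zipper` objects.
#' @return Data frame: `heptad_index` (0-based), `n` (denominator),
#'   `asn_fraction`.
#' @export
asn_per_heptad <- function(zippers) {
  max_h <- max(c(0L, vapply(zippers, function(z) length(z$heptads), 0L)))
  if (max_h == 0L)
    return(data.frame(heptad_index = integer(0), n = integer(0),
                      asn_fraction = numeric(0)))
  rows <- lapply(seq_len(max_h) - 1L, function(k) {
    a <- vapply(zippers, function(z) {
      if (length(z$heptads) > k && "a" %in% names(z$heptads[[k + 1L]]))
        z$heptads[[k + 1L]][["a"]] else NA_character_
    }, "")
    a <- a[!is.na(a)]
    data.frame(heptad_index = k, n = length(a),
               asn_fraction = if (length(a)) mean(a == "N") else 0)
  })
  out <- do.call(rbind, rows)
  out[out$n > 0, , drop = FALSE]
}

#' Per-heptad frequencies of g-e' pair categories
#'
#' Counts are normalised per heptad by the number of zippers contributing
#' a pair at that heptad. `complete` aggregates the four named classes
#' plus `complete_unlisted`; `incomplete` aggregates the two incomplete
#' classes.
#'
#' @param zippers List of `leucine_zipper` objects.
#' @param register_rule Passed to [ge_pairs()].
#' @return List with `by_category` (data frame: heptad_index, category,
#'   count, freq) and `aggregate` (data frame: heptad_index, n,
#'   complete_freq, incomplete_freq).
#' @export
pair_histogram <- function(zippers,
                           register_rule = c("same_heptad", "next_heptad")) {
  register_rule <- match.arg(register_rule)
  pairs <- do.call(rbind, lapply(zippers, ge_pairs, register_rule))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(by_category = data.frame(heptad_index = integer(0),
                                         category = character(0),
                                         count = integer(0),
                                         freq = numeric(0)),
                aggregate = data.frame(heptad_index = integer(0),
                                       n = integer(0),
                                       complete_freq = numeric(0),
                                       incomplete_freq = numeric(0))))
  complete_set <- c("attractive_basic_acidic", "attractive_acidic_basic",
                    "repulsive_basic", "repulsive_acidic", "complete_unlisted")
  by_cat <- do.call(rbind, lapply(sort(unique(pairs$heptad_index)), function(k) {
    p <- pairs[pairs$heptad_index == k, ]
    tab <- table(factor(p$category, levels = GE_CATEGORIES))
    tab <- tab[tab > 0]
    data.frame(heptad_index = k, category = names(tab),
               count = as.integer(tab), freq = as.numeric(tab) / nrow(p),
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(sort(unique(pairs$heptad_index)), function(k) {
    p <- pairs[pairs$heptad_index == k, ]
    data.frame(heptad_index = k, n = nrow(p),
               complete_freq = mean(p$category %in% complete_set),
               incomplete_freq = mean(p$category %in%
                                        c("incomplete_basic", "incomplete_acidic")))
  }))
  list(by_category = by_cat, aggregate = agg)
}
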