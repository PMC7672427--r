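# Free-energy evaluation.  Two independent routes exist on purpose:
#   * hairpin_mfe()  - walks the designed stem of a `hairpin` object (pure R);
#   * enumerate_mfe() - exhaustively enumerates every nested structure of a
#     short sequence in C++ and returns the global minimum.
# Both score with the same energy_model tables, so the enumeration acts as a
# brute-force oracle for the designed fold.

#' Free energy of the designed hairpin fold
#'
#' Sums stacking doublets over adjacent stem pairs, adds the hairpin-loop
#' initiation term for the loop size and a terminal penalty for each AU/GU
#' helix end (the outermost pair and the loop-closing pair).  The unfolded
#' chain is the zero reference, so the result is clipped at 0: a stem whose
#' summed terms are destabilizing simply does not fold.
#'
#' Cloning overhangs must be stripped before calling; only the stem and loop
#' are scored.
#'
#' @param h a [hairpin()].
#' @param model an [energy_model()].
#' @param clip clip positive totals to 0 (default). `clip = FALSE` returns the
#'   raw sum, which is what the additivity tests use.
#' @return Free energy in kcal/mol (<= 0 when `clip = TRUE`).
#' @examples
#' hairpin_mfe(hairpin("hp", "GGGG", "GAAA", "CCCC"))
#' @export
hairpin_mfe <- function(h, model = energy_model(), clip = TRUE) {
  stopifnot(inherits(h, "hairpin"))
  s5 <- .seq_chars(h$stem5); s3 <- .seq_chars(h$stem3)
  L <- length(s5)
  pt <- pair_type(s5, rev(s3))
  if (anyNA(pt)) stop("not a closed stem")
  dg <- loop_init_dg(nchar(h$loop), model)
  if (L > 1L)
    for (i in seq_len(L - 1L)) dg <- dg + .stack_dg(model, pt[i], pt[i + 1L])
  if (.is_au_gu(pt[1L])) dg <- dg + model$au_end   # helix base
  if (.is_au_gu(pt[L])) dg <- dg + model$au_end    # loop-closing pair
  if (clip) min(dg, 0) else dg
}

#' Free energy of an arbitrary nested structure
#'
#' Scores any dot-bracket structure on a sequence under the same model terms
#' as [hairpin_mfe()]: stacking for adjacent pairs, hairpin-loop initiation
#' for pairs enclosing only unpaired bases, and the AU/GU penalty at every
#' helix terminus.  Interior loops, bulges and multibranch loops carry no
#' initiation term in this reduced model.
#'
#' @param seq RNA (or DNA) sequence.
#' @param structure dot-bracket string of the same length.
#' @param model an [energy_model()].
#' @return Free energy in kcal/mol (0 for the open chain).
#' @export
structure_dg <- function(seq, structure, model = energy_model()) {
  seq <- sanitize_rna(seq)
  n <- nchar(seq)
  if (nchar(structure) != n) stop("sequence and structure lengths differ")
  sym <- .seq_chars(structure)
  if (any(!sym %in% c("(", ")", "."))) stop("structure must be dot-bracket")
  chars <- .seq_chars(seq)
  mate <- integer(n); mate[] <- NA_integer_
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (sym[i] == "(") stack <- c(stack, i)
    else if (sym[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      mate[j] <- i; mate[i] <- j
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure")
  dg <- 0
  for (i in seq_len(n)) {
    j <- mate[i]
    if (is.na(j) || j < i) next
    if (j - i - 1L < 3L) stop("hairpin loop shorter than 3 nt")
    pt <- pair_type(chars[i], chars[j])
    if (is.na(pt)) stop(sprintf("bases %d and %d cannot pair", i, j))
    inner_stacked <- !is.na(mate[i + 1L]) && mate[i + 1L] == j - 1L
    if (inner_stacked) {
      pt_in <- pair_type(chars[i + 1L], chars[j - 1L])
      dg <- dg + .stack_dg(model, pt, pt_in)
    }
    if (all(is.na(mate[(i + 1L):(j - 1L)])))            # hairpin loop
      dg <- dg + loop_init_dg(j - i - 1L, model)
    if (.is_au_gu(pt)) {
      outer_term <- i == 1L || j == n || is.na(mate[i - 1L]) || mate[i - 1L] != j + 1L
      if (outer_term) dg <- dg + model$au_end
      if (!inner_stacked) dg <- dg + model$au_end
    }
  }
  dg
}

#' Exhaustive minimum-free-energy search for short sequences
#'
#' Enumerates every nested secondary structure (minimum hairpin loop 3 nt,
#' Watson-Crick and GU pairs) of a short sequence and returns the global
#' minimum under the package energy model.  Ties are broken toward fewer
#' pairs, then toward the lexicographically smallest dot-bracket.  This is
#' the brute-force verification oracle for [hairpin_mfe()]; the length cap
#' keeps the enumeration exact and fast.
#'
#' @param seq RNA (or DNA) sequence.
#' @param model an [energy_model()].
#' @param max_len refuse sequences longer than this (default 25 nt).
#' @return A list with `structure` (dot-bracket), `dg` (kcal/mol, <= 0) and
#'   `n_structures` (number of structures enumerated).
#' @examples
#' enumerate_mfe("AAAAAAAA")          # no pairs possible -> open chain, 0
#' enumerate_mfe("GGGGGAAACCCCC")
#' @export
enumerate_mfe <- function(seq, model = energy_model(), max_len = 25L) {
  seq <- sanitize_rna(seq)
  n <- nchar(seq)
  if (n > max_len)
    stop(sprintf("sequence too long for exhaustive enumeration (cap %d nt)", max_len))
  codes <- match(.seq_chars(seq), c("A", "C", "G", "U")) - 1L
  # 4x4 base-pair type index (1..6 in PAIR_TYPES order, 0 = not pairable)
  pairidx <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  for (k in seq_along(PAIR_TYPES)) {
    b <- .seq_chars(PAIR_TYPES[k])
    pairidx[b[1], b[2]] <- k
  }
  loop_vec <- vapply(seq_len(max(n, 3L)), function(s)
    if (s >= 3L) loop_init_dg(s, model) else NA_real_, numeric(1))
  res <- enum_mfe_cpp(codes, pairidx, model$stack, loop_vec, model$au_end)
  res
}

#' Minimum free energy of a free sequence
#'
#' Companion entry point to [hairpin_mfe()] for sequences rather than
#' `hairpin` objects: returns the enumerated global MFE, which is 0 for
#' sequences that cannot form any structure.
#'
#' @inheritParams enumerate_mfe
#' @return Free energy in kcal/mol (<= 0).
#' @export
sequence_mfe <- function(seq, model = energy_model(), max_len = 25L) {
  enumerate_mfe(seq, model, max_len)$dg
}
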