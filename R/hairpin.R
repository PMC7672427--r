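# Hairpin regulation elements: a closed stem-loop with a cap-relative
# position.  Coordinates are transcript 1-based; the cap nucleotide is +1 and
# `position` is the transcript coordinate of the first stem nucleotide.

#' Construct a 5'-UTR hairpin regulation element
#'
#' A hairpin is a fully paired stem (both arms given 5'->3') closed by a loop
#' of at least 3 nt, placed at a 1-based transcript coordinate (cap = +1).
#' Every aligned stem position must form a Watson-Crick or GU wobble pair:
#' `stem5[i]` pairs with `stem3[len - i + 1]`.
#'
#' @param name element identifier.
#' @param stem5 5' stem arm, 5'->3'.
#' @param loop loop sequence (>= 3 nt).
#' @param stem3 3' stem arm, 5'->3' (same length as `stem5`).
#' @param position transcript coordinate of the first stem nucleotide (>= 1).
#' @return An object of class `hairpin`.
#' @examples
#' h <- hairpin("hp1", "GGGG", "GAAA", "CCCC")
#' stem_gc_content(h)
#' @export
hairpin <- function(name, stem5, loop, stem3, position = 15L) {
  stopifnot(is.character(name), length(name) == 1L)
  stem5 <- sanitize_rna(stem5)
  loop <- sanitize_rna(loop)
  stem3 <- sanitize_rna(stem3)
  .check_scalar(position, "position", lower = 1)
  if (nchar(stem5) != nchar(stem3))
    stop("stem arms must have equal length (got ", nchar(stem5), " and ",
         nchar(stem3), ")")
  if (nchar(stem5) < 1L) stop("no stem")
  if (nchar(loop) < 3L) stop("loop must be at least 3 nt")
  s5 <- .seq_chars(stem5); s3 <- .seq_chars(stem3); L <- length(s5)
  pt <- pair_type(s5, rev(s3))
  if (anyNA(pt))
    stop("not a closed stem: position(s) ", paste(which(is.na(pt)), collapse = ","),
         " cannot pair")
  structure(
    list(name = name, stem5 = stem5, loop = loop, stem3 = stem3,
         position = as.integer(position)),
    class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> %s  (+%d, stem %d bp, loop %d nt)\n",
              x$name, x$position, nchar(x$stem5), nchar(x$loop)))
  cat(" ", hairpin_sequence(x), "\n")
  cat(" ", dot_bracket(x), "\n")
  invisible(x)
}

#' Full hairpin sequence (stem5 + loop + stem3)
#' @param h a [hairpin()].
#' @return RNA sequence string.
#' @export
hairpin_sequence <- function(h) paste0(h$stem5, h$loop, h$stem3)

#' Dot-bracket string of the designed fold
#' @param h a [hairpin()].
#' @return Dot-bracket notation of the hairpin's own stem-loop fold.
#' @export
dot_bracket <- function(h) {
  L <- nchar(h$stem5)
  paste0(strrep("(", L), strrep(".", nchar(h$loop)), strrep(")", L))
}

#' GC fraction of the hairpin stem
#'
#' Counts G and C over both stem arms; the loop is excluded.
#'
#' @param h a [hairpin()].
#' @return Fraction in `[0, 1]`.
#' @export
stem_gc_content <- function(h) {
  stem <- paste0(h$stem5, h$stem3)
  if (nchar(stem) == 0L) stop("no stem")
  chars <- .seq_chars(stem)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Classify a stem GC fraction as low / medium / high
#'
#' Thresholds follow the convention that high-GC stems (> 75%) repress
#' slightly more strongly than low-GC stems (< 40%) of equal stability.
#'
#' @param frac GC fraction in `[0, 1]`.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_gc <- function(frac) {
  .check_scalar(frac, "frac", lower = 0, upper = 1)
  if (frac < GC_LOW_THRESHOLD) "low"
  else if (frac > GC_HIGH_THRESHOLD) "high"
  else "medium"
}
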