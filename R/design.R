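# Element placement in the 5'-UTR and target-driven stem design.
#
# The default cloning site sits at +15 relative to the transcription start
# site (cap = +1).  Elements upstream of +15 truncate the leader; elements
# downstream are pushed out with unstructured 5'-CAA-3' spacer repeats, so
# spacer lengths must be multiples of 3.

# Synthetic stand-in for the 14-nt leader between cap and the +15 cloning
# site (the real vector leader is not bundled); chosen AU-rich and
# structure-free.
DEFAULT_LEADER <- "ACAUUCAUCUUCAA"

#' Place a hairpin element in a 5'-UTR
#'
#' Builds the full UTR sequence so that the first stem nucleotide lands at
#' the hairpin's `position`: positions above the insertion point are reached
#' with CAA spacer repeats, positions below it by truncating the leader.
#'
#' @param h a [hairpin()]; `h$position` must be >= 3 and, when above
#'   `insertion_point`, offset from it by a multiple of 3.
#' @param insertion_point transcript coordinate of the cloning site
#'   (default 15).
#' @param leader leader sequence between cap and insertion point; defaults to
#'   the bundled synthetic 14-nt leader.  Must be at least
#'   `insertion_point - 1` nt.
#' @param downstream sequence appended after the element (may be empty).
#' @return An object of class `placed_element` with fields `hairpin`,
#'   `leader`, `spacer`, `downstream` and `full_utr`.
#' @examples
#' pe <- place_element(hairpin("hp", "GGGG", "GAAA", "CCCC", position = 33))
#' pe$spacer   # six CAA repeats
#' @export
place_element <- function(h, insertion_point = 15L, leader = NULL,
                          downstream = "") {
  stopifnot(inherits(h, "hairpin"))
  .check_scalar(insertion_point, "insertion_point", lower = 1)
  pos <- h$position
  if (pos < 3L) stop("position must be >= 3")
  if (is.null(leader)) leader <- DEFAULT_LEADER
  leader <- if (nzchar(leader)) sanitize_rna(leader) else ""
  downstream <- if (nzchar(downstream)) sanitize_rna(downstream) else ""
  if (nchar(leader) < insertion_point - 1L)
    stop("leader shorter than insertion_point - 1")
  if (pos > insertion_point) {
    gap <- pos - insertion_point
    if (gap %% 3L != 0L)
      stop("spacer length not a multiple of 3 (position ", pos,
           ", insertion point ", insertion_point, ")")
    lead <- substr(leader, 1L, insertion_point - 1L)
    spacer <- strrep("CAA", gap %/% 3L)
  } else {
    lead <- substr(leader, 1L, pos - 1L)
    spacer <- ""
  }
  full <- paste0(lead, spacer, hairpin_sequence(h), downstream)
  structure(
    list(hairpin = h, leader = lead, spacer = spacer,
         downstream = downstream, full_utr = full),
    class = "placed_element")
}

#' @export
print.placed_element <- function(x, ...) {
  cat(sprintf("<placed_element> %s at +%d (leader %d nt, spacer %d nt)\n",
              x$hairpin$name, x$hairpin$position, nchar(x$leader), nchar(x$spacer)))
  cat(" ", x$full_utr, "\n")
  invisible(x)
}

#' Recover an element's position from a placed UTR
#'
#' Locates the hairpin sequence inside a full UTR and returns its 1-based
#' transcript coordinate; used for the placement round trip.
#'
#' @param full_utr UTR sequence.
#' @param h the [hairpin()] expected inside it.
#' @return Integer position (cap = +1).
#' @export
parse_placed_element <- function(full_utr, h) {
  full_utr <- sanitize_rna(full_utr)
  hit <- regexpr(hairpin_sequence(h), full_utr, fixed = TRUE)
  if (hit < 0L) stop("hairpin sequence not found in UTR")
  as.integer(hit)
}

#' Design a stem to a target free energy and GC class
#'
#' Searches stem lengths in ascending order; at each length it samples
#' Watson-Crick pair compositions compatible with the requested GC class
#' (GC-pair count constrained so the stem GC fraction falls in the class
#' band) and accepts the first stem whose [hairpin_mfe()] is within `tol` of
#' the target.  The search is deterministic for a given `seed`.
#'
#' @param target_dg target free energy, kcal/mol (<= 0).
#' @param gc_class `"low"`, `"medium"` or `"high"`.
#' @param loop loop sequence (default `"GAAA"`).
#' @param model an [energy_model()].
#' @param tol acceptance tolerance in kcal/mol.
#' @param position cap-relative position given to the designed element.
#' @param max_stem maximum stem length tried before declaring the target
#'   unreachable.
#' @param tries_per_length candidate stems sampled per length.
#' @param seed RNG seed; fixed default makes the designer reproducible.
#' @param name element name.
#' @return A [hairpin()] satisfying both constraints.
#' @export
design_stem <- function(target_dg, gc_class = c("medium", "low", "high"),
                        loop = "GAAA", model = energy_model(), tol = 0.5,
                        position = 15L, max_stem = 30L,
                        tries_per_length = 250L, seed = 1L,
                        name = "designed") {
  gc_class <- match.arg(gc_class)
  .check_scalar(target_dg, "target_dg", upper = 0)
  .check_scalar(tol, "tol", lower = 0)
  loop <- sanitize_rna(loop)
  if (nchar(loop) < 3L) stop("loop must be at least 3 nt")
  gc_pair_range <- function(len) {
    # stem GC fraction with WC pairs only = n_gc_pairs / len
    lo <- switch(gc_class,
                 low = 0L,
                 medium = ceiling(GC_LOW_THRESHOLD * len),
                 high = floor(GC_HIGH_THRESHOLD * len) + 1L)
    hi <- switch(gc_class,
                 low = ceiling(GC_LOW_THRESHOLD * len) - 1L,
                 medium = floor(GC_HIGH_THRESHOLD * len),
                 high = len)
    # keep fractions strictly inside the class band
    while (lo <= hi && classify_gc(lo / len) != gc_class) lo <- lo + 1L
    while (hi >= lo && classify_gc(hi / len) != gc_class) hi <- hi - 1L
    if (lo > hi) NULL else c(lo, hi)
  }
  with_seed(seed, {
    for (len in 2:max_stem) {
      rng <- gc_pair_range(len)
      if (is.null(rng)) next
      for (k in seq_len(tries_per_length)) {
        n_gc <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
        kinds <- sample(c(rep("gc", n_gc), rep("au", len - n_gc)))
        s5 <- character(len); s3r <- character(len)
        for (i in seq_len(len)) {
          if (kinds[i] == "gc") {
            p <- sample(c("GC", "CG"), 1L)
          } else {
            p <- sample(c("AU", "UA"), 1L)
          }
          b <- .seq_chars(p)
          s5[i] <- b[1]; s3r[i] <- b[2]
        }
        h <- hairpin(name, paste(s5, collapse = ""), loop,
                     paste(rev(s3r), collapse = ""), position = position)
        if (abs(hairpin_mfe(h, model) - target_dg) <= tol &&
            classify_gc(stem_gc_content(h)) == gc_class)
          return(h)
      }
    }
    stop(sprintf("unreachable target: no %s-GC stem up to %d bp reaches %.2f +/- %.2f kcal/mol",
                 gc_class, max_stem, target_dg, tol))
  })
}

# --- external interfaces -----------------------------------------------------

#' Write hairpins to FASTA
#'
#' One record per element; the description carries the cap-relative position,
#' free energy and stem/loop split so [read_hairpin_fasta()] can reconstruct
#' the objects.
#'
#' @param hairpins list of [hairpin()] objects.
#' @param path output file.
#' @param model an [energy_model()] used to annotate free energies.
#' @return `path`, invisibly.
#' @export
write_hairpin_fasta <- function(hairpins, path, model = energy_model()) {
  if (inherits(hairpins, "hairpin")) hairpins <- list(hairpins)
  seqs <- vapply(hairpins, hairpin_sequence, character(1))
  heads <- vapply(hairpins, function(h)
    sprintf("%s position=%d stem_len=%d loop_len=%d dg=%.2f", h$name,
            h$position, nchar(h$stem5), nchar(h$loop),
            hairpin_mfe(h, model)), character(1))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- heads
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", heads), seqs)), path)
  }
  invisible(path)
}

#' Read hairpins from FASTA written by [write_hairpin_fasta()]
#'
#' @param path FASTA file.
#' @return List of [hairpin()] objects.
#' @export
read_hairpin_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    heads <- names(x)
    seqs <- as.character(x)
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    heads <- sub("^>", "", lines[idx])
    seqs <- vapply(seq_along(idx), function(i) {
      to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
      paste(lines[(idx[i] + 1L):to], collapse = "")
    }, character(1))
  }
  lapply(seq_along(seqs), function(i) {
    f <- strsplit(heads[i], "\\s+")[[1]]
    nm <- f[1]
    get_field <- function(key) {
      v <- grep(paste0("^", key, "="), f, value = TRUE)
      if (length(v) == 0) stop("missing FASTA field: ", key)
      as.numeric(sub(paste0(key, "="), "", v[1]))
    }
    pos <- get_field("position"); sl <- get_field("stem_len"); ll <- get_field("loop_len")
    s <- sanitize_rna(seqs[i])
    hairpin(nm,
            substr(s, 1, sl),
            substr(s, sl + 1, sl + ll),
            substr(s, sl + ll + 1, sl + ll + sl),
            position = pos)
  })
}

#' Property table for a set of hairpins
#'
#' @param hairpins list of [hairpin()] objects.
#' @param model an [energy_model()].
#' @param path optional CSV output path.
#' @return `data.frame` with columns `name`, `dg_kcal_mol`, `gc_fraction`,
#'   `gc_class`, `position`.
#' @export
hairpin_property_table <- function(hairpins, model = energy_model(), path = NULL) {
  if (inherits(hairpins, "hairpin")) hairpins <- list(hairpins)
  out <- data.frame(
    name = vapply(hairpins, function(h) h$name, character(1)),
    dg_kcal_mol = vapply(hairpins, hairpin_mfe, numeric(1), model = model),
    gc_fraction = vapply(hairpins, stem_gc_content, numeric(1)),
    position = vapply(hairpins, function(h) h$position, integer(1)),
    stringsAsFactors = FALSE)
  out$gc_class <- vapply(out$gc_fraction, classify_gc, character(1))
  out <- out[c("name", "dg_kcal_mol", "gc_fraction", "gc_class", "position")]
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
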