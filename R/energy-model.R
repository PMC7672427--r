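# Nearest-neighbor free-energy parameters for RNA stem-loops at 37 degC.
#
# The tables embed a published Watson-Crick + GU wobble nearest-neighbor
# subset (stack doublets, hairpin-loop initiation for 3-30 nt with
# 1.75*RT*ln(n/30) extrapolation beyond, and a per-terminal AU/GU penalty).
# Absolute values approximate, but do not exactly reproduce, full-featured
# folding servers: tetraloop bonuses, dangles and special-case loops are
# deliberately excluded so the model stays small, self-contained and
# verifiable by exhaustive enumeration.

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
GC_LOW_THRESHOLD <- 0.40
GC_HIGH_THRESHOLD <- 0.75
RT_37 <- 0.0019872 * 310.15   # kcal/mol

# flip = read the pair from the opposite strand
.flip_pair <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")

.build_stack_table <- function() {
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  set <- function(outer, inner, dg) m[outer, inner] <<- dg
  # Watson-Crick doublets (10 unique parameters)
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "AU", -2.11); set("CG", "UA", -2.08)
  set("GC", "AU", -2.35); set("GC", "UA", -2.24)
  set("CG", "GC", -2.36); set("GC", "GC", -3.26); set("GC", "CG", -3.42)
  # GU wobble doublets (approximate published values)
  set("AU", "GU", -0.55); set("AU", "UG", -1.36)
  set("UA", "GU", -1.00); set("UA", "UG", -1.27)
  set("CG", "GU", -1.41); set("CG", "UG", -2.11)
  set("GC", "GU", -1.53); set("GC", "UG", -2.51)
  set("GU", "GU",  0.50); set("UG", "UG",  0.50)
  set("GU", "UG", -0.50); set("UG", "GU",  0.30)
  # remaining entries by 180-degree rotation symmetry:
  # dg(outer, inner) == dg(flip(inner), flip(outer))
  for (o in PAIR_TYPES) for (i in PAIR_TYPES) {
    if (is.na(m[o, i])) m[o, i] <- m[.flip_pair[i], .flip_pair[o]]
  }
  stopifnot(!anyNA(m))
  m
}

.build_hairpin_loop_table <- function() {
  init <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)   # loop sizes 3..9
  n <- 10:30
  ext <- init[7] + 1.75 * RT_37 * log(n / 9)
  out <- c(init, ext)
  names(out) <- 3:30
  out
}

#' Nearest-neighbor energy model for RNA stem-loops
#'
#' Bundles the stacking doublet table (kcal/mol at 37 degC), the hairpin-loop
#' initiation table (loop sizes 3-30 nt, logarithmically extrapolated beyond
#' 30) and the per-terminal AU/GU helix-end penalty used by [hairpin_mfe()],
#' [structure_dg()] and [enumerate_mfe()].
#'
#' @param au_end_penalty penalty in kcal/mol added for every helix-terminal
#'   AU, UA, GU or UG pair.
#' @return An object of class `energy_model`: a list with elements `stack`
#'   (6 x 6 matrix indexed by pair type), `loop_init` (named vector for loop
#'   sizes 3-30), `au_end` and `temperature` (fixed at 37 degC).
#' @examples
#' m <- energy_model()
#' m$stack["GC", "GC"]   # 5'GG3'/3'CC5' doublet
#' @export
energy_model <- function(au_end_penalty = 0.45) {
  .check_scalar(au_end_penalty, "au_end_penalty", lower = 0)
  structure(
    list(stack = .build_stack_table(),
         loop_init = .build_hairpin_loop_table(),
         au_end = au_end_penalty,
         temperature = 37),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("RNA nearest-neighbor energy model (37 degC)\n")
  cat(sprintf("  %d stack doublets, hairpin-loop init for %d loop sizes,\n",
              length(x$stack), length(x$loop_init)))
  cat(sprintf("  terminal AU/GU penalty %.2f kcal/mol\n", x$au_end))
  invisible(x)
}

#' Hairpin-loop initiation free energy
#'
#' Tabulated for loop sizes 3-30 nt; larger loops use the standard
#' `1.75 * RT * ln(n/30)` Jacobson-Stockmayer extrapolation from the 30-nt
#' entry.
#'
#' @param n loop size in nucleotides (>= 3).
#' @param model an [energy_model()].
#' @return Initiation free energy in kcal/mol (always > 0).
#' @export
loop_init_dg <- function(n, model = energy_model()) {
  .check_scalar(n, "n", lower = 3)
  n <- as.integer(n)
  if (n <= 30L) unname(model$loop_init[as.character(n)])
  else unname(model$loop_init["30"]) + 1.75 * RT_37 * log(n / 30)
}

# --- sequence utilities ------------------------------------------------------

#' Normalize a nucleotide sequence to uppercase RNA
#'
#' DNA input is accepted: `T` is transcribed to `U`; mixed case is uppercased.
#'
#' @param x character vector of sequences.
#' @return Uppercase RNA sequences over the alphabet A, C, G, U.
#' @export
sanitize_rna <- function(x) {
  x <- chartr("tT", "uU", toupper(as.character(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,U,T}: ",
         paste(unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), ""))), collapse = ","))
  x
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Pair type of two RNA bases
#'
#' @param a,b single bases (A, C, G or U).
#' @return One of `"AU"`, `"UA"`, `"GC"`, `"CG"`, `"GU"`, `"UG"`, or `NA` if
#'   the bases cannot pair.
#' @export
pair_type <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% PAIR_TYPES, key, NA_character_)
}

.stack_dg <- function(model, outer, inner) model$stack[outer, inner]

.is_au_gu <- function(pt) pt %in% c("AU", "UA", "GU", "UG")
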