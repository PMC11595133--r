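# Turner 2004 RNA stacking free energies (dG37, kcal/mol), Watson-Crick and
# G:U wobble pairs, transcribed from the "# stack" block of the ViennaRNA
# 2.x distribution parameter set rna_turner2004.par (values there are in
# dekacal/mol). Reference: Turner & Mathews, NNDB (doi:10.1093/nar/gkp892).
# Row = outer pair (X1:Y1), column = inner pair (X2:Y2) of the stack
#   5'-X1 X2-3'
#   3'-Y1 Y2-5'
# Pair names give the top-strand base first: "GU" is top-strand G paired to
# bottom-strand U. The DNA alphabet is used internally, so U is written T.
.nn_pairs <- c("CG", "GC", "GT", "TG", "AT", "TA")
.nn_stack <- matrix(c(
  # CG     GC     GU     UG     AU     UA      (inner)
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # outer CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # outer GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # outer GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # outer UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # outer AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30), # outer UA
  nrow = 6, byrow = TRUE, dimnames = list(.nn_pairs, .nn_pairs))

#' Nearest-neighbor duplex energy model
#'
#' Stacking free-energy table (Turner 2004, 37 degC, kcal/mol) over ordered
#' Watson-Crick and G:U wobble pairs, plus a duplex initiation penalty.
#' Loop and bulge terms are deliberately not modeled: alignment gaps and
#' mismatches simply break stacks.
#'
#' @param init_penalty Duplex initiation free energy in kcal/mol (default
#'   +4.09, Turner 2004).
#' @return List with `stack` (6x6 matrix, pair x pair, in kcal/mol),
#'   `init_penalty` and a `version` tag. Pair names use the DNA alphabet
#'   (T == U) with the top-strand (miRNA/lncRNA query) base first.
#' @export
nn_energy_model <- function(init_penalty = 4.09) {
  list(stack = .nn_stack, init_penalty = init_penalty,
       version = "turner2004-wc-gu")
}

# Classify a base pair (top, bottom): "wc", "gu" or NA (illegal).
pair_class <- function(top, bottom) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(bottom == wc[top], "wc",
         ifelse((top == "G" & bottom == "T") | (top == "T" & bottom == "G"),
                "gu", NA_character_))
}

#' Free energy of a gap-free duplex from its base-pair list
#'
#' The duplex is given as the ordered list of its base pairs (top strand
#' 5'->3'); the energy is the initiation penalty plus the stacking term for
#' every consecutive pair of pairs. Any pair that is neither Watson-Crick
#' nor G:U makes the duplex illegal and the energy `+Inf`.
#'
#' @param pairs Character vector of 2-letter pairs (`"GC"` = top-strand G
#'   paired to bottom-strand C; T and U equivalent), or a 2-column matrix of
#'   top/bottom bases.
#' @param model An [nn_energy_model()].
#' @return Energy in kcal/mol (`+Inf` for an illegal pair).
#' @examples
#' duplex_energy(c("GC", "CG", "AT"), nn_energy_model())
#' @export
duplex_energy <- function(pairs, model = nn_energy_model()) {
  if (is.matrix(pairs)) pairs <- paste0(pairs[, 1], pairs[, 2])
  if (!length(pairs)) stop("empty base-pair list", call. = FALSE)
  pairs <- chartr("U", "T", toupper(pairs))
  if (!all(pairs %in% .nn_pairs)) return(Inf)
  if (length(pairs) == 1L) return(model$init_penalty)
  stacks <- model$stack[cbind(pairs[-length(pairs)], pairs[-1])]
  model$init_penalty + sum(stacks)
}

# Energy of an aligned (possibly gapped/mismatched) duplex: initiation once,
# plus stack terms within maximal runs of contiguous legal pairs. `top` and
# `bottom` are equal-length aligned strings with "-" gaps.
aligned_duplex_energy <- function(top, bottom, model = nn_energy_model()) {
  tt <- strsplit(top, "", fixed = TRUE)[[1]]
  bb <- strsplit(bottom, "", fixed = TRUE)[[1]]
  pr <- paste0(tt, bb)
  legal <- tt != "-" & bb != "-" & pr %in% .nn_pairs
  e <- model$init_penalty
  for (i in which(legal[-length(legal)] & legal[-1]))
    e <- e + model$stack[pr[i], pr[i + 1]]
  e
}
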