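# Elemental bookkeeping: compositions are named integer vectors over the
# tracked elements; charge is carried separately. Polymer compositions
# (proteins, RNAs) are derived from monomer compositions by condensation
# arithmetic so that expression-layer reactions balance by construction.

PC_ELEMENTS <- c("C", "H", "N", "O", "P")

#' Elemental composition vector
#'
#' @param C,H,N,O,P atom counts.
#' @return named numeric vector over the tracked elements (C, H, N, O, P).
#' @export
comp <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  c(C = C, H = H, N = N, O = O, P = P)
}

comp_zero <- function() comp()

comp_add <- function(...) {
  out <- comp_zero()
  for (x in list(...)) out <- out + x[PC_ELEMENTS]
  out
}

comp_scale <- function(x, k) x[PC_ELEMENTS] * k

# Average atomic masses, g/mol.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)

#' Molecular weight from an elemental composition
#'
#' @param composition named vector over C, H, N, O, P.
#' @return mass in g/mmol (numerically equal to kDa).
#' @export
comp_mw <- function(composition) {
  unname(sum(.ATOMIC_MASS[PC_ELEMENTS] * composition[PC_ELEMENTS]) / 1000)
}

#' Amino acid reference table
#'
#' The reduced amino-acid alphabet used by the bundled synthetic network:
#' free-molecule elemental composition, charge at cytosolic pH, and molecular
#' weight of the free amino acid. Proteins are condensation polymers, so a
#' chain of length L has composition `sum(monomers) - (L - 1) * H2O`.
#'
#' @return data.frame with columns `aa`, `C`, `H`, `N`, `O`, `P`, `charge`,
#'   `mw` (g/mmol, free molecule).
#' @export
aa_table <- function() {
  tab <- data.frame(
    aa = c("gly", "ala", "ser", "asp", "glu", "arg"),
    C = c(2, 3, 3, 4, 5, 6),
    H = c(5, 7, 7, 6, 8, 15),
    N = c(1, 1, 1, 1, 1, 4),
    O = c(2, 2, 3, 4, 4, 2),
    P = c(0, 0, 0, 0, 0, 0),
    charge = c(0, 0, 0, -1, -1, 1),
    stringsAsFactors = FALSE
  )
  tab$mw <- vapply(seq_len(nrow(tab)), function(i) {
    comp_mw(comp(tab$C[i], tab$H[i], tab$N[i], tab$O[i], tab$P[i]))
  }, numeric(1))
  tab
}

.WATER <- comp(H = 2, O = 1)

#' Composition and mass of a peptide chain
#'
#' @param counts named integer vector of residue counts per amino acid
#'   (names must appear in [aa_table()]).
#' @return list with `composition` (elemental vector), `charge`, `mw`
#'   (g/mmol) and `length` (residues).
#' @export
peptide_chain <- function(counts) {
  tab <- aa_table()
  stopifnot(all(names(counts) %in% tab$aa), all(counts >= 0))
  L <- sum(counts)
  total <- comp_zero()
  charge <- 0
  for (a in names(counts)) {
    row <- tab[tab$aa == a, ]
    total <- total + comp_scale(comp(row$C, row$H, row$N, row$O, row$P), counts[[a]])
    charge <- charge + row$charge * counts[[a]]
  }
  if (L > 0) total <- total - comp_scale(.WATER, L - 1)
  list(composition = total, charge = charge, mw = comp_mw(total), length = L)
}

# RNA chains are built from AMP residues (the toy model uses ATP as its
# generic NTP): each polymerized residue is NTP minus pyrophosphate.
rna_chain <- function(length, ntp_comp, ntp_charge, ppi_comp, ppi_charge) {
  list(
    composition = comp_scale(ntp_comp - ppi_comp, length),
    charge = (ntp_charge - ppi_charge) * length,
    length = length
  )
}

#' Check elemental and charge balance of reactions
#'
#' Exchange and biomass reactions exempt themselves (they intentionally
#' create or destroy matter at the system boundary).
#'
#' @param model a stoichiometric model (see [sm_model()]).
#' @param elements elements to check; defaults to all tracked elements plus
#'   charge.
#' @param tol absolute imbalance tolerated (compositions are integer-valued,
#'   so the default is tight).
#' @return data.frame of violations (zero rows when balanced).
#' @export
check_balance <- function(model, elements = c(PC_ELEMENTS, "charge"),
                          tol = 1e-6) {
  exempt <- model$rxns$kind %in% c("exchange", "biomass")
  em <- cbind(model$comp, charge = model$mets$charge)
  imbalance <- t(em[, elements, drop = FALSE]) %*% model$S
  viol <- which(abs(imbalance) > tol & !exempt[col(imbalance)], arr.ind = TRUE)
  data.frame(
    reaction = colnames(model$S)[viol[, 2]],
    element = elements[viol[, 1]],
    imbalance = imbalance[viol],
    stringsAsFactors = FALSE
  )
}
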