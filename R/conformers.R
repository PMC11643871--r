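# Rotamer / atropisomer descriptors: Z/E assignment about the N-C(=X) bonds,
# M/P helicity about the N-C(aryl) axis, conformer enumeration, relative
# energies and Boltzmann population weights.

wrap180 <- function(tau) {
  t <- ((tau + 180) %% 360) - 180
  ifelse(t <= -180, t + 360, t)
}

#' Assign a Z/E rotamer descriptor from a torsion
#'
#' Classifies the X=C-N-C(substituent) torsion of an amide-like (thio)urea
#' bond: under the default convention the synperiplanar range (|tau| <= 90
#' degrees) is `Z` and the antiperiplanar range `E`, with |tau| = 90 assigned
#' to `Z` as the documented tie-break.  Because Z/E cartoons in the
#' literature are pictorial rather than algebraic, `convention = "trans_Z"`
#' provides the mirrored definition.
#'
#' @param tau torsion angle(s) in degrees.
#' @param convention `"cis_Z"` (default) or `"trans_Z"`.
#' @return Character vector of `"Z"` / `"E"`.
#' @export
#' @examples
#' assign_ze(c(0, 180, -60))
assign_ze <- function(tau, convention = c("cis_Z", "trans_Z")) {
  convention <- match.arg(convention)
  z <- abs(wrap180(tau)) <= 90
  if (convention == "trans_Z") z <- !z
  ifelse(z, "Z", "E")
}

#' Assign M/P helicity from the aryl torsion
#'
#' Standard helicity convention for the C(X)-N-C(ipso)-C(ortho) torsion of an
#' ortho-restricted N-aryl (thio)urea: positive torsion is `P`, negative `M`.
#' The reference ortho branch is the higher-CIP-priority substituent (e.g. Cl
#' over CH3).  A planar arrangement (tau of 0 or 180 degrees) has no helical
#' axis and raises an error.
#'
#' @param tau_aryl torsion angle(s) in degrees.
#' @param planar_tol angular tolerance for the planar (achiral) case.
#' @return Character vector of `"M"` / `"P"`.
#' @export
#' @examples
#' assign_helicity(c(40, -40))
assign_helicity <- function(tau_aryl, planar_tol = 1e-6) {
  t <- wrap180(tau_aryl)
  if (any(abs(t) < planar_tol | abs(abs(t) - 180) < planar_tol))
    stop("planar aryl torsion: no helicity defined")
  ifelse(t > 0, "P", "M")
}

#' Enumerate the conformer labels of an N-aryl (thio)urea
#'
#' With an antiperiplanar NH/H-2 arrangement fixed by the observed large
#' couplings, each of the two N-C(=X) bonds contributes a Z/E choice, giving
#' four conformers; ortho-disubstitution of the aryl ring adds an M/P
#' atropisomer axis that doubles the count to eight.
#'
#' @param ortho_restricted logical; does the aryl ring carry rotation-blocking
#'   ortho substituents?
#' @param exclude character vector of labels to drop (e.g. `"EE"` when only
#'   the experimentally relevant conformers are tabulated).
#' @return Data frame with columns `ze1` (sugar-side bond), `ze2` (aryl-side
#'   bond), `helicity` (`NA` when unrestricted) and `label`, in deterministic
#'   order.
#' @export
#' @examples
#' enumerate_conformers(FALSE)$label
#' enumerate_conformers(TRUE)$label
enumerate_conformers <- function(ortho_restricted = FALSE, exclude = NULL) {
  ze <- expand.grid(ze2 = c("Z", "E"), ze1 = c("Z", "E"),
                    stringsAsFactors = FALSE)[, c("ze1", "ze2")]
  if (ortho_restricted) {
    out <- merge(ze, data.frame(helicity = c("P", "M")), sort = FALSE)
    out <- out[order(match(out$ze1, c("Z", "E")),
                     match(out$ze2, c("Z", "E")),
                     match(out$helicity, c("P", "M"))), ]
    out$label <- paste0(out$ze1, out$ze2, out$helicity)
  } else {
    out <- ze
    out$helicity <- NA_character_
    out$label <- paste0(out$ze1, out$ze2)
  }
  rownames(out) <- NULL
  if (!is.null(exclude)) out <- out[!out$label %in% exclude, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a conformer ensemble with relative energies
#'
#' Converts raw electronic energies to kcal/mol relative to the most stable
#' member (hartree inputs are scaled by 627.5095 kcal/mol per hartree) and
#' attaches a temperature for population analysis.
#'
#' @param label character vector of conformer labels (unique).
#' @param energy numeric energies.
#' @param unit `"kcal/mol"` or `"hartree"`.
#' @param temperature temperature in K.
#' @return An object of class `conformer_ensemble`: list with a data frame
#'   `members` (`label`, `energy` in kcal/mol, minimum at 0) and
#'   `temperature`.
#' @export
#' @examples
#' relative_energies(c("ZZ", "ZE"), c(-1000.0000, -1000.0016), "hartree")
relative_energies <- function(label, energy,
                              unit = c("kcal/mol", "hartree"),
                              temperature = 298.15) {
  unit <- match.arg(unit)
  stopifnot(length(label) == length(energy), length(energy) >= 1)
  if (anyDuplicated(label)) stop("conformer labels must be unique")
  e <- if (unit == "hartree") energy * .hartree_kcal else energy
  e <- e - min(e)
  structure(list(members = data.frame(label = as.character(label), energy = e,
                                      stringsAsFactors = FALSE),
                 temperature = temperature),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", nrow(x$members), " member(s) at ",
      x$temperature, " K\n", sep = "")
  df <- x$members
  df$population <- boltzmann_populations(x)
  print(df)
  invisible(x)
}

#' Boltzmann population fractions of a conformer ensemble
#'
#' p_i proportional to exp(-E_i / RT) with R = 1.987e-3 kcal/(mol K);
#' fractions sum to 1.
#'
#' @param ensemble a [relative_energies()] ensemble.
#' @param temperature optional temperature override in K.
#' @return Named numeric vector of fractions.
#' @export
#' @examples
#' e <- relative_energies(c("ZZ", "ZE"), c(0, 1.0))
#' boltzmann_populations(e)
boltzmann_populations <- function(ensemble, temperature = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  T <- if (is.null(temperature)) ensemble$temperature else temperature
  if (T <= 0) stop("temperature must be positive")
  w <- exp(-(ensemble$members$energy - min(ensemble$members$energy)) /
             (.R_kcal * T))
  p <- w / sum(w)
  names(p) <- ensemble$members$label
  p
}
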