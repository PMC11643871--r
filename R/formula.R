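# Molecular-formula parsing and mass arithmetic: elemental analysis,
# monoisotopic/adduct masses, and coarse isotope patterns for Cl/S/Br.

#' Construct a molecular formula
#'
#' @param counts named non-negative integer vector, element symbol -> count.
#'   Zero counts are dropped.
#' @param charge integer charge of the species (0 for neutral).
#' @return An object of class `molecular_formula`.
#' @seealso [parse_formula()]
#' @export
molecular_formula <- function(counts, charge = 0L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named vector of element counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  counts <- counts[counts != 0]
  if (length(counts) == 0L || sum(counts) < 1)
    stop("a molecular formula must contain at least one atom")
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.molecular_formula <- function(x, ...) {
  body <- paste0(names(x$counts),
                 ifelse(x$counts == 1, "", x$counts), collapse = "")
  chg <- if (x$charge == 0) "" else
    sprintf(" (%+d)", x$charge)
  paste0(body, chg)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formula strings such as `"C19H23N5O8"`.  Embedded
#' whitespace and middle dots are tolerated (formula listings sometimes carry
#' stray spaces, e.g. `"C13H16N4 O7S"`); parenthesised groups are not
#' supported.  An omitted count means 1; repeated element symbols accumulate.
#'
#' @param text formula string.
#' @param charge integer charge to attach to the parsed species.
#' @return A [molecular_formula()].
#' @export
#' @examples
#' parse_formula("C19H23N5O8")
#' parse_formula("C14H18O5N5ClNa")
parse_formula <- function(text, charge = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[[:space:]\u00b7\u22c5]", "", text)  # whitespace, middle dots
  if (!nzchar(clean)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean, perl = TRUE)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(clean))
    stop("cannot parse formula string: ", text)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.atomic_weights))
      stop("unknown element symbol in formula: '", sym, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  molecular_formula(counts, charge = charge)
}

as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) f else parse_formula(f)
}

#' Elemental analysis (mass-percent composition)
#'
#' Computes the theoretical mass percent of each element from IUPAC
#' conventional atomic weights, the arithmetic behind every
#' "Anal. Calculated" line of a synthesis report.
#'
#' @param f a [molecular_formula()] or a formula string.
#' @return Named numeric vector of mass percentages (full precision; use
#'   [round_half_up()] with `digits = 2` for report formatting).  Percentages
#'   sum to 100.
#' @export
#' @examples
#' round_half_up(elemental_analysis("C19H23N5O8"), 2)
elemental_analysis <- function(f) {
  f <- as_formula(f)
  w <- .atomic_weights[names(f$counts)] * f$counts
  100 * w / sum(w)
}

#' Monoisotopic mass
#'
#' Sum of principal-isotope masses; for an ion of charge +n (or -n), n
#' electron masses are subtracted (added).
#'
#' @param f a [molecular_formula()] or a formula string.
#' @param charge optional charge override; defaults to the formula's own.
#' @return Mass in Da (m/z for singly charged ions).
#' @export
#' @examples
#' monoisotopic_mass("H2O")                        # 18.01056
#' monoisotopic_mass("C13H17O5N5Na", charge = 1)   # 346.1122
monoisotopic_mass <- function(f, charge = NULL) {
  f <- as_formula(f)
  if (!is.null(charge)) f$charge <- as.integer(charge)
  miss <- setdiff(names(f$counts), names(.monoisotopic_masses))
  if (length(miss))
    stop("no principal-isotope mass tabulated for: ",
         paste(miss, collapse = ", "))
  sum(.monoisotopic_masses[names(f$counts)] * f$counts) -
    f$charge * .m_electron
}

.adducts <- list(
  "[M+H]+"  = list(add = c(H = 1L),  charge = 1L),
  "[M+Na]+" = list(add = c(Na = 1L), charge = 1L)
)

add_counts <- function(a, b) {
  for (el in names(b)) {
    a[el] <- (if (el %in% names(a)) a[[el]] else 0L) + b[[el]]
  }
  a
}

#' m/z of a simple adduct ion
#'
#' Monoisotopic m/z of `[M+H]+` or `[M+Na]+` for a neutral formula: the
#' monoisotopic mass of the formula plus H or Na, minus one electron mass.
#'
#' @param f neutral [molecular_formula()] or formula string.
#' @param adduct one of `"[M+H]+"`, `"[M+Na]+"`.
#' @return m/z in Da.
#' @export
#' @examples
#' adduct_mz("C14H18O5N5Cl", "[M+Na]+")   # 394.0889
adduct_mz <- function(f, adduct = c("[M+H]+", "[M+Na]+")) {
  adduct <- match.arg(adduct)
  f <- as_formula(f)
  spec <- .adducts[[adduct]]
  ion <- molecular_formula(add_counts(f$counts, spec$add),
                           charge = f$charge + spec$charge)
  monoisotopic_mass(ion)
}

#' Coarse isotope pattern of a formula or adduct ion
#'
#' Expands the isotopologue distribution over the polyisotopic heavy elements
#' Cl, S and Br (monoisotopic treatment of C, H, N, O, F, Na: their minor
#' isotopes are ignored, which is the level of detail needed to reproduce a
#' qualitative 35Cl/37Cl "3:1" pattern).  Intensities are reported relative to
#' the base peak; peaks below `min_intensity` are dropped.
#'
#' @param f neutral [molecular_formula()] or formula string.
#' @param adduct optional adduct (see [adduct_mz()]); `NULL` for the neutral
#'   species.
#' @param min_intensity relative-intensity floor (fraction of base peak).
#' @return An object of class `isotope_pattern`: a data frame with columns
#'   `mz` (Da, increasing) and `intensity` (base peak = 1).
#' @export
#' @examples
#' isotope_pattern("C14H18O5N5Cl", adduct = "[M+Na]+")
isotope_pattern <- function(f, adduct = NULL, min_intensity = 0.01) {
  f <- as_formula(f)
  if (!is.null(adduct)) {
    spec <- .adducts[[match.arg(adduct, names(.adducts))]]
    f <- molecular_formula(add_counts(f$counts, spec$add),
                           charge = f$charge + spec$charge)
  }
  poly <- intersect(names(f$counts), names(.isotope_tables))
  n_poly <- sum(f$counts[poly])
  if (n_poly > 3)
    stop("combinatorial expansion supports at most 3 polyisotopic heavy ",
         "atoms (Cl, S, Br); formula has ", n_poly)
  base_mass <- monoisotopic_mass(f)
  # distribution over mass shifts relative to the all-principal isotopologue
  dist <- data.frame(shift = 0, p = 1)
  for (el in poly) {
    tab <- .isotope_tables[[el]]
    shifts <- tab$mass - tab$mass[1]
    one <- data.frame(shift = shifts, p = tab$abundance / sum(tab$abundance))
    for (i in seq_len(f$counts[[el]])) {
      dist <- do.call(rbind, lapply(seq_len(nrow(one)), function(j) {
        data.frame(shift = dist$shift + one$shift[j], p = dist$p * one$p[j])
      }))
      key <- round(dist$shift, 5)
      dist <- data.frame(shift = tapply(dist$shift * dist$p, key, sum) /
                           tapply(dist$p, key, sum),
                         p = as.numeric(tapply(dist$p, key, sum)))
    }
  }
  dist$intensity <- dist$p / max(dist$p)
  dist <- dist[dist$intensity >= min_intensity, , drop = FALSE]
  out <- data.frame(mz = base_mass + dist$shift, intensity = dist$intensity)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"))
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", nrow(x), " peak(s)\n", sep = "")
  print(data.frame(mz = round_half_up(x$mz, 4),
                   intensity = round(x$intensity, 4)))
  invisible(x)
}
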