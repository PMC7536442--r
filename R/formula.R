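# Supported elements with nominal (integer) and monoisotopic masses.
# Monoisotopic values: CODATA/IUPAC 2021 atomic masses of the principal
# isotopes (12C, 1H, 14N, 16O, 31P, 32S).
.ELEMENTS <- data.frame(
  element = c("C", "H", "N", "O", "P", "S"),
  nominal = c(12L, 1L, 14L, 16L, 31L, 32L),
  monoisotopic = c(12.0, 1.00782503207, 14.0030740048,
                   15.9949146196, 30.97376163, 31.97207100),
  stringsAsFactors = FALSE
)

.PROTON_MASS <- 1.007276466879   # mass of H minus the electron
.ELECTRON_MASS <- 0.000548579909

#' Parse a molecular formula string
#'
#' Parses a Hill-style molecular formula (e.g. `"C23H45NO4"`) into a named
#' vector of element counts. Only C, H, N, O, P and S are supported, which
#' covers the lipid and small-metabolite space this package annotates.
#'
#' @param formula A single formula string, or an already-parsed count vector
#'   (returned unchanged after validation).
#' @return A named integer vector of element counts with class
#'   `"molecular_formula"`.
#' @examples
#' parse_formula("C23H45NO4")   # palmitoylcarnitine
#' parse_formula("C3H9N")       # trimethylamine
#' @export
parse_formula <- function(formula) {
  if (inherits(formula, "molecular_formula")) return(formula)
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  s <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: '", formula, "'")
  }
  counts <- stats::setNames(integer(nrow(.ELEMENTS)), .ELEMENTS$element)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .ELEMENTS$element) {
      stop("unsupported element '", el, "' in formula '", formula, "'")
    }
    counts[el] <- counts[el] + n
  }
  if (sum(counts) < 1L) stop("formula must contain at least one atom")
  structure(counts, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  nz <- x[x > 0]
  cat(paste0(names(nz), ifelse(nz > 1, nz, "")), sep = "")
  cat("\n")
  invisible(x)
}

#' Neutral (uncharged) mass of a molecular formula
#'
#' @param formula Formula string or parsed `molecular_formula`.
#' @param scale `"nominal"` for integer element masses (C=12, H=1, N=14,
#'   O=16, P=31, S=32) or `"monoisotopic"` for principal-isotope masses.
#' @return The neutral molecular mass (Da).
#' @export
formula_mass <- function(formula, scale = c("monoisotopic", "nominal")) {
  scale <- match.arg(scale)
  counts <- parse_formula(formula)
  masses <- if (scale == "nominal") .ELEMENTS$nominal else .ELEMENTS$monoisotopic
  sum(as.numeric(counts) * masses)
}

#' Subtract one formula from another
#'
#' Element-wise subtraction, used to express a neutral loss as a formula
#' difference (e.g. stearoylcarnitine minus trimethylamine).
#'
#' @param a,b Formula strings or parsed formulas; every count of `b` must
#'   not exceed the matching count of `a`.
#' @return A `molecular_formula`.
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  d <- unclass(a) - unclass(b)
  if (any(d < 0L)) stop("formula subtraction would give negative counts")
  if (sum(d) < 1L) stop("formula subtraction leaves no atoms")
  structure(d, class = "molecular_formula")
}

# adduct table: charge sign and the neutral/charged-species arithmetic.
# delta_nominal uses integer masses with the electron ignored;
# delta_mono includes the electron mass.
.ADDUCTS <- list(
  "[M+H]+"  = list(polarity = "positive", delta_nominal = 1L,
                   delta_mono = 1.00782503207 - .ELECTRON_MASS),
  "[M-H]-"  = list(polarity = "negative", delta_nominal = -1L,
                   delta_mono = -(1.00782503207 - .ELECTRON_MASS)),
  "[M+Na]+" = list(polarity = "positive", delta_nominal = 23L,
                   delta_mono = 22.9897692809 - .ELECTRON_MASS),
  "[M+K]+"  = list(polarity = "positive", delta_nominal = 39L,
                   delta_mono = 38.96370668 - .ELECTRON_MASS),
  "[M+Cl]-" = list(polarity = "negative", delta_nominal = 35L,
                   delta_mono = 34.96885268 + .ELECTRON_MASS)
)

#' Supported adducts
#'
#' @return Character vector of the adduct labels `theoretical_mz()` accepts.
#' @export
supported_adducts <- function() names(.ADDUCTS)

.normalize_adduct <- function(adduct) {
  # tolerate the typographic minus sign
  a <- gsub("−", "-", adduct)
  if (!a %in% names(.ADDUCTS)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  a
}

#' Theoretical m/z of an adduct ion
#'
#' Computes the m/z of a singly charged adduct of a molecular formula at
#' either nominal (integer-mass) or monoisotopic scale. At nominal scale
#' the electron mass is ignored (masses stay integer); at monoisotopic
#' scale the electron mass is included in the adduct arithmetic.
#'
#' @param formula Formula string or parsed `molecular_formula`.
#' @param adduct One of `supported_adducts()`, e.g. `"[M+H]+"`, `"[M-H]-"`.
#' @param scale `"nominal"` or `"monoisotopic"`.
#' @return The theoretical m/z.
#' @examples
#' theoretical_mz("C23H45NO4", "[M+H]+", "nominal")       # 400
#' theoretical_mz("C47H83O13P", "[M-H]-", "nominal")      # 885
#' theoretical_mz("C23H45NO4", "[M+H]+", "monoisotopic")  # 400.3421
#' @export
theoretical_mz <- function(formula, adduct,
                           scale = c("monoisotopic", "nominal")) {
  scale <- match.arg(scale)
  adduct <- .normalize_adduct(adduct)
  m <- formula_mass(formula, scale)
  d <- .ADDUCTS[[adduct]]
  if (scale == "nominal") m + d$delta_nominal else m + d$delta_mono
}

#' Polarity of an adduct
#' @param adduct Adduct label.
#' @return `"positive"` or `"negative"`.
#' @export
adduct_polarity <- function(adduct) .ADDUCTS[[.normalize_adduct(adduct)]]$polarity

#' Fragment m/z after a neutral loss
#'
#' Subtracts the mass of a lost neutral moiety from a (singly charged)
#' parent ion m/z, e.g. the loss of trimethylamine (C3H9N, 59 Da nominal)
#' from the protonated acylcarnitine at m/z 428 gives the fragment at 369.
#'
#' @param parent_mz Parent ion m/z.
#' @param loss Formula of the lost neutral (string or `molecular_formula`).
#' @param scale `"nominal"` or `"monoisotopic"`.
#' @return Fragment m/z.
#' @examples
#' neutral_loss_mz(428, "C3H9N", "nominal")  # 369
#' @export
neutral_loss_mz <- function(parent_mz, loss,
                            scale = c("monoisotopic", "nominal")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(parent_mz), length(parent_mz) == 1L)
  lm <- formula_mass(loss, scale)
  if (lm >= parent_mz) stop("neutral loss mass (", lm,
                            ") must be smaller than the parent m/z")
  parent_mz - lm
}
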